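# Report rendering: the written chronological report and the graphic
# timeline scheme.  Output is deterministic: chronology lines are ordered by
# behavior onset, ties by event order then label; possibly-postictal
# behaviors are segregated under their own heading; fired alert criteria are
# appended with their evidence times.

.fmt_body_parts <- function(bps) {
  if (!length(bps)) return("")
  paste0(" [", paste(vapply(bps, function(bp) {
    paste(bp$side, bp$part)
  }, ""), collapse = "; "), "]")
}

.fmt_qualifiers <- function(q) {
  if (!length(q)) return("")
  paste0(" {", paste(vapply(names(q), function(nm) {
    v <- q[[nm]]
    sprintf("%s=%s", nm, if (is.logical(v)) tolower(as.character(v)) else v)
  }, ""), collapse = ", "), "}")
}

.chronology_line <- function(row) {
  sprintf("t=%d–%ds %s: %s%s%s%s",
          row$start_s, row$end_s, row$event_type, row$label,
          .fmt_body_parts(row$body_parts[[1L]]),
          .fmt_qualifiers(row$qualifiers[[1L]]),
          if (nzchar(row$note)) paste0(" — ", row$note) else "")
}

#' Render the written chronological report
#'
#' Produces the plain-text episode report: a header with the episode id,
#' duration, and flags; one chronology line per ictal behavior in onset
#' order; a "possibly postictal" section; free-text comments; and, when
#' alerts are supplied, a section listing every fired criterion with its
#' evidence times.
#'
#' @param episode a validated [ds_episode()].
#' @param alerts optional named list of `ds_alert`s as returned by
#'   [run_all_rules()].
#' @return a single character string (class `ds_report`), printable as-is.
#' @export
render_text <- function(episode, alerts = NULL) {
  beh <- episode_behaviors(episode)
  flags_on <- names(Filter(isTRUE, episode$flags))
  lines <- c(
    sprintf("Episode %s (duration %d s)", episode$id, episode$duration_s),
    sprintf("Flags: %s",
            if (length(flags_on)) paste(flags_on, collapse = ", ") else "none"),
    ""
  )
  ictal <- beh[!beh$postictal, , drop = FALSE]
  post <- beh[beh$postictal, , drop = FALSE]
  lines <- c(lines, "Chronology:")
  if (nrow(ictal)) {
    for (k in seq_len(nrow(ictal))) {
      lines <- c(lines, paste0("  ", .chronology_line(ictal[k, ])))
    }
  } else {
    lines <- c(lines, "  (no ictal behaviors annotated)")
  }
  if (nrow(post)) {
    lines <- c(lines, "", "Possibly postictal:")
    for (k in seq_len(nrow(post))) {
      lines <- c(lines, paste0("  ", .chronology_line(post[k, ])))
    }
  }
  if (nzchar(trimws(episode$comments))) {
    lines <- c(lines, "", "Comments:", paste0("  ", episode$comments))
  }
  if (!is.null(alerts)) {
    lines <- c(lines, "", "Semiologic extrapolation alerts:")
    for (al in alerts) {
      lines <- c(lines, sprintf("  %s: %s", al$fn, al$status))
      for (cr in al$criteria) {
        if (!cr$fired) next
        lines <- c(lines, sprintf("    - %s", cr$description))
        for (k in seq_len(nrow(cr$evidence))) {
          e <- cr$evidence[k, ]
          lines <- c(lines, sprintf("        %s [%d–%ds] %s", e$kind,
                                    e$start_s, e$end_s, e$description))
        }
      }
      neg <- Filter(function(cr) cr$fired, al$negative_features)
      if (length(neg)) {
        lines <- c(lines, "    features lowering probability:")
        for (cr in neg) {
          lines <- c(lines, sprintf("      - %s", cr$description))
        }
      }
    }
  }
  structure(paste(lines, collapse = "\n"), class = "ds_report")
}

#' @export
print.ds_report <- function(x, ...) {
  cat(unclass(x), "\n", sep = "")
  invisible(x)
}

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the graphic timeline scheme
#'
#' One horizontal lane per ictal event with spans proportional to intervals
#' and behaviors drawn as nested spans inside their event lane; a seconds
#' axis at the bottom. Layout is deterministic; overlapping events get
#' separate lanes and are both drawn in full; a 1-s behavior gets a
#' minimum-width visible span.
#'
#' @param episode a validated [ds_episode()].
#' @param format `"svg"` (vector graphic text) or `"ascii"` (terminal
#'   fallback).
#' @param width drawing width in pixels (svg) or characters (ascii).
#' @return a single character string with the rendered document.
#' @export
render_timeline <- function(episode, format = c("svg", "ascii"), width = 800) {
  format <- match.arg(format)
  if (format == "ascii") return(.timeline_ascii(episode, width))
  dur <- episode$duration_s
  margin_l <- 140; margin_r <- 20; margin_t <- 20
  lane_h <- 26; beh_h <- 10; axis_h <- 30
  plot_w <- width - margin_l - margin_r
  xpos <- function(t) margin_l + plot_w * t / dur
  n_lanes <- length(episode$events)
  height <- margin_t + max(n_lanes, 1L) * lane_h + axis_h
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif" font-size="11">',
    width, height))
  for (i in seq_along(episode$events)) {
    ev <- episode$events[[i]]
    y <- margin_t + (i - 1L) * lane_h
    x0 <- xpos(ev$start_s)
    w <- max(xpos(ev$end_s) - x0, 2)
    out <- c(out,
      sprintf('<text x="%d" y="%.1f" text-anchor="end">%s</text>',
              margin_l - 6L, y + 14, .svg_escape(ev$event_type)),
      sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%d" fill="#9ecae1" stroke="#3182bd"/>',
              x0, y + 2, w, lane_h - 8L))
    for (bh in ev$behaviors) {
      bx <- xpos(bh$start_s)
      bw <- max(xpos(bh$end_s) - bx, 2)
      out <- c(out,
        sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%d" fill="%s" stroke="#636363"><title>%s [%d,%d)s</title></rect>',
                bx, y + 2 + (lane_h - 8L - beh_h) / 2, bw, beh_h,
                if (bh$postictal) "#fdd0a2" else "#fd8d3c",
                .svg_escape(bh$label), bh$start_s, bh$end_s))
    }
  }
  ay <- margin_t + max(n_lanes, 1L) * lane_h + 12L
  out <- c(out,
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
            margin_l, ay, margin_l + plot_w, ay))
  step <- max(1L, as.integer(10^floor(log10(dur))))
  if (dur / step < 4) step <- max(1L, step %/% 2L)
  for (t in unique(c(seq(0L, dur, by = step), dur))) {
    out <- c(out,
      sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="black"/>',
              xpos(t), ay, xpos(t), ay + 4L),
      sprintf('<text x="%.1f" y="%d" text-anchor="middle">%ds</text>',
              xpos(t), ay + 16L, t))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

.timeline_ascii <- function(episode, width = 80) {
  dur <- episode$duration_s
  label_w <- 16L
  plot_w <- max(10L, width - label_w - 2L)
  col_of <- function(t) 1L + as.integer(floor((plot_w - 1L) * t / dur))
  lines <- character(0)
  for (ev in episode$events) {
    bar <- rep(" ", plot_w)
    bar[col_of(ev$start_s):max(col_of(ev$start_s),
                               col_of(ev$end_s) - 1L)] <- "="
    for (bh in ev$behaviors) {
      bar[col_of(bh$start_s):max(col_of(bh$start_s),
                                 col_of(bh$end_s) - 1L)] <- "#"
    }
    lines <- c(lines, sprintf("%-*s|%s|", label_w,
                              substr(ev$event_type, 1L, label_w),
                              paste(bar, collapse = "")))
  }
  axis <- rep("-", plot_w)
  lines <- c(lines, sprintf("%-*s+%s+", label_w, "", paste(axis, collapse = "")),
             sprintf("%-*s0%*ds", label_w, "", plot_w - 1L, dur))
  paste(lines, collapse = "\n")
}
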