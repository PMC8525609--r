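# Jacksonian march detection: spatio-temporal propagation of clonic
# movements across stations of one body side.  Stations are the face, the
# proximal/distal arm and leg segments, and the distal-extremity parts (hand,
# fingers, foot), so that "between face, arm and leg and/or different parts
# of distal extremities" is expressible.
#
# Pipeline: raw per-(side, station) clonic intervals -> exclusion of
# exactly-synchronous bilateral intervals -> per-station union merge ->
# enumeration of valid chains (>=2 distinct stations, strictly increasing
# onsets separated by >= the resolution, gap-free interval union between
# first and last onset, no step past a second at which same-side face and
# leg are simultaneously clonic) -> subsequence-maximal chains only.

.station_of <- c(
  face = "face",
  upper_limb_proximal = "arm_proximal", upper_limb_distal = "arm_distal",
  hand = "hand", fingers = "fingers",
  lower_limb_proximal = "leg_proximal", lower_limb_distal = "leg_distal",
  foot = "foot"
)
.leg_stations <- c("leg_proximal", "leg_distal", "foot")

#' Station identifiers used by march detection
#' @return character vector of the eight march stations.
#' @export
march_stations <- function() unname(.station_of)

# raw (side, station, start, end) rows from clonic behaviors
.clonic_raw <- function(episode) {
  beh <- episode_behaviors(episode)
  sel <- beh[beh$label == "clonic" & !beh$postictal, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(sel))) {
    row <- sel[k, ]
    for (bp in row$body_parts[[1L]]) {
      st <- .station_of[bp$part]
      if (is.na(st)) next
      sides <- switch(bp$side, left = "left", right = "right",
                      bilateral = c("left", "right"), character(0))
      for (s in sides) {
        rows[[length(rows) + 1L]] <- data.frame(
          side = s, station = unname(st),
          start_s = row$start_s, end_s = row$end_s, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(side = character(0), station = character(0),
               start_s = integer(0), end_s = integer(0))
}

# drop intervals exactly synchronous (equal start AND end) with any
# contralateral clonic interval
.exclude_synchronous <- function(raw) {
  if (!nrow(raw)) return(raw)
  keep <- vapply(seq_len(nrow(raw)), function(k) {
    opp <- raw[raw$side != raw$side[k], , drop = FALSE]
    !any(opp$start_s == raw$start_s[k] & opp$end_s == raw$end_s[k])
  }, FALSE)
  raw[keep, , drop = FALSE]
}

# union-merge intervals (matrix cols start, end), overlap or abutment
.merge_intervals <- function(starts, ends) {
  if (!length(starts)) return(cbind(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out <- list()
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] <= me) {
      me <- max(me, ends[k])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# candidate steps for one side: merged intervals per station
.side_steps <- function(raw_side) {
  steps <- list()
  for (st in unique(raw_side$station)) {
    rows <- raw_side[raw_side$station == st, , drop = FALSE]
    m <- .merge_intervals(rows$start_s, rows$end_s)
    for (k in seq_len(nrow(m))) {
      steps[[length(steps) + 1L]] <- list(station = st,
                                          start_s = m[k, "start"],
                                          end_s = m[k, "end"])
    }
  }
  if (length(steps)) {
    ord <- order(vapply(steps, `[[`, 0, "start_s"),
                 vapply(steps, `[[`, "", "station"))
    steps[ord]
  } else steps
}

# blocking intervals: same-side seconds at which face AND leg are clonic
.blocking_intervals <- function(steps) {
  face <- Filter(function(s) s$station == "face", steps)
  legs <- Filter(function(s) s$station %in% .leg_stations, steps)
  out <- list()
  for (f in face) for (l in legs) {
    bs <- max(f$start_s, l$start_s)
    be <- min(f$end_s, l$end_s)
    if (bs < be) out[[length(out) + 1L]] <- c(bs, be)
  }
  out
}

.chain_valid <- function(chain, blocking, min_sep) {
  if (length(chain) < 2L) return(FALSE)
  stations <- vapply(chain, `[[`, "", "station")
  if (anyDuplicated(stations)) return(FALSE)
  onsets <- vapply(chain, `[[`, 0, "start_s")
  if (any(diff(onsets) < min_sep)) return(FALSE)
  # gap-free union between first and last onset
  m <- .merge_intervals(vapply(chain, `[[`, 0, "start_s"),
                        vapply(chain, `[[`, 0, "end_s"))
  first <- onsets[1L]; last <- onsets[length(onsets)]
  covered <- any(m[, "start"] <= first & m[, "end"] >= last)
  if (!covered) return(FALSE)
  # no step past a face+leg simultaneity second reached by the chain
  for (b in blocking) {
    m0 <- max(b[1L], first)
    if (m0 < b[2L] && any(onsets > m0)) return(FALSE)
  }
  TRUE
}

#' Detect Jacksonian march sequences
#'
#' Finds, per body side, maximal chains of clonic-movement propagation
#' between the march stations (see [march_stations()]): at least two distinct
#' stations with strictly increasing onsets separated by at least
#' `march_min_onset_separation_s`, whose interval union leaves no second
#' uncovered between the first and last onset. A chain is not extended past
#' any second at which same-side face and leg stations are simultaneously
#' clonic. Station intervals exactly synchronous (equal start and end) with a
#' contralateral clonic interval are excluded; non-synchronous bilateral
#' activity is analyzed as independent per-side sequences. Only chains that
#' are not ordered sub-chains of another valid chain are returned,
#' onset-ordered.
#'
#' @inheritParams check_focality
#' @return list of `march_sequence` objects, each with `side` and a `steps`
#'   data.frame (`station`, `start_s`, `end_s`, onset = `start_s`).
#' @export
detect_jacksonian <- function(episode, config = rule_config()) {
  raw <- .exclude_synchronous(.clonic_raw(episode))
  min_sep <- config$march_min_onset_separation_s
  out <- list()
  for (side in c("left", "right")) {
    steps <- .side_steps(raw[raw$side == side, , drop = FALSE])
    n <- length(steps)
    if (n < 2L) next
    blocking <- .blocking_intervals(steps)
    # enumerate subsets (steps are onset-sorted; chain order = onset order)
    valid <- list()
    for (mask in seq_len(2^n - 1L)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
      if (length(idx) < 2L) next
      chain <- steps[idx]
      if (.chain_valid(chain, blocking, min_sep)) {
        valid[[length(valid) + 1L]] <- idx
      }
    }
    if (!length(valid)) next
    maximal <- Filter(function(idx) {
      !any(vapply(valid, function(other) {
        length(other) > length(idx) && all(idx %in% other)
      }, FALSE))
    }, valid)
    for (idx in maximal) {
      chain <- steps[idx]
      out[[length(out) + 1L]] <- structure(list(
        side = side,
        steps = data.frame(
          station = vapply(chain, `[[`, "", "station"),
          start_s = as.integer(vapply(chain, `[[`, 0, "start_s")),
          end_s = as.integer(vapply(chain, `[[`, 0, "end_s")),
          stringsAsFactors = FALSE)
      ), class = "march_sequence")
    }
  }
  if (length(out)) {
    ord <- order(vapply(out, function(s) s$steps$start_s[1L], 0L),
                 vapply(out, `[[`, "", "side"))
    out <- out[ord]
  }
  out
}

#' @export
print.march_sequence <- function(x, ...) {
  cat(sprintf("<march_sequence %s: %s>\n", x$side,
              paste(sprintf("%s@%ds", x$steps$station, x$steps$start_s),
                    collapse = " -> ")))
  invisible(x)
}
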