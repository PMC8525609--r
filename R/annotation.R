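# Annotation data model: episode -> events -> behaviors, all timed on an
# integer-second grid relative to clip start (second 0).  Intervals are
# half-open [start_s, end_s): second t is covered iff start_s <= t < end_s.
# Reading is lenient (structure only); validate_episode() is the strict gate.

DS_JSON_VERSION <- "1.0"

.check_interval <- function(start_s, end_s, what = "interval") {
  if (length(start_s) != 1L || length(end_s) != 1L ||
      is.na(start_s) || is.na(end_s) ||
      start_s != trunc(start_s) || end_s != trunc(end_s)) {
    stop(sprintf("%s: start_s and end_s must be single integers", what),
         call. = FALSE)
  }
  if (start_s < 0 || start_s >= end_s) {
    stop(sprintf("%s: need 0 <= start_s < end_s (got [%s, %s))",
                 what, start_s, end_s), call. = FALSE)
  }
  invisible(c(as.integer(start_s), as.integer(end_s)))
}

#' Reference to an involved body part
#' @param part body-part identifier (see [default_body_parts()]).
#' @param side laterality: left, right, bilateral, or axial.
#' @return a `body_part_ref` list.
#' @export
body_part_ref <- function(part, side) {
  structure(list(part = as.character(part), side = as.character(side)),
            class = "body_part_ref")
}

#' An annotated ictal behavior
#'
#' A single observed behavior within an event: its label, half-open
#' `[start_s, end_s)` interval in seconds from clip start, involved body
#' parts, qualifiers, a possibly-postictal flag, and a free-text note.
#'
#' @param event_type event-type identifier of the parent event.
#' @param label behavior label (vocabulary term, or free text under "other").
#' @param start_s,end_s integer seconds from episode onset, `start_s < end_s`.
#' @param body_parts list of [body_part_ref()] (possibly empty).
#' @param qualifiers named list, e.g. `forced = TRUE`,
#'   `fall_control = "fully_controlled"`, `position = "prone"`.
#' @param postictal logical: behavior seemed postictal rather than ictal.
#' @param note free text (mandatory for the free-text label `"other"`).
#' @return a `ds_behavior` list.
#' @export
ds_behavior <- function(event_type, label, start_s, end_s,
                        body_parts = list(), qualifiers = list(),
                        postictal = FALSE, note = "") {
  iv <- .check_interval(start_s, end_s, sprintf("behavior '%s'", label))
  structure(list(
    event_type = as.character(event_type),
    label = as.character(label),
    start_s = iv[1L], end_s = iv[2L],
    body_parts = lapply(body_parts, function(bp) {
      if (!inherits(bp, "body_part_ref")) bp <- body_part_ref(bp$part, bp$side)
      bp
    }),
    qualifiers = qualifiers,
    postictal = isTRUE(postictal),
    note = as.character(note)
  ), class = "ds_behavior")
}

#' An ictal event: a typed phase of the episode
#'
#' @param event_type one of the eleven event-type identifiers.
#' @param start_s,end_s integer seconds from episode onset, `start_s < end_s`.
#' @param behaviors list of [ds_behavior()] contained in the event timeframe.
#' @return a `ds_event` list.
#' @export
ds_event <- function(event_type, start_s, end_s, behaviors = list()) {
  iv <- .check_interval(start_s, end_s, sprintf("event '%s'", event_type))
  structure(list(
    event_type = as.character(event_type),
    start_s = iv[1L], end_s = iv[2L],
    behaviors = behaviors
  ), class = "ds_event")
}

#' Episode-level impression flags
#'
#' The four episode-level questions answered by the encoder. Only
#' `started_from_sleep` is consumed by a rule (SUDEP); the impression flags
#' are recorded for the report and never drive alerts.
#'
#' @param encoder_baseline_impression episode likely represents baseline
#'   behavior.
#' @param encoder_pnes_impression encoder's impression of a psychogenic
#'   non-epileptic seizure.
#' @param encoder_nonepileptic_nonpsychogenic_impression e.g. syncope.
#' @param started_from_sleep episode seems to have started from sleep.
#' @return named logical list of the four episode-level questions.
#' @export
ds_flags <- function(encoder_baseline_impression = FALSE,
                     encoder_pnes_impression = FALSE,
                     encoder_nonepileptic_nonpsychogenic_impression = FALSE,
                     started_from_sleep = FALSE) {
  list(
    encoder_baseline_impression = isTRUE(encoder_baseline_impression),
    encoder_pnes_impression = isTRUE(encoder_pnes_impression),
    encoder_nonepileptic_nonpsychogenic_impression =
      isTRUE(encoder_nonepileptic_nonpsychogenic_impression),
    started_from_sleep = isTRUE(started_from_sleep)
  )
}

#' An annotated ictal episode
#'
#' The top of the hierarchy: the whole recorded episode spanning
#' `[0, duration_s)`, its encoder-impression flags, its events, comments, and
#' an optional ground-truth label used only for evaluation (the rule engine
#' never reads it).
#'
#' @param id episode identifier string.
#' @param duration_s episode duration in whole seconds.
#' @param flags list as produced by [ds_flags()].
#' @param events list of [ds_event()]; event timeframes may overlap.
#' @param comments free text.
#' @param label optional ground-truth tag: focal, generalized, pnes, other, or
#'   unknown.
#' @return a `ds_episode` list.
#' @export
ds_episode <- function(id, duration_s, flags = ds_flags(), events = list(),
                       comments = "", label = NULL) {
  if (length(duration_s) != 1L || is.na(duration_s) ||
      duration_s != trunc(duration_s) || duration_s < 1) {
    stop("duration_s must be a positive whole number of seconds", call. = FALSE)
  }
  structure(list(
    id = as.character(id),
    duration_s = as.integer(duration_s),
    flags = utils::modifyList(ds_flags(), flags),
    events = events,
    comments = as.character(comments),
    label = if (is.null(label)) NULL else as.character(label)
  ), class = "ds_episode")
}

#' Structural and vocabulary validation of an episode
#'
#' Checks every invariant of the annotation model against a schema and
#' returns violations as data, never as errors: behavior containment within
#' the parent event timeframe, event containment within `[0, duration_s)`,
#' behavior/event type agreement, vocabulary membership of labels, body
#' parts, lateralities, and qualifier values, the side constraints of
#' hemibody/whole-body references, and the mandatory note on free-text
#' "other" behaviors. Overlapping event timeframes are explicitly permitted.
#'
#' @param episode a [ds_episode()].
#' @param schema a `semio_schema`; defaults to [default_schema()].
#' @return a data.frame with columns `where`, `rule`, `message`; zero rows
#'   when the episode is valid.
#' @export
validate_episode <- function(episode, schema = default_schema()) {
  stopifnot(inherits(episode, "ds_episode"))
  out <- list()
  bad <- function(where, rule, message) {
    out[[length(out) + 1L]] <<- data.frame(where = where, rule = rule,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  known_types <- event_types(schema)
  for (i in seq_along(episode$events)) {
    ev <- episode$events[[i]]
    ev_where <- sprintf("event[%d] (%s)", i, ev$event_type)
    if (!(ev$event_type %in% known_types)) {
      bad(ev_where, "event_type_vocabulary",
          sprintf("unknown event type '%s'", ev$event_type))
    }
    if (ev$start_s < 0 || ev$end_s > episode$duration_s) {
      bad(ev_where, "event_containment",
          sprintf("event [%d,%d) outside episode [0,%d)",
                  ev$start_s, ev$end_s, episode$duration_s))
    }
    for (j in seq_along(ev$behaviors)) {
      bh <- ev$behaviors[[j]]
      bh_where <- sprintf("event[%d].behavior[%d] (%s)", i, j, bh$label)
      if (!identical(bh$event_type, ev$event_type)) {
        bad(bh_where, "behavior_event_type",
            sprintf("behavior event_type '%s' differs from parent '%s'",
                    bh$event_type, ev$event_type))
      }
      if (bh$start_s < ev$start_s || bh$end_s > ev$end_s) {
        bad(bh_where, "behavior_containment",
            sprintf("behavior [%d,%d) outside event [%d,%d)",
                    bh$start_s, bh$end_s, ev$start_s, ev$end_s))
      }
      if (ev$event_type %in% known_types &&
          !validate_term(schema, ev$event_type, bh$label)) {
        bad(bh_where, "behavior_vocabulary",
            sprintf("label '%s' not in '%s' vocabulary", bh$label,
                    ev$event_type))
      }
      if (identical(bh$label, "other") && !nzchar(trimws(bh$note))) {
        bad(bh_where, "other_requires_note",
            "free-text 'other' behavior requires a note")
      }
      for (bp in bh$body_parts) {
        if (!(bp$part %in% schema$body_parts)) {
          bad(bh_where, "body_part_vocabulary",
              sprintf("unknown body part '%s'", bp$part))
        }
        if (!(bp$side %in% schema$lateralities)) {
          bad(bh_where, "laterality_vocabulary",
              sprintf("unknown laterality '%s'", bp$side))
        }
        if (identical(bp$part, "hemibody") && !(bp$side %in% c("left", "right"))) {
          bad(bh_where, "hemibody_side",
              "hemibody requires side left or right")
        }
        if (identical(bp$part, "whole_body") && !identical(bp$side, "bilateral")) {
          bad(bh_where, "whole_body_side",
              "whole_body requires side bilateral")
        }
      }
      for (qn in names(bh$qualifiers)) {
        vocab <- schema$qualifier_vocabularies[[qn]]
        if (is.null(vocab)) {
          bad(bh_where, "qualifier_vocabulary",
              sprintf("unknown qualifier '%s'", qn))
          next
        }
        qv <- bh$qualifiers[[qn]]
        qv_chr <- if (is.logical(qv)) tolower(as.character(qv)) else as.character(qv)
        if (!(qv_chr %in% vocab)) {
          bad(bh_where, "qualifier_value",
              sprintf("qualifier %s = '%s' not in {%s}", qn, qv_chr,
                      paste(vocab, collapse = ", ")))
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(where = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

# ---- DS-JSON serialization --------------------------------------------------

.behavior_to_doc <- function(bh) {
  list(label = bh$label, start_s = bh$start_s, end_s = bh$end_s,
       body_parts = lapply(bh$body_parts,
                           function(bp) list(part = bp$part, side = bp$side)),
       qualifiers = bh$qualifiers, postictal = bh$postictal, note = bh$note)
}

#' Write an episode to DS-JSON
#'
#' One episode per document. The serialization round-trips: for every valid
#' episode `e`, `read_episode(write_episode(e))` is structurally identical
#' to `e`.
#'
#' @param episode a [ds_episode()].
#' @param path file path; if `NULL` the JSON text is returned invisibly.
#' @return the DS-JSON text, invisibly.
#' @export
write_episode <- function(episode, path = NULL) {
  stopifnot(inherits(episode, "ds_episode"))
  doc <- list(
    ds_json_version = DS_JSON_VERSION,
    episode = list(
      id = episode$id,
      duration_s = episode$duration_s,
      flags = episode$flags,
      events = lapply(episode$events, function(ev) {
        list(event_type = ev$event_type, start_s = ev$start_s,
             end_s = ev$end_s,
             behaviors = lapply(ev$behaviors, .behavior_to_doc))
      }),
      comments = episode$comments,
      label = episode$label
    )
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) writeLines(txt, path)
  invisible(as.character(txt))
}

#' Read an episode from DS-JSON
#'
#' Lenient-load / strict-validate: structural requirements (well-formed JSON,
#' compatible `ds_json_version` major version, integer times with
#' `start_s < end_s`) are enforced here; vocabulary and containment problems
#' are left to [validate_episode()], so an episode with, say, an unknown
#' behavior label still loads and can be inspected.
#'
#' @param path path to a DS-JSON file, or a JSON string.
#' @return a `ds_episode`.
#' @export
read_episode <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ver <- doc$ds_json_version
  if (is.null(ver)) stop("not a DS-JSON document: ds_json_version missing",
                         call. = FALSE)
  major <- function(v) strsplit(as.character(v), ".", fixed = TRUE)[[1L]][1L]
  if (!identical(major(ver), major(DS_JSON_VERSION))) {
    stop(sprintf("DS-JSON major version mismatch: document %s, reader %s",
                 ver, DS_JSON_VERSION), call. = FALSE)
  }
  ep <- doc$episode
  events <- lapply(ep$events, function(ev) {
    behaviors <- lapply(ev$behaviors, function(bh) {
      quals <- bh$qualifiers
      if (is.null(quals) || length(quals) == 0L) quals <- list()
      ds_behavior(
        event_type = ev$event_type, label = bh$label,
        start_s = .as_int(bh$start_s, "behavior start_s"),
        end_s = .as_int(bh$end_s, "behavior end_s"),
        body_parts = lapply(bh$body_parts,
                            function(bp) body_part_ref(bp$part, bp$side)),
        qualifiers = quals,
        postictal = isTRUE(bh$postictal),
        note = if (is.null(bh$note)) "" else bh$note
      )
    })
    ds_event(ev$event_type, .as_int(ev$start_s, "event start_s"),
             .as_int(ev$end_s, "event end_s"), behaviors)
  })
  ds_episode(
    id = ep$id,
    duration_s = .as_int(ep$duration_s, "duration_s"),
    flags = if (is.null(ep$flags)) ds_flags() else lapply(ep$flags, isTRUE),
    events = events,
    comments = if (is.null(ep$comments)) "" else ep$comments,
    label = ep$label
  )
}

.as_int <- function(x, what) {
  if (is.null(x) || length(x) != 1L || is.na(suppressWarnings(as.numeric(x))) ||
      as.numeric(x) != trunc(as.numeric(x))) {
    stop(sprintf("%s must be an integer number of seconds", what),
         call. = FALSE)
  }
  as.integer(x)
}

# ---- queries ----------------------------------------------------------------

#' Flat table of all behaviors in an episode
#'
#' The rule-engine substrate: one row per behavior, in stable order
#' (ascending behavior onset, ties broken by event order then label).
#'
#' @param episode a [ds_episode()].
#' @return data.frame with columns `event_index`, `event_type`, `label`,
#'   `start_s`, `end_s`, `postictal`, and list-columns `body_parts`,
#'   `qualifiers`.
#' @export
episode_behaviors <- function(episode) {
  stopifnot(inherits(episode, "ds_episode"))
  rows <- list()
  for (i in seq_along(episode$events)) {
    ev <- episode$events[[i]]
    for (bh in ev$behaviors) {
      rows[[length(rows) + 1L]] <- list(
        event_index = i, event_type = ev$event_type, label = bh$label,
        start_s = bh$start_s, end_s = bh$end_s, postictal = bh$postictal,
        note = bh$note, body_parts = bh$body_parts, qualifiers = bh$qualifiers
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(event_index = integer(0), event_type = character(0),
                      label = character(0), start_s = integer(0),
                      end_s = integer(0), postictal = logical(0),
                      note = character(0)))
  }
  df <- data.frame(
    event_index = vapply(rows, `[[`, 0L, "event_index"),
    event_type = vapply(rows, `[[`, "", "event_type"),
    label = vapply(rows, `[[`, "", "label"),
    start_s = vapply(rows, `[[`, 0L, "start_s"),
    end_s = vapply(rows, `[[`, 0L, "end_s"),
    postictal = vapply(rows, `[[`, FALSE, "postictal"),
    note = vapply(rows, `[[`, "", "note"),
    stringsAsFactors = FALSE
  )
  df$body_parts <- lapply(rows, `[[`, "body_parts")
  df$qualifiers <- lapply(rows, `[[`, "qualifiers")
  ord <- order(df$start_s, df$event_index, df$label)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select behaviors by field values or an arbitrary predicate
#'
#' @param episode a [ds_episode()].
#' @param event_type,label optional filters (exact match, vectorized "any of").
#' @param postictal optional logical filter.
#' @param predicate optional `function(row)` receiving one row of
#'   [episode_behaviors()] as a list; keep rows where it returns `TRUE`.
#' @return the filtered [episode_behaviors()] data.frame, stable order.
#' @export
behaviors_matching <- function(episode, event_type = NULL, label = NULL,
                               postictal = NULL, predicate = NULL) {
  df <- episode_behaviors(episode)
  keep <- rep(TRUE, nrow(df))
  if (!is.null(event_type)) keep <- keep & df$event_type %in% event_type
  if (!is.null(label)) keep <- keep & df$label %in% label
  if (!is.null(postictal)) keep <- keep & df$postictal == postictal
  if (!is.null(predicate) && nrow(df)) {
    keep <- keep & vapply(seq_len(nrow(df)), function(k) {
      isTRUE(predicate(lapply(df, `[[`, k)))
    }, FALSE)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mirror every laterality in an episode (left <-> right)
#'
#' Utility for symmetry checks: swaps left and right on every body-part
#' reference; bilateral and axial are fixed points.
#'
#' @param episode a [ds_episode()].
#' @return the mirrored `ds_episode`.
#' @export
mirror_episode <- function(episode) {
  flip <- function(side) switch(side, left = "right", right = "left", side)
  episode$events <- lapply(episode$events, function(ev) {
    ev$behaviors <- lapply(ev$behaviors, function(bh) {
      bh$body_parts <- lapply(bh$body_parts, function(bp) {
        bp$side <- flip(bp$side)
        bp
      })
      bh
    })
    ev
  })
  episode
}

#' @export
print.ds_episode <- function(x, ...) {
  n_beh <- sum(vapply(x$events, function(ev) length(ev$behaviors), 0L))
  cat(sprintf("<ds_episode '%s': %ds, %d events, %d behaviors%s>\n",
              x$id, x$duration_s, length(x$events), n_beh,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' @export
print.ds_event <- function(x, ...) {
  cat(sprintf("<ds_event %s [%d,%d): %d behaviors>\n",
              x$event_type, x$start_s, x$end_s, length(x$behaviors)))
  invisible(x)
}
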