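# Semiologic extrapolation rules.  Each rule function consumes a validated
# episode and emits an alert that is either "positive" (>=1 criterion fired,
# with evidence) or "inconclusive" -- never "negative": absence of a feature
# in a video annotation is not evidence of its absence in the seizure.
# The episode's ground-truth label and the encoder-impression flags are never
# consulted (started_from_sleep is the one flag a rule reads, for SUDEP).

#' Rule-engine configuration
#'
#' Thresholds and windows of the extrapolation rules, with the defaults the
#' rules are defined at: a 5-s onset-precedence lead for lateralized and
#' sequence criteria, a 5-min (300-s) strict duration threshold for the
#' psychogenic non-epileptic seizure (PNES) duration criterion, a minimum
#' eyes-closed coverage fraction of 0.5, a 10-s minimum vocalization length
#' (v2 PNES ruleset), a 30-s window after GTCS offset for "ended with"
#' checks, and the 1-s onset-separation resolution of march detection.
#'
#' @param precedence_lead_s inclusive "at least this many seconds before"
#'   onset-to-onset lead (s).
#' @param pnes_duration_s episode duration must strictly exceed this (s).
#' @param pnes_eyes_closed_min_fraction minimum fraction of the episode
#'   covered by eyes-closed annotation, in (0, 1].
#' @param pnes_vocalization_min_s minimum vocalization duration (s), v2 only.
#' @param sudep_end_window_s seconds after GTCS offset still counting as
#'   "ended with".
#' @param march_min_onset_separation_s minimum onset separation between
#'   consecutive march steps (s).
#' @param pnes_ruleset `"v1"` (the originally evaluated four criteria) or
#'   `"v2"` (adds the vocalization criterion and probability-lowering
#'   negative features).
#' @return a `rule_config` list.
#' @export
rule_config <- function(precedence_lead_s = 5L,
                        pnes_duration_s = 300L,
                        pnes_eyes_closed_min_fraction = 0.5,
                        pnes_vocalization_min_s = 10L,
                        sudep_end_window_s = 30L,
                        march_min_onset_separation_s = 1L,
                        pnes_ruleset = c("v1", "v2")) {
  pnes_ruleset <- match.arg(pnes_ruleset)
  stopifnot(precedence_lead_s > 0, pnes_duration_s > 0,
            pnes_vocalization_min_s > 0, sudep_end_window_s > 0,
            march_min_onset_separation_s > 0,
            pnes_eyes_closed_min_fraction > 0,
            pnes_eyes_closed_min_fraction <= 1)
  structure(list(
    precedence_lead_s = as.integer(precedence_lead_s),
    pnes_duration_s = as.integer(pnes_duration_s),
    pnes_eyes_closed_min_fraction = pnes_eyes_closed_min_fraction,
    pnes_vocalization_min_s = as.integer(pnes_vocalization_min_s),
    sudep_end_window_s = as.integer(sudep_end_window_s),
    march_min_onset_separation_s = as.integer(march_min_onset_separation_s),
    pnes_ruleset = pnes_ruleset
  ), class = "rule_config")
}

#' Onset-to-onset precedence with an inclusive lead
#'
#' `TRUE` iff the onset of `b` is at least `lead_s` seconds after the onset
#' of `a` ("at least 5 s before" compares onsets and is inclusive at exactly
#' the lead).
#'
#' @param a,b intervals: any list/vector with `start_s` and `end_s` elements,
#'   or a length-2 numeric `c(start, end)`.
#' @param lead_s nonnegative lead in seconds.
#' @return logical scalar.
#' @examples
#' precedes_by_at_least(c(0, 10), c(5, 12), 5)  # TRUE
#' precedes_by_at_least(c(0, 10), c(4, 12), 5)  # FALSE
#' @export
precedes_by_at_least <- function(a, b, lead_s) {
  .iv_start(b) - .iv_start(a) >= lead_s
}

.iv_start <- function(x) {
  if (is.list(x) && !is.null(x$start_s)) return(x$start_s)
  x[[1L]]
}
.iv_end <- function(x) {
  if (is.list(x) && !is.null(x$end_s)) return(x$end_s)
  x[[2L]]
}

# evidence rows: data.frame(kind, description, start_s, end_s)
.evidence <- function(kind = character(0), description = character(0),
                      start_s = integer(0), end_s = integer(0)) {
  data.frame(kind = kind, description = description,
             start_s = start_s, end_s = end_s, stringsAsFactors = FALSE)
}

.criterion <- function(id, description, fired, evidence = .evidence()) {
  if (fired && nrow(evidence) == 0L) {
    stop("internal: fired criterion must carry evidence")
  }
  if (!fired) evidence <- .evidence()
  list(criterion_id = id, description = description, fired = fired,
       evidence = evidence)
}

.new_alert <- function(fn, criteria, negative_features = list(),
                       sequences = NULL) {
  fired <- vapply(criteria, `[[`, FALSE, "fired")
  structure(list(
    fn = fn,
    status = if (any(fired)) "positive" else "inconclusive",
    criteria = criteria,
    negative_features = negative_features,
    sequences = sequences
  ), class = "ds_alert")
}

#' @export
print.ds_alert <- function(x, ...) {
  cat(sprintf("<ds_alert %s: %s>\n", x$fn, x$status))
  for (cr in x$criteria) {
    if (cr$fired) {
      cat(sprintf("  [*] %s: %s\n", cr$criterion_id, cr$description))
      for (k in seq_len(nrow(cr$evidence))) {
        e <- cr$evidence[k, ]
        cat(sprintf("        %s [%d,%d)s %s\n", e$kind, e$start_s, e$end_s,
                    e$description))
      }
    }
  }
  neg <- Filter(function(cr) cr$fired, x$negative_features)
  if (length(neg)) {
    cat("  features lowering probability:\n")
    for (cr in neg) cat(sprintf("  [-] %s: %s\n", cr$criterion_id,
                                cr$description))
  }
  invisible(x)
}

# unilateral tonic/clonic/dystonic (or paralysis) machinery ------------------

.limb_parts <- c("upper_limb_proximal", "upper_limb_distal", "hand", "fingers",
                 "lower_limb_proximal", "lower_limb_distal", "foot")
.lateralizable_parts <- c("face", .limb_parts, "hemibody")

# earliest onset per side (left/right) of behaviors with given labels;
# a bilateral or whole-body reference counts as involvement of both sides
.side_onsets <- function(beh, labels) {
  sel <- beh[beh$label %in% labels & !beh$postictal, , drop = FALSE]
  res <- list(left = list(any = Inf, unilateral = Inf),
              right = list(any = Inf, unilateral = Inf))
  for (k in seq_len(nrow(sel))) {
    row <- sel[k, ]
    for (bp in row$body_parts[[1L]]) {
      sides <- switch(bp$side,
                      left = "left", right = "right",
                      bilateral = c("left", "right"),
                      character(0))
      for (s in sides) {
        res[[s]]$any <- min(res[[s]]$any, row$start_s)
        if (bp$side %in% c("left", "right") &&
            bp$part %in% .lateralizable_parts) {
          if (row$start_s < res[[s]]$unilateral) {
            res[[s]]$unilateral <- row$start_s
            res[[s]]$uni_row <- row
            res[[s]]$uni_part <- bp$part
          }
        }
      }
    }
  }
  res
}

.lateralized_criterion <- function(id, what, labels, beh, lead_s) {
  so <- .side_onsets(beh, labels)
  ev <- .evidence()
  fired <- FALSE
  for (s in c("left", "right")) {
    opp <- if (s == "left") "right" else "left"
    uni <- so[[s]]$unilateral
    if (!is.finite(uni)) next
    contra <- so[[opp]]$any
    ok <- if (is.finite(contra)) (contra - uni) >= lead_s else TRUE
    if (ok) {
      fired <- TRUE
      row <- so[[s]]$uni_row
      desc <- sprintf("%s %s %s at %ds; contralateral involvement %s", s,
                      so[[s]]$uni_part, row$label, uni,
                      if (is.finite(contra)) sprintf("at %ds", contra)
                      else "absent (interpreted as focal)")
      ev <- rbind(ev, .evidence("behavior", desc, row$start_s, row$end_s))
    }
  }
  .criterion(id, what, fired, ev)
}

#' Focal-onset feature detection
#'
#' Evaluates the eight focality criteria on the episode's non-postictal
#' annotation: (1) figure-of-4 posturing; (2) fencer posturing; (3) forced
#' head turn; (4) forced gaze deviation; (5) a hyperkinetic event starting at
#' least `precedence_lead_s` s before a GTCS event; (6) an aura event
#' starting at least that lead before every non-aura, non-trigger event (at
#' least one such event must exist); (7) a unilateral tonic, clonic, or
#' dystonic movement of arm, leg, side of face, or hemibody preceding the
#' earliest contralateral involvement by at least the lead — or with no
#' contralateral involvement at all; (8) the same for paralysis.
#'
#' @param episode a validated [ds_episode()].
#' @param config a [rule_config()].
#' @return a `ds_alert` (status positive or inconclusive).
#' @export
check_focality <- function(episode, config = rule_config()) {
  beh <- episode_behaviors(episode)
  ictal <- beh[!beh$postictal, , drop = FALSE]
  lead <- config$precedence_lead_s

  present <- function(id, what, sel) {
    ev <- if (nrow(sel)) {
      .evidence("behavior",
                sprintf("%s (%s)", sel$label, sel$event_type),
                sel$start_s, sel$end_s)
    } else .evidence()
    .criterion(id, what, nrow(sel) > 0L, ev)
  }
  qual_true <- function(rows, qual) {
    if (!nrow(rows)) return(rows[0L, , drop = FALSE])
    keep <- vapply(rows$qualifiers, function(q) {
      isTRUE(q[[qual]]) || identical(q[[qual]], "true")
    }, FALSE)
    rows[keep, , drop = FALSE]
  }

  c1 <- present("focality.1", "Figure-of-4 posturing",
                ictal[ictal$label == "figure_of_4", , drop = FALSE])
  c2 <- present("focality.2", "Fencer posturing",
                ictal[ictal$label == "fencer_posturing", , drop = FALSE])
  c3 <- present("focality.3", "Forced head turn",
                qual_true(ictal[ictal$label == "head_turn", , drop = FALSE],
                          "forced"))
  c4 <- present("focality.4", "Forced gaze deviation",
                qual_true(ictal[ictal$label == "gaze_deviation", , drop = FALSE],
                          "forced"))

  ev_types <- vapply(episode$events, `[[`, "", "event_type")
  ev_starts <- vapply(episode$events, `[[`, 0L, "start_s")
  ev_ends <- vapply(episode$events, `[[`, 0L, "end_s")

  # (5) hyperkinetic event >= lead before some GTCS event (onsets)
  hk <- which(ev_types == "hyperkinetic")
  gt <- which(ev_types == "gtcs")
  c5_pairs <- .evidence()
  for (i in hk) for (j in gt) {
    if (ev_starts[j] - ev_starts[i] >= lead) {
      c5_pairs <- rbind(
        c5_pairs,
        .evidence("event", sprintf("hyperkinetic at %ds, GTCS at %ds",
                                   ev_starts[i], ev_starts[j]),
                  ev_starts[i], ev_ends[j]))
    }
  }
  c5 <- .criterion("focality.5",
                   sprintf("Hyperkinetic event at least %d s before GTCS onset",
                           lead),
                   nrow(c5_pairs) > 0L, c5_pairs)

  # (6) some aura event precedes every non-aura/non-trigger event by >= lead
  au <- which(ev_types == "aura")
  others <- which(!(ev_types %in% c("aura", "trigger")))
  c6_ev <- .evidence()
  c6_fired <- FALSE
  if (length(au) && length(others)) {
    for (i in au) {
      if (all(ev_starts[others] - ev_starts[i] >= lead)) {
        c6_fired <- TRUE
        c6_ev <- rbind(c6_ev, .evidence(
          "event",
          sprintf("aura at %ds precedes all other events (earliest at %ds)",
                  ev_starts[i], min(ev_starts[others])),
          ev_starts[i], ev_ends[i]))
      }
    }
  }
  c6 <- .criterion("focality.6",
                   sprintf("Aura event at least %d s before any non-aura, non-trigger event",
                           lead),
                   c6_fired, c6_ev)

  c7 <- .lateralized_criterion(
    "focality.7",
    sprintf("Unilateral tonic/clonic/dystonic movement at least %d s before contralateral involvement",
            lead),
    c("tonic", "clonic", "dystonic"), beh, lead)
  c8 <- .lateralized_criterion(
    "focality.8",
    sprintf("Unilateral paralysis at least %d s before contralateral paralysis",
            lead),
    "paralysis", beh, lead)

  .new_alert("focality", list(c1, c2, c3, c4, c5, c6, c7, c8))
}

# total seconds of [0, duration) covered by the union of intervals
.coverage_seconds <- function(starts, ends, duration) {
  if (!length(starts)) return(0L)
  starts <- pmax(starts, 0L)
  ends <- pmin(ends, duration)
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[1L]; cur_e <- ends[1L]
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] <= cur_e) {
      cur_e <- max(cur_e, ends[k])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[k]; cur_e <- ends[k]
    }
  }
  total + (cur_e - cur_s)
}

#' Psychogenic non-epileptic seizure (PNES) feature detection
#'
#' v1 criteria: (1) eyes-closed annotation covering at least
#' `pnes_eyes_closed_min_fraction` of the episode; (2) resisted eye opening;
#' (3) a fully controlled fall; (4) episode duration strictly greater than
#' `pnes_duration_s`. The v2 ruleset adds positive criterion (5): a
#' vocalization of at least `pnes_vocalization_min_s` seconds, excluding
#' ictal crying and ictal laughter; and three probability-lowering negative
#' features reported independently of the positive statement: onset from
#' sleep, ictal physical trauma, and urine loss.
#'
#' @inheritParams check_focality
#' @return a `ds_alert`; under v2 it additionally carries
#'   `negative_features`.
#' @export
check_pnes <- function(episode, config = rule_config()) {
  beh <- episode_behaviors(episode)
  ictal <- beh[!beh$postictal, , drop = FALSE]

  ec <- ictal[ictal$label == "eyes_closed", , drop = FALSE]
  cov <- .coverage_seconds(ec$start_s, ec$end_s, episode$duration_s)
  frac <- cov / episode$duration_s
  c1 <- .criterion(
    "pnes.1",
    sprintf("Eyes closed during the ictal episode (coverage %.2f >= %.2f)",
            frac, config$pnes_eyes_closed_min_fraction),
    frac >= config$pnes_eyes_closed_min_fraction && nrow(ec) > 0L,
    if (nrow(ec)) .evidence("behavior", rep("eyes_closed", nrow(ec)),
                            ec$start_s, ec$end_s) else .evidence())

  reo <- ictal[vapply(ictal$qualifiers, function(q) {
    isTRUE(q$resisted_eye_opening) ||
      identical(q$resisted_eye_opening, "true")
  }, FALSE), , drop = FALSE]
  c2 <- .criterion(
    "pnes.2", "Resisted attempt to open eyes by observer",
    nrow(reo) > 0L,
    if (nrow(reo)) .evidence("behavior", reo$label, reo$start_s, reo$end_s)
    else .evidence())

  falls <- ictal[ictal$label == "falling" &
                   vapply(ictal$qualifiers, function(q) {
                     identical(q$fall_control, "fully_controlled")
                   }, FALSE), , drop = FALSE]
  c3 <- .criterion(
    "pnes.3", "Fully controlled fall during the ictal episode",
    nrow(falls) > 0L,
    if (nrow(falls)) .evidence("behavior", "falling (fully controlled)",
                               falls$start_s, falls$end_s) else .evidence())

  c4 <- .criterion(
    "pnes.4",
    sprintf("Ictal episode longer than %d s (duration %d s)",
            config$pnes_duration_s, episode$duration_s),
    episode$duration_s > config$pnes_duration_s,
    if (episode$duration_s > config$pnes_duration_s) {
      .evidence("episode", sprintf("duration %d s", episode$duration_s),
                0L, episode$duration_s)
    } else .evidence())

  criteria <- list(c1, c2, c3, c4)
  negative <- list()

  if (identical(config$pnes_ruleset, "v2")) {
    voc <- ictal[ictal$event_type == "voice" &
                   !(ictal$label %in% c("crying", "laughter")) &
                   (ictal$end_s - ictal$start_s) >= config$pnes_vocalization_min_s,
                 , drop = FALSE]
    criteria <- c(criteria, list(.criterion(
      "pnes.5",
      sprintf("Vocalization lasting %d s or longer (excluding ictal cry or laughter)",
              config$pnes_vocalization_min_s),
      nrow(voc) > 0L,
      if (nrow(voc)) .evidence("behavior", voc$label, voc$start_s, voc$end_s)
      else .evidence())))

    trauma <- beh[beh$label == "physical_trauma", , drop = FALSE]
    urine <- beh[beh$label == "urine_loss", , drop = FALSE]
    negative <- list(
      .criterion("pnes.neg.1", "Episode started from sleep",
                 isTRUE(episode$flags$started_from_sleep),
                 if (isTRUE(episode$flags$started_from_sleep)) {
                   .evidence("episode", "started_from_sleep flag", 0L,
                             episode$duration_s)
                 } else .evidence()),
      .criterion("pnes.neg.2", "Ictal self-injury (physical trauma)",
                 nrow(trauma) > 0L,
                 if (nrow(trauma)) .evidence("behavior", "physical_trauma",
                                             trauma$start_s, trauma$end_s)
                 else .evidence()),
      .criterion("pnes.neg.3", "Urinary incontinence",
                 nrow(urine) > 0L,
                 if (nrow(urine)) .evidence("behavior", "urine_loss",
                                            urine$start_s, urine$end_s)
                 else .evidence())
    )
  }

  .new_alert("pnes", criteria, negative_features = negative)
}

#' SUDEP semiologic risk-factor detection
#'
#' Criterion 1 is the presence of a generalized tonic-clonic seizure (GTCS)
#' event; criteria 2-5 are evaluated only when it fires: (2) the episode
#' started from sleep; (3) apnea with onset within
#' `[gtcs_end - 5, gtcs_end + sudep_end_window_s]`; (4) the same for
#' cyanosis; (5) the position annotation in effect at GTCS offset (covering
#' it, or the latest one at/before it) is prone. Postictal-flagged behaviors
#' are eligible evidence for criteria 3-5, since these findings follow the
#' convulsion.
#'
#' @inheritParams check_focality
#' @return a `ds_alert`.
#' @export
check_sudep <- function(episode, config = rule_config()) {
  ev_types <- vapply(episode$events, `[[`, "", "event_type")
  gt <- which(ev_types == "gtcs")
  gt_starts <- vapply(episode$events[gt], `[[`, 0L, "start_s")
  gt_ends <- vapply(episode$events[gt], `[[`, 0L, "end_s")

  c1 <- .criterion(
    "sudep.1", "Presence of B/GTCS", length(gt) > 0L,
    if (length(gt)) .evidence("event", rep("GTCS", length(gt)),
                              gt_starts, gt_ends) else .evidence())
  if (!c1$fired) {
    return(.new_alert("sudep", list(
      c1,
      .criterion("sudep.2", "GTCS started from sleep", FALSE),
      .criterion("sudep.3", "GTCS ended with apnea", FALSE),
      .criterion("sudep.4", "GTCS ended with cyanosis", FALSE),
      .criterion("sudep.5", "GTCS ended in prone position", FALSE))))
  }

  beh <- episode_behaviors(episode)  # postictal eligible for 3-5
  w <- config$sudep_end_window_s

  c2 <- .criterion(
    "sudep.2", "GTCS started from sleep",
    isTRUE(episode$flags$started_from_sleep),
    if (isTRUE(episode$flags$started_from_sleep)) {
      .evidence("episode", "started_from_sleep flag", 0L, episode$duration_s)
    } else .evidence())

  ended_with <- function(id, what, label) {
    rows <- beh[beh$label == label, , drop = FALSE]
    ev <- .evidence()
    for (k in seq_len(nrow(rows))) {
      onset <- rows$start_s[k]
      hit <- any(onset >= gt_ends - 5L & onset <= gt_ends + w)
      if (hit) {
        ev <- rbind(ev, .evidence("behavior",
                                  sprintf("%s at %ds (GTCS offset %s)", label,
                                          onset,
                                          paste(gt_ends, collapse = ",")),
                                  rows$start_s[k], rows$end_s[k]))
      }
    }
    .criterion(id, what, nrow(ev) > 0L, ev)
  }
  c3 <- ended_with("sudep.3", "GTCS ended with apnea", "apnea")
  c4 <- ended_with("sudep.4", "GTCS ended with cyanosis", "cyanosis")

  # position in effect at GTCS offset: a position-bearing behavior covering
  # the offset second, else the latest with onset at/before the offset
  pos_rows <- beh[vapply(beh$qualifiers, function(q) !is.null(q$position),
                         FALSE), , drop = FALSE]
  c5_ev <- .evidence()
  for (ge in gt_ends) {
    if (!nrow(pos_rows)) break
    covering <- pos_rows[pos_rows$start_s <= ge & pos_rows$end_s > ge, ,
                         drop = FALSE]
    cand <- if (nrow(covering)) {
      covering[which.max(covering$start_s), , drop = FALSE]
    } else {
      before <- pos_rows[pos_rows$start_s <= ge, , drop = FALSE]
      if (nrow(before)) before[which.max(before$start_s), , drop = FALSE]
      else pos_rows[0L, , drop = FALSE]
    }
    if (nrow(cand) &&
        identical(cand$qualifiers[[1L]]$position, "prone")) {
      c5_ev <- rbind(c5_ev, .evidence(
        "behavior", sprintf("prone position at GTCS offset %ds", ge),
        cand$start_s, cand$end_s))
    }
  }
  c5 <- .criterion("sudep.5", "GTCS ended in prone position",
                   nrow(c5_ev) > 0L, c5_ev)

  .new_alert("sudep", list(c1, c2, c3, c4, c5))
}

#' Run every extrapolation function on an episode
#'
#' @inheritParams check_focality
#' @return named list of `ds_alert`s: focality, pnes, jacksonian, sudep. The
#'   Jacksonian alert is positive iff [detect_jacksonian()] finds at least
#'   one march sequence; the sequences ride along in `$sequences`.
#' @export
run_all_rules <- function(episode, config = rule_config()) {
  seqs <- detect_jacksonian(episode, config)
  jk_ev <- if (length(seqs)) {
    do.call(rbind, lapply(seqs, function(s) {
      .evidence("sequence",
                sprintf("%s-sided march: %s", s$side,
                        paste(s$steps$station, collapse = " -> ")),
                min(s$steps$start_s), max(s$steps$end_s))
    }))
  } else .evidence()
  jk <- .new_alert("jacksonian", list(
    .criterion("jacksonian.1",
               "Spatio-temporal clonic propagation on the same body side",
               length(seqs) > 0L, jk_ev)),
    sequences = seqs)
  list(
    focality = check_focality(episode, config),
    pnes = check_pnes(episode, config),
    jacksonian = jk,
    sudep = check_sudep(episode, config)
  )
}
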