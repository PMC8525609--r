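# Seeded generator of labeled synthetic episodes.  Archetypes emulate the
# onset-ordered behavior sequences of the episode kinds a mixed video-EEG
# cohort contains: versive and unilateral-motor focal seizures, aura-onset
# and hyperkinetic-to-convulsive seizures, convulsions out of sleep,
# dialeptic episodes, a Jacksonian march, long eyes-closed psychogenic
# events, brief-motor psychogenic events (deliberately free of every PNES
# rule feature, the sensitivity-lowering confound), and baseline behavior.
# All randomness flows from one local Mersenne-Twister stream per call; the
# caller's RNG state is never touched.

.archetype_names <- c("focal_versive", "focal_unilateral_motor", "aura_onset",
                      "hyperkinetic_to_gtcs", "gtcs_from_sleep",
                      "pnes_long_closed_eyes", "pnes_brief_motor",
                      "dialeptic", "jacksonian", "baseline")

.archetype_defaults <- list(
  focal_versive          = list(duration_range = c(40L, 120L), label = "focal"),
  focal_unilateral_motor = list(duration_range = c(30L, 90L),  label = "focal"),
  aura_onset             = list(duration_range = c(40L, 120L), label = "focal"),
  hyperkinetic_to_gtcs   = list(duration_range = c(60L, 180L), label = "focal"),
  gtcs_from_sleep        = list(duration_range = c(60L, 180L), label = "generalized"),
  pnes_long_closed_eyes  = list(duration_range = c(310L, 900L), label = "pnes"),
  pnes_brief_motor       = list(duration_range = c(20L, 90L),  label = "pnes"),
  dialeptic              = list(duration_range = c(30L, 120L), label = "focal"),
  jacksonian             = list(duration_range = c(40L, 90L),  label = "focal"),
  baseline               = list(duration_range = c(30L, 120L), label = "other")
)

# run expr with a dedicated RNG stream; caller's .Random.seed is restored
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

.rint <- function(a, b) if (a >= b) as.integer(a) else
  as.integer(sample(seq.int(a, b), 1L))
.coin <- function(p) stats::runif(1L) < p

#' Specification of a synthetic episode archetype
#'
#' @param name one of `"focal_versive"`, `"focal_unilateral_motor"`,
#'   `"aura_onset"`, `"hyperkinetic_to_gtcs"`, `"gtcs_from_sleep"`,
#'   `"pnes_long_closed_eyes"`, `"pnes_brief_motor"`, `"dialeptic"`,
#'   `"jacksonian"`, `"baseline"`.
#' @param duration_range length-2 integer vector of episode duration bounds
#'   (s), within `[10, 3600]`; defaults are archetype-specific.
#' @param feature_prob probability in `[0, 1]` that the archetype-defining
#'   feature is inserted; at 1 the corresponding rule fires by construction,
#'   at 0 the generated episode carries a lookalike that misses the rule.
#' @param noise_rate expected non-specific "other" behaviors per minute.
#' @return an `archetype_spec` list.
#' @export
archetype_spec <- function(name, duration_range = NULL, feature_prob = 1,
                           noise_rate = 0.5) {
  name <- match.arg(name, .archetype_names)
  def <- .archetype_defaults[[name]]
  if (is.null(duration_range)) duration_range <- def$duration_range
  stopifnot(length(duration_range) == 2L,
            duration_range[1L] <= duration_range[2L],
            duration_range[1L] >= 10, duration_range[2L] <= 3600,
            feature_prob >= 0, feature_prob <= 1, noise_rate >= 0)
  structure(list(name = name,
                 duration_range = as.integer(duration_range),
                 feature_prob = feature_prob,
                 noise_rate = noise_rate,
                 label = def$label),
            class = "archetype_spec")
}

.noise_labels <- c("unspecified_movements_of_trunk_face_limbs",
                   "head_nodding", "side_to_side_head_movements", "walking")

.noise_events <- function(dur, rate_per_min, min_start = 0L) {
  n <- stats::rpois(1L, rate_per_min * dur / 60)
  evs <- list()
  for (k in seq_len(n)) {
    len <- .rint(1L, min(8L, dur - min_start))
    s <- .rint(min_start, dur - len)
    lab <- sample(.noise_labels, 1L)
    bp <- if (lab == "unspecified_movements_of_trunk_face_limbs") {
      list(body_part_ref("trunk", "axial"))
    } else list()
    evs[[k]] <- ds_event("other", s, s + len, list(
      ds_behavior("other", lab, s, s + len, body_parts = bp)))
  }
  evs
}

.simple_motor_event <- function(label, start, end, part, side, quals = list()) {
  ds_event("simple_motor", start, end, list(
    ds_behavior("simple_motor", label, start, end,
                body_parts = list(body_part_ref(part, side)),
                qualifiers = quals)))
}

.gen_core_events <- function(spec, dur, with_feature) {
  flags <- ds_flags()
  events <- switch(spec$name,
    focal_versive = {
      t0 <- .rint(0L, max(0L, dur %/% 4L))
      len <- .rint(4L, 15L)
      t1 <- min(t0 + len, dur)
      side <- sample(c("left", "right"), 1L)
      list(ds_event("simple_motor", t0, t1, list(
        ds_behavior("simple_motor", "head_turn", t0, t1,
                    body_parts = list(body_part_ref("head", side)),
                    qualifiers = list(forced = with_feature)))))
    },
    focal_unilateral_motor = {
      side <- sample(c("left", "right"), 1L)
      opp <- if (side == "left") "right" else "left"
      mv <- sample(c("tonic", "clonic", "dystonic"), 1L)
      t0 <- .rint(0L, max(0L, dur %/% 4L))
      len <- .rint(8L, min(25L, dur - t0))
      t1 <- t0 + len
      evs <- list(.simple_motor_event(mv, t0, t1, "upper_limb_distal", side))
      if (with_feature) {
        if (.coin(0.5) && t0 + 5L < dur) {
          c0 <- min(t0 + 5L + .rint(0L, 5L), dur - 1L)
          evs <- c(evs, list(.simple_motor_event(mv, c0, min(c0 + len, dur),
                                                 "upper_limb_distal", opp)))
        }
      } else {
        # simultaneous contralateral onset: not lateralizing
        evs <- c(evs, list(.simple_motor_event(mv, t0, t1,
                                               "upper_limb_distal", opp)))
      }
      evs
    },
    aura_onset = {
      a_len <- .rint(5L, 20L)
      aura <- ds_event("aura", 0L, a_len, list(
        ds_behavior("aura", sample(c("somatosensory", "cephalic",
                                     "experiential"), 1L), 0L, a_len)))
      gap <- if (with_feature) 5L + .rint(0L, 10L) else .rint(0L, 4L)
      m0 <- min(gap, dur - 2L)
      m1 <- min(m0 + .rint(5L, 20L), dur)
      motor <- ds_event("automatisms", m0, m1, list(
        ds_behavior("automatisms", "oral_automatisms", m0, m1)))
      list(aura, motor)
    },
    hyperkinetic_to_gtcs = {
      h0 <- .rint(0L, 5L)
      h1 <- h0 + .rint(6L, 20L)
      gap <- if (with_feature) 5L + .rint(0L, 10L) else .rint(0L, 4L)
      g0 <- h0 + gap
      g1 <- min(g0 + .rint(20L, 60L), dur)
      list(
        ds_event("hyperkinetic", h0, min(h1, dur), list(
          ds_behavior("hyperkinetic",
                      sample(c("bimanual_bipedal_automatisms", "rocking"), 1L),
                      h0, min(h1, dur)))),
        ds_event("gtcs", g0, g1))
    },
    gtcs_from_sleep = {
      flags$started_from_sleep <- with_feature
      g0 <- .rint(0L, 10L)
      g1 <- min(g0 + .rint(30L, 90L), dur)
      evs <- list(ds_event("gtcs", g0, g1))
      if (.coin(0.4) && g1 + 2L < dur) {
        a0 <- min(g1 + .rint(0L, 10L), dur - 1L)
        a1 <- min(a0 + .rint(5L, 20L), dur)
        evs <- c(evs, list(ds_event("autonomic", a0, a1, list(
          ds_behavior("autonomic", "apnea", a0, a1, postictal = TRUE)))))
      }
      evs
    },
    pnes_long_closed_eyes = {
      evs <- list()
      if (with_feature && .coin(0.6)) {
        ec_len <- as.integer(ceiling(0.6 * dur)) + .rint(0L, dur %/% 5L)
        ec_len <- min(ec_len, dur)
        e0 <- .rint(0L, dur - ec_len)
        evs <- c(evs, list(ds_event("eye_movements", e0, e0 + ec_len, list(
          ds_behavior("eye_movements", "eyes_closed", e0, e0 + ec_len)))))
      }
      t0 <- .rint(0L, dur %/% 3L)
      t1 <- min(t0 + .rint(20L, dur %/% 2L), dur)
      evs <- c(evs, list(ds_event("other", t0, t1, list(
        ds_behavior("other", "body_part_shaking", t0, t1,
                    body_parts = list(body_part_ref("trunk", "axial")))))))
      evs
    },
    pnes_brief_motor = {
      # deliberately none of the PNES rule features: brief, eyes unannotated,
      # no controlled fall, no long vocalization
      t0 <- .rint(0L, max(0L, dur %/% 4L))
      t1 <- min(t0 + .rint(5L, 20L), dur)
      list(ds_event("other", t0, t1, list(
        ds_behavior("other", "unspecified_movements_of_trunk_face_limbs",
                    t0, t1,
                    body_parts = list(body_part_ref("trunk", "axial"))),
        ds_behavior("other", "side_to_side_head_movements",
                    t0, min(t0 + 5L, t1)))))
    },
    dialeptic = {
      t0 <- .rint(0L, 5L)
      t1 <- min(t0 + .rint(15L, 60L), dur)
      evs <- list(ds_event("dialeptic", t0, t1, list(
        ds_behavior("dialeptic", "cessation_of_activity", t0, t1),
        ds_behavior("dialeptic", sample(c("completely_irresponsive",
                                          "partially_irresponsive"), 1L),
                    t0, t1))))
      if (.coin(0.4)) {
        a0 <- min(t0 + .rint(2L, 10L), dur - 2L)
        a1 <- min(a0 + .rint(5L, 15L), dur)
        evs <- c(evs, list(ds_event("automatisms", a0, a1, list(
          ds_behavior("automatisms", "oral_automatisms", a0, a1)))))
      }
      evs
    },
    jacksonian = {
      side <- sample(c("left", "right"), 1L)
      t0 <- .rint(0L, max(0L, dur - 30L))
      f_end <- t0 + 8L
      behaviors <- list(
        ds_behavior("simple_motor", "clonic", t0, f_end,
                    body_parts = list(body_part_ref("face", side))))
      if (with_feature) {
        a0 <- t0 + 3L; a1 <- a0 + 9L   # overlaps face: gap-free
        l0 <- a0 + 5L; l1 <- l0 + 8L   # starts at face offset: no face+leg
        behaviors <- c(behaviors, list(
          ds_behavior("simple_motor", "clonic", a0, a1,
                      body_parts = list(body_part_ref("upper_limb_distal", side))),
          ds_behavior("simple_motor", "clonic", l0, l1,
                      body_parts = list(body_part_ref("lower_limb_distal", side)))))
        ev_end <- l1
      } else {
        # single contiguous station after an uncovered epoch: no march
        a0 <- f_end + 2L; a1 <- a0 + 9L
        behaviors <- c(behaviors, list(
          ds_behavior("simple_motor", "clonic", a0, a1,
                      body_parts = list(body_part_ref("upper_limb_distal", side)))))
        ev_end <- a1
      }
      list(ds_event("simple_motor", t0, min(ev_end, dur), behaviors))
    },
    baseline = {
      flags$encoder_baseline_impression <- TRUE
      list()
    })
  list(events = events, flags = flags)
}

#' Generate one labeled synthetic episode
#'
#' Deterministic in `(spec, seed)`: the same pair always yields a
#' byte-identical DS-JSON document. The output always passes
#' [validate_episode()] against the default schema, and carries the
#' archetype's ground-truth label plus the archetype name as attribute
#' `"archetype"`.
#'
#' @param spec an [archetype_spec()], or an archetype name (defaults used).
#' @param seed integer seed for this episode's private RNG stream.
#' @return a `ds_episode`.
#' @examples
#' ep <- generate_episode("gtcs_from_sleep", seed = 7)
#' check_sudep(ep)$status   # "positive"
#' @export
generate_episode <- function(spec, seed) {
  if (is.character(spec)) spec <- archetype_spec(spec)
  stopifnot(inherits(spec, "archetype_spec"))
  .with_local_seed(seed, {
    with_feature <- .coin(spec$feature_prob)
    dur <- if (spec$name == "pnes_long_closed_eyes" && !with_feature) {
      # defining feature is the >5-min duration; without it, stay under
      .rint(120L, 295L)
    } else {
      .rint(spec$duration_range[1L], spec$duration_range[2L])
    }
    core <- .gen_core_events(spec, dur, with_feature)
    # aura-onset archetype: keep incidental movements clear of the aura lead
    noise_min_start <- if (spec$name == "aura_onset") 25L else 0L
    events <- c(core$events,
                .noise_events(dur, spec$noise_rate, noise_min_start))
    if (length(events)) {
      events <- events[order(vapply(events, `[[`, 0L, "start_s"),
                             vapply(events, `[[`, 0L, "end_s"))]
    }
    ep <- ds_episode(
      id = sprintf("%s-%d", spec$name, as.integer(seed)),
      duration_s = dur,
      flags = core$flags,
      events = events,
      label = spec$label
    )
    attr(ep, "archetype") <- spec$name
    ep
  })
}

#' Generate a labeled synthetic cohort
#'
#' Archetype counts follow a seeded multinomial draw over `weights`; every
#' episode gets a sub-seed derived from the cohort seed, so the whole cohort
#' is reproducible from `(n, weights, seed)`.
#'
#' @param n number of episodes.
#' @param weights named nonnegative archetype weights (need not sum to 1);
#'   the default mix reflects a mixed epilepsy-monitoring cohort dominated by
#'   focal motor and dialeptic episodes with a minority of psychogenic and
#'   convulsive ones.
#' @param seed integer cohort seed.
#' @param specs optional named list of [archetype_spec()]s overriding the
#'   per-archetype defaults.
#' @return list of `ds_episode`s (class `ds_cohort`).
#' @export
generate_cohort <- function(n, weights = default_cohort_weights(), seed,
                            specs = NULL) {
  stopifnot(n >= 0, length(weights) > 0, all(weights >= 0), any(weights > 0))
  arch_names <- names(weights)
  stopifnot(!is.null(arch_names), all(arch_names %in% .archetype_names))
  if (n == 0L) return(structure(list(), class = "ds_cohort"))
  .with_local_seed(seed, {
    draws <- sample(arch_names, n, replace = TRUE, prob = weights)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    eps <- lapply(seq_len(n), function(i) {
      sp <- if (!is.null(specs) && !is.null(specs[[draws[i]]])) {
        specs[[draws[i]]]
      } else archetype_spec(draws[i])
      ep <- generate_episode(sp, sub_seeds[i])
      ep$id <- sprintf("ep%03d-%s", i, draws[i])
      ep
    })
    structure(eps, class = "ds_cohort")
  })
}

#' Default archetype weights for a synthetic cohort
#' @return named numeric vector over the ten archetypes.
#' @export
default_cohort_weights <- function() {
  c(focal_versive = 10, focal_unilateral_motor = 8, aura_onset = 5,
    hyperkinetic_to_gtcs = 5, gtcs_from_sleep = 6,
    pnes_long_closed_eyes = 6, pnes_brief_motor = 6,
    dialeptic = 10, jacksonian = 0, baseline = 4)
}

#' Ground-truth manifest of a cohort
#' @param cohort list of generated `ds_episode`s.
#' @return data.frame with `episode_id`, `label`, `archetype`.
#' @export
cohort_labels <- function(cohort) {
  data.frame(
    episode_id = vapply(cohort, `[[`, "", "id"),
    label = vapply(cohort, function(e) e$label %||% "unknown", ""),
    archetype = vapply(cohort, function(e) {
      a <- attr(e, "archetype")
      if (is.null(a)) sub("^ep[0-9]+-", "", e$id) else a
    }, ""),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
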