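# Focality, PNES, and SUDEP rule functions: directed criterion checks,
# boundary cases, and the alert contract (positive/inconclusive only).

fired_ids <- function(alert) {
  vapply(Filter(function(cr) cr$fired, alert$criteria), `[[`, "",
         "criterion_id")
}

test_that("onset precedence is inclusive at the lead", {
  expect_true(precedes_by_at_least(c(0, 10), c(5, 12), 5))
  expect_false(precedes_by_at_least(c(0, 10), c(4, 12), 5))
  expect_true(precedes_by_at_least(c(3, 8), c(3, 9), 0))
  expect_true(precedes_by_at_least(list(start_s = 0, end_s = 2),
                                   list(start_s = 7, end_s = 9), 5))
})

test_that("postural and forced-deviation focality criteria fire on presence", {
  a <- check_focality(wrap_episode(
    mk_behavior("simple_motor", "fencer_posturing", 3, 9,
                parts = list(bp("upper_limb_proximal", "left")))))
  expect_identical(a$status, "positive")
  expect_identical(fired_ids(a), "focality.2")

  a <- check_focality(wrap_episode(
    mk_behavior("simple_motor", "figure_of_4", 3, 9,
                parts = list(bp("upper_limb_proximal", "right")))))
  expect_identical(fired_ids(a), "focality.1")

  # forced qualifier is required for head turn and gaze deviation
  forced <- wrap_episode(
    mk_behavior("simple_motor", "head_turn", 0, 6,
                parts = list(bp("head", "left")),
                quals = list(forced = TRUE)),
    mk_behavior("eye_movements", "gaze_deviation", 0, 6,
                quals = list(forced = TRUE)))
  expect_setequal(fired_ids(check_focality(forced)),
                  c("focality.3", "focality.4"))
  lax <- wrap_episode(
    mk_behavior("simple_motor", "head_turn", 0, 6,
                parts = list(bp("head", "left")),
                quals = list(forced = FALSE)))
  expect_identical(check_focality(lax)$status, "inconclusive")

  # postictal behaviors are not focality evidence
  post <- wrap_episode(
    mk_behavior("simple_motor", "fencer_posturing", 3, 9, postictal = TRUE))
  expect_identical(check_focality(post)$status, "inconclusive")
})

test_that("event-sequence focality criteria respect the 5-s lead", {
  hk_gtcs <- function(gap) {
    ds_episode("e", 120, events = list(
      ds_event("hyperkinetic", 0, 15, list(
        ds_behavior("hyperkinetic", "rocking", 0, 15))),
      ds_event("gtcs", gap, gap + 40)))
  }
  expect_identical(fired_ids(check_focality(hk_gtcs(5))), "focality.5")
  expect_identical(check_focality(hk_gtcs(4))$status, "inconclusive")

  aura_then <- function(gap) {
    ds_episode("e", 120, events = list(
      ds_event("aura", 0, 10, list(ds_behavior("aura", "somatosensory", 0, 10))),
      ds_event("trigger", 1, 3, list(ds_behavior("trigger", "startle", 1, 3))),
      ds_event("automatisms", gap, gap + 20, list(
        ds_behavior("automatisms", "oral_automatisms", gap, gap + 20)))))
  }
  expect_identical(fired_ids(check_focality(aura_then(5))), "focality.6")
  expect_identical(check_focality(aura_then(4))$status, "inconclusive")

  # an aura-only episode has no sequence to witness
  aura_only <- ds_episode("e", 60, events = list(
    ds_event("aura", 0, 10, list(ds_behavior("aura", "cephalic", 0, 10)))))
  expect_identical(check_focality(aura_only)$status, "inconclusive")
})

test_that("unilateral motor precedence fires at >=5 s or without contralateral", {
  uni <- function(contra_onset = NULL, mv = "clonic") {
    behs <- list(mk_behavior("simple_motor", mv, 0, 10,
                             parts = list(bp("upper_limb_distal", "left"))))
    if (!is.null(contra_onset)) {
      behs <- c(behs, list(
        mk_behavior("simple_motor", mv, contra_onset, contra_onset + 10,
                    parts = list(bp("upper_limb_distal", "right")))))
    }
    do.call(wrap_episode, behs)
  }
  expect_identical(fired_ids(check_focality(uni(5))), "focality.7")
  expect_identical(check_focality(uni(4))$status, "inconclusive")
  # purely unilateral motor episode fires (interpreted as focal)
  expect_identical(fired_ids(check_focality(uni(NULL))), "focality.7")
  # paralysis mirrors the movement rule under its own criterion
  expect_identical(fired_ids(check_focality(uni(6, "paralysis"))),
                   "focality.8")
  # contralateral involvement counts regardless of body part or subtype
  mixed <- wrap_episode(
    mk_behavior("simple_motor", "clonic", 0, 10,
                parts = list(bp("upper_limb_distal", "left"))),
    mk_behavior("simple_motor", "dystonic", 2, 12,
                parts = list(bp("foot", "right"))))
  expect_identical(check_focality(mixed)$status, "inconclusive")
  # a bilateral reference is involvement of both sides at once
  bilat <- wrap_episode(
    mk_behavior("simple_motor", "tonic", 0, 10,
                parts = list(bp("whole_body", "bilateral"))))
  expect_identical(check_focality(bilat)$status, "inconclusive")
  expect_identical(check_focality(ds_episode("empty", 30))$status,
                   "inconclusive")
})

test_that("PNES v1 criteria: coverage, resistance, controlled fall, duration", {
  # eyes closed covering 0.83 of a 240-s episode
  ec <- ds_episode("e", 240, events = list(
    ds_event("eye_movements", 0, 240, list(
      ds_behavior("eye_movements", "eyes_closed", 0, 200)))))
  a <- check_pnes(ec)
  expect_identical(fired_ids(a), "pnes.1")
  # below half coverage: inconclusive
  ec2 <- ds_episode("e", 240, events = list(
    ds_event("eye_movements", 0, 240, list(
      ds_behavior("eye_movements", "eyes_closed", 0, 100)))))
  expect_identical(check_pnes(ec2)$status, "inconclusive")

  reo <- wrap_episode(mk_behavior("eye_movements", "eyes_closed", 0, 10,
                                  quals = list(resisted_eye_opening = TRUE)),
                      duration = 120)
  expect_true("pnes.2" %in% fired_ids(check_pnes(reo)))

  fall <- wrap_episode(mk_behavior("other", "falling", 5, 8,
                                   quals = list(fall_control = "fully_controlled")),
                       duration = 120)
  expect_identical(fired_ids(check_pnes(fall)), "pnes.3")
  fall2 <- wrap_episode(mk_behavior("other", "falling", 5, 8,
                                    quals = list(fall_control = "uncontrolled")),
                        duration = 120)
  expect_identical(check_pnes(fall2)$status, "inconclusive")

  # the duration criterion is strict: 301 s fires, 300 s does not
  expect_identical(fired_ids(check_pnes(ds_episode("e", 301))), "pnes.4")
  expect_identical(check_pnes(ds_episode("e", 300))$status, "inconclusive")
})

test_that("PNES v2 adds the vocalization criterion and negative features", {
  cfg <- rule_config(pnes_ruleset = "v2")
  voc <- function(label, len) {
    wrap_episode(mk_behavior("voice", label, 10, 10 + len), duration = 120)
  }
  expect_true("pnes.5" %in%
                fired_ids(check_pnes(voc("non_verbal_vocalization_without_panic_behavior", 15), cfg)))
  # 9 s falls short of the 10-s minimum
  expect_identical(
    check_pnes(voc("non_verbal_vocalization_without_panic_behavior", 9),
               cfg)$status, "inconclusive")
  # ictal cry and laughter are excluded
  expect_identical(check_pnes(voc("crying", 15), cfg)$status, "inconclusive")
  expect_identical(check_pnes(voc("laughter", 15), cfg)$status, "inconclusive")
  # v1 never fires on vocalization
  expect_identical(
    check_pnes(voc("non_verbal_vocalization_without_panic_behavior", 15))$status,
    "inconclusive")

  neg <- wrap_episode(
    mk_behavior("other", "physical_trauma", 5, 8),
    mk_behavior("autonomic", "urine_loss", 20, 22),
    duration = 320, flags = ds_flags(started_from_sleep = TRUE))
  a <- check_pnes(neg, cfg)
  # positive statement (duration) and probability-lowering features coexist
  expect_identical(a$status, "positive")
  expect_setequal(
    vapply(Filter(function(cr) cr$fired, a$negative_features), `[[`, "",
           "criterion_id"),
    c("pnes.neg.1", "pnes.neg.2", "pnes.neg.3"))
})

test_that("SUDEP criteria gate on GTCS presence and use the offset window", {
  gtcs_ep <- function(..., flags = ds_flags(), duration = 150) {
    ds_episode("e", duration, flags = flags,
               events = c(list(ds_event("gtcs", 10, 70)), list(...)))
  }
  a <- check_sudep(gtcs_ep())
  expect_identical(fired_ids(a), "sudep.1")

  a <- check_sudep(gtcs_ep(flags = ds_flags(started_from_sleep = TRUE)))
  expect_setequal(fired_ids(a), c("sudep.1", "sudep.2"))

  apnea_at <- function(t) {
    ds_event("autonomic", t, t + 10,
             list(ds_behavior("autonomic", "apnea", t, t + 10,
                              postictal = TRUE)))
  }
  # onset 72 lies in [65, 100]: fires; onset 101 does not
  expect_true("sudep.3" %in% fired_ids(check_sudep(gtcs_ep(apnea_at(72)))))
  expect_false("sudep.3" %in% fired_ids(check_sudep(gtcs_ep(apnea_at(101),
                                                            duration = 160))))
  # shortly before the offset also counts ("ended with")
  expect_true("sudep.3" %in% fired_ids(check_sudep(gtcs_ep(apnea_at(66)))))

  cy <- ds_event("autonomic", 75, 80,
                 list(ds_behavior("autonomic", "cyanosis", 75, 80,
                                  postictal = TRUE)))
  expect_true("sudep.4" %in% fired_ids(check_sudep(gtcs_ep(cy))))

  # prone position in effect at GTCS offset
  prone <- ds_event("other", 40, 45, list(
    ds_behavior("other", "patients_position_change", 40, 45,
                qualifiers = list(position = "prone"))))
  expect_true("sudep.5" %in% fired_ids(check_sudep(gtcs_ep(prone))))
  supine_later <- ds_event("other", 60, 66, list(
    ds_behavior("other", "patients_position_change", 60, 66,
                qualifiers = list(position = "supine"))))
  expect_false("sudep.5" %in%
                 fired_ids(check_sudep(gtcs_ep(prone, supine_later))))
  # absent any position annotation, criterion 5 cannot fire
  expect_false("sudep.5" %in% fired_ids(check_sudep(gtcs_ep())))

  # apnea alone, no GTCS: inconclusive
  no_gtcs <- ds_episode("e", 100, events = list(apnea_at(50)))
  expect_identical(check_sudep(no_gtcs)$status, "inconclusive")
})

test_that("alerts only ever report positive or inconclusive, with evidence", {
  set.seed(11)
  for (k in 1:20) {
    arch <- sample(c("focal_versive", "pnes_brief_motor", "gtcs_from_sleep",
                     "baseline", "jacksonian", "dialeptic"), 1L)
    ep <- generate_episode(arch, k)
    for (al in run_all_rules(ep)) {
      expect_true(al$status %in% c("positive", "inconclusive"))
      for (cr in al$criteria) {
        if (cr$fired) expect_gt(nrow(cr$evidence), 0L)
      }
    }
  }
})

test_that("laterality mirroring preserves every fired-criteria set", {
  set.seed(23)
  for (k in 1:15) {
    arch <- sample(c("focal_unilateral_motor", "jacksonian", "focal_versive",
                     "hyperkinetic_to_gtcs", "pnes_long_closed_eyes"), 1L)
    ep <- generate_episode(arch, 100 + k)
    mir <- mirror_episode(ep)
    a1 <- run_all_rules(ep)
    a2 <- run_all_rules(mir)
    for (fn in names(a1)) {
      expect_identical(fired_ids(a2[[fn]]), fired_ids(a1[[fn]]),
                       label = paste(arch, fn, k))
    }
    # march sides mirror
    s1 <- detect_jacksonian(ep)
    s2 <- detect_jacksonian(mir)
    flip <- function(s) unname(c(left = "right", right = "left")[s])
    expect_identical(vapply(s2, `[[`, "", "side"),
                     flip(vapply(s1, `[[`, "", "side")))
  }
})

test_that("presence criteria are monotone under added annotation", {
  base <- wrap_episode(
    mk_behavior("simple_motor", "fencer_posturing", 3, 9),
    mk_behavior("simple_motor", "figure_of_4", 4, 9),
    mk_behavior("simple_motor", "head_turn", 0, 6,
                parts = list(bp("head", "left")), quals = list(forced = TRUE)),
    mk_behavior("eye_movements", "gaze_deviation", 0, 6,
                quals = list(forced = TRUE)),
    duration = 90)
  base$events <- c(base$events, list(ds_event("gtcs", 30, 80)))
  before_f <- fired_ids(check_focality(base))
  before_s <- fired_ids(check_sudep(base))
  expect_true(all(c("focality.1", "focality.2", "focality.3", "focality.4")
                  %in% before_f))
  expect_true("sudep.1" %in% before_s)

  set.seed(7)
  addable <- list(
    function(d) ds_event("automatisms", 0, d, list(
      ds_behavior("automatisms", "stepping", sample(0:(d - 2), 1), d))),
    function(d) ds_event("simple_motor", 0, d, list(
      ds_behavior("simple_motor", "clonic", sample(0:(d - 2), 1), d,
                  body_parts = list(bp("upper_limb_distal",
                                       sample(c("left", "right"), 1)))))),
    function(d) ds_event("dialeptic", 0, d, list(
      ds_behavior("dialeptic", "amnesia", 0, d))),
    function(d) ds_event("gtcs", sample(0:(d - 2), 1), d))
  grown <- base
  for (k in 1:12) {
    grown$events <- c(grown$events,
                      list(addable[[sample(length(addable), 1)]](grown$duration_s)))
    expect_identical(nrow(validate_episode(grown)), 0L)
    expect_true(all(c("focality.1", "focality.2", "focality.3", "focality.4")
                    %in% fired_ids(check_focality(grown))))
    expect_true("sudep.1" %in% fired_ids(check_sudep(grown)))
  }
})

test_that("rules are invariant under a whole-episode time shift", {
  shift_episode <- function(ep, k) {
    ep$duration_s <- ep$duration_s + k
    ep$events <- lapply(ep$events, function(ev) {
      ev$start_s <- ev$start_s + k; ev$end_s <- ev$end_s + k
      ev$behaviors <- lapply(ev$behaviors, function(b) {
        b$start_s <- b$start_s + k; b$end_s <- b$end_s + k
        b
      })
      ev
    })
    ep
  }
  for (seed in 1:8) {
    arch <- c("focal_unilateral_motor", "jacksonian", "gtcs_from_sleep",
              "hyperkinetic_to_gtcs")[(seed %% 4) + 1]
    ep <- generate_episode(arch, 300 + seed)
    sh <- shift_episode(ep, 17L)
    expect_identical(fired_ids(check_focality(sh)),
                     fired_ids(check_focality(ep)))
    expect_identical(fired_ids(check_sudep(sh)), fired_ids(check_sudep(ep)))
    expect_identical(length(detect_jacksonian(sh)),
                     length(detect_jacksonian(ep)))
  }
})
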