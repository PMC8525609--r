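# semiology

Structured encoding of seizure-video semiology, with rule-based semiologic
alerts.

Interpretation of video-EEG monitoring is usually written up as free text:
slow to produce, non-standardized, and unusable for computation. This
package implements the alternative for R users — clinical neurophysiologists,
epilepsy researchers, and methodologists working on automated seizure
analysis: every reviewed episode is encoded as a hierarchy of **episode →
events → behaviors** against a controlled vocabulary of eleven ictal event
types, with integer-second timing, body parts, lateralities, and qualifiers.
On top of the encoding sit four **semiologic extrapolation rules** that scan
a completed annotation and raise decision-support alerts, each either
*positive* (with explicit evidence) or *inconclusive* — never "negative":

1. **Focality** — eight highly specific features of focal rather than
   generalized onset: figure-of-4 and fencer posturing, forced head turn,
   forced gaze deviation, a hyperkinetic phase preceding a generalized
   tonic-clonic seizure (GTCS) by ≥ 5 s, an aura preceding all other events
   by ≥ 5 s, and unilateral tonic/clonic/dystonic movement (or paralysis)
   preceding contralateral involvement by ≥ 5 s (onset-to-onset, inclusive).
2. **PNES** — features of psychogenic non-epileptic seizures: ictal eye
   closure covering ≥ ½ of the episode, resisted eye opening, a fully
   controlled fall, duration > 5 min; an updated ruleset (v2) adds
   vocalizations ≥ 10 s (excluding ictal cry/laughter) and reports
   probability-*lowering* features (onset from sleep, self-injury, urinary
   incontinence) as an independent statement.
3. **Jacksonian march** — spatio-temporal propagation of clonic movements
   across same-side stations (face, arm, leg, distal-extremity parts):
   chains of ≥ 2 stations with onsets separated by ≥ 1 s, gap-free clonic
   coverage between first and last onset, truncated at any second of
   simultaneous same-side face + leg involvement, with exactly synchronous
   bilateral movements excluded.
4. **SUDEP risk** — presence of a GTCS, gated sub-criteria for onset from
   sleep, apnea or cyanosis at the GTCS offset, and prone position at the
   end of the convulsion.

Around the core sit a deterministic report renderer (chronological text
report plus an SVG/ASCII timeline), a seeded generator of labeled synthetic
episodes for ten clinical archetypes, and evaluation statistics
(sensitivity/specificity with exact Clopper–Pearson intervals,
`lower = qbeta(α/2, x, n−x+1)`, `upper = qbeta(1−α/2, x+1, n−x)`).

## Worked example

```r
library(semiology)

ep <- ds_episode(
  id = "case-014", duration_s = 150,
  flags = ds_flags(started_from_sleep = TRUE),
  events = list(
    ds_event("simple_motor", 5, 40, list(
      ds_behavior("simple_motor", "head_turn", 5, 15,
                  body_parts = list(body_part_ref("head", "left")),
                  qualifiers = list(forced = TRUE)),
      ds_behavior("simple_motor", "clonic", 12, 40,
                  body_parts = list(body_part_ref("upper_limb_distal", "right"))))),
    ds_event("gtcs", 40, 110),
    ds_event("autonomic", 108, 125, list(
      ds_behavior("autonomic", "apnea", 112, 125, postictal = TRUE)))))

validate_episode(ep)        # zero rows: the annotation is well-formed
print(render_text(ep, run_all_rules(ep)))
```

```
Episode case-014 (duration 150 s)
Flags: started_from_sleep

Chronology:
  t=5–15s simple_motor: head_turn [left head] {forced=true}
  t=12–40s simple_motor: clonic [right upper_limb_distal]

Possibly postictal:
  t=112–125s autonomic: apnea

Semiologic extrapolation alerts:
  focality: positive
    - Forced head turn
        behavior [5–15s] head_turn (simple_motor)
    - Unilateral tonic/clonic/dystonic movement at least 5 s before contralateral involvement
        behavior [12–40s] right upper_limb_distal clonic at 12s; contralateral involvement absent (interpreted as focal)
  pnes: inconclusive
  jacksonian: inconclusive
  sudep: positive
    - Presence of B/GTCS
        event [40–110s] GTCS
    - GTCS started from sleep
        episode [0–150s] started_from_sleep flag
    - GTCS ended with apnea
        behavior [112–125s] apnea at 112s (GTCS offset 110)
```

Reading the output: the forced (not merely mild) head version and the
right-arm clonic activity without any contralateral involvement are each
lateralizing, so the focality alert is positive with both criteria cited.
The convulsion out of sleep ending in apnea trips three SUDEP risk factors.
The PNES and march alerts stay inconclusive — the episode is short, eyes
are unannotated, and there is no same-side clonic propagation chain.

The same machinery is scriptable from a shell via the thin `exec/ds` entry
point (`ds validate`, `ds report`, `ds extrapolate`, `ds simulate`,
`ds evaluate`, `ds export-schema`), exchanging one-episode DS-JSON
documents.

## Synthetic cohorts and evaluation

```r
cohort <- generate_cohort(120, default_cohort_weights(), seed = 8)
evaluate_cohort(cohort, "pnes")
#> Evaluation of 'pnes' on 120 episodes
#> <confusion: tp=9 fp=0 tn=100 fn=11>
#>   sensitivity: 45.00% (95% CI 23.06–68.47%)
#>   specificity: 100.00% (95% CI 96.38–100.00%)
```

The brief-motor psychogenic archetype deliberately carries none of the PNES
rule features, so rule sensitivity on a mixed cohort sits well below 1 while
specificity stays high — the regime the rule set is known to occupy. See the
vignette (`vignettes/encoding-and-extrapolation.Rmd`) for the model, every
tunable threshold, and the design decisions.

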