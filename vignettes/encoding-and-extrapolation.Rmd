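---
title: "Encoding seizure semiology and extrapolating alerts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding seizure semiology and extrapolating alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiology)
```

## The encoding model

Video review of suspected seizures is usually summarized as free text, which
is slow to produce, hard to standardize, and nearly impossible to compute
on. This package implements a structured alternative: every reviewed episode
is encoded as a three-level hierarchy,

* the **ictal episode** — the whole recorded fit, spanning
  `[0, duration_s)` seconds from clip start, with four episode-level
  questions (baseline-behavior impression, psychogenic impression,
  non-epileptic/non-psychogenic impression, onset from sleep);
* **ictal events** — typed phases drawn from a closed list of eleven event
  types (simple motor, automatisms, autonomic, eye movements, hyperkinetic,
  voice phenomena, dialeptic, GTCS, aura, other, trigger), each with its own
  timeframe; event timeframes may overlap, since a convulsion and, say, an
  autonomic phenomenon genuinely co-occur;
* **ictal behaviors** — individual observations inside an event, each with
  its own interval contained in the event timeframe, optional body-part
  references with laterality, qualifiers (forced movement, hand posture,
  fall control, resisted eye opening, body position), a possibly-postictal
  flag, and a free-text note.

All times are integer seconds: one second is the temporal resolution of the
encoding, and an annotation shorter than that cannot be expressed. Intervals
are half-open, `[start_s, end_s)`; second `t` is covered iff
`start_s <= t < end_s`. This makes abutting intervals (`[0,4)` then
`[4,9)`) gap-free by construction and gives "same start and end timings" a
single unambiguous meaning (equal `start_s` *and* equal `end_s`).

The controlled vocabulary lives in a `semio_schema` object
(`default_schema()`), serializable to JSON and extensible: documents may add
event types, behaviors, body parts, or qualifier vocabularies, and loading
re-checks uniqueness and qualifier resolution. Labels are snake_case
identifiers derived from the display strings. The built-in vocabulary
reproduces the scheme's behavioral table; the full descriptor tree used in
practice is considerably larger (well over a hundred descriptors once
subtypes are counted), so the only cardinality this package asserts is the
event-type count of eleven. Two additions were necessary for the rules to
have a substrate: a `head_turn` behavior under simple motor (the
forced-head-turn criterion names it but the behavioral table omits it) and
a free-text `other`
behavior admissible under every event type, carrying a mandatory note — the
original encoders used exactly this escape hatch for position changes,
button pushes, and crying.

The body-part taxonomy (head, face, eyes, trunk, pelvis, proximal/distal
upper and lower limb, hand, fingers, foot, hemibody, whole body) is the
package's own choice: it is the coarsest partition under which the march
rules can distinguish face, arm, and leg *and* "different parts of distal
extremities", and under which unilateral versus contralateral motor
involvement is expressible. Lateralities are left, right, bilateral, and
axial (for midline structures).

Reading DS-JSON is deliberately lenient while `validate_episode()` is
strict: a document with an unknown behavior label still loads, so a reviewer
can inspect it, but validation reports the violation as data. Structural
impossibilities — non-integer times, `start_s >= end_s`, a major
format-version mismatch — are refused at read time.

## The four extrapolation rules

Each rule maps a validated episode to an alert that is either **positive**
(at least one criterion fired, with explicit evidence references) or
**inconclusive**. No rule ever reports "negative": absence of an annotation
is weak evidence, and the design intent is decision support, not diagnosis.
The encoder-impression flags never drive a rule; the single flag a rule
consumes is *started from sleep* (SUDEP criterion 2). The ground-truth label
carried by synthetic episodes is invisible to the rules by interface.

Tunable parameters (`rule_config()`), with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `precedence_lead_s` | 5 s | "at least 5 s before", onset-to-onset, inclusive |
| `pnes_duration_s` | 300 s | episode duration must *strictly* exceed this |
| `pnes_eyes_closed_min_fraction` | 0.5 | eyes-closed coverage of the episode |
| `pnes_vocalization_min_s` | 10 s | minimum vocalization length (v2 ruleset) |
| `sudep_end_window_s` | 30 s | "ended with" window after GTCS offset |
| `march_min_onset_separation_s` | 1 s | march onset resolution |
| `pnes_ruleset` | v1 | v1 = the four evaluated criteria; v2 adds vocalization + negative features |

Decisions made where the rule text left room:

* **Inclusive lead.** "At least 5 s before" compares onsets and fires at
  exactly 5. The stated motivation for the threshold is conservatism about
  equivocal near-simultaneous onsets; an onset difference of exactly the
  threshold is, by that reading, already unequivocal.
* **No contralateral involvement at all.** The unilateral-motor and
  unilateral-paralysis criteria are worded as a lead over contralateral
  involvement. A purely unilateral motor episode — contralateral side never
  involved — fires: it is the maximally lateralizing case, and the wording
  bounds only the bilateral situation. The evidence text marks this
  interpretation. Contralateral involvement means any tonic, clonic, or
  dystonic behavior (respectively paralysis) on the opposite side, whatever
  the body part; a `bilateral` or whole-body reference counts as involvement
  of both sides at its onset.
* **Aura-first needs a witness.** The aura-precedence criterion requires at
  least one non-aura, non-trigger event to exist; an aura-only episode is
  inconclusive, since there is no sequence to witness.
* **Eyes closed "during the episode"** is operationalized as union coverage
  of at least half the episode (configurable): eye closure should dominate
  the episode rather than merely occur in it.
* **"Ended with"** comes with no stated window; the package uses
  `[offset - 5, offset + 30]` seconds around the GTCS offset, configurable.
  Postictal-flagged behaviors are eligible evidence here — apnea after the
  convulsion is precisely a postictal finding.
* **Prone at offset** uses the position annotation in effect at the GTCS
  offset: a position-bearing behavior covering the offset second, otherwise
  the latest one starting at or before it. With no position annotation the
  criterion cannot fire.
* **v1 is the default PNES ruleset** — it is the version that was evaluated;
  v2 (long non-cry/non-laughter vocalizations as a fifth positive criterion,
  plus sleep onset, self-injury, and urinary incontinence as
  probability-lowering features) is selected by configuration. Negative
  features never veto the positive statement; they are reported
  independently, mirroring the two-statement design.

## March detection

Jacksonian march detection is a sequence test, not a presence test. Clonic
behaviors are projected onto per-side *stations* (face, proximal/distal arm,
hand, fingers, proximal/distal leg, foot); repeated or overlapping intervals
at one station are union-merged, so a station's onset is the start of its
contiguous clonic run. A march is a chain of at least two distinct stations
on one side with strictly increasing onsets separated by at least the 1-s
resolution, whose interval union leaves no uncovered second between the
first and last onset.

Two rules prune chains. Exactly synchronous bilateral intervals (equal start
and end against any contralateral clonic interval) are excluded before
chaining — a single behavior annotated with a *bilateral* body part
therefore self-excludes, which is consistent with the rule's intent;
non-synchronous bilateral activity is analyzed per side. And when face and
leg stations on one side are simultaneously clonic at some second, the chain
is not extended past that second. The rule text is ambiguous about whether
the chain built so far survives such a moment; this implementation keeps the
chain up to the blocking second and refuses only steps with strictly later
onsets. That makes the detector deliberately *non-monotone*: adding an
annotation can remove a reported sequence, and the tests assert this
directly.

Reported sequences are **maximal**: a chain that is an ordered sub-chain of
another valid chain is suppressed. A weaker notion — chains merely not
extendable at either end — would additionally report skip-a-station chains
(face → leg alongside face → hand → leg), which clinically describe the
same propagation; the subsequence form reports it once. Correctness is
established by
exhaustive comparison against an independent brute-force enumerator that
re-derives candidate steps with per-second set arithmetic and checks the
four rules literally, on 1,000 random small episodes per run.

## The synthetic generator

No annotated cohort is distributed with, or available to, this package, so
all testing substrate comes from `generate_episode()` /
`generate_cohort()`: ten archetypes emulating the episode kinds a mixed
monitoring cohort contains (versive focal, unilateral-motor focal,
aura-onset, hyperkinetic-to-convulsive, convulsion out of sleep, long
eyes-closed psychogenic, brief-motor psychogenic, dialeptic, Jacksonian
march, baseline). Each archetype inserts its defining feature with a
configurable probability (default 1) and draws duration, sides, onsets, and
lookalike alternatives from a per-call Mersenne–Twister stream; the caller's
RNG state is untouched, and `(spec, seed)` determines the DS-JSON output
byte for byte. Incidental "noise" behaviors are drawn from the catch-all
vocabulary (non-specific movements, head nodding, walking) at 0.5 events
per minute, matching how the original encoders used the category, and are
chosen so that they cannot trip any rule.

Two archetypes are deliberate confounds. `pnes_brief_motor` carries none of
the PNES rule features (brief, eyes unannotated, no controlled fall, no long
vocalization), modeling the brief motor psychogenic events that the
evaluated rule missed — on a mixed cohort the PNES sensitivity is therefore
strictly below 1 while specificity stays high, qualitatively reproducing the
reported 50%/97% regime. `dialeptic` episodes are labeled focal but carry no
focality feature, reproducing the main sensitivity sink of the focality
rule. With the defining-feature probability at 0, each archetype emits a
*lookalike that misses its rule* (non-forced head turn, sub-threshold leads,
a gapped march, a short psychogenic event).

What the generator does **not** emulate: real inter-annotator variability,
body-part ambiguity, timing jitter against ground truth, co-occurring
multi-type semiology, or the archetype frequencies of any particular
clinical cohort (the default weights are a plausible mix, not a contract).
Passing tests therefore demonstrate that the rules implement their stated
logic on well-formed annotations — not clinical sensitivity or specificity
on real video.

## Evaluation statistics

Alert performance is scored as a standard 2×2 tally with sensitivity
`tp/(tp+fn)` and specificity `tn/(tn+fp)`; undefined denominators are
reported as such, never silently dropped. Confidence intervals are exact
Clopper–Pearson, computed via the beta-quantile identity
(`qbeta(alpha/2, x, n-x+1)` and `qbeta(1-alpha/2, x+1, n-x)`, with the
conventional 0 and 1 endpoints at `x = 0` and `x = n`). The choice is not
stylistic: the interval conventionally quoted for this rule set's
evaluation — 21.09–78.91% for 6 detections out of 12 — is the exact
interval (Wald and Wilson give different numbers), so the package fixes the
exact method. The tests verify the implementation against an independent
oracle that inverts the binomial tails by bisection, to 1e-6 on a grid of
`(x, n)`, plus a Monte-Carlo check that empirical coverage stays at or
above the nominal level. Worked examples start from detection *counts* and
recompute every percentage and interval from them, rather than carrying
pre-rounded percentages forward.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations as follows:
oracle agreement on 1,000 random clonic episodes of at most six behaviors;
archetype fidelity on 200 episodes per archetype; a 120-episode mixed cohort
for confound behavior; 500 episodes for feature-rate recovery (within
`3·sqrt(p(1-p)/n)` of the configured probability); 350–400 replicates per
`(p, n)` cell for CI coverage. All of it regenerates from seeds at run time;
nothing is stored. The command-line `simulate` subcommand refuses to run
without an explicit `--seed` and writes a run manifest next to its outputs.

## Known limitations

* The schema reproduces the scheme's behavioral table, not the full
  descriptor tree; subtype-level vocabularies (e.g., specific
  hand postures) are present only where a rule needs them.
* The focality rule neither localizes nor weighs criteria; it is a
  disjunction of highly specific features, inheriting their limited
  sensitivity.
* March detection sees only what was annotated: a march finer than the
  body-part taxonomy, or annotated as generic limb movement rather than
  clonic behavior, is invisible.
* The ±5-s/30-s "ended with" window and the 0.5 eyes-closed fraction are
  package choices where the source gives none; both are configurable and
  their defaults are stated here rather than hidden.
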