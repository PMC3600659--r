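---
title: "Models and methods behind prlterp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prlterp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlterp)
```

prlterp re-implements, as a tested reusable pipeline, the computational
chain used in studies of feedback-driven decision making in addiction: a
probabilistic reversal learning task (PRLT), its behavioural dependent
measures, feedback-locked ERP scoring (FRN, P3), and correlation-based
identification of cortical FRN sources. Because no participant data are
deposited for studies of this kind, the package ships first-class
synthetic generators — a reinforcement-learning cohort and a synthetic
EEG/current-density model — whose defaults define a single, documented
"stated world" against which every statistical routine is validated.
This vignette explains the models, the defaults, the numerical choices,
and what a green test does and does not establish.

## The task engine

The PRLT has four 40-trial phases. Within a phase one colour is the
"correct" option; choosing it is rewarded (+5 points) on a fixed
percentage of trials (75% or 87.5%, order counterbalanced across
participants) and punished (−5) on the rest (*false negative feedback*);
choosing the wrong option mirrors this. The correct colour flips at
every phase boundary and nowhere else.

Two design choices deserve emphasis:

* **Exact-count scheduling.** False feedback is pre-scheduled per phase
  by exact count — `round(p * 40)` veridical trials, positions
  shuffled — rather than drawn i.i.d. per trial. The printed
  contingencies (75%, 87.5%) have integer products with the phase
  length (30, 35), and exact counts make contingency checks
  deterministic: an always-correct chooser is rewarded on *exactly*
  75% of trials in a 75% phase. Configurations whose `p * trials`
  is non-integer are rejected.
* **The veridical flag is a property of the trial**, applied to
  whichever option is chosen. A single per-trial lottery keeps the
  schedule choice-independent and reproducible; the alternative (an
  independent lottery per option) would make the realised contingency
  depend on behaviour.

Trial/phase/block indices are 1-based in all logs. Screen geometry is
not modelled beyond a balanced-random left/right bit (half of each
phase's trials place the correct option on the left).

## The synthetic cohort

The reference behavioural analyses correlate two interview-derived
exposure composites with task measures: *intensity* = amount ×
frequency (per-month exposure) and *severity* = amount × frequency ×
duration (lifetime exposure), both rank-transformed within design to
de-skew them. The cohort generator draws exposure triples from
lognormal distributions (defaults: gamblers, median 30 units/episode,
12 episodes/month, 84 months; cocaine users, 1 g/episode, 10
episodes/month, 120 months) and feeds within-group rank scores
`u = (rank − ½)/n ∈ (0, 1)` into the agent's parameters.

The agent is a standard two-option delta-rule learner — this is
explicitly a stand-in: the behavioural study fits no model. Choice is
softmax with inverse temperature `beta`, an additive stickiness bonus
for repeating the previous choice, and a lapse probability of uniform
random choice; learning rates are valence-asymmetric (`alpha_gain`,
`alpha_loss`); rewards are normalised to ±1 inside the learner (points
are bookkeeping). Values start at zero and are **not** reset at
reversals, so reversal cost emerges from relearning. Decision latency
is `(base + conflict·(1 − |ΔV|) + intensity_gain·u) · exp(ε)` with
lognormal noise — slower under choice conflict and under higher
exposure intensity.

### Effect maps and their calibration

The stated world reproduces three reported effect directions:

| effect | carrier | default |
|---|---|---|
| severity ↓ asymptote | lapse `0.02 + 0.40·u_sev` | lapse up to ≈0.42 |
| intensity ↑ reversal cost | `alpha_loss 0.95 − 0.87·u_int` (floor 0.08), stickiness `+0.05·u_int` | first-block score ≈6.1 → ≈1.3 |
| intensity ↑ latency | `+350 ms · u_int` | ≈0–350 ms |

The defaults were fixed by simulation *before* the acceptance tests
were frozen, to satisfy the prescribed recovery property (each effect
detected at p < 0.05 in ≥80% of 100 replications at n = 21). Three
findings from that calibration are worth recording because they are
scientific properties of the task, not implementation detail:

1. **Noise-based asymptote suppression masks reversal cost.** Any
   mechanism that pushes asymptotic accuracy toward chance (lapse,
   low beta) *raises* first-block post-reversal scores, because a
   perseverating agent is below chance immediately after a reversal.
   Severity-driven lapse therefore works against the intensity effect
   in collinear participants; the partial correlations remove only its
   linear part.
2. **`alpha_loss` is non-monotone for reversal cost below ≈0.08.** With
   very slow loss learning the *punished wrong option* also retains its
   value during a phase, shrinking the end-of-phase value gap and
   paradoxically easing the next reversal. The effect map therefore
   floors `alpha_loss` at 0.08.
3. **Stickiness saturates.** Above ≈0.3 (on the value scale) a sticky
   agent also locks onto the *new* correct option quickly once sampled,
   and the first-block dose-response flattens, which is why stickiness
   is only a small secondary carrier here.

The operating regime (beta 15, `alpha_gain` 0.15, `alpha_loss` 0.95 at
baseline) makes reversals fast and nearly deterministic for unexposed
agents, giving the dose-response enough range (first-block ≈6 → ≈1.3
of 10) to be detectable at n = 21 over the irreducible trial noise
(SD ≈ 1.4 on the mean of three post-reversal blocks). The implied
default partial correlations (≈ −0.6) are *stronger* than those
reported for real cohorts (≈ −0.5, significant at exactly p = 0.05 at
n = 21); a paper-faithful effect size has only ~60% power at that
sample size, so the detection requirement dictates the stronger world.
Users wanting paper-scale effects should roughly halve the slopes.

Duration spreads (sdlog 1.5 / 1.2) keep the intensity–severity rank
correlation near 0.5–0.6. The two composites are algebraically coupled
(severity = intensity × duration); with narrow duration spreads they
correlate ≈0.85 and the two partial-correlation analyses become nearly
unidentifiable at n ≈ 21 — a caveat that applies equally to real
interview data.

## Synthetic EEG and ERP scoring

Feedback-locked epochs span −200 to +350 ms at 250 Hz (samples every
4 ms, t = 0 at feedback onset, so the last sample is at 348 ms).
Condition templates are sums of three *compact-support* Gaussian
components — a positive peak (150–220 ms, largest at FCz), a
valence-dependent FRN deflection (220–350 ms, largest at FCz), and a
late P3 (largest at Pz) — plus per-channel 1/f-like and white noise.
Compact supports make every windowed score analytically computable, so
the zero-noise round trip is exact to machine precision: the NF
deflection amplitude is solved per participant from the configured
differential via the window mean of the unit bump on the actual sample
grid.

Scoring follows the reference pipeline exactly:

* **Artifact rejection**: an epoch is excluded iff any sample on any
  channel is *strictly* outside ±100 μV ("outside the range" is read
  as strict; a sample at exactly 100 μV is retained — the boundary
  decision is documented and tested on an amplitude grid). Retention
  below 27 NF / 51 PF epochs warns but does not abort: those numbers
  were empirical minima in the reference cohort, not rules.
* **FRN per condition** = mean amplitude in 220–350 ms minus the
  *maximum sample* in 150–220 ms (inclusive bounds; the maximum is
  used even when negative, with a warning). The differential FRN score
  is PF − NF.
* **P3 per condition** = mean of the last 50 ms referenced to the mean
  of the preceding 100 ms; the differential is NF − PF (note the
  opposite order).
* Averages are baseline-corrected to the −200..0 ms mean. The FRN is
  peak-referenced and hence offset-invariant; baseline correction
  matters only for display and for the P3 reference logic.

Two known properties of these estimators, visible in the tests:

* **P3 contamination.** The FRN deflection overlaps both P3 windows,
  so even with identical P3 templates the P3 differential picks up a
  small FRN leakage term — precisely the contamination that motivates
  referencing the last 50 ms to the preceding 100 ms. The zero-noise
  test asserts the analytic leakage value rather than zero.
* **Peak-reference bias.** The windowed maximum is upward-biased under
  noise, and the bias is larger for the condition with fewer trials
  (NF), leaving a small *positive* bias in the differential. At the
  default noise (white 1.5 + pink 2.5 μV per sample) the bias is
  ≈0.05 μV; at realistic single-trial noise it reaches ≈0.1–0.15 μV.
  The defaults are chosen so the unbiasedness invariant (<0.1 μV)
  holds; the mechanism itself is a caveat for real data.

Ocular artifacts are *not* synthesised (ICA-based correction is out of
scope; epochs are generated ocular-clean); only amplitude artifacts are
injected, to exercise rejection. The noise model is 1/f + white only —
no alpha peaks, no line noise, no channel covariance — so green ERP
tests establish correctness of the scoring arithmetic, not robustness
to real EEG pathology.

## Current-density maps and source mapping

The package consumes (and synthesises) participant × voxel
window-averaged current densities; it does not solve an inverse
problem. The source-mapping procedure is the reference three-step
rule: (1) average each voxel's activation over 220–330 ms (note: the
source window deliberately differs from the 220–350 ms scoring
window, matching the reference procedure); (2) correlate, across
participants, each voxel's density with the differential FRN score at
FCz; (3) single out areas in which at least 10 voxels correlate
significantly (p < 0.05, two-sided, no further voxelwise multiplicity
correction). Counts are reported for *all* areas because the reference
table itself lists areas with 4 and 9 significant voxels despite the
stated ≥10 rule; users can apply either convention.

The generator draws, for each voxel of area *a* with target correlation
ρₐ, `density = offset + scale·(ρₐ·z + e)` with `z` the standardised FRN
vector and `e` unit-variance noise split 70/30 into an area-shared and
a voxel-specific part. The shared part models the spatial smoothness of
distributed inverse solutions; it leaves each voxel's marginal
correlation at ρₐ but makes voxels within an area rise and fall
together, which is what lets an area pass or fail the 10-voxel rule as
a unit (with fully independent voxels, "all 10 voxels significant"
would only occur in ≈0.97¹⁰ ≈ 74% of cohorts even at ρ = −0.70).
Control-group targets are the reference values (BA9 −0.70, BA10 −0.75,
BA13 −0.71, BA23 −0.75, BA46 −0.74) plus two null areas; clinical-group
targets mirror the reference clinical tables.

Cross-group comparisons of correlations use the independent-samples
Fisher-z test with Bonferroni correction over the five reference areas
(the reference text does not name its test; Fisher-z is the standard
choice). Bootstrap p values for voxel correlations (percentile, 2000
replicates, seedable) are provided because the reference analysis
mentions bootstrapping without parameters; parametric t-based p values
are the default and the two agree in rejection decisions for strong
effects.

## Repeated-measures inference

`mixed_anova()` and `ancova_rm()` implement the classical univariate
repeated-measures approach via orthonormal within-subject contrast
projection: per-subject cell means are projected onto Kronecker
products of orthonormal contrasts (effect factors) and normalised unit
vectors (averaged factors); each within stratum is a multivariate
linear model on the between-subject design, and the averaged univariate
F equals the textbook mixed-model F in balanced designs (verified
exactly against `stats::aov`). Between-subject hypotheses are Type III
(sum-to-zero coding), which matters for the unbalanced default group
sizes (23/21/20).

Greenhouse–Geisser epsilon is computed from the stratum residual
covariance (equivalently, Box's epsilon of the double-centered
covariance), clamped to `[1/(k−1), 1]`. Following the reference
convention ("where it was necessary"), the correction is applied only
when Mauchly's test rejects sphericity at α = 0.05; both corrected and
uncorrected p values are reported. One mathematical caveat: for F < 1
the GG-adjusted p can be *smaller* than the unadjusted p (shrinking
both dfs is not monotone there); the adjustment is conservative
exactly where significance decisions live (F ≥ 1).

ANCOVA covariates are centered before entering the design; covariate
main effects are tested in the between-subject stratum and
covariate × within interactions either modelled (default) or pooled
into error — the reference text does not say which was done, so both
modes exist. Post hocs are pairwise pooled-variance t tests (LSD raw,
or Bonferroni-multiplied), matching the reference's reported
`t(n₁+n₂−2)` statistics.

## Determinism and seeds

Every stochastic operation takes an explicit seed and restores the
caller's RNG state. `run_study()` derives labelled stage seeds from a
single master seed (`derive_seed(master, label)`, a 31-bit polynomial
hash), so the full bundle is byte-identical across reruns and any stage
can be reproduced in isolation. The report writer excludes wall-clock
timing from the serialized summary for this reason.

## Known limitations

* The agent is a convenience model: no claim is made that participants
  implement asymmetric delta-rule learning, and alternative carriers of
  the reversal-cost effect (e.g. perseveration) are plausible.
* The EEG generator's value is analytic tractability, not realism; it
  cannot validate preprocessing choices (filtering, re-referencing,
  ICA), which are out of scope.
* The voxel grid is abstract (area label + index); no atlas handling,
  no 6239-voxel standard grid, no inverse solution.
* Group-level F statistics of the reference study are not reproducible
  targets (the participant data are unavailable); the pipeline instead
  validates against exact task arithmetic, hand-computable oracles,
  sampling-distribution calibrations, and direction-recovery
  properties.
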