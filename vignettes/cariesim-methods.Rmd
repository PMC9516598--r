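---
title: "Methods: a lifetime caries microsimulation with value-of-information analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime caries microsimulation with value-of-information analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesim)
```

## The decision problem

A dentist screens posterior teeth for proximal caries with a yearly
visual-tactile examination and bitewing radiographs every second year. A
CNN-based detector can support the radiograph read at a fee of 4–12 EUR per
application. Better sensitivity for initial lesions means more lesions are
arrested cheaply by resin infiltration instead of progressing to restorative
care; worse specificity means more sound surfaces are treated unnecessarily —
and an unnecessary restoration exposes the tooth to the whole downstream
failure cascade. Whether AI support pays off therefore depends on accuracy
(which itself depends on how much data the model was trained on), on the fee,
and on how much disease there is to find (the cohort's risk profile). The
package quantifies both the cost-effectiveness of the two strategies and the
monetary value of *resolving* each of those uncertainties before deciding.

## State machine and cycle semantics

Each tooth is simulated independently in discrete annual cycles over a
66-year horizon (the expected remaining lifetime of a 12-year-old's
posterior tooth). One lesion per tooth is modeled. The states and allowed
transitions are:

* **Natural progression** (one step per cycle): `SOUND → E2 → D1 → D2D3`,
  with per-cycle probabilities multiplied by the risk profile's progression
  multiplier (capped at 1). `ARRESTED` lesions may relapse to `D1`.
* **Treatment on detection**: initial lesions (E2, D1 — radiograph-only
  detections) are infiltrated and become `ARRESTED`; advanced lesions
  (D2–D3, detected radiographically or visual-tactilely) are restored.
* **Failure cascade**: `RESTORED` accumulates failures (each resolved as
  repair with probability `p_repair = 0.5`, otherwise replacement); the
  k-th failure (default `k = 3`) places a crown. A failed crown is replaced
  once; its second failure moves to root canal treatment, as do endodontic
  complications arising in `RESTORED`/`CROWNED` (drawn first in each cycle,
  with the same annual probability in both states). Root-filled teeth fail
  to nonsurgical and then surgical retreatment; when the surgical retreat
  fails no options remain and the tooth is extracted and replaced by an
  implant-supported crown — the absorbing state.

The within-cycle order is fixed and documented for reproducibility:
examination fees, then examination and treatment decision, then natural
progression, then treated-state failure draws. Retention years count the
cycles a tooth enters alive; there is no half-cycle correction. Costs are
discounted by the whole-year index of the cycle in which they occur
(`cost/(1+r)^t`, 3% per annum in the base case); retention is *not*
discounted — costs accrue over the lifetime while the effectiveness measure
is reported against the undiscounted 66-year horizon.

Two equivalent engines implement the walk: a compiled Rcpp cohort loop used
by `run_cohort()`/`run_psa()` and a readable per-tooth R reference
(`simulate_tooth()`, also the source of full cost-event traces). Both use
R's RNG, are bit-identical under forced (0/1) probabilities and are
cross-checked distributionally in the test suite.

## Screening and the harm pathway of false positives

On a radiograph cycle the radiographic read (dentist's or AI's
depth-specific sensitivity) and the visual-tactile read (advanced lesions
only) are combined by logical OR. Sound *and arrested* surfaces can be
falsely flagged with probability one minus specificity; a false positive
asserts a stage — advanced with probability `fp_advanced_share = 0.2`
(restoration: the tooth enters the failure cascade), initial otherwise
(infiltration fee, surface unchanged). This staging rule is a modeling
choice: some acted-on false positive pathway must exist for specificity to
matter at all, and treating one in five as advanced keeps the harm channel
present without dominating. Both strategies charge the same exam fees; only
the AI fee differs between arms.

The AI fee is charged per *application* on radiograph cycles and shared
across the teeth one application covers (`ai_teeth_per_application = 6` in
the fixture). This matters: charging the full fee to every simulated tooth
every second year would make the fee stream (~120 EUR discounted) the
dominant driver of the comparison, whereas the published sensitivity
analyses show lifetime costs moving by only ~20 EUR across the 4–12 EUR fee
range — consistent with a shared fee and with the finding that resolving
the fee's uncertainty is worthless.

## Parameters, uncertainty and the calibrated fixture

All inputs live in a fixture (`make_fixture()`, serialized as YAML with
bit-exact round trips). Scalars carry point, uniform or triangular
uncertainty; the PSA draws every uncertain input independently per draw
(no correlation structure is asserted). Base-case uncertain inputs:

* transition probabilities — triangular, mode ±30%;
* dentist and visual-tactile accuracy — triangular around meta-analysis-scale
  values (dentist sensitivity 0.30/0.40/0.65 for E2/D1/D2–D3, specificity
  0.982; visual-tactile sensitivity 0.35 for D2–D3 only);
* AI accuracy — triangular around a saturating learning curve (below);
* the AI fee — uniform 4–12 EUR per application (published range);
* the cohort risk profile — an equal-probability draw between the low- and
  high-risk cohort (deliberate maximum uncertainty about deployment);
* the training-data fraction — an equal-probability draw over
  {10%, 25%, 50%, 100%}, each carrying its own accuracy distributions.

The AI learning curves follow
`floor + (asymptote − floor)(1 − exp(−rate · f))` with triangular
half-widths shrinking exponentially in `f`: accuracy grows monotonically
with training data, the largest gain is from 10% to 25%, and uncertainty
shrinks as data grow. The constructor rejects rates too small to satisfy
the diminishing-returns property. Sensitivity curves use rate 7
(floors 0.50/0.60/0.76, asymptotes 0.74/0.80/0.92 for E2/D1/D2–D3); the
specificity curve uses rate 4 (floor 0.950, asymptote 0.985), so that with
little training data the AI is *less* specific than the dentist — the
mechanism that makes AI support more costly in low-risk cohorts at small
training fractions — while matching dentist specificity at full data.

Because the originating study's supplementary appendix (exact transition
probabilities and accuracy-by-fraction tables) is not publicly available,
all values above except the published ones (fee range, 3% discounting,
66-year horizon, exam schedule, cohort sizes) are synthetic. They were
calibrated once, as the package's study conditions, so that the comparator
arm reproduces the published cohort-level outcomes (lifetime cost and
retention of the dentist-only arm in low-risk, high-risk and mixed cohorts)
and the published qualitative structure (AI dominant in the base case; AI
more effective but more costly in low-risk cohorts at 10–25% training
data; fee uncertainty worthless). The fixture manifest records per-field
provenance (`published` vs `synthetic`). A second, generator-jittered
`"synthetic"` variant exists to exercise the pipeline away from the
calibrated point.

## Cost-effectiveness and value-of-information estimators

Per draw, each strategy's cohort means (cost, retention) are one PSA sample
of the expected outcomes; summary intervals are 2.5–97.5 percentiles across
draws of these per-draw means (within-cohort percentiles across teeth are
reported separately by `run_cohort()`). Strategies within a draw share the
cohort sub-seed by default (common random numbers), reducing the variance
of incremental estimates; all sub-seeds derive deterministically from one
root seed.

* **ICER / dominance**: `icer()` labels cheaper-and-more-effective as
  dominant rather than reporting a negative ratio.
* **CE-plane quadrants**: boundary draws count toward the more-effective
  and less-costly sides, so shares always sum to 1.
* **CEAC**: at each willingness-to-pay λ (grid 0–100 EUR per retention
  year), the probability a strategy attains the strictly highest
  NMB = λ·e − c; exact ties split equally.
* **EVPI**: mean over draws of the per-draw best NMB minus the best mean
  NMB. λ = 0 is the headline threshold (no accepted willingness to pay per
  retention year exists), where EVPI depends on costs alone.
* **EVPPI**: single-loop conditional-mean estimator — draws are grouped by
  the recorded parameter value (exactly for the discrete risk profile and
  training fraction; 10 quantile bins for the continuous fee), the best
  strategy is chosen per group mean, and the frequency-weighted gain over
  the unconditional optimum is reported. Unbiased for discrete parameters
  and standard for low-cardinality designs; a nested two-level Monte Carlo
  estimator would add cost without benefit here. Grouping estimators are
  biased upward by within-group noise, which shrinks with the number of
  draws — another reason the headline runs use 500+ draws.
* **Monte Carlo error**: nonparametric bootstrap over draws (default 200
  resamples) attaches standard errors to every VOI curve point.

All VOI quantities are per individual, on the same per-tooth-cohort scale
as costs; population scaling is out of scope.

## Problem sizes and numerical checks

The headline configuration is 1,000 teeth per cohort per draw and 500 PSA
draws (seconds on one CPU with the compiled engine); the test suite uses
cohorts of 50–1,500 teeth and 4–500 draws depending on what a check needs.
Verification includes exact hand-traced forced cascades, a closed-form
collapsed-chain retention oracle (two geometric phases plus a deterministic
cascade tail, evaluated by exact tail summation), exact brute-force
enumeration oracles for EVPI/EVPPI/CEAC on small tables, closed-form exam-fee
streams, binomial rate checks at n = 10^5, and byte-exact seed
reproducibility of full PSA runs.

Degenerate inputs are handled explicitly: point distributions sample
constantly; a parameter draw outside a probability bound raises an error
rather than being clamped; zero-probability configurations leave states
unchanged; the absorbing state rejects further steps.

## What the synthetic fixture does and does not show

Passing tests on the calibrated fixture demonstrate that the *machinery* —
state machine, accuracy propagation, economics, VOI estimators — behaves
correctly and that the published qualitative findings emerge from inputs
with the published structure. They do not validate the synthetic parameter
values against clinical data: absolute euro and retention levels track the
published outcomes only because the generator was calibrated to them, and
real-data features the generator does not emulate include correlated
parameter uncertainty, heterogeneity within a risk cohort, dentists
deviating from AI suggestions, treatment options beyond the modeled
cascade, and patient-level effects (mortality, adjacent-tooth interactions,
multiple lesions per tooth). Cost-utility analysis is deliberately out of
scope; retention years are the sole effectiveness measure.
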