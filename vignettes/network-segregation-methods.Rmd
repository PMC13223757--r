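---
title: "Network segregation and behavior: models, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network segregation and behavior: models, pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsegfc)
```

## The scientific question

Resting-state functional connectivity (RSFC) describes how the brain is
organized when it is not doing any particular task: the time series of
hundreds of regions of interest (ROIs) are correlated, and the resulting
matrix is summarized at the level of functional networks. A network is
*segregated* when its ROIs talk mostly to each other and only sparsely to
the rest of the brain. For a network $k$ with mean within-network Fisher-z
connectivity $W_k$ and mean connectivity $B_k$ from its ROIs to all ROIs
outside it, the segregation index is

$$S_k = \frac{W_k - B_k}{W_k},$$

a unitless proportion: 1 means a perfectly isolated module, 0 means the
network is indistinguishable from its surround. This package implements a
complete, testable pipeline that relates $S_k$ (over a 300-ROI, 14-network
parcellation; 13 networks are analyzed, the unassigned ROIs are excluded
from network-level means) to a behavioral outcome — the success of
cognitive reappraisal, scored as the drop in negativity ratings when
down-regulating versus naturally viewing negative images — across a wide
age range, controlling for head motion and for linear and quadratic age.

Because individual human imaging data cannot ship with a package, the
first-class citizen here is a synthetic cohort generator with planted,
recoverable ground truth. Every stage of the pipeline is exercised against
that truth.

## Processing model

**Motion censoring.** Framewise displacement (FD) is computed from the six
realignment parameters as the sum of absolute backward differences, with
rotations converted to arc length on a 50 mm head radius (the standard
convention). The FD trace is low-pass filtered (zero-phase second-order
Butterworth, default cutoff 0.1 Hz) before thresholding, because at short
repetition times raw FD is dominated by high-frequency pseudo-motion;
censoring decisions use the filtered trace, while the subject-level mean
FD covariate is the mean of the filtered FD over *all* acquired frames
(the source analyses do not state which frames enter that mean; using all
frames makes the covariate independent of the censoring outcome). The
cascade is then: censor frames with FD > 0.2 mm (a frame exactly at
threshold is kept — "greater than" is read strictly); remove retained
islands shorter than 5 frames (exactly 5 is kept); fully censor runs with
fewer than 50 retained frames (exactly 50 is kept); finally keep the first
800 retained frames in acquisition order and censor the rest, flagging
subjects who cannot reach 800 frames as ineligible rather than erroring.
The fixed 800-frame selection (13.3 minutes at TR = 1 s) equalizes data
quantity across subjects, which matters because correlation estimates — and
therefore segregation — are biased by sampling variance that depends on
frame count.

**Time-series cleaning.** The order is fixed: per-run demeaning and linear
detrending; nuisance regression (global signal, optional CSF/WM channels,
and a 24-parameter motion block: 6 realignment parameters, their first
differences, and the squares of those 12); linear interpolation across
censored frames; zero-phase band-pass at 0.009–0.08 Hz. The nuisance fit
uses retained frames only, so high-motion frames cannot leverage the
coefficients; residuals are then computed for all frames so the
interpolation and filter see a complete series. Interpolated frames exist
only to stabilize the filter and are re-censored before any correlation is
computed. Interpolation is linear between nearest retained neighbours
(nearest-value at run edges); spectral interpolation would be a reasonable
extension but the simpler scheme is transparent and is only ever applied
to frames that are later discarded. Both filters use an odd-reflection
padded forward–backward Butterworth, so constants map to themselves and
edge transients do not leak into the retained frames.

**Connectivity and metrics.** Pearson correlations over exactly the 800
selected frames (concatenated across runs — the selection is defined over
the concatenation, so correlating per run and averaging would not match
it), Fisher z-transform, then negatives set to zero before any averaging.
Zeroing rather than excluding matters: global-signal regression introduces
spurious negative correlations, and the zeros still count in the
denominators of $W_k$ and $B_k$. $B_k$ is brain-wide by default (it
includes unassigned ROIs, since "all other ROIs in the brain" is the
defining phrase); a `betweenMode = "labeled"` switch restricts it to the
13 labeled networks, and pairwise means $B_{kj}$ always use labeled
networks. Whether the original brain-wide mean included unassigned ROIs is
genuinely unstated; the switch records the ambiguity instead of hiding it.

## Association models

Reappraisal success (standardized) is modeled from each network's
segregation with standardized age and its square as covariates, after the
subject-level mean FD has been regressed out of every RSFC measure,
cohort-wide, once. The quadratic age term is the square of standardized
age, not orthogonalized against the linear term — the source analyses
report both terms in one model without orthogonal polynomials, and the
un-orthogonalized parameterization keeps coefficients interpretable;
orthogonalization would change individual coefficients but not the overall
fits. RSFC predictors stay on their residualized (not re-standardized)
scale; recovery checks therefore compare *standardized* coefficients
(`B * sd(x)` with the response standardized) against planted effects.

Two multiplicity columns are reported for the 13 per-network models:
Benjamini–Hochberg over the 13 overall-model F p-values (the convention of
the source analyses), and BH over the 13 segregation-coefficient p-values.
The distinction is substantive: with a real quadratic age effect in every
model, all 13 overall fits are significant and the overall-model column
cannot distinguish networks; the segregation-coefficient column is the
correction that answers "which network". Within/between follow-up models
add the two connectivity terms and their interactions with linear age
(quadratic-age interactions are available behind a flag, default off,
matching the reported single interaction rows).

**Selection with stability.** For the seed network's between-network
effect, 15 candidates (its within connectivity, 12 pairwise between
terms, linear and quadratic age) enter augmented backward elimination:
at each step the candidate whose removal most lowers the AIC is dropped,
and a drop can be vetoed if it would change a *passive* (protected)
term's coefficient by more than `tau = 0.05` of its magnitude (floored at
its SE). The veto deliberately guards passive terms only: guarding every
remaining candidate's near-zero coefficient at a relative threshold vetoes
essentially every drop, which freezes the full model and contradicts both
the intended "most pure-noise candidates are eliminated" behavior and the
published stability profiles this mirrors. With only the intercept
passive, the procedure behaves as backward elimination by AIC; `tau = Inf`
makes that reduction exact. Stability is then assessed by rerunning the
selection on bootstrap resamples (1000 in the full protocol; smaller
values are used in examples and tests purely as problem-size choices):
inclusion frequency, zero-filled bootstrap percentiles, the RMSD ratio
(spread of zero-filled bootstrap estimates around the full-model estimate,
relative to the full-model SE), and the relative conditional bias (mean
selected-only estimate versus the full-model estimate, in percent).
Unselected candidates contribute zeros to the unconditional summaries,
matching the convention of reporting 0 for terms absent from the selected
model.

## The synthetic cohort

The generator is layered so that every downstream stage has a recoverable
truth:

1. **Ground truth.** Ages are uniform on 6–80 (n = 227 by default).
   Subject-level within-network Fisher z is drawn around 0.5 (SD 0.10) per
   network, between-network z around 0.1 (a shared level with SD 0.01 plus
   pair-specific SD 0.05). True segregation follows from these by the
   defining formula, with ROI-count weighting for the brain-wide between
   mean. True success is
   `1.02 + 0.75 * (β_age2 (z_age² − mean) + Σ β_k z(S_k) + noise)`,
   with the residual noise completing the standardized latent to unit
   variance by default; the defaults plant a single segregation effect
   (DMN, 0.35 standardized) and a quadratic age effect (−0.25), the
   magnitudes the pipeline is designed to detect, with success calibrated
   to mean 1.02, SD 0.75 on the rating-difference scale.
2. **Measurement.** Measured metrics are the true ones plus frame-budget
   sampling noise (SD 0.02 for within-z, 0.005 per between pair) plus a
   motion confound: standardized mean FD inflates measured between-network
   z (slope 0.013), which induces the negative segregation–FD correlation
   of about −0.4 that FD residualization is designed to remove. The
   confound lives in the *measurement*, not in the truth — motion corrupts
   what we observe about a brain, not the brain — which is exactly why
   residualizing on FD recovers rather than attenuates planted effects.
3. **Time series.** For full-pipeline runs, each subject's runs are drawn
   from the block covariance implied by their within/between targets
   (equicorrelated within blocks, constant across each block pair — the
   simplest structure with a closed-form segregation limit; positive
   definiteness is checked at the Cholesky factorization). On top: a
   shared global component (amplitude 1), per-ROI linear drifts (SD 0.5),
   and at motion-spike frames a large spatially heterogeneous artifact
   with a spin-history-like 4-frame decay tail. The tail is the part
   motion regressors cannot capture (the regressors are back at baseline
   while the artifact persists), which is precisely the part frame
   censoring removes — without it, motion regression alone would make
   censoring redundant in the simulation, which real data says it is not.
4. **Motion.** Realignment traces are a slow random walk (0.01 mm/frame)
   plus sparse one-frame displacement spikes (rate 0.02/frame at 0.6 mm,
   subject rates log-normally scattered around that), stored as three
   rotations in radians then three translations in mm.
5. **Behavior.** 20 trials per condition; Look-Negative around latent 3.5,
   Look-Neutral around 1.5, Decrease at 3.5 minus the subject's true
   success; trial noise (SD 0.6) on the latent scale, then rounding half
   away from zero and clipping to the 1–5 integer scale. Rounding before
   averaging mimics real button-press responses; it (together with trial
   noise and clipping) attenuates standardized planted effects by a few
   percent, which is visible as a small, expected negative bias in
   recovery simulations.

What the generator does *not* emulate: hemodynamics, spatial structure
within ROIs, task-evoked signal, distance-dependent artifact profiles,
non-Gaussian rating styles, and any dependence of true connectivity on
age. Passing tests therefore demonstrate that the *pipeline* is correct
and well-calibrated under a faithful statistical model of the study
design — not that the scientific findings would replicate in new human
data.

## Numerical choices and degenerate inputs

- Filters: second-order Butterworth, forward–backward (zero phase), with
  odd-reflection end padding; cutoffs at or above Nyquist are errors.
- A fully censored run cannot be interpolated (error); a subject below
  800 frames is a flagged exclusion, never an exception.
- Zero-variance ROI columns abort correlation with the ROI named;
  `W_k <= 0` yields a flagged missing segregation with a warning, and the
  subject drops out of that network's model only.
- Collinear nuisance columns are dropped with a warning; collinear model
  designs are errors naming the offending columns.
- Rank-deficient bootstrap resamples are redrawn and counted.
- Ties in AIC-drop candidates resolve in candidate order; selection stops
  when no admissible drop lowers AIC, so the selected AIC never exceeds
  the full-model AIC.

## Problem sizes

Simulation-based checks in the test suite use cohort sizes of 227 (the
design size) for model-level recovery, 500 replicates for bias/coverage,
50 replicate subjects at 800 frames for the closed-form segregation
check, 200 bootstrap resamples for selection stability, and a 20-subject
demo cohort for the end-to-end pipeline — sizes chosen to estimate each
quantity with comfortable margin while keeping a full run on one CPU in
minutes.

## Known limitations

- The cleaning stage includes global-signal regression, which shifts all
  correlations downward; measured segregation after the full pipeline is
  therefore compressed toward 1 relative to the planted block truth (the
  negative between-z mass is zeroed). Subject ranking — what the
  association models consume — is preserved, and the closed-form checks
  are run on the raw block draws where the limit is exact.
- Linear (not spectral) interpolation under the band-pass slightly colors
  the spectrum at censored locations; immaterial here because those
  frames are re-censored.
- The t-test on network-averaged task-contrast values supports both a
  subjects axis (df = n_subjects − 1, the default) and an ROI axis
  (df = n_ROIs − 1); published network tests of this kind sometimes report
  ROI-axis degrees of freedom, and the switch records that ambiguity.
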