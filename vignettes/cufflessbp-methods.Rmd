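---
title: "Cuffless blood-pressure estimation: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufflessbp)
```

## The problem

Continuous, cuff-free blood-pressure monitoring estimates systolic and
diastolic pressure (SBP/DBP, mmHg) from signals that are cheap to acquire
continuously: a single-lead ECG and a fingertip photoplethysmogram (PPG).
The physiological basis is pulse-wave propagation: stiffer, more pressurized
arteries transmit the pulse faster (shorter pulse transit time, PTT) and
reshape the pulse waveform (narrower widths, altered diastolic runoff).
`cufflessbp` implements that estimation chain end to end: waveform cleaning
and landmark detection, beat-level morphological features, an
information-theoretic feature selector built on multivariate symmetric
uncertainty (MSU), an elastic-net regression, and standards-based grading of
the resulting errors.

Because the waveform corpora used in this literature are large, access
controlled, and screened by hand, the package ships a first-class synthetic
cohort generator with exact ground truth. Every stage is tested against that
generator; what those tests do and do not establish about real data is
discussed at the end.

## Signal model and preprocessing

**ECG.** Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) at fixed
physiologic offsets, so R-peak locations are exact by construction. Cleaning
applies, in order: a zero-phase Butterworth high-pass at the passband's low
edge (0.5 Hz default) for DC/baseline rejection, an FIR band-stop notch at
the powerline frequency (50 Hz default, 60 Hz configurable), an order-50
linear-phase FIR band-pass, and a 5-sample centered moving average. The FIR
order is forced even so the group delay is exactly `order/2` samples and is
compensated by an integer shift; at 125 Hz and order 50 that shift is
0.200 s (one reported value in the literature is 0.196 s for the same
configuration; the analytic `order/2` value is used here). The separate
high-pass stage exists because an order-50 FIR at 125 Hz has a transition
band of roughly 2.5 Hz and cannot itself realize a 0.5 Hz cutoff.

**QRS detection** is classic Pan–Tompkins: 5–15 Hz band-pass, five-point
derivative, squaring, 150 ms moving-window integration, dual adaptive
thresholds with search-back, a 200 ms refractory period, and refinement to
the local ECG maximum. On noise-free synthetic records it recovers every
beat within 3 samples; with 5% amplitude noise its F1 at a 5-sample
tolerance stays above 0.99 (both properties are asserted in the test suite).

**PPG landmarks.** The systolic peak is located on a Daubechies-3
wavelet-denoised copy of the signal (periodized DWT, universal soft
threshold; the db3 shape resembles a pulse upstroke). Around it the detector
places the foot (preceding local minimum), maximum-slope point, dicrotic
notch (first local minimum after the peak, with a second-derivative
zero-crossing fallback for weakly pulsatile beats), and diastolic peak.
Derived timings are crest time (foot to peak), delta-T (interval between
successive positive-to-negative zero crossings of the first derivative), and
the second-derivative a–e wave amplitudes. Beats with missing or mis-ordered
landmarks are flagged and masked, never imputed.

## Features and targets

Per beat the package computes heart rate, normalized pulse amplitudes and
their ratio, PTT from the R peak to a configurable anchor (maximum-slope
point by default — the common pulse-arrival-time definition; foot and
systolic peak are alternatives), systolic and diastolic times, pulse widths
at fractions 1/10, 1/4, 1/3, 1/2 of the peak amplitude split into systolic
and diastolic parts (linear interpolation at threshold crossings gives
sub-sample accuracy; widths are provably monotone in the fraction), total
widths at 2/3 and 3/4, the a–e amplitude ratios b/a, c/a, e/a, (b−e)/a, and
ECG wave durations/amplitudes. Reference SBP/DBP are the per-beat maximum
and minimum of the synchronized arterial-pressure channel. Widths measured
at a low fraction can fail to recross the threshold before the next beat at
fast heart rates; such widths stay masked for that beat.

Beats are aggregated to analysis windows by the per-feature median (default
one 30 s window per record in the shipped configurations), which is robust
to isolated detection errors; a window needs at least 5 accepted beats, and
a feature masked in more than half of a window's beats stays masked.

## Dependence measures

All entropic quantities use plug-in (maximum-likelihood) estimates on
discretized variables, base-2 logarithms, and the convention 0·log 0 = 0:

* entropy `H(X)`, conditional entropy `H(X|Y) = H(X,Y) − H(Y)`,
  mutual information `MI = H(X) − H(X|Y)`;
* symmetric uncertainty `SU = 2·MI/(H(X)+H(Y))` in [0, 1];
* joint entropy of n variables and total correlation
  `C = Σ H(X_i) − H(X_{1:n})`;
* multivariate symmetric uncertainty
  `MSU = n/(n−1) · (1 − H(X_{1:n}) / Σ H(X_i))`, which reduces exactly to SU
  at n = 2 (asserted to 1e-12 over randomized inputs).

Continuous features are discretized by equal-frequency binning with
`max(2, floor(sqrt(n)/2))` bins capped at 10; ties are broken by value
order and edges are stored for reuse on held-out data. No bias correction
is applied. The joint-table estimator carries a capacity guard (at most 1e7
potential cells); multivariate MSU over larger surviving sets is evaluated
at coarser bins so the guard always holds.

## The hybrid selector

**Step 1 (relevance).** Every feature's SU with the target is computed
(pairwise MSU equals SU) and features are ranked. The default relevance rule
is a chi-square independence test on the plug-in MI — under independence
`2·n·ln2·MI` is asymptotically chi-square with `(r−1)(c−1)` degrees of
freedom — at significance 0.001. A fixed SU threshold is also supported.
The test-based default was chosen after an analysis of the additive
synthetic target: when k features contribute comparable variance shares,
each feature's SU is bounded near `~1/k` of the total dependence budget
(about 0.06–0.10 at five contributors, for any bin count), so any fixed
threshold of ~0.1 either rejects genuinely relevant features or, if set very
low, floats dangerously close to the estimation-bias floor that grows as
`(bins−1)²/n`. The chi-square rule tracks that floor automatically for the
bin counts and sample size in hand.

**Step 2 (redundancy).** Walking the relevant set S1 in SU order, a
lower-ranked feature `f_j` is marked redundant to a kept feature `f_i` when
`SU(f_i, f_j) ≥ p · SU(f_j, target)`. The constant p starts at 2.0 and is
reduced by 0.1 per round down to 1.0; after each round the MSU of the
surviving set plus target is computed and the schedule stops early once it
reaches 0.05 ("near zero"). In practice a set containing genuinely relevant
features keeps a substantial MSU with the target, so the schedule typically
runs to the floor — the stop matters for weakly dependent tables. Every
removal is recorded in an audit log (which feature displaced which, at which
p), making the reduction reproducible from the log alone. The start value
of p and the stopping constant are configuration defaults; both are
free parameters of the procedure with no canonical published value.

**ReliefF.** The continuous pressure target is discretized into 5 quantile
classes so the multiclass weight update with class priors applies. For each
instance the k = 10 nearest hits and, per other class, k nearest misses are
found under Manhattan distance on min-max-scaled features, and each
feature's weight is decreased by its mean diff to hits and increased by the
prior-weighted mean diff to misses, normalized by `m·k` (all instances are
sampled by default). A pre-ranking step by SU exists to cut the cost of the
neighbor scans on wide tables, but its default is to keep *all* features:
a marginal-SU cut is blind to pure interactions — an XOR-style pair has
chance-level marginal SU — and interactions are precisely what ReliefF
contributes over the fast-correlation filter. On 12-feature tables with a
planted sign-product pair, ReliefF ranks both members above every noise
feature in ≥90% of seeds (asserted).

**Fusion.** The FC-MSU order and the ReliefF order are combined by mean
rank (features absent from one list get its worst rank + 1; ties break by
the FC rank, then column order) and the top 12 features proceed to
regression. Twelve is the conventional final list length for this feature
family; the fusion rule itself (mean rank) is a design choice, as no
canonical combination rule exists.

## Regression

The elastic net minimizes
`SSE + λ·α·Σ|β_j| + λ·(1−α)/2·Σβ_j²` by cyclic coordinate descent with
soft thresholding; α = 1 is the lasso, α = 0 ridge, λ = 0 ordinary least
squares. One shared λ scales both penalty terms — the α = 0/1 limits only
make sense on a shared scale. Predictors are standardized internally and
the response centered; coefficients are reported on both scales. The
objective is asserted non-increasing every sweep; convergence is declared
when the largest coefficient change falls below 1e-7 (10,000-sweep cap).
Correctness is pinned by closed forms — OLS at λ = 0, the ridge solution
`(XᵀX + λ/2·I)⁻¹Xᵀy` at α = 0, soft thresholding at λα/2 on orthonormal
designs at α = 1 — by KKT optimality checks at intermediate α, and by an
independent solver comparison for the lasso.

Model selection is seeded k-fold cross-validation over a grid of (λ, α),
minimizing mean held-out MSE (a one-standard-error option exists). Fits are
warm-started down the λ path, and the final model is refit with the same
warm-started path, so the returned estimator is the one the CV error
actually measured — without warm starts, ill-conditioned small-λ fits stop
early and CV silently scores a different (implicitly regularized) estimator
than the final refit. Grids default to 50 log-spaced λ in [1e-3, 1e3] and
α ∈ {0, 0.25, 0.5, 0.75, 1} with 10 folds in `cv_select()`; the pipeline
configuration uses a reduced grid (20 λ in [1e-2, 1e3], α ∈ {0, 0.5, 1},
5 folds) that gives indistinguishable selections on these problem sizes at
a fraction of the cost.

Residual variance is estimated as `RSS/(n − m)` with m the count of nonzero
coefficients plus one for the intercept.

## Evaluation

Errors are `predicted − reference` (mmHg). Reports carry RMSE, MAE, mean
error and its SD, the cumulative percentages of absolute errors within 5,
10 and 15 mmHg with the corresponding grade (A requires 60/85/95, B
50/75/90, C 40/65/85, else D), and an advisory device-standard check
(|mean error| ≤ 5 and SD ≤ 8 mmHg) whose thresholds come from the AAMI
standard, not from this package's method — it is labelled advisory for that
reason.

## The synthetic cohort: what it emulates, and what it does not

`synth_config()` describes a cohort of 125 Hz synchronized ECG/PPG/ABP
records, one subject each. Subject physiology is drawn once per record:
heart rate in [55, 95] bpm, PTT in [0.15, 0.35] s, and pulse morphology —
an asymmetric systolic bump (rise SD 0.04–0.06 s, decay SD 0.09–0.13 s) plus
a delayed smaller diastolic bump, separated enough that a dicrotic notch
provably exists. The asymmetry matters: a symmetric bump has no identifiable
foot, and during development the extracted PTT of a symmetric-pulse draft
correlated only ~0.7 with the generating PTT on noise-free data — the
testbed, not the method, was the bottleneck. Real pulses rise steeply, so
the asymmetric shape is also the more faithful one.

True pressures follow
`SBP = c0 + c1/PTT + c2·HR + c3·W50 + c4·exp(−W10/τ) + ε`, with an
analogous DBP model, where W50/W10 are the template's widths at 50%/10% of
peak amplitude measured analytically on a fine grid, τ = 0.5 s, and
ε ~ N(0, `bp_noise_sd`). Coefficients default to values spanning a
realistic adult range (roughly 95–165 SBP, 55–95 DBP over the default
draws). The ABP trace is the pulse template affinely rescaled so its
per-beat extrema equal the true SBP/DBP exactly. All ground-truth landmark
times are recorded at the analytic extrema of the composite template, so
detector tolerances can be asserted at the single-sample level.

The planted-structure table generator builds
`y = Σ a_i X_i + Σ b_j g(X_j) + ε` with g an even transform (square,
|sine|, absolute value) of a symmetric Uniform(−1,1) variable — centered so
the nonlinear features carry no linear component and their Pearson
correlation with y is ~0 by design. The nonlinear coefficient defaults to 2,
which variance-matches a centered even transform to a unit-weight linear
contribution; redundant copies add N(0, 0.3) perturbation, large enough
that a parent reliably outranks its copy yet small enough that the copy
stays clearly redundant (SU with parent ≈ 0.3–0.45).

**Limitations.** The generator does not model respiration coupling, motion
artifacts, arrhythmias, reflected-wave dynamics, sensor saturation, or
drift in the BP-generating relationship over time; subjects contribute one
stationary record each, and the pressure model is the same for every
subject. Passing tests therefore demonstrate that the pipeline recovers a
known generating structure through realistic waveform geometry and noise —
not that it attains any particular accuracy on clinical data. The quality
screen (missing fraction > 5%, flatlines > 2 s, heart rate outside
[30, 200] bpm, pressure outside [30, 250] mmHg) is likewise an automated
stand-in for the manual record vetting practiced on real corpora.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script use: a 300-subject cohort
(30 s records, mild 2% waveform noise, 3 mmHg pressure noise, one window
per record, 75 held-out subjects), 50-seed Monte-Carlo loops for the
selector properties at n = 2000 rows, and 20-seed loops for ReliefF and
QRS detection. These sizes give stable rates while keeping a full run in
minutes on one core. Degenerate inputs are handled explicitly: constant
signals refuse normalization, constant variables discretize to a single
category with a warning, SU/MSU of all-constant sets return NA with a flag,
zero-variance and mostly-masked feature columns are dropped before
selection, and fold assignment refuses folds with fewer than two rows.

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synth = synth_config(n_subjects = 60, duration_s = 30,
                       noise_sd = 0.02, bp_noise_sd = 3, seed = 1),
  seed = 1)
res <- run_pipeline(cfg)
res                       # per-target RMSE/MAE, BHS grade, AAMI advisory
tidy(res$sbp$model)       # coefficients on both scales
autoplot(res$sbp$model)   # CV curve
autoplot(res$sbp$selection)
```
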