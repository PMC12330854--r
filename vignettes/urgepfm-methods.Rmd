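---
title: "Timing-free mapping of urge-related activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing-free mapping of urge-related activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urgepfm)
```

## The problem

Urges — the mounting discomfort before a blink, a tic, a swallow — have no
experimenter-controlled onset, so the standard fMRI analysis strategy of
regressing the signal on known task timings cannot isolate them cleanly.
`urgepfm` implements two complementary analyses of a blink-suppression
experiment in which participants alternate 60 s blocks of free blinking
("Okay") and blink suppression ("Suppress") between two 30 s "Random"
baseline pads (420 s runs), while continuously rating their urge-to-blink on
a 0–100 scale at 10 Hz:

1. a conventional first-level GLM with a parametric urge regressor, and
2. a *timing-free* route: voxelwise sparse haemodynamic deconvolution of
   multi-echo fMRI, event detection against a volume-shuffled surrogate
   null, and consensus clustering of the single-event activation maps.

Because no imaging data are deposited with the study this package emulates,
every analysis ships with a synthetic-data generator that reproduces the
statistical structure the pipeline assumes, plus the ground truth needed for
recovery testing.

## The signal model

Under a linear time-invariant model, a neuronal event at time $\tau$ produces
a BOLD response $h(t-\tau)$, with $h$ the canonical double-gamma HRF
(response delay 6 s, undershoot delay 16 s, dispersions 1 s, response:
undershoot ratio 6, 32 s support — `canonical_hrf()`). For multi-echo
acquisitions the fractional signal change of echo $k$ under an
R2\*-only model is

$$\frac{\Delta S_k(t)}{\bar S_k} \;=\; -\,TE_k \,\cdot\, \Delta R_2^*(t),
\qquad \Delta R_2^*(t) = (h * s)(t),$$

where $s(t)$ is the activity-inducing impulse train in $s^{-1}$ and $TE_k$
is in seconds. Negative $\Delta R_2^*$ means positive BOLD. The package uses
TR = 1800 ms and TEs = 12/35/58 ms by default; percent-change traces of any
two echoes are proportional with ratio $TE_j/TE_i$ in the noiseless case,
which the test suite checks at machine precision.

The kernel is deliberately left unnormalised (its scale is a convention that
cancels between the simulator and the deconvolution and is recorded in the
HRF metadata); `normalise = "peak"` is available.

## Sparse deconvolution with BIC selection

`deconvolve_run()` estimates $s$ voxel by voxel. The percent signal change
of each echo (Legendre detrending of order 4 — the order used by the
package's nuisance convention — then division by the voxel's temporal mean,
`percent_signal_change()`) is stacked across echoes and regressed on the
vertical stack of $-TE_k H$ blocks (`multiecho_design()`), where $H$ is the
causal Toeplitz convolution operator. The estimator is the lasso,

$$\hat\beta(\lambda) = \arg\min_\beta \tfrac12\,\lVert y - X\beta\rVert^2
  + \lambda\lVert\beta\rVert_1,$$

solved *exactly* along a 50-point logarithmic grid from $\lambda_{max}$ (the
smallest $\lambda$ with an empty model) down to $\lambda_{max}/1000$ by a
LARS-type homotopy in Gram form (`solve_sparse_path()`; the solution path is
piecewise linear in $\lambda$, so grid solutions are obtained by
interpolation between breakpoints and satisfy the stationarity conditions up
to roundoff — the suite verifies them at $10^{-8}$ and cross-checks the
objective against an independent lasso solver and against exhaustive
small-support search).

Two details matter for correctness:

* **Nuisance symmetry.** The data are detrended, so the design columns are
  residualised against the same Legendre basis. Otherwise the projection
  removes part of the event response and biases amplitudes; with the
  symmetric treatment a noiseless run is recovered exactly (up to the
  percent-change convention of dividing by the signal-inclusive temporal
  mean, a relative compression of order $10^{-3}$ for sparse events).
* **Model selection.** The regularisation parameter is chosen per voxel by
  $\mathrm{BIC}(\lambda) = n\log(\mathrm{RSS}_\lambda/n) + k_\lambda\log n$
  with $k_\lambda$ the support size and $n$ the number of stacked
  observations. The RSS entering the criterion is that of the *penalised*
  (shrunk) solution: near $\lambda_{max}$ a spurious coefficient is heavily
  shrunk and barely improves the fit, which is precisely what keeps
  pure-noise voxels empty. Were the criterion evaluated on debiased
  (OLS-refitted) solutions, the first noise coefficient would enter whenever
  the largest squared correlation among $\sim T$ candidate onsets exceeded
  $\log n \approx 6.4$ — which happens for most noise realisations at
  $T = 200$ — and specificity would collapse. The *reported* coefficients at
  the selected $\lambda$ are nonetheless debiased by OLS on the support, so
  noiseless amplitude recovery is exact. Both choices are recorded in the
  result (`bic_rss`), and `bic_rss = "debiased"` scores debiased fits
  instead. Ties in BIC resolve to the larger $\lambda$ (sparser model), and
  RSS is floored at $y^\top y \times 10^{-24}$ so numerically exact fits
  compare by sparsity alone.

For efficiency the per-voxel path is computed entirely in Gram form
($X^\top y$, $X^\top X$, $y^\top y$), so the cost does not grow with the
number of stacked observations, and the batch driver abandons the grid early
once the support exceeds `max_support` (default $T/3$): a $k$-coefficient
noise fit gains roughly $k/n$ in log-RSS but pays $k\log(n)/n > k/n$ in
penalty, so such models can never minimise the BIC.

The final TR of a run deserves a note: the HRF kernel starts at zero, so the
design column for an onset in the last volume is identically zero. Such
columns are skipped by the solver and the generator never plants events
there.

## Event detection against a surrogate null

The deconvolved 4D estimate is cleaned and summarised exactly in the order
of the timing-free pipeline:

1. `temporal_max_filter()` — each value is replaced by the largest-magnitude
   (sign-preserving) value in a 3-point window;
2. `spatial_cluster_mask()` — per volume, connected components of nonzero
   voxels (6-connectivity by default, configurable to 18/26) smaller than 10
   voxels are removed; the surviving mask is applied to the *unfiltered*
   estimates;
3. `compute_ats()` — the activation timeseries (ATS) counts, per timepoint,
   the voxels with negative deconvolved coefficients (positive BOLD).

The detection threshold comes from a surrogate run
(`surrogate_threshold()`): one seeded permutation of the volume order,
shared across voxels and echoes and applied to the raw data before the
percent-change step, is pushed through the identical pipeline. The threshold
is the median of the surrogate ATS counts, zeros included (a literal reading
of "median amplitude"; a nonzero-only variant would only raise the
threshold). The run is expected to be trimmed to the experimental segment
first (`trim_random_pads()`): with 420 s at TR 1.8 s the run has 233 whole
volumes and the segment between the Random pads contains exactly 200.

`select_roi_peaks()` restricts the ATS to a region of interest (the study's
analog is the right insula; the phantom uses a labelled cuboid), thresholds
it at the median of the ROI-restricted surrogate ATS (strict `>`), and
returns one peak per maximal supra-threshold segment: the segment maximum,
with plateaus resolved to their midpoint (earlier sample for even length).
An empty result is valid — not every run clears the surrogate threshold.
The spec's source describes the threshold both as "exceeds the surrogate
ATS" and as its median; the median rule is implemented as operative.

## Consensus clustering of event maps

The 3D estimate maps at the selected peaks (stacked across runs with
`collect_event_maps()`) are grouped by k-means on the raw map vectors —
with a squared-Euclidean objective this is the same geometry as clustering
the pairwise Euclidean distance matrix. `consensus_select_k()` subsamples
80% of the maps 100 times per candidate $k \in \{2,\dots,15\}$ and computes,
for every pair co-subsampled at least once, its co-assignment proportion
$m_{ij}$. The consensus value is

$$C(k) = \underset{\text{pairs}}{\mathrm{mean}}\; \left[m_{ij}^2 +
 (1-m_{ij})^2\right],$$

the probability that two independent subsampled clusterings agree about a
random pair; it equals 1 exactly when the partition is perfectly
reproducible. The naive alternative — the raw fraction of pairs assigned
together, available as `method = "together"` — is monotonically inflated as
$k$ shrinks (merging groups can only raise it) and would select $k = 2$ on
any stack, so it is reported for reference but not used for selection.
Ties at the maximum resolve to the *larger* $k$: exact ties only occur when
a coarse merge and its refinement are both perfectly stable, and the finer
partition then carries the extra structure. Each subsampled k-means is
initialised with kmeans++ seeding (centres spread with probability
proportional to squared distance); with naive random starts, local optima
dominate the consensus value and mask the planted structure. The final partition
(`kmeans_maps()`) uses 50 restarts and keeps the best within-cluster sum of
squares; given a seed both steps are deterministic.

`cluster_zmaps()` averages the member maps voxelwise, Z-normalises in space
(spatial mean 0, SD 1), multiplies by $-1$ so positive values encode
positive BOLD, and binarizes at $Z \ge 3.2$. The mean of the member maps is
used rather than the k-means centroid object; with the squared-Euclidean
objective the two coincide.

## GLM comparator and overlap metrics

`build_design_matrix()` constructs the 10-regressor first-level design:
boxcars for Random, Okay and Suppress; a parametric urge regressor (one 1 s
impulse per experimental second weighted by the standardised urge score,
with Random-period ratings removed); a blink-event regressor; and one
temporal derivative per base regressor (first differences, zero prepended).
Regressors are built on a 0.1 s neural grid, convolved with the double-gamma
kernel there, and sampled at the volume acquisition times — at TR = 1.8 s
the 1 s urge impulses cannot be represented on the volume grid directly,
which is why the fine-grid construction is used. `fit_glm()` is ordinary
least squares per voxel (the synthetic noise is white by default; no
prewhitening — an AR(1) stress flag exists in the generator for sensitivity
checks), contrast t statistics are converted to standard-normal Z with
tail-accurate log-space arithmetic, and maps are binarized at $Z \ge 3.2$.
Under white noise the empirical $P(Z \ge 3.2)$ matches the normal tail
($6.87\times10^{-4}$) to Monte-Carlo precision over $10^6$ voxel draws.

`conjunction()` is the voxelwise AND of two thresholded maps;
`overlap_metrics()` reports $|A|, |B|, |A\cap B|$, the percentage of the GLM
mask covered ($100\,|A\cap B|/|B|$), Jaccard and Dice (with
$D = 2J/(1+J)$ as an exact identity). `overlap_table()` crosses every
cluster map with every named GLM mask. Run-level maps here are thresholded
voxelwise; the group-level mixed-effects averaging and random-field cluster
correction used for published group maps are out of scope, so run-level
overlap percentages are structurally, not numerically, comparable to
group-level ones.

## Behavioural statistics

The behavioural half mirrors the in-scanner analysis:

* `downsample_standardise()` — urge to 1 Hz by within-second means (means
  preserve the slow urge dynamics better than decimation), then Z-scores per
  run, separately for Random and for experimental (Okay+Suppress) samples.
  Whether the condition split preceded standardisation in the source
  analysis is ambiguous; the per-run, per-condition-set rule is implemented.
  Time bins are half-open $[s, s+1)$ with the origin at the first volume.
* `binarize_blinks()` — blink occurrence per second (not counts).
* `blink_urge_logistic()` — maximum-likelihood logistic regression of blink
  occurrence on urge Z, reporting $B$, $\exp(B)$, Wald, the model
  $\chi^2$, and Cox & Snell $R^2$. Single-class outcomes and (possibly
  quiet) perfect separation raise classed errors rather than returning
  unbounded estimates.
* `periblink_average()` — the 11-sample ($\pm 5$ s) peri-blink urge window,
  averaged within condition; blinks within 5 s of a block edge are
  discarded, and participants with no retained escape blinks signal an
  empty curve so they can be excluded, as in the source analysis.
* `periblink_stats()` — per participant: peak latency (earliest lag on
  ties, logged via a message), and skewness/kurtosis of the curve treated as
  a distribution over lags after subtracting the curve minimum
  (non-negative weights; the source reports distribution-shape statistics
  without a formula, so the construction is explicit and configurable in
  code). Group tests are two-tailed one-sample tests of latency against 0,
  skewness against 0 and kurtosis against 3 — the reported "excess
  kurtosis" values in this literature sit near 3 and are compared against
  normality, which only makes sense on the raw-kurtosis scale, so kurtosis
  is tested against 3 and excess = kurtosis − 3 is reported alongside. A
  Shapiro–Wilk check at $\alpha = 0.05$ selects the t test versus the
  Wilcoxon signed-rank test.
* `curvilinear_fit()` — linear and quadratic least squares on the group
  curve; the quadratic model is chosen iff its squared term is significant
  at $p \le 0.05$.
* `summarise_blocks()` / `block_summary_tests()` — per-condition mean urge
  (raw 0–100 scale) and blinks/min, compared one-tailed (urge higher under
  Suppress by paired t; blinks fewer under Suppress by paired Wilcoxon,
  since count data fail parametric assumptions). Zero-difference inputs
  carry no directional evidence and report $p = 0.5$.

## The synthetic-data generator

`simulate_urge_and_blinks()` produces the behavioural traces the pipeline
assumes: urge grows linearly under Suppress (3 rating units/s), relaxes to a
low set point when blinking is allowed, and is relieved exponentially
($\tau = 0.8$ s) after each blink — by 35% of its momentary value after an
escape blink, by 5 units otherwise. Relief begins 0.7 s after the blink
(a rating/relief latency; the trackball cursor cannot drop instantly), which
makes the 1 Hz peri-blink template attain its maximum in the second
containing the blink under suppression — the planted latency is 0 by
construction. Blinks are drawn per 0.1 s bin as Bernoulli events with hazard
5.12/min under Suppress and an urge-modulated hazard around 38/min
otherwise, with a 0.5 s refractory period; white rating noise (SD 3 per
sample) is added before clipping to $[0, 100]$, and the unclipped latent
trace is kept so planted-template checks are exact. The defaults were set
once to land near the study-level block summaries (urge roughly 20% vs 60%,
blinks roughly 25/min vs 5/min) and are not tuned further; per-condition
blink-rate variability beyond those means is plausible rather than
calibrated, since the source reports only group SEMs.

`make_ground_truth()` + `simulate_multiecho_run()` build the imaging
phantom: cuboid ROIs (default four of $4\times4\times3$ voxels on a
$20\times20\times10$ grid — a desk-scale stand-in for a brain; correctness
does not depend on grid size) whose voxels share sparse
$\Delta R_2^*$ impulse trains, expressed across echoes through the
linear-TE model, scaled by a smooth mean image, and summed with a global
low-order Legendre drift and white Gaussian noise in percent units (an
optional AR(1) flag is deliberately absent from the defaults: the pipeline's
detrending targets drifts, and autocorrelated noise is a stress test, not
the baseline). `amplitude_for_cnr()` converts a target contrast-to-noise
ratio (peak percent change at the middle echo over noise SD) into an
amplitude; CNR 3 with noise SD 0.5% corresponds to a 1.5% peak — an
ordinary single-event BOLD amplitude.

What the generator does *not* emulate: scanner physics (k-space, motion,
spin history), multiband artefacts, physiological noise structure, or the
residue of ICA denoising. Passing recovery tests on these phantoms
demonstrates that the algorithms are implemented correctly and behave as
designed under their own assumptions — not that those assumptions hold in
any particular real dataset.

## Problem sizes and numerical choices

The shipped verification uses: a noiseless $20\times20\times10$, $T = 200$,
3-echo phantom for exact recovery; 20 seeds of CNR-3 phantoms
($12\times12\times6$, one 48-voxel ROI, 6 events) against matched nulls for
detection; 50 event-free $10\times10\times5$ phantoms for surrogate
exchangeability (two-sample Kolmogorov–Smirnov on ATS counts); 50 planted
3-group stacks ($N = 60$ maps) for consensus recovery; $10^6$ white-noise
voxel draws for GLM calibration; and 200-seed simulations for the
behavioural recoveries. These sizes were chosen as the smallest at which
the binomial/Monte-Carlo error of each property is comfortably below its
acceptance margin.

Degenerate inputs are handled explicitly rather than propagated: zero-mean
voxels inside a mask error by name in `percent_signal_change()` and are
warned-and-zero-filled in `deconvolve_run()`; zero-variance standardisation
groups, single-class logistic outcomes, empty ROIs, all-zero contrasts and
rank-deficient designs all raise classed errors
(`urgepfm_*_error`/`_warning`) that calling code can match.

## Known limitations

* The lasso path is exact, but on rank-deficient active sets (possible once
  the support approaches $T$ minus the detrending rank) the homotopy stops
  and the path is returned truncated; BIC-selected models live far from
  that regime.
* OLS (no prewhitening) in the GLM is calibrated for white noise only.
* The surrogate uses one seeded permutation per run, not an average over
  draws; with $T = 200$ the median of a single surrogate ATS is already
  stable.
* Reported overlap percentages are run-level; group-level corrected masks
  would require the out-of-scope mixed-effects machinery.
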