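---
title: "Methods: sliding-window dALFF, state dynamics and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window dALFF, state dynamics and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Resting-state BOLD activity in the 0.01–0.08 Hz band is summarized per voxel
by the amplitude of low-frequency fluctuations (ALFF): the mean of the
one-sided amplitude spectrum over the in-band frequency bins. Static ALFF
assumes temporal stationarity over the whole acquisition; the *dynamic* ALFF
(dALFF) analysis drops that assumption by recomputing ALFF inside a sliding
window (window length $w$ TRs, step $s$ TRs, $W = \lfloor (T-w)/s \rfloor + 1$
windows) and summarizing the across-window variability per voxel by the
coefficient of variation,

$$\mathrm{CV} = \frac{\mathrm{SD}(\mathrm{ALFF}_1,\dots,\mathrm{ALFF}_W)}
                     {\mathrm{mean}(\mathrm{ALFF}_1,\dots,\mathrm{ALFF}_W)},$$

with the sample SD (denominator $W-1$). CV maps are computed at three window
lengths (30, 50, 80 TR at TR = 2 s, i.e. 60/100/160 s) with step 1 TR; the
multiplicity is deliberate, since no single window length is canonical.

Spectral normalization is fixed so that a unit-amplitude sinusoid at a bin
frequency contributes amplitude 1 at its bin: this gives closed-form test
expectations, and any consistent normalization cancels in the CV. Band-bin
membership is closed on both ends. Each window segment is linearly detrended
before its DFT by default (standard for windowed spectral estimates; no
single convention exists in the toolbox lineage, so it is a flag).

### A numerical caveat on windowed spectra

Two identities that look obvious hold only under an alignment condition.
A noiseless stationary sinusoid gives *exactly* equal windowed ALFF only
when each window holds an integer number of cycles (otherwise spectral
leakage is phase-dependent and the window values wobble at the percent
level); and within-window detrending itself removes a phase-dependent
linear component from a sinusoid, so with detrending on, even full-period
windows vary by up to roughly 20% relative. The exact-zero CV cases in the
test suite therefore use full-period windows (25 TR = 50 s for carriers at
multiples of 0.02 Hz) with detrending off and no drift. For real,
noise-dominated data none of this matters — it is a property of pure tones.

## Group inference

Per voxel, an OLS model `[intercept, group, age (mean-centered), sex (0/1)]`
gives the group-contrast t statistic (patient − control, df = n − 4).
Cluster-level correction follows Gaussian random field practice: t is
converted to z by matching tail probabilities; each tail is thresholded at
`voxel_p/2` (two-tailed default 0.05); connected components (26-neighbour
default) are formed separately for positive and negative excursions; the
search volume is converted to resels using the per-axis smoothness FWHM
estimated from the variance of lag-1 spatial differences of standardized
residual maps (Gaussian-ACF inversion, clamped at a voxel-scale floor so
unsmoothed noise cannot report zero smoothness); and the corrected cluster
p uses the standard expected-cluster-count and extent-tail (exponential,
$k^{2/3}$) approximation. Clusters with corrected p < 0.05 are kept.

Because the RFT approximation is optimistic in small samples, a
permutation route is the package's authoritative oracle: group labels are
permuted (covariates travel with their subjects), the maximum cluster size
over both tails forms the null, and the add-one p is used. The acceptance
suite requires GRF family-wise error ≤ 0.10 at nominal 0.05 and
GRF/permutation agreement (Dice ≥ 0.7) on planted effects.

A deliberate consequence of z-standardizing CV maps within the mask before
group statistics (the default, a toggle): a strong focal increase inflates a
subject's map SD, which pushes that subject's background slightly negative
and can produce a genuine *negative* background cluster. Recovery tests
therefore compare positive-sign clusters against the planted truth.

## State dynamics

All subjects' windowed ALFF maps (one vector per window) are pooled and
clustered with k-means under the Manhattan (L1) distance: assignment by
nearest-centroid L1 distance, centroid update by the component-wise median
(the exact L1 minimizer). Descriptions of "cityblock k-means" in this
literature sometimes speak of minimizing within-cluster *squares* while
prescribing the L1 distance — the two conflict; this package minimizes the
L1 cost, the quantity a median-update k-means actually descends. Initialization
is distance-weighted careful seeding (L1 analogue of k-means++), best of
`n_init = 10` restarts; empty clusters are re-seeded from the farthest
window; the L1 cost is asserted non-increasing across iterations on every
run. States are relabeled by descending overall occupancy so "state 1" is
always the modal state. `select_k` reports the full cost/silhouette curve
and picks the elbow by the maximum second difference of cost — there is no
canonical rule for how many brain states describe a cohort, so the choice
is exposed and user-overridable.

Per subject, the temporal metrics are fractional occupancy, mean dwell time
(mean maximal-run length, in windows and in seconds via TR × step), number
of transitions, visits per minute ("frequency" is ambiguous between
fractional occupancy and visit rate, so both are reported), and the bigram
transition matrix (rows over visited states; unvisited states flagged).
Group comparisons of these metrics share the normality-routed two-sample
test (Shapiro–Wilk on each group at 0.05: t-test when both pass, Wilcoxon
otherwise).

## Classification

Features are the mean CV per differential cluster (the labeled surviving
mask from inference), one feature per cluster. The classifier is a binary
soft-margin SVM with RBF kernel $K(x,y) = \exp(-\gamma\|x-y\|^2)$, trained
by an SMO dual solver written for this package (no SVM library is assumed);
$(C, \gamma)$ are selected by inner 5-fold cross-validated accuracy over a
powers-of-two grid ($C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$; step 4 by
default for runtime, step 2 reproduces the classic dense grid). The outer
evaluation is leave-one-out by default, matching field practice at n ≈ 47;
a documented resubstitution mode exists because near-100% accuracies
reported in this literature can reflect training-set evaluation, and
neither mode is tuned toward any particular published figure — reported
accuracies are properties of a cohort, not of the method. Feature
standardization uses training-fold statistics only, and a leakage canary
(adding out-of-fold copies of a test subject must not change its
prediction) is part of the test suite. A permutation test
(p = (1 + #{perm ≥ obs})/(n_perm + 1)) guards reported accuracies. Note
that under permuted labels leave-one-out is pessimistically biased (the
training majority class is the opposite of the held-out label), a
well-known small-sample artifact; the 50%-null calibration check therefore
uses stratified outer folds.

## Clinical correlation

Per differential region, the region values (not the clinical scores) are
tested with Shapiro–Wilk; normality p < 0.05 routes to Spearman, otherwise
Pearson — exactly one branch populated per region, mirroring the
two-column (Pearson | Spearman) table layout conventional in this
literature. No across-region correction is applied in the primary columns
(matching that convention); a Bonferroni column is emitted additionally.

## The synthetic cohort generator

Because the study's raw data are not deposited, every stage is exercised on
synthetic 4D BOLD with known ground truth. Each in-mask voxel is

$$x(t) = \text{baseline} + \text{drift}(t) + \big(1 + m\,g(t)\big)\,c(t) + \varepsilon(t),$$

where $c(t)$ is a sum of three carrier tones at 0.02/0.04/0.06 Hz (inside
the analysis band; fixed tones give analytic ALFF expectations), $g(t)$ is
a slow sinusoidal envelope at 0.005 Hz (strictly below the band, so the
modulation itself cannot leak into the ALFF band) with random phase per
subject, and $m \ge 0$ is the modulation depth — the single dial that
creates window-to-window ALFF variance and hence CV. Planted effect blocks
give patients $m = 0.8$ vs controls $m = 0.1$ by default against a 0.2
background common to both groups; all other generation is identical between
groups. Noise is AR(1) (coefficient 0.3) Gaussian with innovation SD 0.5
against carrier amplitude 1, spatially smoothed (6 mm FWHM) — the blur is
applied to the noise only so the planted geometry stays block-exact for
Dice-based recovery tests. Drift is a random low-order polynomial; the
default acquisition is 240 volumes at TR 2 s (the first 10 discarded in
preprocessing) on a spatially scaled-down grid (24×24×16, 3 mm). Covariates
are age ~ U(20, 80), sex ~ Bernoulli(0.5) and a Poisson(4) clinical score
mimicking a low-range anxiety scale, independent of the imaging effect so
clinical correlations are null by construction.

State cohorts replace the envelope with a spatial amplitude prototype that
is piecewise constant over epochs (default 30 TR) and follows a first-order
Markov chain over k prototypes; epoch-level labels are the ground truth,
and recovery tests analyze non-overlapping windows aligned with epochs.

What a green test does **not** establish: the generator has no hemodynamic
response, no physiological (cardiac/respiratory) structure, no motion, no
anatomy — so passing recovery says the *pipeline math* is right at the
stated effect sizes, not that the effect sizes of any real cohort are
attainable.

## Numerical and design choices

* Window count: $W = \lfloor (T-w)/s\rfloor + 1$; 230 volumes give
  201/181/151 windows at 30/50/80 TR, step 1.
* Zero across-window mean voxels get CV = 0 plus a flag (never NaN).
* Smoothing uses separable Gaussian kernels with reflective padding (flat
  fields exactly preserved); FWHM→σ via $2\sqrt{2\ln 2}$.
* Preprocessing order is fixed: discard → detrend → (nuisance) → smooth.
  Nuisance regressors for synthetic data are drift polynomials only; real
  data may supply any confound matrix (rank checked, collinear columns
  named).
* Smoothing FWHM (6 mm) and the nuisance set are config parameters with
  field-standard defaults; neither has a canonical value.
* t→z by matching tail probabilities; cluster connectivity 26 (configurable
  6/18); positive and negative tails corrected separately at `voxel_p/2`.
* Ties in k-means assignment break to the lowest state index; k-means is
  deterministic given its seed.
* The NIfTI-1 reader/writer is minimal by design (single-file .nii/.nii.gz,
  sform affine, TR in pixdim), written against the format spec and
  cross-checked against an independent implementation in the test suite.

## Known limitations

RFT corrected p-values use the leading 3D EC-density term only — adequate
at the smoothness/volume regimes tested, optimistic otherwise (use the
permutation route when in doubt). The SMO solver targets small-n cluster
feature sets, not large-scale problems. Anatomical labeling uses synthetic
block atlases; no MNI-space registration is performed anywhere (synthetic
data live in a common space by construction, and normalization of real data
is out of scope).
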