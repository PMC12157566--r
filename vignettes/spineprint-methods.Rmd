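---
title: "Fingerprinting functional connectivity in the brain and spinal cord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting functional connectivity in the brain and spinal cord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineprint)
```

# The scientific question

Resting-state fMRI functional connectivity (FC) — the matrix of Pearson
correlations between region-averaged BOLD time series — is stable enough
within an individual, and variable enough between individuals, to act as a
"fingerprint": given two runs per subject, the run-1 FC profile of a subject
is typically more similar to their own run-2 profile than to anyone else's.
`spineprint` implements the complete analysis needed to ask whether this
holds not only for the brain but also for the cervical spinal cord, where
regions are far smaller, temporal signal-to-noise is several-fold lower, and
physiological noise (cardiac pulsation, respiration, CSF flow) is much more
intrusive.

The package covers five stages, each usable on its own:

1. **Parcellation schemes** (`build_spinal_scheme()`, `build_brain_scheme()`,
   `combine_schemes()`) fix the region ordering of every matrix.
2. **Denoising** (`retroicor_design()`, `csf_regressor()`,
   `clean_timeseries()`, `robust_parcel_mean()`, `tsnr()`).
3. **Connectivity** (`compute_fc()`, `vectorize_upper()`, `extract_block()`).
4. **Fingerprinting and reliability** (`identifiability_matrix()`, `idiff()`,
   `cohens_d()`, `success_rate()`, `pca_differential_identifiability()`,
   `edge_icc()`, `threshold_percentile()`, `nodal_strength()`).
5. **Cross-regression** (`fit_cross_regression()`, `residual_fingerprint()`)
   for simultaneous brain + cord acquisitions.

A seeded synthetic cohort generator (`cohort_spec()`, `generate_cohort()`,
`generate_driven_pair()`) stands in for scanner data throughout the test
suite.

# Parcellation

The spinal cross-section is divided into 14 regions: bilateral gray-matter
dorsal horns (`dh`), intermediate zone (`iz`) and ventral horns (`vh`), and
bilateral white-matter spinal lemniscus (`sl`), corticospinal tract (`cst`),
fasciculus cuneatus (`fc`) and fasciculus gracilis (`fg`). The scheme is
replicated over the acquired cervical levels, so 3, 5 and 7 levels give 42,
70 and 98 regions. The within-level order is fixed canonically as the
GM block then the WM block, left before right within each region
(`dh_L, dh_R, iz_L, iz_R, vh_L, vh_R, sl_L, sl_R, cst_L, cst_R, fc_L, fc_R,
fg_L, fg_R`). Published figures that alternate gray and white regions left
to right are ambiguous at the level of individual labels; fixing one order
and using it everywhere is what matters, since every matrix, vector and map
in the package inherits it.

The brain scheme is 100 cortical regions sorted by the seven canonical
resting-state networks (VIS, SM, DA, VA, L, FP, DMN), left hemisphere before
right within each network, plus 19 subcortical regions last — 119 in total.
`default_brain_labels()` provides a synthetic label table with this
structure when no real atlas table is at hand.

# Denoising model

**Physiological regressors.** Cardiac and respiratory cycles are
quasi-periodic; their influence on each volume is modelled by a Fourier
expansion of the instantaneous phase. The cardiac phase grows linearly from
0 to $2\pi$ between successive pulse peaks; the respiratory phase combines
the amplitude's empirical percentile (histogram equalization, magnitude up
to $\pi$) with the sign of the smoothed derivative, distinguishing
inhalation from exhalation at the same lung volume. With cardiac and
respiratory orders $c$ and $r$ and interaction order $i$ (sines and cosines
of $m_c\varphi_c \pm m_r\varphi_r$), the design has $2c + 2r + 4i^2$
columns; the guideline setting $(4, 4, 2)$ gives 32 regressors. The
interaction is deliberately defined through sum/difference phases rather
than elementwise products of basis columns — only the former reproduces the
standard 32-regressor count. A CSF regressor averages the 10% most variable
CSF voxels, where pulsatile flow dominates.

**Joint projection.** Confound regression and band-pass filtering interact
badly when applied sequentially: regression re-introduces stop-band energy
and filtering breaks orthogonality to the confounds. `clean_timeseries()`
therefore builds a discrete-cosine basis of every frequency outside the
pass band (default 0.01–0.13 Hz, the band where spinal BOLD fluctuations
live), concatenates it with the confounds and an intercept, and removes the
joint least-squares fit in a single projection. Two properties follow by
construction and are asserted in the tests: residuals are orthogonal to
every confound column at machine precision, and the operation is idempotent.
Rank deficiency among confounds is handled by an SVD pseudoinverse.

A note on attenuation: an exact projection annihilates the stop-band *basis*,
but a finite-length off-bin sinusoid also carries spectral leakage inside
the retained pass band, which no exact filter may remove. For a 0.2 Hz tone
at $T = 288$, TR 2.08 s, the total residual power is a few times $10^{-3}$
of the input — almost all of it pass-band leakage — while the residual power
*at 0.2 Hz* (the proper stop-band attenuation measure) is below $10^{-4}$,
i.e. better than 40 dB. The tests measure attenuation at the tone frequency.

**Robust parcellation.** Region time series are formed by a trimmed mean:
at each time point, voxel values below the 5th or above the 95th cross-voxel
percentile are excluded before averaging, suppressing vascular and edge
voxels. The trim is vacuous below 5 voxels, where the plain mean is used.
An alternative reading — trimming extreme *time points* per voxel — exists;
the cross-voxel reading is implemented because the trim is meant to guard
against spatial outliers within a region. Note the breakdown point: a 5%
trim per tail only protects while the per-tail outlier fraction at a given
time point stays below 5% of the region's voxels.

# Fingerprinting metrics

With two runs per subject, each run-$r$ FC matrix is unfolded into the
vector of its $M = N(N-1)/2$ upper-triangle edges (row-major over $i < j$;
this edge order is canonical across the package). The **identifiability
matrix** $I$ is the $N_s \times N_s$ matrix of Pearson correlations between
run-1 and run-2 FC vectors; it is asymmetric. Let $I_{self}$ be the mean
diagonal and $I_{others}$ the mean of all $N_s(N_s-1)$ off-diagonal entries
(both halves, no symmetrization); then

$$\mathrm{Idiff} = I_{self} - I_{others}, \qquad
d = \frac{I_{self} - I_{others}}
         {\sqrt{(\sigma^2_{self} + \sigma^2_{others})/2}},$$

with sample variances. Idiff is reported on the correlation scale. The
**top-K success rate** counts a subject as identified when their diagonal
entry is strictly larger than all but at most $K-1$ off-diagonal entries of
their row (row-wise matching only: run 1 queries run 2); ties with the
diagonal count as failures — a deterministic, conservative rule with
probability zero on continuous data. Chance level is $100/N_s$ percent.

**Differential identifiability.** The $2N_s$ FC vectors are stacked as
columns, each edge is centered across columns, and the profiles are
reconstructed from the top $m$ principal components plus the edge means;
Idiff is recomputed for each $m$ and maximized. Orientation matters: the
centering is per edge so that at $m = 2N_s$ the reconstruction is exact and
the raw Idiff is recovered to $10^{-8}$ (a test). At $m = 1$ the single
component captures the structure shared across subjects, and Idiff collapses
toward zero — useful as a negative control. $m \ge 1$ is allowed for this
reason, even though only $m \ge 2$ is informative for maximization.

# Edge-wise reliability

For each edge, a one-way random-effects ANOVA with subjects as groups and
$k = 2$ runs as repeats gives

$$\mathrm{ICC}(1,1) = \frac{MSR - MSW}{MSR + (k-1)\,MSW},$$

with $MSR$ the between-subject and $MSW$ the within-subject mean square.
The per-edge values are folded back into the symmetric region space
(diagonal undefined). Thresholding retains edges at or above the q-quantile
(default 95th percentile, linear interpolation between order statistics —
`stats::quantile` type 7, documented so retained-edge counts are
reproducible) of the finite upper-triangle values; **nodal strength** then
aggregates each region's row of the thresholded map. Both a sum (default)
and a mean mode exist because the two appear interchangeably in practice;
reports name the mode used. For multi-level spinal maps,
`average_within_level_blocks()` collapses the within-level $14 \times 14$
diagonal blocks across levels and datasets, NaN-aware; between-level edges
are deliberately excluded, the minimal reading of averaging "across levels".

# Brain–spine cross-regression

For simultaneous acquisitions the two region sets share the time axis, and
each target region's series is regressed on *all* predictor regions'
series: $Y = \beta X + \varepsilon$ with $Y$ ($N_t \times T$) and $X$
($N_p \times T$) mean-centered over time in place of an intercept. This
per-target multiple regression over time samples is the only reading that
produces residuals of shape $N_t \times T$; coefficients use a minimum-norm
pseudoinverse, and a ridge option exists for $T$ close to $N_p$ (off by
default — plain least squares is the model). Residual FC profiles feed the
identifiability pipeline unchanged (`residual_fingerprint()`). Fits are
per run; pooling runs would leak run-specific structure across the
test-retest boundary. Under the null (independent $X$, $Y$), the expected
per-target $R^2$ is the overfitting floor $N_p/(T-1)$ — a tested property
that also signals when a predictor set is too large for the run length.

# The synthetic cohort generator

`generate_cohort()` draws, per subject $i$ and run $r$, $T$ samples of a
zero-mean multivariate normal with correlation

$$\Sigma_{i,r} = (1-\alpha-\gamma)\,C_{group}
  + \alpha\,C_{subj(i)} + \gamma\,C_{run(i,r)},$$

plus iid observation noise, with every component a random low-rank-plus-ridge
correlation matrix (`random_correlation()`: $\mathrm{cov2cor}(WW^\top +
\delta I)$, $W$ an $N \times q$ standard normal, $\delta = 0.05q$). The
convex weights keep the marginal scale comparable across settings; since a
convex mixture of positive-definite correlation matrices is positive
definite, the nearest-PD eigenvalue-clipping projection is needed only for
degenerate user-supplied targets. All component draws use seeds derived
deterministically from the spec seed, so cohorts are bit-for-bit
reproducible; derived seeds are returned alongside the data.

$\alpha$ is the subject-stable (fingerprint) weight, $\gamma$ the
run-specific weight. $\alpha = 0$ removes all subject identity (K=1 accuracy
falls to $100/N_s$ percent); $\alpha = 0.9$ with low noise yields perfect
identification. `generate_driven_pair()` additionally builds a target
cohort $Y = A_i X + \text{noise}$ with a sparse subject-specific mixing
$A_i$ fixed across runs, the ground-truth configuration in which regressing
$X$ out of $Y$ must destroy $Y$'s fingerprint while regressing $Y$ out of
$X$ leaves $X$'s essentially intact.

Default study conditions are 15 subjects, 98 regions (a 7-level spinal
scheme), 230 volumes at TR 1.55 s — the shape of a simultaneous
brain+cord acquisition — with $\alpha = 0.3$, $\gamma = 0.2$, noise SD 0.5
and latent rank 8: a regime with a clear but imperfect fingerprint, chosen
once as a realistic middle ground between the chance and saturation
extremes. What the generator does *not* emulate: hemodynamic
autocorrelation (an AR(1) option is deliberately omitted from the default
path), motion artefacts, physiological structure in the noise, and
inter-region distance effects. Tests passing on this cohort therefore
validate the *estimators* — that the pipeline recovers planted statistical
structure and degrades to chance when none exists — not the physiology of
real spinal data.

```{r, eval = FALSE}
spec <- cohort_spec(n_subjects = 15, alpha = 0.3, gamma = 0.2, seed = 1)
v <- cohort_fc_vectors(generate_cohort(spec))
fp <- fingerprint_analysis(v$run1, v$run2)
print(fp)
```

# Numerical choices and degenerate inputs

* Pearson correlations via `stats::cor`; diagonals of FC matrices set to
  exactly 1; constant series are an error naming the offending region.
* Quantiles everywhere use linear interpolation (type 7).
* Identifiability ties (diagonal equal to an off-diagonal entry) fail, so
  success rates are deterministic.
* Edges with zero variance across subjects and runs give ICC `NaN` and are
  excluded from percentiles; an all-`NaN` map is an error.
* Rank-deficient confound or predictor matrices are resolved by SVD
  pseudoinverse (minimum-norm solutions); an over-complete denoising basis
  (more nuisance columns than time points) is an error rather than a silent
  zero residual.
* FC vector length $M$ must satisfy $M \ge 3$ for identifiability
  correlations; two-subject cohorts are the minimum for Idiff and ICC.

# Problem sizes used in the test suite

Structural and oracle tests run at small sizes (4–15 subjects, 6–20
regions). The parameter-recovery study runs at the default study shape
(15 subjects, 98 regions, 230 volumes): 200 replicates at $\alpha = 0$ for
the chance-level check, 20 at $\alpha = 0.9$ for the saturation check, and
100 replicates per point of the $\alpha$-grid $\{0, 0.2, 0.4, 0.6, 0.8\}$
for the monotonicity of Idiff and mean edge ICC. The driven-pair
directionality study uses 50 replicates of 10 subjects, 20 driver and 10
target regions, 200 volumes.

# Known limitations

* No dynamic (time-resolved) fingerprints, partial correlation, or
  tangent-space embeddings; the analysis is static Pearson FC only.
* No image-domain processing: motion correction, segmentation and template
  registration are upstream of this package, which starts at voxel- or
  region-level matrices.
* ICC confidence intervals are not computed (only the point estimate is
  used for mapping and thresholding).
* Cross-regression is simultaneous and undirected in time; lagged or
  causal models are out of scope.
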