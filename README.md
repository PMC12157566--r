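# spineprint

Functional connectome fingerprinting for the brain **and the cervical spinal
cord**: given two resting-state fMRI runs per subject, can an individual be
recognised from the correlation structure of their parcelled time series
alone? `spineprint` implements the full analysis for researchers working
with parcelled (or toy voxel-level) fMRI matrices — spinal cord imaging
groups in particular, where small regions, low temporal SNR and heavy
physiological noise make the question hard.

## What it computes

With $N_s$ subjects and FC vectors $c_i^{(r)}$ (the $M = N(N-1)/2$
upper-triangle Pearson correlations of run $r$'s $N \times N$ FC matrix),
the **identifiability matrix** is
$I_{ij} = \mathrm{corr}\big(c_i^{(1)}, c_j^{(2)}\big)$, and

$$\mathrm{Idiff} = I_{self} - I_{others}, \qquad
d = \frac{I_{self} - I_{others}}{\sqrt{(\sigma^2_{self}+\sigma^2_{others})/2}},$$

where $I_{self}$ averages the diagonal and $I_{others}$ all off-diagonal
entries. Top-K accuracy counts subjects whose diagonal entry ranks in their
row's top K (chance $= 100/N_s$ %). Around this core the package provides:

* spinal (14 regions/level: bilateral `dh`, `iz`, `vh` gray matter; `sl`,
  `cst`, `fc`, `fg` white matter) and brain (7 networks + subcortex, 119
  regions) parcellation schemes;
* RETROICOR-style Fourier nuisance designs ($2c + 2r + 4i^2$ regressors;
  32 at orders 4/4/2), CSF regressors, and joint confound + band-pass
  cleaning by a single orthogonal projection (0.01–0.13 Hz default);
* robust (5th–95th percentile trimmed-mean) parcellation and tSNR;
* differential identifiability: Idiff maximized over reconstruction from
  the top-$m$ principal components of the stacked FC profiles;
* edge-wise ICC(1,1) reliability maps, 95th-percentile thresholding, nodal
  strength;
* brain↔spine cross-regression ($Y = \beta X + \varepsilon$ over the shared
  time axis) and fingerprinting of the residuals;
* a fully seeded synthetic cohort generator with separable group,
  subject-stable and run-specific correlation components.

## Worked example

```r
library(spineprint)

scheme <- build_spinal_scheme(c("C4", "C5", "C6"))   # 42 regions
spec <- cohort_spec(n_subjects = 12, n_regions = 42, n_timepoints = 200,
                    alpha = 0.15, gamma = 0.2, noise_sd = 0.8, seed = 42)
cohort <- generate_cohort(spec, scheme = scheme)

v  <- cohort_fc_vectors(cohort)
fp <- fingerprint_analysis(v$run1, v$run2)
print(fp)
#> identifiability_result (12 subjects)
#>   Iself = 0.766  Iothers = 0.734  Idiff = 0.032  Cohen's d = 1.69
#>   top-K accuracy (%): K=1: 58.3, K=2: 83.3, K=3: 91.7, K=4: 91.7, K=5: 91.7  [chance 8.3%]

print(pca_differential_identifiability(v$run1, v$run2))
#> differential identifiability: m* = 10, Idiff* = 0.082 (24 m values)

map <- edge_icc(v$run1, v$run2, scheme = scheme)
thr <- threshold_percentile(map, 0.95)
```

The subject-stable weight `alpha = 0.15` plants a weak fingerprint: 7 of 12
subjects are identified at K = 1 (58.3%, against 8.3% chance), the accuracy
curve rises with K, and Idiff = 0.032 on the correlation scale with a large
effect size (d = 1.69) — self-similarities separate cleanly from
between-subject similarities even when the absolute difference is small.
Reconstructing FC profiles from the 10 leading principal components more
than doubles Idiff (differential identifiability). The ICC map's 95th
percentile (0.541 here) selects the most reliable edges, and nodal strength
ranks regions by their share of those edges. `run_full_analysis()` chains
all stages from a config list or manifest and writes a JSON report;
`inst/cli/spineprint.R` is a thin command-line wrapper over the same
functions.

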