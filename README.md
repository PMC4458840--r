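# connectograd

Connectopic gradient mapping and model-based seed connectivity for fMRI
regions of interest, in R.

## The problem

Small cortical regions — the entorhinal cortex is the motivating case — often
change their long-range functional connectivity *gradually* across space
rather than breaking into sharp parcels. A seed-based analysis can ask
whether two halves of the region couple differently to two distributed
cortical networks, but it presupposes both the halving and the networks.
`connectograd` implements the complementary data-driven approach: find the
dominant modes of functional-connectivity *change* within the region, with
no seeds and no prior parcellation, and only then parcel the region by
splitting each mode at its median.

## The method

For a region of interest **R** inside gray matter **G**:

1. **Fingerprints.** Rearrange the BOLD series into time × voxel matrices
   for R and for G∖R; convert to percent signal change and high-pass filter
   (128 s discrete-cosine basis). Reduce G∖R losslessly by SVD, keeping the
   component time courses `U·S` at numerical rank. Each R-voxel's
   *connectivity fingerprint* is its vector of Pearson correlations with
   those components.
2. **η² similarity.** For fingerprints *a*, *b*:
   η² = 1 − Σᵢ[(aᵢ−mᵢ)² + (bᵢ−mᵢ)²] / Σᵢ[(aᵢ−M̄)² + (bᵢ−M̄)²],
   with mᵢ = (aᵢ+bᵢ)/2 and M̄ the grand mean — a bounded [0, 1] similarity.
3. **Laplacian Eigenmaps.** Use the similarity matrix (diagonal zeroed) as
   graph weights W, D = diag(row sums), and solve L v = λ D v with
   L = D − W. The eigenvectors of the smallest nonzero eigenvalues are the
   spatial modes of connectivity change; group-level modes come from the
   element-wise mean of subject similarity matrices.
4. **Scoring and parcellation.** Topology preservation is the Spearman
   correlation between pairwise η² and proximity along a mode; each mode's
   median split yields two equally sized clusters.

Around this core the package provides the model-based workflow (SVD
representative ROI time series, partial correlations with Fisher-Z,
dual-regression seed-pair maps, one-sample sign-flip max-statistic
permutation inference), motion QC (framewise displacement with the 50 mm
rotation convention, scrubbing of volumes t−1…t+2 around supra-0.5 mm
events, mean + 1 SD participant exclusion), temporal/spatial SNR, a
canonical-HRF stimulus GLM, and a synthetic-data generator whose ground
truth (a linear connectivity gradient inside the ROI) makes every stage
testable by parameter recovery.

## Worked example

```r
library(connectograd)

cfg    <- synth_config(n_subjects = 4, seed = 7)   # 24^3 grid, 8^3 ROI
cohort <- make_cohort(cfg)
res    <- lapply(cohort, function(s)
  connectopic_gradients(s$run, s$roi, s$gray))
grp    <- group_gradient(lapply(res, function(x) x$similarity),
                         coords = res[[1]]$coordinates)
grp
#> <gradient_set> 512 voxels, 2 mode(s)
#>   mode 1: lambda = 0.8542, topology rho = 0.953
#>   mode 2: lambda = 0.9998, topology rho = 0.157

u <- cohort[[1]]$truth$u                 # ground-truth gradient coordinate
abs(cor(grp$modes[, 1], u, method = "spearman"))
#> [1] 0.9921586

table(median_split(grp$modes[, 1]))
#>   1   2
#> 256 256
```

The dominant mode (the eigenvector with the smallest nonzero eigenvalue,
λ = 0.854) orders the 512 ROI voxels almost exactly as the built-in
gradient does (|Spearman ρ| = 0.992) and preserves the rank order of the
high-dimensional fingerprint similarities well (topology ρ = 0.953); the
second mode carries little structure by comparison. Its median split gives
two clusters of exactly 50% of the voxels.

QC example — one scheduled 0.7 mm movement censors four volumes:

```r
trace <- make_motion_trace(synth_config(
  seed = 7, motion_spikes = list(list(volume = 80, magnitude_mm = 0.7))))
glance(scrub(framewise_displacement(trace), 0.5))
#> # A tibble: 1 × 4
#>   n_volumes n_events n_removed threshold_mm
#> 1       200        1         4          0.5
```

An end-to-end pipeline (simulate → QC → gradients → clusters → seed
connectivity → GLM summary) is available as `run_pipeline()` /
`report_pipeline()` or from the shell:

```sh
Rscript scripts/connectograd.R all --out-dir out --seed 1
```

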