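---
title: "Connectopic gradient mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectopic gradient mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectograd)
```

## The model

`connectograd` asks how the long-range functional connectivity of voxels
inside a small region of interest (ROI) changes across the region. The
underlying assumption is that each ROI voxel's BOLD series is a mixture of a
few distributed network signals, with mixing weights that vary smoothly in
space. If that holds, the voxels' *connectivity fingerprints* — their
correlations with activity outside the ROI — lie near a low-dimensional
manifold, and a spectral embedding of their pairwise similarities recovers
the spatial direction(s) along which connectivity changes.

The chain per subject is:

1. time × voxel matrices for the ROI and for gray matter outside it
   (gray-matter restriction is applied by mask intersection before any
   correlation is computed);
2. percent signal change, then high-pass filtering;
3. lossless SVD reduction of the outside data: the component time courses
   `U·S`, truncated at numerical rank only, span the same column space as
   the raw data, so correlations against them lose nothing while making the
   fingerprint dimension manageable;
4. fingerprints = Pearson correlations of ROI voxels with the components;
5. η² similarity between all fingerprint pairs;
6. Laplacian Eigenmaps (LE) of the similarity graph.

Group results average the per-subject similarity matrices element-wise
before the embedding, which presumes voxel-wise ROI correspondence across
subjects (template space); the package requires pre-aligned ROIs and does
not register subjects itself.

### The η² similarity

For two fingerprints $a, b$ with $m_i = (a_i + b_i)/2$ and grand mean
$\bar M$:

$$\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
                    {\sum_i (a_i - \bar M)^2 + (b_i - \bar M)^2}.$$

It is symmetric, bounded in $[0, 1]$, equals 1 for identical profiles and 0
for a profile and its negation about a zero grand mean. The vectorized
implementation reduces the numerator to half the squared Euclidean row
distance and is tested against a literal double loop to $10^{-12}$.

### The embedding

With $W$ the similarity matrix (diagonal zeroed), $D$ its row-sum diagonal
and $L = D - W$, the modes solve the generalized problem
$L v = \lambda D v$. Numerically this is computed through the symmetric
normalized Laplacian $D^{-1/2} L D^{-1/2}$ — a dense symmetric
eigendecomposition — and back-transformed, which is mathematically identical
but avoids the non-symmetric solver. The $\lambda = 0$ constant vector is
discarded; returned modes are scaled to unit $D$-norm and satisfy
$\|L v - \lambda D v\| \le 10^{-8}\|v\|$ (in practice $\sim 10^{-14}$).
Because η² is non-negative, graph weights need no further conditioning; a
numerically repeated zero eigenvalue is reported as a disconnected ROI.

Eigenvector signs are arbitrary, so each mode is oriented to correlate
positively with the ROI's first spatial principal-axis coordinate (with the
principal axis itself sign-canonicalized); `align_sign()` additionally
aligns modes across sessions for reproducibility comparisons. Ties in
eigenvalues (e.g. a perfectly regular similarity structure) make individual
eigenvectors non-unique; only their span is then meaningful, which the
tests respect by comparing subspaces or correlations rather than entries.

### Scoring and parcellation

Topology preservation is Spearman's rank correlation between
$\{\eta^2_{ij}\}$ and $\{-|v_i - v_j|\}$ over all unordered voxel pairs —
exact, not subsampled, which is feasible at desk-scale ROI sizes (512
voxels → 130,816 pairs). It is reported without a p-value because the
embedding maximizes it by construction. `median_split()` parcels a mode at
its median; voxels exactly at the median join the below-median cluster in
canonical voxel order until that cluster holds ⌈n/2⌉ voxels, so even-sized
ROIs with distinct values split exactly 50/50.

## Preprocessing and QC parameters

| parameter | default | meaning |
|---|---|---|
| high-pass cutoff | 128 s | discrete-cosine drift basis, plus intercept and a linear trend |
| FD threshold | 0.5 mm | scrubbing trigger on framewise displacement |
| rotation radius | 50 mm | converts rotation differentials to arc length in FD |
| scrub window | t−1 … t+2 | censored volumes per supra-threshold event |
| exclusion rule | mean + 1 SD | on per-subject counts of supra-threshold events |

The high-pass basis includes an explicit linear-trend column alongside the
cosines: a pure polynomial ramp then vanishes exactly instead of leaking
through the truncated cosine set, and the operator remains a projection, so
filtering is idempotent. Framewise displacement uses backward differences
with FD of the first volume defined as 0. Standard deviations are sample
(n−1) throughout, including temporal SNR: the spec'd hand value for an
alternating (4, 6) series is approached as $5/\sqrt{n/(n-1)} \to 5$.
Temporal SNR averages the per-voxel mean/SD ratio over the region by
default; the region-mean-series alternative is exposed as
`method = "roi_mean"` because the verbal definition admits both readings.

## Model-based analyses

Representative ROI time series are the first left-singular time course of
the demeaned voxel matrix (sign-fixed against the voxel series).
Partial correlations regress both targets on all controls plus an
intercept and correlate the residuals — verified against the
precision-matrix formula to $10^{-8}$ — and are Fisher-Z transformed before
any across-subject statistic. Network representative series pool all of a
network's sphere voxels into one SVD rather than averaging per-sphere
series, mirroring the single-SVD treatment of ROIs. Group inference on
contrast maps uses one-sample sign-flipping with the max-|t| statistic
(familywise-error corrected, identity flip always included, full
enumeration when $2^n$ is below the requested permutation count). This
replaces cluster-enhancement methods deliberately: the max-statistic test
is exact, assumption-light, and enumerable at test scale.

The stimulus GLM uses the standard double-gamma canonical HRF (response
peak ~5 s, undershoot ~16 s, 1:6 amplitude ratio, unit peak), boxcars
convolved on a 16× oversampled grid, six demeaned motion regressors and an
intercept, and plain OLS per voxel — no prewhitening, since single-subject
autocorrelation does not enter the group-level randomization inference. No
group-level variance smoothing is applied; the pipeline manifest records
this as a deviation.

## The synthetic generator

`synth_config()` fixes the study conditions: a 24³ voxel grid at 2 mm, TR
2.7 s, 200 volumes, 10 subjects; an 8×8×8 ROI whose voxels mix two network
time courses with weights linear in the anterior–posterior voxel index
(ground truth `u` ∈ [0, 1]); two 6×6×6 network blocks and a plain
gray-matter block; multiplicative signal
`baseline · (1 + (1−u)·s_A + u·s_B + noise)` with noise SD 0.5; network
courses are moving-average-smoothed Gaussian noise (window 5),
standardized, redrawn until pairwise |r| < 0.2. Motion traces are
low-amplitude (0.01 mm) sinusoidal drift; scheduled spikes are persistent
translation steps whose framewise displacement equals the scheduled
magnitude to 10⁻⁹. Event schedules are balanced two-condition tables with
2 s stimuli and uniform 1.5–8.5 s ITIs (mean 5 s). The task-network mixing
amplitude is a free parameter (default 1) because no principled value
exists for how strongly such a gradient should express in task data.

These choices emulate what the analyses assume — autocorrelated shared
signals, a smooth monotone mixing gradient, template-space voxel
correspondence — and deliberately omit hemodynamic forward modelling of
the resting signal, physiological noise, scanner artefacts and spatial
autocorrelation of the noise. Passing recovery tests therefore shows the
*pipeline* is correct and identifiable under its own assumptions, not that
real acquisitions satisfy those assumptions.

## Numerical and design notes

- SVD truncation threshold: singular values above
  `max(dim) · eps · s₁`, i.e. numerical rank, so the reduction stays
  lossless in floating point.
- Constant (zero-variance) ROI voxels have undefined correlations; they are
  dropped before similarity computation, warned about, and recorded on the
  fingerprint object.
- Sphere ROIs use a closed ball (≤ radius) on voxel-center world
  coordinates: a 4 mm sphere on a 2 mm grid centered on a voxel center
  contains exactly 33 voxels, which pins down the boundary rule.
- Anterior–posterior ROI splits cut midway between the extreme occupied
  coronal slices, the middle slice joining the posterior half; mediolateral
  splits run per coronal slice around the in-slice median of world x, ties
  joining the lateral half — fixed, documented tie-breaks rather than
  conventions left to the caller.
- The per-hemisphere workflow is one pipeline run per hemisphere mask;
  nothing couples the hemispheres.
- Problem sizes in tests and the acceptance script (10-subject cohorts on a
  24³ grid, 512-voxel ROI, 200 volumes; 40×10 fingerprint oracles; n = 4
  exhaustive sign-flip enumeration) were chosen as the smallest scales at
  which every property is non-trivially exercised; the full suite runs in
  well under a minute of compute per cohort.

## Known limitations

- Group averaging of similarity matrices requires voxel-wise ROI
  correspondence; no registration is provided.
- The embedding returns modes up to eigenvalue degeneracy; near-degenerate
  eigenvalues make individual modes unstable even when their span is
  stable.
- Median splits force equal cluster sizes by design; a genuinely bimodal
  but unbalanced organization would be misrepresented.
- The scrubbing report identifies censored volumes but downstream
  operations are not automatically re-run on censored data; callers subset
  the time axis with the report's `kept` indices.
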