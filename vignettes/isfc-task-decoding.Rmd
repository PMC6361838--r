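---
title: "Methods: ISFC estimation and task-state decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISFC estimation and task-state decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfcdecode)
```

## The estimator

Inter-subject functional correlation (ISFC) targets the component of
functional connectivity that is locked to a shared, time-aligned task. For
subject $k$ with node-by-time matrix $X_k$ ($P$ nodes, $N$ time points),
each row normalised to zero mean and unit variance, the raw estimate is

$$\tilde C_k = \frac{1}{N}\, X_k \Big[\frac{1}{K-1}\sum_{q\neq k} X_q\Big]^{\!\top},$$

the cross-correlation between subject $k$'s nodes and the average series of
all other subjects. Intrinsic fluctuations and artefacts are uncorrelated
across brains, so they attenuate in the reference average and contribute
only noise to the product; stimulus- and goal-locked signal survives. Each
coefficient is Fisher $z$-transformed ($\mathrm{atanh}$), the matrix is
symmetrised as $(\tilde C_k + \tilde C_k^\top)/2$, and subjects are averaged
into a group matrix. The diagonal of the ISFC matrix is the inter-subject
correlation of a node with itself and is treated as a genuine connection:
the edge set of a symmetric $P \times P$ matrix is the diagonal-inclusive
upper triangle in row-major order, $P(P+1)/2$ edges ($34980$ for $P = 264$).
`edge_index(P, include_diagonal = FALSE)` exposes the other convention.

Two readings of the cross-product are possible, and they differ: the rows of
the leave-one-out average do not themselves have unit variance, so the
literal product is a correlation damped column-wise by the reference rows'
standard deviations, while renormalising the reference first gives an exact
Pearson coefficient. `isfc_matrix()` implements the literal product as the
default and exposes `renormalize_reference = TRUE`; the two differ by a
positive column scaling (verified numerically in the tests), which leaves
template-matching decisions essentially unchanged but matters if absolute
values are interpreted.

The pipeline order is fixed: raw product, then Fisher $z$, then
symmetrisation, then group averaging. Fisher's transform is applied with the
argument clamped to $|r| \le 1 - 10^{-6}$ so that self-comparisons (diagonal
elements when target and reference coincide) stay finite.

## Template-matching classification

Task decoding is correlation template matching under leave-one-subject-out
cross-validation (`losocv()`). Per fold:

1. each training subject's runs are averaged per task and row-normalised;
2. a group ISFC template per task is built within the training set (each
   subject against the leave-one-out mean of the *other training* subjects);
3. each held-out run is normalised, its ISFC is computed against the
   across-training-subject mean series of each task, and the run is assigned
   the task whose template yields the larger spatial correlation of edge
   vectors.

The held-out subject's data never enters template construction (asserted in
the tests by mutating held-out data and checking templates bit-identical).
Scores tied to the last bit go to the first task in canonical order
(`beh`), with a warning — a deterministic, auditable tie-break; with
continuous data ties essentially never occur. The FC comparison arm is the
same procedure with within-subject Pearson matrices: per-run correlation
matrices averaged within subject per task and then across subjects (raw
$r$; Fisher averaging is exposed but off by default for FC).

## Similarity analysis and permutation inference

`similarity_analysis()` splits the $K$ subjects into the
$\binom{K}{K/2}/2$ unordered pairs of complementary half-groups (462 for
$K = 12$), builds each half's group ISFC per task, and records within-task
versus between-task spatial correlations. The test statistic is
$\overline{\text{within}} - \overline{\text{between}}$, referenced to a null
built by pooling all values and resplitting at random
(`similarity_permutation_test()`). p-values are exceedance fractions floored
at $1/n_\text{perm}$ — with 1000 permutations the smallest reportable p is
0.001.

Classification significance uses label permutation
(`label_permutation_test()`): task labels of all runs are shuffled and the
entire LOSOCV (template construction included) is re-run per permutation.
Two schemes are provided. The global scheme shuffles all labels jointly;
because a global shuffle occasionally strands a subject with no runs of one
task (making its per-task average undefined), draws are repeated until every
subject retains at least one run per task. The stratified scheme shuffles
within subject, preserving each subject's task balance exactly; it is the
scheme used for the small-design calibration runs below. For families of
statistics (subnetwork cells, scan lengths, edges) the per-permutation
maximum forms a single shared null — max-statistic family-wise error
control. The empirical quantile uses the nearest-rank rule
($\lceil q\,n\rceil$-th order statistic), which is conservative and
reproducible.

## Edge-wise discriminative mapping

The spatial correlation of two $z$-normalised edge vectors is the mean of
their element-wise products, so each edge's product measures its
contribution to a template match. For a run of true task $m$, edge $e$
scores 1 when $C_m(e)\,C_{m,r}(e) > C_u(e)\,C_{m,r}(e)$ ($u \neq m$,
strict inequality; ties score 0, so identical templates yield an all-zero
map). Normalisation is applied per fold over the edge subset in use — the
fold is the unit of classification, so its own templates and test vector
are the natural normalisation scope. Averaging the binaries over all
(run, fold) instances gives $\phi(e) \in [0,1]$; edges are selected where
$\phi$ exceeds the 95th percentile of the permutation null of
$\max_e \phi(e)$.

## Signal-level cleaning

`clean_run()` chains linear projections in a fixed order: linear
detrending; nuisance regression (confounds plus their backward-difference
derivatives, rank-deficient columns dropped with a warning); high-pass
filtering; task-evoked removal; row normalisation. Choices worth noting:

* **High-pass as DCT regression.** Removing all discrete-cosine components
  below the cutoff (default 0.08 Hz; configurable, and necessarily below
  Nyquist $1/2\,\mathrm{TR}$) keeps every cleaning step an exact linear
  projection — they compose predictably and have exact spectral nulls,
  unlike an IIR filter. 0.08 Hz is an aggressive cutoff for connectivity
  work; it is a parameter, not a constant.
* **Canonical HRF.** Double-gamma with response peak 6 s, undershoot peak
  16 s, response:undershoot ratio 6, 32 s kernel, sampled at TR; task
  regressors are condition-wise boxcars convolved with this kernel.
* **Normalisation convention.** Row scaling uses the population ($1/N$)
  standard deviation so that the $1/N$ cross-product of two normalised rows
  is exactly a Pearson correlation (unit self-correlation). Constant rows
  are an error that names the offending node.
* **Framewise displacement.** Sum of absolute frame-to-frame differences of
  the three translations (mm) plus the three rotations (rad) scaled by a
  50 mm head radius; the summary per run is the mean over the $N-1$ frames.

All projection steps are linear (checked numerically) and the chain is
idempotent at the normalisation step.

## The synthetic generator

`generate_dataset()` emulates the study design the estimator assumes:
$K = 12$ subjects, 5 runs per task of each of two attention tasks, 196 time
points at TR $= 2$ s (a 392 s run). Node series decompose as

$$x(t) = \sigma_s A_m s_{m,r}(t) + \sigma_i B_k g_{k,r}(t) + \sigma_n \varepsilon(t).$$

* $s_{m,r}$ — stimulus-locked latents, **bit-identical across subjects** for
  a given (task, run index). This is the alignment assumption of ISFC. In a
  real experiment with per-subject randomised clip order the alignment is
  only approximate; the generator emulates the aligned-signal idealisation
  and cannot simultaneously emulate order randomisation.
* $A_m$ — task loading matrices ($P \times L$). Each latent loads on one
  contiguous subnetwork block of the fixture atlas, with the two tasks
  loading shifted block sets, so the ground-truth task-differential edges
  are known exactly (`ground_truth$diff_edges`).
* $B_k$ — intrinsic loadings, task-independent per subject:
  $B_k = \sqrt{1-w^2}\,B + w\,E_k$ with common $B$ and per-subject $E_k$.
  The weight $w$ (`intrinsic_idiosyncrasy`, default 0.8) makes intrinsic
  connectivity mostly subject-specific, which is what defeats cross-subject
  transfer of FC templates (the connectome-fingerprinting regime) while
  leaving ISFC untouched, since intrinsic latents $g_{k,r}$ are independent
  across subjects either way. At $w = 0$ all subjects share one intrinsic
  covariance and FC decodes the task nearly as well as ISFC.
* Latents are white by default (`ar = 0`), making the node covariance
  analytically $\sigma_s^2 A_m A_m^\top + \sigma_i^2 B_k B_k^\top +
  \sigma_n^2 I$ (verified at $N = 10^4$ in the tests); an AR(1) option
  exists for autocorrelated latents. $B$ is scaled so expected intrinsic
  node variance equals $\sigma_i^2$ regardless of $L_{int}$.

The default variances ($\sigma_s = 0.25$, $\sigma_i = 1.5$,
$\sigma_n = 1$) were chosen once, by a coarse grid over $\sigma_s \times w$,
to reproduce the qualitative regime of interest at desk scale — intrinsic
variance dominating the shared signal, ISFC decoding around 95% while FC
stays near 60% — and then frozen. The defaults are the benchmark; tests and
the acceptance script do not tune them.

What the generator does **not** emulate: haemodynamic smoothing of the
latents, spatially structured noise, scanner drifts and spike artefacts,
stimulus-order randomisation, counterbalancing effects, and realistic
motion coupling. Passing tests on this benchmark therefore demonstrate the
estimator's algebra and the pipeline's statistical calibration, not
performance on real BOLD data.

## Problem sizes and numerical tolerances

The test-suite and acceptance-script simulations use: the full benchmark
(12 subjects, 60 nodes, 196 time points) for the ISFC/FC contrast,
similarity (462 splits), discriminative mapping (100-permutation max-null)
and scan-length curves (lengths 20–180, 10 repetitions); a reduced design
(6 subjects, 24 nodes, 80 time points) for 1000-permutation null
calibration and for the 20-simulation family-wise-error check. These sizes
keep every run deterministic from a single seed and complete in minutes
while leaving the qualitative contrasts far from their decision thresholds.

Exact linear-algebra identities are asserted at $10^{-12}$, OLS
orthogonality at $10^{-8}$, and Monte-Carlo quantities at bounds derived
from their sampling variance (e.g. covariance recovery within six standard
errors of the largest element). The scan-length curve is required to be
non-decreasing within a 0.05 sampling tolerance between adjacent grid
points.

## Known limitations

* Two tasks only in the decoding surface; the template-matching core
  generalises, but report containers assume a binary contrast.
* ISFC requires temporally aligned stimulation across subjects; the
  estimator is not meaningful for rest or unaligned designs (the
  scan-length windows are therefore shared across subjects, never drawn
  independently per run).
* The permutation machinery re-runs the full analysis per permutation;
  costs scale linearly in `n_perm`, and nulls can be persisted via
  `null_distribution()` objects if needed.
* No NIfTI/volume handling: voxel-level input arrives as a voxel-by-time
  matrix plus a voxel-to-node label vector (`extract_node_series()`), and
  rendering is delegated to external viewers via `export_brainnet()`.
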