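---
title: "kompot: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kompot: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

kompot compares single-cell conditions on a continuous cell-state
manifold: condition-specific Gaussian-process (GP) functions for
log-density and for log-expression are estimated over a shared
diffusion-map space, and per-cell / per-gene statistics are derived from
their posteriors. This vignette is the package's own account of the
models, the parameters that matter, the numerical choices, and the limits
of what the test suite establishes.

## 1. Cell-state space

The input is a co-embedded, batch-corrected latent representation
(`latent_embedding()`); kompot performs no integration itself and all
conditions share one space. `compute_diffusion_map()` builds an exact kNN
graph (Euclidean), an adaptive-bandwidth Gaussian kernel
$K_{ij} = \exp(-d_{ij}^2/(\sigma_i\sigma_j))$ with $\sigma_i$ the distance
to the `n_neighbors`-th neighbor, symmetrizes by the arithmetic mean, and
eigendecomposes the anisotropically normalized Markov operator.

Parameters:

* `n_neighbors` (default 30) — graph scale; too small disconnects the
  manifold (a disconnected graph is an error, not a warning, because a
  single connected manifold is assumed).
* `alpha` (default 1) — anisotropic normalization exponent. At 1 the
  operator approaches the Laplace–Beltrami limit, removing the influence
  of sampling density on the geometry. This matters here more than in
  generic spectral embedding: density is the *measurand* of the DA module,
  so the state space should not encode it a second time.
* `n_components` (default 10) and `scale_by_eigenvalues` (default off) —
  how many coordinates and whether to weight them. Eigenvalue scaling is
  cosmetic for downstream GPs, whose kernels have their own length-scale;
  both remain configurable because no canonical choice exists.

Reproducibility: eigenvector signs are fixed (largest-magnitude entry
positive), making results deterministic and rotation-invariant up to
numerical tolerance. Eigendecomposition is dense; desk-scale datasets
(≲ 5000 cells) need no iterative solver.

## 2. Density model

For the cells of one condition, the nearest-neighbor distance $r_i$ of
cell $i$ is modeled as the waiting distance of a locally homogeneous
Poisson process in intrinsic dimension $d$:

$$\log p(r_i \mid g_i) = g_i + \log d + \log V_d + (d-1)\log r_i -
e^{g_i} V_d r_i^d,$$

with $V_d$ the unit-$d$-ball volume and $g(\cdot)$ the latent log-density
(natural-log cells per volume) under a Matérn-5/2 GP prior with a learned
constant mean. `fit_density()` computes the MAP in a whitened
parameterization (L-BFGS; non-convergence is an error carrying the final
gradient norm) and a Gaussian approximation of the posterior for
uncertainty. Above `landmark_threshold` (5000) cells the latent function
is represented on k-means inducing points.

### Intrinsic dimension

`estimate_intrinsic_dimension()` is the two-NN maximum-likelihood
estimator $\hat d = 1/\mathrm{mean}_i \log(r_{2i}/r_{1i})$, global across
the dataset, scale-invariant, clipped to $[1, \text{ambient}]$. A correct
$d$ is what gives density the unit cells/volume and makes the
$\log N$ normalization meaningful. A spatially varying dimension is out of
scope.

### Hyperparameters

* **Length-scale** — `ls_mult` (default 6) × the median 25-NN distance.
  A single nearest-neighbor distance is an extremely noisy density
  observation (its log has variance $\pi^2/6$ in natural units), so the
  prior must pool hundreds of cells. The default multiplier was chosen
  once by a calibration study on the package's own synthetic benchmarks:
  it is the smallest of the scales examined at which null-data z-scores
  ($\Delta/\sqrt{\sigma_a^2+\sigma_b^2}$) are not anti-conservative in any
  density stratum, while leaving mixture-shift recovery and the analytic
  log-density correlation unchanged. It is deliberately *not* re-optimized
  per fit by marginal likelihood: the heuristic is stable across
  same-geometry condition fits (< 2 % spread), and that stability matters
  more for the *difference* statistic Δ than absolute optimality.
* **Amplitude** — the robust (1 %–99 % clipped) SD of the pointwise MLE
  $g^0_i = -\log V_d - d\log r_i$; the clipping guards against jittered
  duplicates whose $g^0$ is arbitrarily large.
* **Duplicates** — exact duplicates break the likelihood ($r=0$) and are
  perturbed with a warning. The jitter is data-scaled
  ($\max(10^{-10}, 10^{-7}\times$ median kNN distance$)$): an absolute
  $10^{-10}$ perturbation would vanish below the floating-point
  cancellation floor of squared-distance computation.

### Uncertainty: moment matching vs. plain Laplace

The predictive variance comes from the Gaussian approximation
$(K^{-1}+H)^{-1}$ propagated through the GP predictive equations, with two
deliberate choices:

1. The precision matrix is over the *full* parameter vector including the
   learned constant mean. Omitting the mean is strictly anti-conservative:
   its error shifts the entire log-density coherently, which is exactly
   the failure mode a normalized difference statistic is sensitive to.
2. The per-cell likelihood curvature $e^{g}V_d r^d$ (= 1 at the per-cell
   optimum) is divided by $\mathrm{trigamma}(1)=\pi^2/6$ by default
   (`uncertainty = "moment_matched"`). The per-site likelihood is a skewed
   log-Gamma form whose exact single-site posterior variance is
   $\mathrm{trigamma}(1) \approx 1.645$, not $1/\text{curvature} = 1$;
   plain mode curvature therefore overstates the information of each cell.
   Empirically, plain Laplace (`uncertainty = "laplace"`, also available)
   makes null-data PTPs anti-conservative (the fraction of cells with
   PTP < 0.05 exceeds 0.10 in the median seed), while moment matching
   restores calibration. The cost is mild conservatism where many cells
   pool (the CLT-argument variance of a pooled estimate is $1/n$, not
   $\pi^2/6n$); we consider a conservative posterior tail the right
   default for a significance statistic.

## 3. Differential abundance

With independent per-condition posteriors, the density change at state
$x$ is $\delta(x) \sim \mathcal N(\mu_b-\mu_a,\ \sigma_a^2+\sigma_b^2)$.
Normalization subtracts $\log N$ per condition (valid only with a correct
intrinsic dimension), giving
$\Delta(x) = \mu_b - \mu_a - \log(N_a/N_b)$, and
$\mathrm{PTP} = \Phi(-|\Delta|/\sqrt{\sigma_a^2+\sigma_b^2})$.

Choices worth knowing:

* Natural-log convention throughout; display layers may convert.
* The two-sided rule (|Δ|) resolves the tail direction by the sign of the
  point estimate; PTP ∈ (0, 0.5], equal to 0.5 iff Δ = 0. In the
  degenerate both-σ-zero limit PTP is 0 (Δ ≠ 0) or 0.5 (Δ = 0).
* Both densities are evaluated at the union of all cells' states, so every
  cell receives a statistic wherever it was observed.
* **No multiple-testing correction.** PTPs are Bayesian posterior tail
  probabilities reported as-is, not frequentist p-values; thresholding
  them controls nothing frequentist. Defaults (|Δ| > 1, PTP < 10⁻³) are
  deliberately stringent.
* More than two conditions are handled as all ordered pairwise
  comparisons.

## 4. Expression model and differential expression

`fit_expression_gp()` is landmark (inducing-point) GP regression from
cell states to log-normalized expression, with a kernel and homoskedastic
noise shared by all genes of a condition. The sharing is what makes
thousands of genes tractable: the expensive factorizations and the
landmark posterior covariance Σ (k × k) are computed once, and genes
differ only through their mean vectors. Per-gene kernels would invalidate
that reuse and are intentionally not the default. At landmarks = training
points the model is algebraically the exact GP (verified against an
independent exact-GP oracle), and with noise → 0 it interpolates.

Expression must arrive log-normalized (validated: finite, non-negative,
max < 50); kompot does not normalize counts. Noise SD defaults to 0.3 on
the log scale — a deliberately generous figure for residual
(non-smooth-manifold) variation in log1p-normalized data; it is shared
across genes and configurable.

`compare_expression()` evaluates both predictors at a landmark set
re-selected (k-means, k = `de_n_landmarks`, default 50) from the evaluated
cell group's states — *re-selected* rather than masked from global
landmarks so that covariance resolution tracks the subset's extent and
Σₐ+Σ_b stays well-conditioned. Per-gene:

* `mean_lfc` — unweighted mean over the group's states of
  $\mu_b(x,g)-\mu_a(x,g)$ (a density-weighted mean is a reasonable
  alternative; unweighted is the documented default).
* `mahalanobis` — $D = \sqrt{(\mu_a-\mu_b)^\top(\Sigma_a+\Sigma_b)^{-1}
  (\mu_a-\mu_b)}$ via one Cholesky factorization reused across genes
  (never an explicit inverse), jitter escalating $0 \to 10^{-10} \to
  10^{-4}$ relative. The root, not the quadratic form, is returned: D
  reads as "posterior standard deviations of coordinated shift", and at
  k = 1 reduces exactly to the abundance z-score.
* Categories: significant (|mean_lfc| > 0.15 and D > 3) and divergent
  (|mean_lfc| < 0.07 and D > 6) — the latter captures coordinated but
  opposing shifts whose net fold change cancels; such genes are invisible
  to fold-change-only rankings.
* D is a ranking score. No null distribution is attached and no
  multiple-testing correction is applied; the planted-effect tests
  establish rank separation, not error control.

## 5. Synthetic data: what it emulates, what it does not

`make_mixture_manifold()` generates either isotropic Gaussian mixtures
(components 6 SD apart by default — clearly separated, mildly overlapping)
or branching line segments with Gaussian cross-section (branch noise
SD 0.1, branches meeting at the origin), with condition-specific component
weights and *analytic* per-condition densities ($N_c$ × mixture pdf, so
true Δ is available at every cell). `plant_expression()` draws smooth
baseline gene functions (random affine form through a sigmoid, scaled
0.5–2.5, offset 2 so negative effects cannot push values below zero) plus
Gaussian noise (default SD 0.1 on the log scale) and adds per-gene
effects: null, global shift, localized shift (one component), opposing
shift (±δ on branches 1/2). Default test sizes are 500–1000 cells per
condition, 30–50 genes, δ = 1.

These are statistical test doubles. They emulate what the method assumes —
smooth manifolds, condition-dependent state abundance, smooth expression
functions — and none of what real scRNA-seq adds: counts, dropout,
library-size variation, batch structure, doublets. A green test therefore
establishes correctness of the statistics under the model's assumptions,
not robustness to violations of them. An optional negative-binomial count
layer (`as_count_layer()`) exists purely to exercise input tolerance.

## 6. Determinism and serialization

Every stochastic step (generators, k-means++, inducing-point selection)
takes an explicit seed; `run_pipeline()` derives per-stage sub-seeds from
the single config seed. Library code never touches the caller's RNG state.
Output tables are TSV with 17-significant-digit numerics, so fixed-seed
reruns are byte-identical; the run manifest (always written, also on
failure, with the failing stage) carries the timestamp and is excluded
from that contract. Fixture bundles round-trip to 1e-12. Models serialize
with `saveRDS`; config files are JSON.

## 7. Known limitations

* PTP calibration is approximate: hyperparameter uncertainty
  (length-scale, amplitude) is not propagated, and the moment-matched
  variance is conservative in dense regions.
* The constant-dimension assumption biases density where the manifold's
  local dimension varies.
* Subset DE re-selects landmarks, so D values are not directly comparable
  across subsets of very different sizes.
* Replicate-aware (sample-level) testing, covariate adjustment, raw-count
  likelihoods, pseudotime and enrichment are out of scope.
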