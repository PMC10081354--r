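---
title: "Methods: geodesic mean estimation with mSPD-NN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geodesic mean estimation with mSPD-NN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the numerical choices, and
the known limitations of the package. Code chunks are illustrative and not
evaluated at build time.

## The model

A functional connectome is summarized as a symmetric positive definite
(SPD) matrix $\Gamma \in \mathcal{P}_P^+$. The package works throughout
with the affine-invariant Riemannian metric, under which the distance
between two SPD matrices is

$$\delta(\Gamma_1, \Gamma_2)
  = \lVert \log(\Gamma_1^{-1/2}\,\Gamma_2\,\Gamma_1^{-1/2}) \rVert_F ,$$

computed via the symmetric whitened form for numerical stability (the
algebraically equivalent $\log(\Gamma_1^{-1}\Gamma_2)$ involves a
non-symmetric matrix logarithm). The group representative of a collection
$\{\Gamma_n\}_{n=1}^N$ with weights $w_n$ is the weighted Fréchet mean

$$G^\ast = \arg\min_G \sum_n w_n\, \delta^2(G, \Gamma_n),$$

whose first-order optimality condition is the *matrix-normal equation*

$$\sum_n w_n \log\!\big(G^{-1/2}\,\Gamma_n\,G^{-1/2}\big) = 0 .$$

`condition_fit(G, collection)` evaluates the squared Frobenius norm of this
residual (scaled by $1/P^2$) at any candidate mean and is the package's
estimator-agnostic quality diagnostic: it is zero if and only if the
candidate is stationary, and requires no knowledge of how the candidate was
produced.

## mSPD-NN

The network is a single tied-weight bilinear layer. With
$\tilde W = W + \lambda I$ and $V = \tilde W \tilde W^\top$, each input is
mapped to $V \Gamma_n V$, and training minimizes

$$L(W) = \frac{1}{P^2}\,\Big\lVert \sum_n w_n \log(V\,\Gamma_n\,V)
  \Big\rVert_F^2 .$$

At a global minimum the matrix-normal equation holds for $G = V^{-2}$, so
the mean is recovered as $\hat G = V^{-2}$ at the trained weights. The
ridge $\lambda$ (default `1e-4`) keeps $\tilde W$ full rank so that the
matrix logarithm stays defined along the whole trajectory; it perturbs the
optimum only through the parametrization, not the loss landscape in $V$.

Weights are initialized i.i.d. uniform on $[-1/\sqrt P,\, 1/\sqrt P]$,
controlled by `init_seed` for exact reproducibility.

### Optimization: presets, batch mode, and the polish phase

`mspdnn_config()` exposes two presets.

* **`"default"`** follows the reference training recipe for
  connectome-scale inputs: Adam, learning rate `0.001` decayed by `0.8`
  every 50 epochs, at most 100 epochs, stopping when the loss falls below
  `1e-4`. On well-conditioned correlation-matrix inputs (eigenvalues near
  1) this is adequate; the stopping tolerance, not machine precision, is
  its accuracy contract.

* **`"accurate"`** exists because the default schedule demonstrably
  underfits on generic SPD inputs with eigenvalue spread: with a step
  budget of $100$ epochs and a learning rate of $10^{-3}$, the iterate can
  move only $O(0.1)$ per entry, while the distance to the optimum is often
  $O(1)$. The accurate preset uses learning rate `0.01` held constant for
  the first 70% of 200 epochs (annealing from the start freezes the
  iterate prematurely) and then the same geometric decay, followed by a
  **full-batch L-BFGS polish** of the identical loss in $W$. The polish
  restarts with the objective rescaled to order 1 because quasi-Newton
  relative-progress stopping rules become absolute for objectives below 1;
  two to three restarts drive the residual to numerical stationarity
  (condition fits of $10^{-26}$ and below). This is an optimizer choice on
  the same model and loss, not a model change.

Batch mode is a deliberate design decision. One full-batch step per epoch
is, under the budgets above, far too little movement; the package therefore
defaults to **per-sample (stochastic) Adam steps** — one step per sample
per epoch — which optimizes the same objective because the sum of
per-sample matrix-normal losses coincides with the Fréchet objective's
stationarity structure. `batch = "full"` is retained and is exactly
order-invariant; the stochastic mode is order-dependent during training,
but with the accurate preset both modes converge to the unique optimum, so
permutation invariance holds to far below the documented `1e-6` at the
returned mean.

### Baselines

* `gradient_descent_mean()` is classical fixed-step Riemannian gradient
  descent from the arithmetic-mean initializer:
  $G \leftarrow G^{1/2} \exp\!\big(s \sum_n w_n \log(G^{-1/2} \Gamma_n
  G^{-1/2})\big) G^{1/2}$, default step $s = 0.5$ (step 1 solves commuting
  collections in one iteration; 0.5 is a safe contraction for generic
  collections), tolerance `1e-10` on the tangent-update norm, 200
  iterations. Hitting the cap reports `converged = FALSE` instead of an
  error, so benchmark sweeps never abort.
* `ale_mean()` approximately jointly diagonalizes the collection with
  Pham's Jacobi-like sweeps (`ajd_pham`), averages the logs of the
  diagonals in that basis, and maps back. It is exact on common
  principal components (CPC) data and on any two-matrix collection (every
  SPD pair is jointly diagonalizable), and degrades gracefully as the
  shared-basis assumption is violated — which is precisely what the noise
  benchmark measures.

## Synthetic generators: what they do and do not model

`sample_cpc_dataset()` draws $\Gamma_n = B\,C_n\,B^\top$ with one shared
basis $B$ (i.i.d. standard normal entries) and per-sample diagonal weights
$c_{nk} = \max(z_{nk}^2, 0.001)$, $z \sim \mathcal N(0,1)$. Positivity
forces the square (a chi-squared(1) variate); the clip avoids near-singular
samples. The closed-form optimal mean
$G^\ast = B \exp\!\big(\tfrac1N \sum_n \log C_n\big) B^\top$
(`theoretical_cpc_mean`) is what makes this generator an oracle. Bases
whose condition number exceeds $10^{12}$, or that produce any sample
failing SPD validation, are resampled with an incremented sub-seed; the
coefficient draw is independent of that mechanism, so accepted datasets are
unchanged by it.

`add_structured_noise()` perturbs each sample by $\tfrac1P x_n x_n^\top$,
$x_n \sim \mathcal N(0, \sigma^2 I)$ — a rank-one, positive semidefinite
corruption that breaks the shared-basis structure without leaving the SPD
cone. This targets the ALE mean's modelling assumption specifically; it is
not a realistic fMRI noise model (no temporal structure, no
subject-specific variance profiles).

`sample_clustered_cohorts()` places cohort centroids at controlled geodesic
separation along Frobenius-orthonormal tangent directions and members at an
exact geodesic distance (`within_spread`) from their centroid. It is a test
fixture with a known geometry, not a generative model of patient cohorts.

Realism limits common to all three: simulated matrices are dense SPD with
moderate dimension; they are not correlation matrices (unit diagonal is not
enforced), carry no parcellation structure, and noise enters the matrices
directly rather than through time series.

## Evaluation harnesses

`run_scalability_experiment()` and `run_noise_experiment()` sweep dataset
size, dimension, or noise level, recording per fit the condition fit, the
normalized recovery error
$d_{\text{mean}} = \delta^2(\hat G, G^\ast) / \lVert G^\ast \rVert_R^2$
(only when a closed-form reference exists), runtime, and convergence.
Individual fit failures become `converged = FALSE` rows rather than
aborting a sweep. The default grids (`values = c(5, 10, 20)`, ten
replicates, noise grid $\sigma \in \{0.2, \dots, 1.0\}$ at $P = 30$,
$N = 20$) are the package's own desk-scale profile, chosen to finish in
minutes on one CPU; larger published-scale grids are reached by passing
them explicitly. `vary_across` controls whether replicates redraw the data,
the initialization, or both (default `"both"`, which is what a practitioner
re-running an analysis end to end experiences); `"init"` isolates optimizer
variance and is what `initialization_concordance()` consumes.

## Group-analysis pipeline

* `correlation_connectome()` shrinks the Pearson matrix toward the
  identity, $(1-s)C + sI$ (default $s = 0.05$), because raw correlation
  matrices of short series are rank deficient.
* `bootstrap_group_distance()` subsamples each group per trial, estimates
  both means, and compares between-group distances against matched
  split-half within-group distances with a one-sided paired Wilcoxon
  signed-rank test. The pairing against split-half distances is a design
  decision: it gives each trial an internal null of the same sample size.
* `permutation_edge_selection()` uses the absolute entrywise difference of
  group means as the per-edge statistic, re-estimates both means per label
  shuffle, applies the add-one permutation p-value, and controls FDR with
  Benjamini–Hochberg over the upper triangle (default `alpha = 0.001`).
  Whether the per-shuffle means should be full-group or bootstrapped
  estimates is ambiguous in the source narrative; the package defaults to
  full-group means and exposes `subjects_per_estimate` to switch every
  estimate to seeded subsamples.
* `classify_with_selected_features()` is deliberately thin glue around
  `randomForest` and `pROC`: edge selection is the scientific step,
  classification merely quantifies its usefulness.
* `mspd_em_cluster()` alternates nearest-centroid assignment under the
  geodesic distance with mSPD-NN re-estimation of centroids. Ties go to the
  lowest cluster index and empty clusters keep their previous centroid —
  both rules chosen for determinism and auditability.

## Reproducibility

Every stochastic operation takes an explicit seed; seeds are restored after
use, so library calls never disturb the caller's RNG stream. The CLI writes
a JSON manifest per run (command, resolved parameters, every seed, package
version). Text formats store floats at 17 significant digits, so write/read
round-trips are exact.

## Limitations

* The affine-invariant metric requires strictly positive definite inputs;
  rank-deficient connectomes must be regularized first
  (`correlation_connectome` does this).
* Pham's joint diagonalization assumes a real, positive definite family
  and can converge slowly for large, strongly non-commuting collections.
* The stochastic training default makes the *trajectory* order-dependent;
  use `batch = "full"` where bitwise order invariance of the whole run
  matters.
* Fit cost grows with $O(P^3)$ per matrix logarithm and linearly in $N$
  per epoch; dimensions in the hundreds are feasible but not tuned for.
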