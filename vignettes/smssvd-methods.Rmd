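---
title: "Adaptive signal decomposition by submatrix selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive signal decomposition by submatrix selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smssvd)
```

## The model

The package decomposes a variables-by-samples matrix $X \in \mathbb{R}^{P \times N}$
(the $P \gg N$ orientation usual for expression matrices) into a sum of
orthogonal low-rank *signals*,

$$ X \approx U \Sigma V^T = \sum_{k} U_k \Sigma_k V_k^T, $$

where each signal is found adaptively: a subset of variables is selected so
that mostly-noise variables are avoided, a low-rank representation of the
selected submatrix is computed by truncated SVD, and that representation is
then *expanded* back to all variables. The expansion is the SVD of $X$
restricted to the subspace $\Pi$ of sample space spanned by the submatrix's
right singular vectors: computing the thin SVD of the $P \times d$ matrix
$X B$ (with $B$ an orthonormal basis of $\Pi$) and rotating the right factor
back gives factors that satisfy $XV = U\Sigma$, have orthonormal columns,
and leave the selected variables' low-rank representation untouched
($S^T U \Sigma V^T = \tilde U \tilde\Sigma \tilde V^T$). After each signal,
deflation $X_{k+1} = (I - U_k U_k^T) X_k$ reduces the rank by exactly $d_k$
and forces all later signals to be orthogonal to the current one on both the
variable and the sample side. With variable selection disabled the procedure
reproduces the truncated SVD; with selection it trades global optimality for
adaptive noise suppression per signal, and $U\Sigma V^T \neq X$ in general —
the difference is the removed noise.

Assumptions worth keeping in mind: the method is purely linear-algebraic (no
distributional model of the data); signals are taken to be low-rank with
support concentrated on a subset of variables whose *sample variance* is
informative; and no centering is applied by default, because the restricted-SVD
identities are statements about the raw linear map. PCA-style use can opt in
with `center_variables = TRUE`.

## Variable selection and the projection score

For each candidate standard-deviation threshold $t$, the subset keeps the
variables with sample std (denominator $N-1$) strictly above $t$. A subset's
usefulness for a rank-$d$ representation is measured by the informativeness

$$ \tau_d = \sqrt{\frac{\sigma_1^2 + \cdots + \sigma_d^2}
                      {\sigma_1^2 + \cdots + \sigma_r^2}} $$

of the selected submatrix, compared against a randomization null: the mean
$\tau_d$ over copies of the submatrix in which every variable's entries are
independently permuted across samples. The permutation destroys
inter-variable correlation (hence any low-rank structure) while preserving
each variable's marginal distribution exactly, so no distributional
assumption is needed. The *projection score* is the difference
$\tau_d(\text{observed}) - \overline{\tau_d(\text{randomized})}$; positive
values mean the subset carries more rank-$d$ structure than chance. The
score is optimized jointly over a threshold grid and $d = 1..d_{\max}$, and
the arg-max supplies both the selection and the signal dimension — this is
what makes the procedure parameter-free.

### Tunable parameters

* `n_randomizations` (default 10): randomized copies per grid cell. The
  null $\tau_d$ concentrates tightly, so few copies suffice; raising it
  mainly smooths the score surface.
* `threshold_grid_size` (default 32): thresholds are the empirical quantiles
  of the per-variable stds at levels $0, 1/32, \ldots, 31/32$, deduplicated
  and always including 0, so the grid adapts to any data scale.
* `d_max` (default 20, further capped by $N-1$ and the remaining dimension
  budget): largest candidate dimension per iteration.
* `target_dim`: total dimensions to extract. With `target_dim = NULL`
  ("library mode") iteration continues while the optimal score is positive
  and the residual is numerically nonzero.
* `seed`: all randomization streams derive from it deterministically.

### Numerical and determinism choices

* **Sign convention.** Each singular triplet is flipped so the
  largest-magnitude entry of the $U$ column is positive (ties: lowest
  index), making results reproducible across linear-algebra backends.
* **Numerical rank.** Singular values above $10^{-12}\,\sigma_{\max}$ count.
  Inside the score grid, singular values come from a symmetric
  eigendecomposition of the smaller Gram matrix (fast in the $P \gg N$
  regime but accurate only to about $\sqrt{\varepsilon}$ relative), so grid
  cells use a $10^{-7}$ relative validity cutoff and the chosen cell is
  re-verified with a full LAPACK SVD at $10^{-12}$ before being accepted.
* **Tie-breaking at the arg-max**: smaller $d$ first, then larger threshold
  (fewer variables) — parsimony, deterministically.
* **Dimension-budget overshoot**: if the optimal $d_k$ would exceed the
  remaining budget, the candidate grid is capped by the budget and, as a
  belt-and-braces rule, a final signal is truncated to its leading singular
  values.
* **Ties across the $d$-th singular value** of the submatrix are not given
  special treatment: truncation is at exactly $d$ and the selected subspace
  is then non-unique; with the deterministic LAPACK ordering the result is
  still reproducible.
* **Signal order** is discovery order; the concatenated singular values are
  descending within each signal but are not re-sorted across signals.
* **Randomization streams** are keyed per (iteration, threshold cell,
  randomized copy, variable), with the variable key being the variable's
  rank in the std ordering. Consequences: scores are independent of
  evaluation order, reproducible under a fixed seed, exactly invariant under
  row reordering of the input (up to std ties), and each grid cell redraws
  its own permutations (reusing draws across cells would correlate the
  score surface; we prefer independent cells).
* The permutation generator is an explicitly coded Mersenne Twister with a
  hand-written Fisher–Yates shuffle, so streams do not depend on compiler or
  standard-library internals.

## The synthetic benchmark

`generate_dataset()` plants $K$ mutually orthogonal signals
$Y_k = U_k \Sigma_k V_k^T$ in a $P \times N$ matrix: each new factor column
is an i.i.d. Gaussian vector projected onto the orthogonal complement of all
previously drawn columns (for $U_k$, within a support of $L$ randomly chosen
variables, then zero-padded — which still guarantees full-space
orthogonality), and the singular values follow the geometric schedule
$(\Sigma_k)_{ii} = 0.6^{k-1}\, 0.9^{i-1}$, so power declines both between
signals and within each signal. Gaussian noise $\varepsilon_{ij} \sim
N(0, \sigma_{ij})$ is added everywhere, only outside the union of supports,
or not at all. Defaults $N = 100$, $K = 8$ mirror the benchmark conditions
the generator emulates; `two_signal_fixture()` pins the two-signal geometry
($P = 5000$, $N = 32$, two rank-2 signals with disjoint 64-variable
supports).

What the generator does *not* emulate about real expression data: count
distributions and mean–variance coupling, batch structure, heavy tails,
missingness, and correlated (structured) noise. A green test on this
generator therefore establishes the linear-algebraic and selection behavior
of the method under its own stated model, not performance on any particular
real dataset.

### Noise scale and what "recoverable" means

With the schedule above, the strongest signal has $\|Y_1\|_F \approx 1.35$
spread over an $L \times N$ block, so its per-variable sample stds are only
about $0.02$–$0.07$ for $L = 64$. Two consequences that shaped the test
suite:

* For i.i.d. noise of scale $\sigma$, the top noise singular value is about
  $\sigma(\sqrt P + \sqrt N)$ — already $\approx 7.6$ for $P = 5000$,
  $\sigma = 0.1$ — so at $\sigma \gtrsim 0.05$ *no* method can recover the
  planted signals and error comparisons only measure how noise fits leak
  onto the supports. The full-noise benchmark tests at those scales are
  therefore directional comparisons, not recovery claims.
* Variance filtering can only isolate a noise-free support if the support
  rows' stds exceed the *maximum* noise std ($\approx 1.4\sigma$ over
  thousands of rows). The partial-noise demonstration uses
  $\sigma = 0.005$, derived from this inequality before running the test;
  at that scale adaptive selection beats the truncated SVD on every signal
  with relative errors below $0.01$. Exact (machine-precision) recovery
  would additionally require the score optimum to retain *only* noise-free
  rows, which the score does not guarantee — a known limitation.
* Noiseless recovery is exact when supports are row-disjoint (restriction
  then preserves the SVD's block separation); with overlapping supports the
  selected-submatrix SVD mixes signals and recovery is only approximate.

## Evaluation apparatus

* `reconstruction_error()` is the Frobenius error restricted to the rows of
  the signal's support; entries outside the support never count.
* `greedy_match()` assigns decomposition components (rank-1 triplets) to
  planted signals, exactly rank-$Y_k$ many per signal, committing at each
  step the assignment that lowers the total error most (ties: lowest
  component index, then lowest signal index). On components produced by
  actual decompositions of planted data the greedy optimum coincides with
  the exhaustive-search optimum on every small instance we enumerate; on
  adversarial arbitrary components it can be suboptimal — the test suite
  checks the weaker property that it dominates random valid assignments.
* `gmm_aic()` fits one maximum-likelihood Gaussian per class with priors
  proportional to class sizes and reports $\mathrm{AIC} = 2k - 2\ell$ with
  $k = C\,(D + D(D+1)/2)$. The log-likelihood is the *conditional*
  (classification) likelihood of the labels given the coordinates via
  Bayes' rule — the labels are the random object being explained. The
  alternative joint reading (likelihood of coordinates and labels) is
  documented here but not implemented. No covariance regularization is
  applied by default; an optional ridge flag exists for tiny classes.

## Known limitations

* The score surface on noise-dominated data is nearly flat, so the selected
  $(S, d)$ there is effectively arbitrary (though deterministic under the
  seed); downstream, library mode may keep iterating on such data because
  the maximum of many near-zero scores is usually positive.
* Missing values are rejected, not imputed; normalization is the user's
  responsibility upstream.
* Weights-mode selection is supported throughout the linear algebra, but
  the threshold optimizer only produces subset selections.
* No kernel extension and no sparse/penalized (lasso-style) selection.
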