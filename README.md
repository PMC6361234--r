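# smssvd

Parameter-free, unsupervised signal decomposition for variables-by-samples
data matrices — the `P × N`, `P ≫ N` orientation typical of bulk and
single-cell expression data, where a handful of overlaid low-rank signals
(biology, batch, artefacts) sit on top of noise that dominates most
variables.

## What it does

Each iteration extracts one signal in four steps:

1. **Selection** — choose the variable subset `S` (variables with sample
   std above a threshold) and the signal dimension `d` that jointly
   maximize the *projection score*: the top-`d` singular-mass fraction
   τ_d of the selected submatrix minus its mean under a within-variable
   permutation null,
   `τ_d = sqrt((σ₁² + … + σ_d²) / (σ₁² + … + σ_r²))`.
2. **SVD** — rank-`d` truncated SVD `Ũ Σ̃ Ṽᵀ` of the submatrix `SᵀX`.
3. **Expansion** — SVD of `X` restricted to the subspace spanned by `Ṽ`,
   computed from the thin SVD of `X Ṽ`. This expands the signal to all `P`
   variables while leaving the selected ones untouched
   (`Sᵀ U Σ Vᵀ = Ũ Σ̃ Ṽᵀ`) and satisfies `X V = U Σ`.
4. **Deflation** — `X ← (I − U Uᵀ) X`, which lowers the rank by exactly `d`
   and makes every later signal orthogonal to this one.

The concatenated factors `U Σ Vᵀ` form an SVD-like, denoised, low-rank
decomposition with orthonormal `U` and `V` across all signals. With
selection disabled the result *is* the truncated SVD. The package also
ships the matching synthetic benchmark (orthogonal sparse-support signals
with geometric power decay `0.6^(k−1) 0.9^(i−1)` plus Gaussian noise),
support-restricted reconstruction error with greedy component matching,
Gaussian-mixture AIC scoring of sample representations, and TSV/CSV/
MatrixMarket I/O with a small CLI.

## Worked example

```r
library(smssvd)

# two orthogonal rank-2 signals on disjoint 64-variable supports,
# light noise everywhere
ds  <- generate_dataset(synthetic_config(P = 2000, L = 64, d = 2, N = 60,
                                         K = 2, noise_sigma = 0.005,
                                         disjoint_supports = TRUE, seed = 7))
res <- smssvd(ds$X, target_dim = 4, config = smssvd_config(seed = 1))
print(res)
#> smssvd decomposition: 1 signal(s), total dimension 4
#>   signal 1: d = 4, 125 variables, threshold 0.006229, score 0.4609, sigma = [1.025, 0.9263, 0.6444, 0.5899]

gm <- greedy_match(rank1_components(res), ds$signals)
round(gm$per_signal_error, 5)
#> [1] 0.08248 0.07841
```

The optimizer picked a threshold keeping 125 of 2000 variables —
essentially the union of the two planted 64-variable supports — and a
4-dimensional signal whose singular values (1.03, 0.93, 0.64, 0.59) track
the planted schedule (1, 0.9, 0.6, 0.54). The support-restricted errors
0.082 and 0.078 are 6% and 10% of the planted signal strengths (1.345 and
0.807); the rank-4 truncated SVD baseline scores 0.083 and 0.081 on the
same data. The gap widens sharply when noise is confined to non-signal
variables — see the partial-noise tests and the methods vignette
(`vignettes/smssvd-methods.Rmd`) for when selection helps and when nothing
can.

Command line:

```sh
Rscript -e 'smssvd::smssvd_cli()' simulate --p 2000 --l 64 --d 2 --n 60 --k 2 \
    --noise-sigma 0.005 --seed 7 --out sim
Rscript -e 'smssvd::smssvd_cli()' decompose --input sim.X.tsv --dims 4 --out run
# run.U.tsv, run.V.tsv, run.sigma.tsv, run.signals.json, run.scoregrid.<k>.tsv
```

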