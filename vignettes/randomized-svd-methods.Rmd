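---
title: "Methods: randomized truncated SVD for expression matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomized truncated SVD for expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcasketch)
```

## The problem

Single-cell and spatial profiling experiments routinely produce matrices of
tens or hundreds of thousands of samples (cells, spots, pixels) by hundreds
to thousands of features (genes, probes, peaks). Downstream analysis —
clustering, embedding, trajectory inference — runs on the leading principal
components, because that is where the correlated biological signal sits;
the bulk of the spectrum is measurement noise. Computing a full SVD to use
30–100 components is wasteful, and iterative Lanczos-type solvers, while
accurate, are hard to parallelize. Randomized sketching trades a provably
small amount of accuracy for a computation made of plain dense matrix
products.

## Preparation model

`prep_matrix()` applies, in a fixed order:

1. **Orientation** — transpose so rows are samples. When undeclared, the
   longer axis is taken to be the samples: expression matrices have many
   more cells than genes, and this heuristic resolves every realistic case.
   A square undeclared matrix is refused rather than guessed.
2. **Log transform** — `log(x + pseudocount)`, base 2 or e. The pseudocount
   (default 1) exists because count matrices contain zeros; it must be
   positive whenever zeros are present. Variance-stabilization of counts
   before PCA is standard practice; nothing downstream depends on the
   choice of base.
3. **Centering** — subtract column means. PCA on an uncentered matrix mixes
   the mean structure into PC1.
4. **Scaling** — divide by the column sample standard deviation (n − 1
   denominator, the R convention). A zero-variance feature would divide by
   zero; the policy is `drop` by default (with a warning and a provenance
   record), with `keep_zero` (retain the column as exact zeros) and `error`
   as alternatives. The policy only engages when scaling is requested — an
   unscaled constant column is harmless.

The fixed order (transpose → log → center → scale) is the only one in which
each step's assumption (non-negativity for the log; feature-wise moments
for centering/scaling) refers to a well-defined matrix. Every applied step
is recorded in the output's `provenance`, and the means/sds used are kept
so the transformation is invertible in principle.

## The decomposition

**Exact path.** `exact_svd()` computes the full decomposition and truncates.
It never sketches: its role is to be the gold standard, both as the optimal
rank-k approximation (Eckart–Young) and as the reference in all agreement
statistics.

**Randomized path.** `randomized_svd(M, k, oversample, power_iters, seed)`:

1. Draw `Ω` ~ N(0,1), p × (k + oversample), from the backend's seeded
   sampler.
2. `Y = MΩ`; `Q = qr(Y)$Q`.
3. Repeat `power_iters` times: `Q = qr(M · qr(Mᵀ Q)$Q)$Q`. Re-orthonormalizing
   at every half-step is the numerically stable form of multiplying by
   `(MMᵀ)^q`; the raw product underflows the small singular directions in
   floating point long before q gets large.
4. `B = QᵀM` (small: (k+oversample) × p); exact SVD of `B`; `U = Q·U_B`;
   truncate to `k`.

Because the computed triplets live in the span of the sketch, each
approximate singular value is bounded above by its exact counterpart — a
property the tests assert rather than assume.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | — | components returned; 30–100 covers typical expression work |
| `oversample` | `min(10, min(dim) − k)` | extra sketch columns; cheap insurance for subspace capture |
| `power_iters` | 2 | subspace-iteration rounds; raise when the spectrum decays slowly |
| `seed` | 1 | drives the Gaussian sketch; identical seeds give bit-identical results |

Oversampling of ~10 and 2 power iterations are the widely used defaults for
this family of algorithms. The default oversampling self-limits on small
matrices (the sketch can never be wider than `min(dim)`) so that toy
examples and edge cases run under defaults; an *explicitly* requested
sketch wider than `min(dim)` is an error, because silently shrinking a
user's explicit choice would misrepresent what was computed.

**Sign convention.** SVD signs are arbitrary: `(u, v)` and `(−u, −v)` are
the same triplet. Every decomposition (and the synthetic generator's truth
factors) pins each U column's largest-magnitude entry to be positive, so
repeated runs, different methods, and truth factors are directly
comparable. For *cross*-decomposition comparisons `align_signs()`
additionally flips candidate components whose U columns point away from
the reference — necessary because two near-identical decompositions can
still disagree on the convention when a column's extreme entries are
nearly tied. Ties in singular values leave the component *order* within
the tied block backend-dependent; comparisons in degenerate cases should
compare projections, not individual vectors.

**Precision.** All computation is in R doubles (64-bit). The backend
contract is the place where a 32-bit accelerated implementation would
plug in.

## Validation statistics

Given a candidate and the exact reference of the same matrix at rank k:

* **SSE ratio** `‖M − M̂_cand‖²_F / ‖M − M̂_exact,k‖²_F ≥ 1`, with equality
  iff the candidate matches the optimal truncation's error. This normalizes
  reconstruction error by the best achievable at that rank, making values
  comparable across matrices.
* **CCC (Lin)** `2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`, population (1/n)
  moments — Lin's original estimator; the sample-moment variant differs
  only in the weight of the mean-shift term and is deliberately not
  offered, to keep one canonical definition. Applied to the singular-value
  vectors directly and to PC score vectors after sign alignment (without
  alignment a perfect decomposition with one flipped sign would score
  CCC ≈ −1 on that component).
* **Frobenius error**, absolute and relative. The relative divisor is
  `‖M‖_F` by default; a centered-sum-of-squares divisor is available
  because "square root of the variance in the data" is genuinely ambiguous
  between the two, and the divisor used is recorded in the report.

Reports keep full precision; rounding (6 decimals for SSE ratios, 4 for
CCC) happens only in the presentation-layer TSV and print method.

## Synthetic data: what it emulates, what it does not

`make_lowrank(n, m, spectrum, noise_sd, seed)` builds
`U diag(spectrum) Vᵀ + noise_sd·G` with seeded orthonormal factors (QR of
Gaussian matrices) — ground truth for recovery tests. One caveat the tests
respect: additive noise *inflates* the singular values of the observed
matrix; a true value σ near the noise floor appears as roughly
`sqrt(σ² + noise_sd²(n + m))`. Recovery of the clean spectrum is therefore
only meaningful for components well above the noise floor; below it, the
correct check is agreement with the exact decomposition of the same noisy
matrix, which *is* achievable and is what the randomized path promises.

`make_counts(n_cells, n_genes, n_programs, mean_depth, dispersion, seed)`
emulates the shape of real expression data: a sparse, non-negative integer
genes × cells matrix, negative-binomial (Gamma–Poisson — the de facto model
for sequencing counts) around a rank-`n_programs` rate matrix (softplus of
a low-rank Gaussian factor product, rescaled to the requested mean depth).
Defaults (3 programs, mean depth 5, dispersion 2) give the sparsity and
overdispersion typical of probe-panel spatial data. Per-gene variance
decomposes as `mean + mean²/dispersion + var(rate across cells)`; the last
term comes from the latent programs and does not vanish as dispersion
grows, so the generator approaches a *mixed* Poisson, not a homogeneous
one, in the large-dispersion limit.

What the generator does **not** emulate: batch effects, spatial
autocorrelation, discrete cell-type structure, gene–gene correlation beyond
the low-rank programs, and — most consequentially — the spectral decay
profile of real tissue data. Real expression matrices concentrate variance
in the leading components much more sharply than the flat Marchenko–Pastur
bulk a low-rank-plus-noise model produces. Sketching accuracy at a given
`(oversample, power_iters)` improves with spectral decay, so agreement
statistics measured on the synthetic fixtures are a *conservative* proxy:
passing here does not guarantee the same SSE ratio on real data, but the
structural guarantees (optimality bound, determinism, sign consistency,
exact-path machine-precision reconstruction) are matrix-independent.

## Numerical choices and degenerate inputs

* Thin QR in the reference backend normalizes R to a non-negative diagonal,
  making the factorization of a full-rank matrix unique (and `qr(I) = (I, I)`).
* The Gaussian sampler saves and restores the caller's RNG state, so
  decompositions never perturb user-level random streams.
* Zero matrices decompose to zero spectra; all-zero spectra produce zero
  scores with a warning (variance shares are undefined there).
* The SSE ratio refuses a reference SSE below 1e-300 (matrix of rank ≤ k):
  the ratio is 0/0 and reporting anything would be noise.
* Matrix Market indices are 1-based on disk (the format's convention);
  everything in memory is ordinary R 1-based indexing via the `Matrix`
  package.

## Problem sizes in the test suite

The suite validates on matrices up to 2000 × 300 (the benchmark-protocol
fixture), 200 × 80 (spectrum recovery, 20 seeds), and sweeps of ~100 small
seeded matrices for oracle agreement — sizes chosen so the whole suite
runs in seconds while still exercising n ≫ p, p ≫ n, rank-deficient,
tied-spectrum, and zero cases. The acceptance script regenerates
everything from a single seed at the same sizes.

## Known limitations

* Sparse input is densified before decomposition; there is no sparse-aware
  sketching or out-of-core path.
* Only the reference (base R) backend ships; GPU support is a contract
  (`device = "gpu"` errors unless a registered backend reports GPU
  availability — never a silent fallback), not an implementation.
* The exact path computes the *full* SVD even for small k; that is its job
  as a reference, not a performance feature.
* CCC is reported as a point estimate; no confidence intervals.
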