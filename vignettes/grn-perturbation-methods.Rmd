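---
title: "Methods: two-level GRN construction and in silico perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level GRN construction and in silico perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnperturb)
```

## The problem

Genome-wide association data relate a quantitative phenotype `y` (length
N) to a genotype matrix `X` (N x J, allele dosages in {0, 1, 2}). A binary
annotation mask `M` (J x G) links each SNP to the gene(s) whose boundary it
falls in. `grnperturb` turns this into a two-level gene regulatory network
— SNP nodes, gene nodes, directed SNP-to-gene edges along the mask,
optional within-level edges — restricted to the variables a sparse
variable-selection model deems significant. The network can then be
*perturbed*: nodes are deleted, the deletion is propagated into `(X, M)`,
the model is refit, and the rebuilt network is diffed against the
original. This emulates an in silico knockout: when a selected SNP is
removed, correlated proxies of the underlying signal (linkage
disequilibrium partners) can emerge in the refitted network.

## The selection model

The reference backend (`ssvi`) is a spike-and-slab linear regression fit
per molecular level by coordinate-ascent variational inference:

$$y = Z\beta + \epsilon,\qquad \epsilon \sim N(0, \sigma^2 I),\qquad
\beta_k \sim \pi\,N(0, \sigma^2\sigma_\beta^2) + (1-\pi)\,\delta_0 .$$

The fully factorized approximation carries, per coordinate, an inclusion
probability $\alpha_k$ (the PIP), a conditional slab mean $\mu_k$ and
variance $s_k^2$. Coordinates are updated in fixed column order
(Gauss–Seidel), with a closed-form residual-variance update after each
sweep; iteration stops when the largest per-sweep PIP change falls below
`tol`. Level 1 uses the column-standardized `X`. Level 2 uses the
gene-level design

$$H_{\cdot g} = \mathrm{standardize}\Big(\sum_j M_{jg}\, X^{std}_{\cdot j}\Big),$$

a declared stand-in for whatever hierarchical structure a production
method might learn: it is the simplest design in which a gene inherits its
member SNPs' signal. Its main caveat is sign cancellation — two causal
SNPs of opposite effect in one gene can cancel in the sum — which is a
property of the aggregate, not of the fitting algorithm, and is visible in
the recovery benchmark discussion below.

### Hyperparameters

| Parameter | Default | Meaning |
|---|---|---|
| `pi` | `min(0.1, 10/K)` | prior inclusion probability; expects at most ~10 active variables |
| `h2` | 0.5 | heritability proxy used to size the slab |
| `sigma_beta2` | `h2 / ((1 - h2) * pi * K)` | slab variance relative to `sigma^2`; sizes `pi * K` active standardized columns to explain ~`h2` of the variance |
| `tol` | 1e-4 | max absolute PIP change per sweep |
| `max_iterations` | 500 | a non-converged fit returns `converged = FALSE` with a warning, never silently |

All resolved values are echoed into the `selection_result` metadata so a
fit is auditable from its output alone.

### Initialization and ties

Initialization is the *symmetric* point $\alpha_k = \pi$, $\mu_k = 0$ —
deterministic, so identical inputs give bit-identical results regardless
of the recorded seed. A consequence worth understanding: for exactly
collinear columns, sequential coordinate ascent is winner-take-all — the
first updated column absorbs the whole effect and the duplicate is left
near the prior. The exact posterior (see the enumeration oracle) instead
splits mass equally. We keep the sequential update deliberately: the
concentration behavior is what makes knockout handoff visible (delete the
winner and the partner takes over), and it mirrors how sparse selection
methods behave on real LD. Off-signal, symmetry is preserved exactly.

### The enumeration oracle

`exact_pip_enumeration` computes exact PIPs for K <= 12 by scoring all
$2^K$ subsets with the closed-form marginal likelihood of the conjugate
normal model matching the slab ($\beta_S \mid \sigma^2 \sim N(0,
\sigma^2\sigma_\beta^2 I)$, Jeffreys prior on $\sigma^2$). It shares no
code path with the variational fit (bit-mask subset iteration plus
Cholesky there, and the test suite re-derives it a third way with `combn`
and dense `solve`). Agreement between the two routes — rank correlation
and top-variable identity over random instances — is an acceptance
criterion, not an assumption.

### minSNP

The `minsnp` backend assigns each SNP the two-sided p-value of the slope
t-test in `y ~ 1 + X[, j]` (computed in closed form from the sample
correlation; the tests compare against `lm()`), and each gene the minimum
over its member SNPs, uncorrected — the minSNP convention. A Šidák-style
correction `1 - (1 - p)^m` is available behind the `sidak` flag but off by
default. Constant SNP columns get p = 1 with a degenerate-fit flag; genes
with no annotated SNPs are excluded and reported.

## Network construction

* **Thresholds.** PIPs: significant iff `score >= cutoff` (inclusive — the
  median probability model at 0.5 keeps a variable sitting exactly at
  0.5). P-values: `score <= cutoff`. The direction for p-values is an
  inference; only PIP thresholds are demonstrated upstream.
* **Cross-level edges.** `j -> g` iff `M[j, g] = 1` and both endpoints are
  significant; always directed SNP-to-gene.
* **Within-level edges.** `none`, `complete`, or `sparse`. Sparse
  connectivity is operationalized as absolute Pearson correlation
  `|r| >= tau` on the level's data columns (genotypes at level 1, the `H`
  design at level 2), with `|r|` stored as the edge weight. The edge
  statistic behind sparse mode is a design choice of this package — the
  upstream platform exposes an edge-threshold toggle without defining the
  statistic — and it is isolated in `sparse_within_edges` so it can be
  swapped.
* **Orphans.** A significant SNP whose annotated genes all fail the gene
  threshold is kept as a node with zero cross-level edges and flagged
  `orphan`, rather than dropped: removing a selected variable because its
  gene did not pass would hide level-1 information.
* **Aesthetics.** Nodes carry level, score, and significance only; color
  and shape mappings belong to renderers.

`diff_grn` canonicalizes undirected edges by sorted endpoint pair, so
re-ordered endpoints are not spurious changes; persisting nodes report
`score_after - score_before`.

## Perturbation semantics

Deleting a SNP removes its `X` column and mask row. Deleting a gene
removes its mask column; member SNPs are *not* deleted — any SNP left
unannotated is re-assigned to a synthetic intergenic group (cascade
recorded). This preserves the level-1 design: the knockout removes the
grouping, not the genotype data. Edge deletion without node deletion is
supported only at the network level (the likelihood has no per-edge term)
— a documented limitation. Re-deleting an already-deleted id errors rather
than silently no-ops. Records store both networks, the diff, the backend
configuration, and MD5 fingerprints of the input files; `replay` re-runs
the recorded perturbation and verifies the regenerated network is
identical, raising a stale-record error if any input changed on disk.

## The simulator as a stated world

`simulate_dataset`'s defaults are a scaled-down heterogeneous-stock mouse
study: n = 200 animals in 10 balanced families, J = 1000 SNPs, G = 250
genes, 5 causal SNPs, h² = 0.6, 10% unannotated (intergenic) SNPs, LD
blocks of 5 with latent adjacent correlation 0.5. Mechanisms:

* **LD** by a Gaussian copula: a latent AR(1) normal per block, discretized
  through binomial(2, maf) quantiles. Discretization attenuates the
  realized genotype correlation below the latent target (about 10–15% at
  common allele frequencies); tests assert the realized band.
* **Families** as a per-family logit-scale allele-frequency jitter
  (sd 0.3) — enough structure to make family-mean imputation meaningful,
  with no attempt at pedigree realism.
* **Phenotype** `y = X_std beta + eps` with the noise orthogonalized
  against the genetic values and scaled so `var(Xb)/var(y)` equals h²
  *exactly* in-sample; the truth object records causal ids, effects, and
  both target and realized h².

What the simulator does **not** emulate: recombination maps, coalescent
genealogies, population stratification beyond the family jitter, dominance
or epistasis, genotyping error. A green recovery test therefore
establishes that the method ranks truly additive, truly sparse signal
correctly at realistic scale — not that it is robust to confounding.

Two benchmark-specific choices, decided once:

* **Recovery benchmark effects.** The causal-gene recovery criterion
  ("every causal gene outranks the median null gene in >= 18/20 seeds")
  uses equal-magnitude effects (`effect_distribution = "constant"`), each
  causal SNP carrying h²/5 of the variance. With Gaussian effects roughly
  40% of 5-causal replicate sets contain an effectively-null draw
  (|beta| < 0.15) or an opposite-signed pair that cancels in the gene
  aggregate, making the "every causal gene" clause unattainable for any
  method; the AUC clause holds under either distribution.
* **Handoff benchmark regime.** The knockout-handoff fixture uses an LD
  pair at genotype correlation 0.95 (built by copy-with-resampling, so the
  correlation is structural rather than attenuated) with h² = 0.08 for the
  single causal SNP at n = 500. That effect size is chosen from the
  model's own detection boundary: the causal SNP is individually far above
  the PIP = 0.5 threshold, while the partner's *conditional* signal
  (fraction `1 - r^2` of the effect) sits below it — the regime in which a
  knockout visibly hands the signal to the partner.

## Numerical and interface choices

* Readers are strict: out-of-contract tokens (non-binary mask entries,
  genotypes outside {0,1,2}/NA, malformed scores) raise typed errors with
  locations; nothing is silently coerced. Score values survive write/read
  at full precision (`%.17g`; JSON written with full-precision digits).
* MAF filtering uses the strict inequality (`> 0.05`): a SNP with minor
  allele frequency exactly at the threshold is removed. Monomorphic SNPs
  are always removed.
* Imputed genotypes are real-valued family means, not re-rounded to
  {0,1,2} — dosage information is worth keeping, and downstream
  standardization is indifferent. A SNP unobserved in an entire family
  falls back to its across-family mean, flagged in the report.
* Constant covariate columns are absorbed by the intercept during
  residualization; genuinely collinear covariates raise an error naming
  the offending columns.
* "Intergenic region between two genes" is operationalized as maximal runs
  of consecutive unannotated mask rows, one synthetic group per run, with
  row order standing in for genomic order (no coordinate scheme exists in
  the inputs).
* Determinism: every stochastic component is a pure function of its seed;
  the composite pipeline is byte-reproducible (score CSVs, network JSON
  and GraphML) under a fixed seed. Timestamps appear only in the run log
  and perturbation records, never in scientific outputs.

## Known limitations

* The gene-level design is a fixed linear aggregate; it cannot represent
  within-gene effect heterogeneity and can cancel opposite-signed effects.
* Sequential coordinate ascent under-propagates posterior uncertainty in
  tight LD (concentration instead of mass-splitting); exact enumeration is
  available for small K when calibrated uncertainty matters.
* Two molecular levels only; sparse within-level edges are marginal
  correlations, not conditional-independence estimates.
* The permutation-null false-positive rate at the PIP = 0.5 cutoff is
  small but not zero (borderline PIPs just above 0.5 appear in a few
  percent of permutations, matching the exact posterior) — a property of
  the 0.5 rule at these priors, not an implementation artifact.
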