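---
title: "Methods: condition-specific heritability of gene expression along chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-specific heritability of gene expression along chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`exprherit` analyses gene expression measured as TPM across a structured
diversity panel of inbred genotypes assayed under two conditions (control and
salt stress) with two biological replicates each. The pipeline has six
stages, each a small set of exported functions:

1. **Expression classes.** Zero TPM is treated as a missing observation — no
   pseudocount is added, and non-zero values are analysed as log2 TPM. Each
   gene's per-condition missing rate (replicates pooled) classifies it as
   *constitutive* (rate < 0.05), *mixed*, or *repressed* (rate > 0.95), with
   strict inequalities so boundary rates fall into the mixed class. The
   cross-condition 3×3 contingency table and its symmetric between-class
   transition counts summarize how stable the classes are across conditions.
2. **Structure adjustment.** Principal components of the column-centered
   (not variance-scaled) dosage matrix capture subpopulation structure.
   Expression is residualized by OLS on an intercept plus the top *k* = 3
   components, separately for each condition × replicate stratum, so that
   neither repeatability nor the mixed models absorb subpopulation means as
   spurious genetic variance. Masked cells never enter a fit; a stratum with
   fewer than *k* + 2 observed values gets undefined residuals.
3. **Kinship.** Markers with minor allele frequency strictly below 5% are
   removed; the genomic relationship matrix is VanRaden method 1,
   `K = W W' / (2 * sum(p(1-p)))` with `W = dosages - 2p` at observed allele
   frequencies, then symmetrized and eigenvalue-clipped to positive
   semidefiniteness (tolerance 1e-8) because the spectral REML solver
   requires `K ⪰ 0`.
4. **Heritability.** Three per-gene estimators, applied per condition to
   genes with < 5% missing values across all samples:
   * *repeatability* — the Pearson (or Spearman) correlation of replicate 1
     vs replicate 2 across genotypes, an upper bound on h² for inbred lines;
   * *two-step GREML* — genotype means regressed with kinship as the random
     effect (`Z = I`);
   * *single-step GREML* — all replicate observations stacked with `Z`
     mapping observations to genotypes, so replicate variance is modelled
     rather than averaged away.
   The REML solver is described below; h² is defined on the variance-
   component scale σg²/(σg² + σe²). Because K's diagonal is not exactly 1 in
   a structured panel, this differs slightly from the observation-scale
   variance ratio; the stored components let either be recovered.
5. **Significance.** A pooled permutation null: each iteration picks a gene
   and condition at random, shuffles its expression values across that
   condition's samples, and re-estimates single-step h². The empirical
   (1 − α) quantile (type-7, α = 0.01) is the significance threshold; genes
   are *general*, *control-specific*, *salt-specific* (strictly above the
   threshold in both / exactly one condition), or *not heritable*.
6. **Chromosome scans.** Sliding windows (class densities at 3 Mb / 100 kb;
   enrichment at 1.5 Mb / 100 kb) with genes assigned by midpoint. Window
   enrichment of salt-specific genes among heritable genes uses the
   one-tailed hypergeometric (Fisher) tail, with a window-specific
   bootstrap null: draws of `n_salt` genes from the heritable pool,
   `adjusted_p = (1 + #{null p ≤ observed p}) / (1 + B)`, escalated from
   B = 4000 up to 50,000 for windows with zero exceedances; significance is
   strict at α = 0.001, and significant windows merge into regions when
   they overlap or abut within one step. Expression-class densities in
   fixed 500 kb bins are correlated (Spearman by default) with an A/B
   chromatin-compartment eigenvector track re-binned by length-weighted
   averaging; the sign convention is positive = A (euchromatic) compartment.

# The spectral REML solver

The mixed model is `y = 1μ + Zg + e` with `g ~ N(0, σg² K)` and
`e ~ N(0, σe² I)`. Let `U` be an orthonormal basis of the complement of the
intercept, rotated so that `U' Z K Z' U` is diagonal with eigenvalues ξ, and
`η = U'y`. With δ = σe²/σg², the restricted log-likelihood profiled over σg²
is

```
l(δ) = 0.5 [ m log(m / 2π) − m − m log(Σ ηᵢ²/(ξᵢ + δ)) − Σ log(ξᵢ + δ) ],
```

with m = n − 1, `σ̂g² = Σ ηᵢ²/(ξᵢ + δ) / m` and `σ̂e² = δ σ̂g²`. This is the
efficient mixed-model (EMMA) strategy: one eigendecomposition per design,
then each evaluation is O(n). The decomposition depends only on (K, Z), so
it is computed once and reused across genes and permutations — this is what
makes the 40,000-iteration permutation null and transcriptome-scale fits
cheap.

Numerical choices:

* the variance ratio λ = σg²/σe² is profiled on a 100-point log-spaced grid
  over e⁻¹⁰..e¹⁰, then the best bracket is refined with a derivative-free
  scalar optimizer to |Δ log λ| < 1e-8 — deterministic and free of
  gradient pathologies at the boundary;
* boundary optima are returned with `converged = TRUE`: λ → 0 is reported
  as σg² = 0 (h² = 0), λ → ∞ as σe² ≈ 0 (h² → 1);
* a response with numerically zero variance raises a classed degenerate
  condition; the estimator wrappers catch it and return a flagged `NA`
  estimate rather than failing a transcriptome run;
* confidence intervals invert the profile restricted likelihood at the
  χ²(1) 0.95 cutoff and are truncated to [0, 1]. Wald intervals are not
  offered: at this sample size many estimates sit on the boundary of the
  parameter space, where the Hessian approximation is invalid.

The test suite checks the solver against two independent oracles: a
brute-force direct-inversion REML evaluation (dense `solve`/`determinant`
over orthonormal contrasts) on random small instances, and the closed-form
one-way ANOVA estimators σ̂g² = (MSB − MSW)/r, σ̂e² = MSW for the balanced
K = I design.

# The permutation null: why samples are shuffled independently

Two shuffling schemes are implemented. The default (`shuffle = "samples"`)
permutes all of a condition's values independently, destroying both the
genotype–kinship association and the replicate pairing. The alternative
(`shuffle = "genotype_pairs"`) permutes genotype labels while keeping
replicate pairs intact.

The default is deliberate. The single-step estimator identifies genetic
variance through two routes: the kinship structure of the genotype effects
and the correlation of replicates within genotype. With a marker-derived K
that is strongly diagonally dominant (weakly related inbred lines), the
second route dominates — and it survives genotype relabelling. On simulated
data with a heritable fraction of genes, the pair-preserving "null"
distribution simply reproduces the upper tail of the heritable genes' h²
distribution, and no gene can exceed its quantile. Independently shuffled
vectors carry no genetic signal by construction, so their h² distribution is
the estimator's true null; on simulated null genes the resulting α = 0.01
threshold yields an empirical type-I error statistically indistinguishable
from 0.01 (see the calibration test). The pair-preserving variant is kept
as a diagnostic for how much of a gene's apparent heritability rides on
replicate pairing rather than on K.

One pooled null is built across genes (one shuffled vector per iteration,
gene sampled with replacement), rather than per-gene nulls: the threshold is
a single genome-wide quantile, and the iteration budget is a parameter
(40,000 by default; the desk-scale workflow uses 10,000 and the calibration
test 5,000, which stabilizes the 0.99 quantile to well within the
Monte-Carlo error the tests tolerate).

# The synthetic-data generator

Every stage is tested against generated data with known truth; the defaults
encode the study design the pipeline assumes:

* **Genotypes** — Balding–Nichols: ancestral frequency per marker
  ~ Uniform(0.1, 0.9), subpopulation frequency ~ Beta(p(1−F)/F,
  (1−p)(1−F)/F) with F = 0.2 across 5 subpopulations in near-equal blocks
  of 84 genotypes; 2000 markers placed uniformly on 4 chromosomes of 30 Mb.
  This is the simplest generative model that reproduces PCA-separable
  subpopulations. F = 0.2 gives a top-3 PC variance share several-fold above
  the unstructured baseline, qualitatively matching a diversity panel with
  a few major subgroups.
* **Expression** — for each gene and condition, a genetic value
  `u ~ N(0, σg² K)` drawn against the *same* VanRaden kinship the estimators
  use (the analysis consumes only K-level signal, so marker-effect
  simulation would add nothing any stage could detect), plus per-replicate
  noise with sd 0.7 on the log2 scale — a typical replicate scatter for
  deeply sequenced bulk RNA-seq; variances are scaled so
  σg²/(σg² + σe²) hits the target h² exactly. Mean h² realized from the
  generating variances therefore matches the target by construction.
* **Classes and zero-inflation** — class fractions 0.3/0.4/0.3
  (constitutive/mixed/repressed) with per-gene zero probabilities drawn
  inside each class's defining band (< 1%, 15–85%, > 98.5%), so realized
  missingness classifies back to the truth for ≥ 99% of genes at 168
  samples per condition. Constitutive means sit in the positive log2 range,
  mixed and repressed means in the negative range, reproducing the bimodal
  expressed/low-expressed structure. Zeros overwrite the latent draw, so
  the missing-mask contract of the expression container is exercised. A
  gene's salt class differs from its control class with probability 0.1
  (adjacent classes only), giving a contingency table with off-diagonal
  mass but an empty constitutive↔repressed corner.
* **Placement** — class probabilities are tilted by chromosome position
  (repressed genes toward the center, constitutive genes toward the arms,
  multipliers averaging to one so genome-wide fractions are preserved),
  which creates the pericentromeric repression the density scan and the
  compartment correlation are designed to detect.
* **Heritability architecture** — non-hotspot genes are general /
  control-specific / salt-specific / non-heritable with probabilities
  0.40/0.20/0.08/0.32 (echoing the relative abundance of the three
  significant classes reported for diversity-panel expression), with target
  h² from {0.3, 0.5, 0.7}; two planted hotspots each force 17 genes inside
  a 1.5 Mb interval to salt-only heritability at h² = 0.6 — the magnitude
  of the enrichment signals the window scan is meant to find.
* **Tracks** — the eigenvector per 500 kb bin is the standardized
  constitutive-gene density plus Gaussian noise (sd 0.5 on the standardized
  scale, i.e. signal-to-noise 2:1, keeping the expected density–eigenvector
  correlation near 0.9); the pericentromere track marks the central 20% of
  each chromosome.

What the generator does *not* emulate: read counts and library-size
effects, isoforms, cis/trans eQTL architecture (no stage maps eQTLs),
linkage disequilibrium beyond subpopulation structure, and any
condition-dependence of the compartment track. Passing tests therefore
demonstrate that the estimators and scans recover the signal classes they
model, at the study's sample size — not that real rice data meet those
modelling assumptions.

# Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| class thresholds | 0.05 / 0.95 | missing-rate | strict inequalities; boundary = mixed |
| PCA components `k` | 3 | — | tied to how many axes separate the panel's subgroups |
| `min_maf` | 0.05 | allele freq. | strict `<` removal; 0.05 exactly is retained |
| λ search box | e⁻¹⁰..e¹⁰ | variance ratio | grid 100 points, refine to 1e-8 |
| permutation iterations | 40,000 | — | quantile stability; warn below 1,000 |
| α (heritability) | 0.01 | type-I rate | single pooled threshold, no per-gene FDR |
| window / step | 1.5 Mb / 100 kb | bp | densities use 3 Mb windows |
| bootstrap B / B_max | 4,000 / 50,000 | — | escalate on zero exceedances |
| α (windows) | 0.001 | — | strict `<` on adjusted p |
| compartment bin | 500 kb | bp | a required parameter: density–eigenvector correlations are bin-size dependent, so the Hi-C analysis bin is the default |

# Degenerate inputs and tie-breaks

* Genes whose replicate vector has zero variance get a flagged `NA`
  repeatability, not an error.
* Windows with no heritable gene get Fisher p = 1 by convention, flagged.
* A gene midpoint on a boundary shared by overlapping windows is counted in
  every covering window (sliding windows overlap by design); with tiling
  windows the counts are conserved exactly, which is tested.
* Midpoint assignment (floor of the coordinate mean) was chosen over any
  overlap rule so that a gene belongs to a deterministic set of windows and
  the conservation property holds; genes straddling window edges are never
  double-counted within a tiling.
* The adjusted p is never exactly 0 thanks to the (+1)/(B+1) correction,
  which also gives the escalation rule a concrete trigger (zero
  exceedances).
* Chromosome length defaults to the maximum annotated gene end unless a
  length table is supplied.
* PCA component signs are fixed by making the largest-magnitude score
  positive, so results are reproducible across BLAS implementations.

# Problem sizes

The bundled workflow (`analysis/`) and the test suite run everything at
desk scale, chosen so the full pipeline completes in minutes on a single
core while keeping every estimator in its operating regime: 84 genotypes ×
2 × 2 samples (the study design), 2,000 markers, 3,000 genes on 4 × 30 Mb
chromosomes, 10,000 permutation iterations in the workflow (5,000 in the
calibration test, 40,000 as the package default), and 4,000-iteration
bootstrap scans. Estimator recovery harnesses use 50 genes per true-h²
level and 2,000 null genes for threshold calibration.

# Known limitations

* The two-step and single-step estimators share the single-kinship additive
  model; architectures with strong cis effects or non-additive variance are
  outside the model, and the moderate two-step/single-step agreement the
  workflow reports reflects that mean-collapsing and replicate-modelling
  weight such genes differently.
* The permutation threshold is a single pooled quantile: genes with
  atypical missingness patterns are judged against a null built from
  complete-data genes.
* Logistic-scale heritability of the zero/low/high encoding is not
  attempted — at 336 samples such models are not reliably estimable.
* The compartment correlation consumes the eigenvector as a given track;
  Hi-C contact-map processing is upstream of this package.
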