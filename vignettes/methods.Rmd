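---
title: "Joint confounder and regulator learning for eQTL scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint confounder and regulator learning for eQTL scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model implemented in `panamaqtl`, the
choices made where the design was genuinely open, the numerical details that
matter in practice, and — just as importantly — what the bundled simulator
does and does not emulate, hence what a passing test suite does and does not
establish about real data.

## The generative model

Let `Y` be the `N × G` matrix of centered expression (samples × genes). Each
gene's trait vector is modelled as a sum of SNP effects, hidden factor
effects, optional known-covariate effects and noise. Per-gene regression
weights on the SNPs and on the factors carry independent zero-mean Gaussian
priors and are marginalised, which turns the model into a multivariate
Gaussian with a single sample-covariance shared by all genes:

$$
y_g \sim \mathcal N(0,\;K), \qquad
K \;=\; \sum_{k=1}^{K_{\max}} \sigma^2_k\, x_k x_k^\top
\;+\; \sum_{s \in S^*} \theta_s\, g_s g_s^\top
\;+\; \sigma^2_c\, C \;+\; \sigma^2_e I .
$$

The marginal log-likelihood factorises over genes and depends on the data
only through `S = Y Yᵀ`:

$$
\mathcal L = -\tfrac{GN}{2}\log 2\pi - \tfrac{G}{2}\log|K|
             - \tfrac12\,\mathrm{tr}\!\left(K^{-1} S\right).
$$

Assumptions worth stating explicitly: expression is complete (no missing
values), roughly Gaussian after log-transformation, and centred per gene (the
mean term is handled by centring, so no intercept appears in the variance
model); genotypes are complete with entries in {0,1} (cross designs) or
{0,1,2} (dosages) and enter the covariance raw — uncentred and unscaled — so
`θ_s` stays interpretable as a per-allele variance.

## Maximum likelihood, ARD, and the factor dictionary

All of `X = [x_1 … x_{K_max}]` and the log-variances
`(log σ²_k, log θ_s, log σ²_c, log σ²_e)` are optimised jointly by L-BFGS
with analytic gradients. The log parameterisation enforces positivity; the
objective trace is recorded and is non-decreasing over accepted steps.

`K_max` (default 20) is deliberately generous: with per-factor variances free,
maximum likelihood drives unused `σ²_k` towards zero — automatic relevance
determination. A factor is *reported* as effective when its variance exceeds
`ard_threshold` (default 0.01) times the sum of all variance parameters;
below-threshold factors stay in the matrix but contribute essentially
nothing. The threshold is a reporting device, not a model change. In the
factor-only case (no regulators, no covariates) the ML optimum has a closed
form — the probabilistic-PCA eigendecomposition of `S/G` — and the optimiser
is checked against it in the test suite.

Scale indeterminacy (`x_k → c x_k`, `σ²_k → σ²_k/c²`) is resolved after
convergence by rescaling every factor column to squared norm `N`, with the
variance absorbing the scale.

### Initialisation decides a likelihood ridge — and is chosen to protect genetic signal

A factor direction and a regulator genotype direction are additively
interchangeable in `K`: along a shared direction only `σ²_k + θ_s` is
identified, so the likelihood has a flat ridge in how that variance is
split. Gradient methods do not move along flat ridges; *the initialisation
decides the split*. The package therefore initialises:

* with no regulators: `X` from the top principal components of `Y`,
  `σ²_k` matched to the PC variances, `σ²_e` to half the mean gene variance;
* with regulators `S*`: each `θ_s` from the average squared per-gene
  regression effect of `g_s` (a moment estimate of the variance it explains),
  and `X` from the principal components of `Y` **residualised on the
  regulator genotypes** — so confounder structure, not genetic structure,
  seeds the factor space;
* the known-covariate scale `σ²_c` from projecting the off-diagonal sample
  covariance onto `C`. A near-zero start would be sticky: on the log scale
  the gradient is proportional to the parameter itself.

An earlier variant that initialised `θ_s` at a tiny constant left hotspot
variance inside the factors (the ridge never moved), making the
regulator-excluding correction behave exactly like a factor-only one; the
residualised initialisation is what makes the joint model deliver its
intended behaviour.

## Iterative regulator selection

Regulators cannot be fixed a priori — they are discovered from the data:

1. fit the variance model with the current regulator set (initially empty);
2. scan genome-wide under the factor covariance (regulators excluded);
3. for each SNP count the genes significant at genome-wide BH FDR
   `regulator_fdr` (default 0.01); rank SNPs by that count, breaking ties by
   smaller best p-value, then genome order;
4. greedily keep SNPs with at least `regulator_min_genes` (default 5)
   significant genes, skipping any SNP within `regulator_exclusion_bp`
   (default 100 kb) of an already kept SNP on the same chromosome — a
   pragmatic guard against selecting a hotspot twice through linkage;
5. truncate at `max_regulators` (default 10) and repeat until the set is
   unchanged (or `max_outer_iterations`, default 5; in practice two or three
   passes suffice).

The count-of-significant-targets score is the natural operationalisation of
"strong effects on multiple genes"; everything is deterministic given the
seed.

A bootstrap caveat discovered while validating the loop: selection can only
find a hotspot that retains *some* significance under the factor-only
covariance of the first pass. A single hotspot dominating the genetic
variance can be absorbed so completely that nothing reaches the count
threshold; with several moderate hotspots (the regime of the default
scenario) the scheme is reliable.

## The association scan

The testing model for gene `y` and SNP `g` is
`y ~ N(1μ + gβ, σ²(K' + δI))` with `K'` the fixed correction covariance:

* `panama` — factors plus known covariates; regulators **excluded**, so their
  downstream targets remain discoverable;
* `panama_trans` — additionally includes the regulator terms (the
  conservative variant, behaving like covariance-based corrections);
* `linear` — `K' = 0`; the likelihood profile is then constant in `δ` and
  every test reduces exactly to the ordinary-regression likelihood-ratio
  test (verified to 1e-8 in the tests).

`K'` is eigendecomposed once (`K' = U Λ Uᵀ`, eigenvalues clipped at zero;
anything below −1e-8 is an error); phenotypes, genotypes and the intercept
are rotated into that basis, after which the profiled likelihood at any `δ`
— GLS `β̂`, profiled `σ̂²`, and the log-likelihood — costs O(N). The weight
`δ = σ²_e/σ²_K` is re-optimised for **every test**, separately in the null
and alternative models: a grid of 100 log-spaced points in `[1e-5, 1e5]`
followed by golden-section refinement (60 iterations) between the best grid
point's neighbours. The alternative is additionally evaluated at the null's
optimum, which guarantees `LRT = 2(ℓ₁ − ℓ₀) ≥ 0` numerically (it is clipped
at zero regardless). P-values are the χ²₁ survival function of the LRT —
one fixed-effect degree of freedom — and q-values are Benjamini–Hochberg over
the complete gene × SNP table. The grid+golden inner loop is implemented in
C++ (RcppArmadillo), with a readable R reference path (`lrt_single`,
`profiled_loglik`) cross-checked against it.

Degenerate inputs: SNPs with genotype variance below `min_snp_variance` are
skipped and recorded; a SNP collinear with the intercept inside a weighted
solve falls back to the null fit for that test; zero-variance genes are
flagged at centring time and excluded from fitting and testing.

### Labels, counting, and inflation

A pair is *cis* when the SNP lies within `cis_window_bp` (default 10 kb) of
the gene's ORF on the same chromosome, with 0-based half-open intervals and
distance 0 inside the ORF; everything else is *trans*. To avoid recounting
one locus through linked SNPs, summaries count at most one cis association
per gene (best q) and at most one trans association per gene and chromosome.
The genomic-control inflation factor is
`λ = median(LRT) / median(χ²₁)` with the reference median computed from the
distribution (≈0.4549); λ > 1 signals inflation, λ < 1 conservativeness.

## The synthetic study generator

`simulate_eqtl_study()` produces a complete study with ground truth. Its
defaults are the package's *standard scenario*, shaped like a yeast
segregant cross at desk scale: 100 samples, 500 genes, 300 SNPs on 5
chromosomes at 5 kb spacing, Markov genotypes with adjacent-SNP flip
probability 0.1, 100 cis-affected genes (one cis SNP each, within 10 kb),
10 trans hotspots × 20 target genes (targets always on other chromosomes, so
every hotspot association is unambiguously trans; hotspot loci placed at
least 100 kb apart), 3 hidden confounders, and variance shares
genetic/confounder/noise = 0.3/0.4/0.3. Effect sizes are Gaussian with the
cis scale (sd 1) twice the trans scale (sd 0.5) — cis effects on expression
are typically the stronger — and each component is globally rescaled so the
realised average per-gene variance shares match the request. With
`replicate_design = TRUE` every sample is duplicated across two conditions
sharing genotypes (hence the genetic expression component), and the matching
strain-block kinship is attached as the known covariance. Subsampling knobs
(`trans_keep_fraction`, `confounder_strength`) support sensitivity sweeps.
Identical parameters and seed give bit-identical studies.

`estimate_sim_params()` implements the reverse, fit-then-simulate direction:
from a fitted model and its association table it extracts significant cis
counts, hotspot number and size (per-SNP significant trans-gene counts,
clustered within the linkage exclusion window), empirical effect-size
distributions (resampling the fitted effects of counted associations),
confounder count and variance shares. When given the dataset it classifies
switched-on factors as genetic or confounding by the fraction of their
variance explained by per-chromosome genotype principal components
(threshold 0.5): linked genetic effects form genuine low-rank expression
structure that maximum likelihood keeps as factors, and counting those as
confounders would overstate both the confounder number and share. Closure —
simulate, fit, re-estimate — recovers the generating parameters on the
standard scenario (the test suite checks counts and shares over seeded
replicates).

### What the generator does *not* emulate

These limits matter when reading the test results:

* **Confounders are sampled independently of the genotypes.** Real
  expression heterogeneity often overlaps statistically with genetic signal
  — environmental responses propagate through regulatory networks, and
  estimated confounders in real studies carry genetic structure. Under
  independence, the correlation between any SNP and a purely confounded gene
  is the null correlation, so an *uncorrected* linear scan remains
  median-calibrated (λ ≈ 1) no matter how strong the confounding; the
  package's own calibration runs show exactly that. Confounding here
  degrades power and FDR calibration rather than inflating λ, which is the
  milder of the two failure modes seen in practice.
* **Desk scale changes the learning problem.** With G in the hundreds, the
  sample covariance of LD-linked cis effects produces eigenvalues several
  times the noise edge, and maximum likelihood legitimately keeps them as
  factors; the learned correction therefore absorbs some genuine cis
  variance that an oracle correction would not. This effect scales like
  `N/G` and shrinks at the gene counts of real microarray or RNA-Seq
  studies. Consequently, comparisons between the learned correction and an
  uncorrected scan on the default scenario are tighter than the idealised
  correction suggests — the evaluation suite reports the idealised
  covariance (`baseline_covariance(..., "ideal")`) alongside precisely so
  this gap is measurable rather than hidden.
* No microarray noise model, no RNA-Seq counts, no coalescent-realistic
  genotypes, no missing data.

## Evaluation metrics

Truth matching is linkage-tolerant: a called (gene, SNP) pair counts as a
true recovery when the SNP lies within `match_window_bp` (default 50 kb) of
a causal SNP for that gene on the same chromosome. ROC curves sweep the
p-value threshold with tied p-values moving together; the AUC is trapezoidal
(equivalently, Mann–Whitney with half credit for ties) and invariant to
monotone transforms of p. FDR calibration compares the BH control level at
each cutoff with the empirical false fraction among calls, omitting empty
cutoffs. Hotspot profiles count significant trans genes per SNP; ranking
consistency reports top-k overlap between two profiles with deterministic
tie-breaking.

## Numerical choices and problem sizes

Convergence uses a relative objective-change tolerance of 1e-6 with at most
2000 optimizer iterations; covariances are symmetrised and checked PSD to
−1e-8 before rotation; profiled residual sums of squares are floored at
machine-tiny values before logs. The test suite runs the standard scenario
at its native size (100 × 500 × 300, shared across tests via memoisation)
and smaller instances (N ≤ 20) wherever a dense oracle — per-gene
multivariate-normal densities, finite-difference gradients, brute-force
(β, σ², δ) optimisation — provides the reference.

## Known limitations

* One covariance, all genes: the correction covariance is fixed for the
  whole scan (per-test refitting adjusts only the overall covariance/noise
  weight). When samples are replicate-structured, genes differ in how much
  of their variance is strain-shared, and a single block-term weight is
  necessarily a compromise: adding the replicate kinship removes the
  inflation of an uncorrected analysis but tends to overshoot into mild
  conservativeness (λ slightly below 1). The same trade-off is why the
  regulator-including covariance (`panama_trans`) is the conservative
  variant.
* Regulator discovery is bounded by first-pass power (see above) and by
  `max_regulators`; loci regulating fewer than `regulator_min_genes` genes
  are never treated as regulators and may be partially absorbed by factors.
* The χ²₁ reference is asymptotic; at N = 100 the null LRT runs a few
  percent hot, visible as λ just above 1 in null simulations.
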