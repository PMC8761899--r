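---
title: "Models and methods: genomic selection in connected RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genomic selection in connected RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery:
the models, the defaults and where they come from, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## The study design being emulated

The package targets a common breeding-program layout: three recombinant
inbred line (RIL) populations derived from paired crosses among three
elite parents (so every pair of populations shares one parent), evaluated
together in multi-environment yield trials. The default configuration is
306 lines (102/100/104 per cross), F6-derived by single-seed descent,
phenotyped for grain yield (t/ha) and grain protein content (% dry matter)
in three environments with three complete blocks each. Protein yield per
unit area is never a free trait: it is the per-plot product
yield × protein/100, and everything downstream treats it that way.

## Phenotype model and variance components

Plot values follow

$$Y_{kijr} = m + R_k + G_{i(k)} + E_j + B_{r(j)} + (RE)_{kj} + (GE)_{i(k)j} + e_{kijr}$$

with environment fixed and everything else random. Two estimation paths:

* **Balanced EMS (primary).** For the single-environment genotype+block
  model and the pooled multi-environment model, components come from the
  classical expected-mean-squares equations
  (`se2 = MS_e`, `sge2 = (MS_GE − MS_e)/n`, `sg2 = (MS_G − MS_GE)/(ne)`),
  with F tests of each random term against its EMS denominator. The EMS
  path is exactly testable by hand, which is why it is the default; on
  balanced data with interior estimates it coincides with REML. The test
  suite asserts EMS-vs-lme4 agreement to 1e-4 *relative* — the residual gap
  is lme4's optimizer tolerance, not an estimator difference.
* **REML (lme4).** The nested model with the RIL-population factor is
  always fitted by REML, because population sizes of 102/100/104 make that
  nested classification unbalanced and the textbook EMS coefficients no
  longer apply. Unbalanced inputs to the pooled model are routed the same
  way. REML p-values are not reported (the F-ratio machinery does not
  carry over); the components themselves are what downstream stages use.

Negative method-of-moments estimates are truncated at zero and flagged in
the returned object rather than silently hidden.

Heritability is always on a genotype-mean basis:
$H^2 = \sigma_G^2/(\sigma_G^2 + \sigma_e^2/n)$ within an environment and
$H^2 = \sigma_G^2/(\sigma_G^2 + \sigma_{GE}^2/e + \sigma_e^2/(en))$ across
environments. BLUPs are H²-shrunken line means,
$\mathrm{BLUP}_i = \bar y + H^2(\bar y_i - \bar y)$ — the standard
genotype-mean BLUP for a balanced trial. The shrinkage *target* is
configurable (`center` argument): shrinking toward an environment mean
instead of the grand mean shifts downstream genomic-selection inputs
slightly, and the literature the heritabilities support does not pin the
choice down, so it is exposed rather than hard-coded.

Genetic correlations come in two flavors. Across environments,
$r_g = r/(H_1 H_2)$ divides the line-mean correlation by the
heritability attenuation; noisy $H$ can push $|r_g|$ past 1, so the raw
value is returned together with a clamped companion (tables display the
clamp). Between traits within an environment, the genotypic covariance is
estimated from MANOVA mean cross-products,
$\mathrm{Cov}_G = (\mathrm{MCP}_G - \mathrm{MCP}_e)/n$, with a first-order
delta-method standard error that treats the genotypic (co)variances as
independent with $\mathrm{Var(MS)} \approx 2\,\mathrm{MS}^2/df$ analogues;
the SE is labelled approximate because the cross-covariances it ignores
are nonzero in finite samples.

## The simulator: what is exact, what is stochastic

* **Meiosis.** Haldane map function, no interference:
  $r = (1 - e^{-2d/100})/2$ for distance $d$ cM. Gametes are Markov chains
  along each chromosome. Residual heterozygosity after $g$ selfing
  generations has expectation $0.5^g$ and heterozygotes are kept as dosage
  1 — F6-derived lines are not perfectly inbred.
* **Parents.** Each marker is assigned one of four patterns (all parents
  equal, or exactly one parent divergent) with probabilities solved in
  closed form from the three pairwise divergence targets. The default
  (0.30, 0.45, 0.45) makes the third parent the outlier, mirroring an
  exotic founder crossed to two related elite lines.
* **Genetic values.** The two traits share causal loci; effect pairs are
  bivariate normal. Line main values are rescaled so their sample variance
  equals the target $\sigma_G^2$ *exactly*, and GEI deviations are drawn
  iid per line × environment (the unrestricted compound-symmetry structure
  an ANOVA/REML analysis estimates) and rescaled so their double-centered
  interaction mean square equals $\sigma_{GE}^2$ exactly. Recovery noise in
  the tests therefore comes only from error variance and estimator
  sampling, not from the generator.
  An earlier design centered the GEI deviations per line; that removes the
  $\sigma_{GE}^2/e$ share of line-mean variance that the unrestricted EMS
  estimator subtracts, and biases $\hat\sigma_G^2$ down by exactly that
  amount — the iid construction is the one consistent with the estimators.
* **Trait correlation scale.** The `rg_traits` target is defined on the
  per-environment genotypic scale — what a within-environment MANOVA
  estimates. Because each trait's GEI is drawn independently, the
  per-environment genotypic variance is $\sigma_G^2 + \sigma_{GE}^2$ while
  the cross-trait covariance comes from main effects only; the effect-level
  correlation is therefore scaled up by
  $1/\sqrt{\frac{\sigma_G^2}{\sigma_G^2+\sigma_{GE}^2}(X)\cdot
  \frac{\sigma_G^2}{\sigma_G^2+\sigma_{GE}^2}(Y)}$. Targets that would
  need an effect correlation beyond ±1 are clamped with a warning.
* **Defaults from the published pea panel.** Genotypic/GEI variances:
  yield 0.575/1.435, protein 0.724/0.302 (so protein's genetic:GEI ratio is
  ~2.4 and yield's ~0.4). Error variances are *derived*, not guessed: the
  published multi-environment heritabilities (0.52 yield, 0.82 protein,
  with e = n = 3) invert to $\sigma_e^2 \approx 0.472$ and 0.524. Trait
  means and environment effects follow the printed trial means
  (yield 6.31/4.59/2.90 t/ha; protein 25.32/23.22/24.26%); the trait
  correlation target 0.15 sits mid-range of the published per-environment
  estimates (0.12–0.18). Block effects (SD 0.15 t/ha and 0.10%) are small
  nuisance effects of the magnitude routine RCB trials show; nothing
  downstream is sensitive to them.
* **Missingness.** Entry-wise Bernoulli with probability
  $1-(1-\mathrm{mpm}_j)(1-\mathrm{mps}_i)$, combining marker and sample
  rates, which reproduces the marginal rates GBS filtering thresholds act
  on. It does not emulate depth-dependent or allele-biased missingness.
* **Not emulated:** sequencing reads, genotype likelihoods, multiallelic
  sites, linkage between causal loci and trait-specific (non-shared) QTL,
  selection during line development, or spatial field trend. Tests passing
  on this generator show the estimators are correct under their assumed
  model; they do not certify behavior under, e.g., spatially correlated
  error.
* The genetic map defaults to 7 chromosomes × 100 cM — marker density per
  chromosome is fully configurable because the real panel's map density is
  not a published quantity.

## Marker quality control

Filtering order is fixed: markers first (missing rate > mpm, then
monomorphic, then MAF < maf_min computed on non-missing calls with
heterozygotes contributing one allele copy), then samples
(missing rate > mps). Defaults mpm = 0.2, mps = 0.25, maf_min = 0.05.
MAF is computed at the marker stage, before sample filtering; if exact
survivor counts matter for a particular reanalysis the thresholds and
order are the places to look. Imputation offers per-marker mode (ties to
the lower code) and k-nearest-neighbour vote (default k = 5, allele-share
distance on shared non-missing markers, ties resolved toward the mode);
knn exploits LD and beats mode on structured panels, which the tests check
by self-masking. A random-forest imputer would be a drop-in alternative
behind the same interface; downstream stages only require a complete
matrix, and the imputation method is not what limits predictive ability
here.

## Whole-genome regression

rrBLUP estimates $\lambda = \sigma_e^2/\sigma_u^2$ by maximizing the
restricted likelihood through one eigendecomposition of the marker kinship
$XX^\top$, profiling out the intercept and $\sigma_u^2$, with the search
bounded in $[10^{-5}, 10^5]$ (a boundary estimate — e.g. on pure-noise
phenotypes — triggers a warning, not an error). Effects are recovered in
kinship form, $u = X^\top (XX^\top + \lambda I)^{-1}(y-\mu)$, identical to
the ridge form and cheaper when markers outnumber lines. Markers are
centered by training-set means and not scaled, so effects are in
allele-dose units; scaling is a legitimate variant but changes effect
interpretation, so it is left to the caller.

The Bayesian samplers (C++): Bayes A (per-marker scaled-inv-χ² variances),
Bayes C (common variance, inclusion indicators, π ~ Beta(1, 9) sampled),
Bayesian Lasso (exponential mixture with Gamma(1.1, 0.1) hyperprior on
λ²). Priors default to effect df ν = 4.1 with scales set so the
prior-mean genetic variance is `h2_prior` (0.5) of var(y) — the convention
of the whole-genome-regression literature; every knob is an argument.
Default chain 12,000/2,000/5 keeps posterior means stable at ~300-line
panels; the tests and the acceptance script run 2,500–6,000-iteration
chains, which the model-comparison results show is already enough for
fold-level predictive ability (the four models agree to < 0.02 there).
Degenerate inputs: constant phenotypes are rejected for all models (the
same zero-variance contract as rrBLUP) — a Gibbs chain on var(y) = 0 has
no meaningful posterior; null *signal* (noise phenotypes) is the tested
behavior, and posterior effects collapse toward zero as they should.
Residual-variance draws that overflow abort with diagnostics.

## Cross-validation bookkeeping

Training targets are the per-line mean of environment-wise BLUPs over the
two training environments; the validation observation is the BLUP in the
held-out environment. Folds are stratified so each fold's per-population
counts differ from proportionality by at most one line, and partitions are
re-drawn independently each repetition (whether the original scheme
rotated one fixed partition is unknowable from the outside; independent
re-draws have the cleaner Monte Carlo interpretation). Predictive ability
is scored within population — pooling populations would inflate r through
population-mean differences. Undefined correlations (constant predictions,
or fewer than three validation lines of a population in a fold) are
recorded as missing and *excluded* from means, never zero-filled: zeros
would bias the aggregate toward pessimism exactly where cells are
smallest. The aggregation order is fixed and logged: folds → repetitions →
environment sets → populations → grand mean; with missing cells, different
orders give different grand means, so one order is the contract.

## GWAS

The null model $y = C\beta + g + e$, $g \sim N(0, \sigma_g^2 K)$ with the
Astle–Balding kinship and 10 genotype PCs in $C$, is fitted once by REML
(eigendecomposition of K, 1-D profile over the variance ratio); every
marker is then tested by GLS with $V = \sigma_g^2 K + \sigma_e^2 I$ held
fixed — the EMMAX/P3D scheme. Per-marker REML would cost hundreds of times
more for a calibration difference that the null simulations show is
negligible at this panel size. Population labels are deliberately *not*
fixed effects; structure is handled by PCs + kinship only. Explained
variance per marker is the squared partial correlation between the
rotated, covariate-residualized marker and phenotype, ×100 — an
oracle-checked quantity that is guaranteed per-marker ∈ [0, 100] but not
additive across markers in LD. A singular rotated covariance gets a 1e-8
ridge jitter with a warning. Multiple testing: Bonferroni α/M and the
Benjamini–Hochberg step-up implemented literally (sort, largest rank k
with $p_{(k)} \le kq/M$; no passing rank → threshold undefined, selection
empty — the fallback inspection of top markers is exposed but makes no
calibration claim). Significant markers are merged into loci by single
linkage on allelic R² > 0.8; single linkage is the permissive reading of
"pairs above threshold share a locus" and merges chains, which is the
conservative direction for counting distinct loci.

Detection power context: with kinship correction, a locus explaining ~6%
of phenotypic variance in a 306-line panel surfaces in the top LD cluster
reliably, but the *causal* marker itself need not rank first — its signal
is shared with neighbours and partly absorbed into K (proximal
contamination). That matches the marginal real-data situation (a handful
of protein loci at FDR, none at Bonferroni) and is why the tests assert
top-cluster recovery, not rank-1 identity.

## Selection gain

Selection intensity uses the large-sample truncation formula
$i = \phi(z_p)/p$ rather than printed Falconer tables — it reproduces the
four reference table values (1.755, 1.400, 2.023, 2.309) to three
decimals. The budget logic keeps the cost multiplier $c_P/c_G$ unrounded
internally (220/60 = 3.6667; 20%/3.6667 → 5.5%, whereas dividing by the
displayed "3.7" would print 5.4%), and the `intensity_ratio` default
follows table arithmetic — GS fraction display-rounded to one decimal
percent, intensities rounded to three decimals before the quotient — so
the reference ratios 1.316 and 1.445 and their compromise mean 1.381
reproduce exactly; `tabular = FALSE` gives the continuous value. Annual
gains are $\Delta G'_G = i_G r_{Ac} s_A/t_G$ vs
$\Delta G'_P = i_P H s_A/t_P$; the efficiency ratio cancels $s_A$ and
doubles exactly when $t_P$ doubles. One known external inconsistency: the
published efficiency-ratio table is ~5% above what its own printed
$H_C = 0.676$ and $r_{Ac}$ give under the displayed formula (its
per-population H inputs are not printed); this package reports the formula
value and leaves the discrepancy documented rather than absorbed.

## Problem sizes in tests and the acceptance script

Simulation-backed checks run at the design scale of 306 lines × 3
environments × 3 blocks, with marker density chosen per purpose: ~100
markers for variance-component recovery (LD is irrelevant to ANOVA
recovery, so density only costs time), ~300–420 post-filter markers for
prediction and GWAS (enough for realistic LD structure), and replicate
counts of 20–50 seeds for averaged recovery statements. These sizes make
the full suite and the acceptance script each run in about a minute while
keeping every estimator in its intended regime.

## Known limitations

Single-trait prediction only (no multi-trait or GBLUP-with-pedigree
variants); no dominance or epistasis; compound-symmetry GEI (no
environment-specific genetic variances or factor-analytic structure); the
delta-method SE for the trait genetic correlation is first-order; the
EMS F tests assume balance; and the simulator's missingness is
depth-agnostic. Each of these is a deliberate scope line, not an oversight.
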