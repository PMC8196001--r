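---
title: "From variant to bilirubin to hypertension: methods behind the workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From variant to bilirubin to hypertension: methods behind the workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bilicausal` implements, end to end, the statistical machinery of a
GWAS-to-Mendelian-randomization analysis of serum total bilirubin (TBIL)
and hypertension: mixed-model association with a kinship random effect,
Bayesian fine mapping, REML SNP heritability with LD-informed weights,
additive Bayesian network structure learning, and two-stage least-squares
causal inference with diagnostics, meta-analysis and analytic power. The
individual-level cohorts such an analysis runs on are not distributable,
so the package ships a synthetic-cohort generator whose causal chain —
variant → bilirubin → hypertension — has the same architecture, and every
stage is validated against that generator. This vignette records the
models, the defaults and the design decisions.

## The synthetic cohort

`sim_config()` / `simulate_cohort()` generate genotypes and phenotypes
with the statistical structure the downstream analyses assume.

**Genotypes.** Haplotypes come from a Gaussian copula: within an LD block
of `ld_block_size` consecutive variants (default 25), latent normals share
an exchangeable correlation `within_block_rho` (default 0.6) and are
thresholded at the allele-frequency quantile. This produces tunable
within-block r² and exact independence across blocks — sufficient for
methods that consume an LD matrix, which is all the downstream stages
need; it makes no attempt at coalescent realism, recombination maps, or
allele-frequency spectra. Subpopulation allele frequencies follow the
Balding–Nichols model (`n_subpops = 2`, `fst = 0.01` by default, the
order of magnitude expected between West African source populations).
Cryptic relatedness is injected as `n_sib_pairs = 50` sibling pairs that
inherit whole parental haplotypes (expected kinship 1/4; no
recombination, so sharing is coarser than in real siblings).

**Exposure.** Serum bilirubin is built on a unit-variance scale as

  X = a·Z + g + u_x·U + e + covariate effects,

where `Z` is the causal-variant dosage (EAF 0.49), `a` is calibrated so
`Var(a·Z)/Var(X) ≈ target_iv_r2` (default 0.12, the share of TBIL
variance a single UGT1A1 variant explains in African-ancestry cohorts),
`g` is a polygenic term with variance fraction `polygenic_h2` (default
0.385, the reported SNP heritability), `U` is a standard-normal
confounder, and the fixed covariate effects default to a positive male
effect (men have higher mean bilirubin), and small age and BMI effects.
Two deliberate structural choices:

* the polygenic background excludes the causal variant's *entire LD
  block*, so the region carries exactly one association signal — the
  single-signal architecture the conditional scan and fine mapping are
  designed around, and without which the instrument calibration would be
  contaminated by random covariance with block-mates;
* when `exposure_effect` is supplied directly (e.g. 0.59 SD per allele
  for effect-recovery experiments), the residual variance is shrunk so
  that `Var(X) ≈ 1` and the effect is recoverable on the
  inverse-normal-transformed scale.

**Outcome.** Hypertension is a logistic liability,
`logit P(Y=1) = c + log_or_per_sd·(X/SD(X)) + u_y·U + covariate effects`,
with `log_or_per_sd = log(0.46)` (protective) and the intercept `c`
solved by root finding so the population-averaged prevalence matches
`outcome_prevalence = 0.26` (tolerance 1e-4; an unreachable prevalence is
an error, not a silent clamp). How hypertension would be defined
clinically (threshold vs medication) is irrelevant here: the outcome is
an abstract binary trait. The confounder loadings default to
`u_x = 0.3`, `u_y = 0.5`, chosen so that naive logistic regression of Y
on X is visibly biased — the generator must make confounding *real* for
the Mendelian-randomization consistency experiments to mean anything.

`realized_truth()` recomputes, from the generated data, the realized EAF,
instrument R², generative heritability (causal + polygenic variance over
total) and prevalence; recovery tests compare estimates to these realized
values rather than to the nominal configuration.

What passing tests on this generator does *not* show: robustness to
imputation error (info scores are consumed, never generated), to
non-normal exposure distributions, to assortative mating or
fine-structure, or to case–control ascertainment. The generator samples
the population; nothing is ascertained on phenotype.

## Association: EMMAX-style mixed model

`lmm_assoc()` follows the standard two-step pipeline. The trait is first
regressed on age and sex (`residualize()`), the residuals rank-inverse
normalized (`rank_inverse_normal()`, Blom offset 3/8 — the offset is a
documented convention choice and configurable), and the transformed trait
analyzed with BMI, T2D and the significant ancestry PCs as fixed effects.
BMI and T2D enter at the mixed-model step, after the transformation —
the two-step order is ambiguous in pipelines of this kind; this one is
implemented exactly as stated and kept fixed.

The null model `y = Wα + u + e`, `Var(u) = σ_g² K`, is fitted once by
REML (`reml_fit()`): K is eigendecomposed, the restricted likelihood is
profiled down to the variance ratio and maximized by Brent search on the
log-ratio (tolerance 1e-8, search bounds e±12, boundary fits flagged).
Each variant is then tested with the ratio held fixed — the EMMAX
approximation. In the whitened coordinates the per-variant test is an
ordinary regression t-test with a per-variant residual variance; this
choice (rather than plugging in the null-model variance) makes the scan
*exactly* equal to OLS when `K = I`, which the suite asserts to 1e-6.
A Wald test is reported because effect and SE are the quantities of
interest downstream. Variants collinear with the fixed effects — e.g.
perfect proxies of a conditioning variant in `conditional_scan()` — are
flagged `"collinear"` and reported with `NA` rather than dropped
silently. `genomic_control()` is the median association χ² over 0.4549.

The number of ancestry PCs comes from `significant_pcs()`: eigenvalues of
the kinship matrix are tested sequentially against the Tracy–Widom (GOE)
law under the Patterson moment-matching normalization, stopping at the
first non-significant eigenvalue (α = 0.05). The TW distribution itself
is tabulated in the package from the Painlevé II representation and
interpolated monotonically; the table reproduces the standard critical
values (0.9793, 2.0234, 3.2724 at p = 0.05, 0.01, 0.001) to five
decimals. The test assumes approximately independent markers, so the
workflow computes PCs on an LD-pruned set (`ld_prune()`, greedy r² <
0.05); with block LD left in, the eigenvalue spectrum is wider than the
null and the test badly over-counts components. Sibling pairs also
register as genuine (family) structure; the mixed model absorbs
relatedness through K regardless, so a few extra PCs are harmless.

## SNP heritability

`reml_h2()` fits `Var(y) = σ_g² G + σ_e² I` by the same eigendecomposition
REML and reports `h² = σ_g²/(σ_g²+σ_e²)` with a delta-method SE from the
expected information matrix, flagging boundary estimates. `G` is a
weighted kinship (`weighted_kinship()`, trace-normalized to mean diagonal
1) built from `ld_weights()`: `w_j = 1 / Σ_{k∈window(j)} r²_jk` with the
self term included — an *inverse local LD score*. This is a deliberate
simplification of tagging-based weight solvers, which solve a quadratic
program; the inverse-LD-score form preserves the essential behaviour
(redundantly tagged variants are down-weighted, `d` perfect copies each
get `1/d`) while remaining closed-form and directly testable. No
MAF-dependent effect-size scaling is applied: dosages are standardized
per variant, and the default workflow restricts to common variants
(MAF > 0.05, 1 Mb windows). The suite checks REML against a brute-force
101-point grid search of the restricted likelihood (agreement to three
decimals of h²) and recovers a generative h² of 0.385 to within ±0.05
averaged over 20 cohorts of 2000 samples × 4000 variants.

## Fine mapping

`config_log_bf()` implements the multivariate approximate Bayes factor on
summary statistics: for a causal configuration `c`, the z-scores satisfy
`z_c ~ N(0, R_cc)` under the null and
`N(0, R_cc + n·σ_a²·R_cc R_cc)` under the alternative, with all
arithmetic in log space (Cholesky factorizations; singular `R_cc` is
ridge-regularized with a logged epsilon). The prior effect SD is averaged
over the grid `{0.1, 0.2, 0.4}` with equal weights — the conventional
default; the original analysis does not state its grid, so this is a
documented choice, not a reconstruction. `pip()` enumerates all
configurations up to `max_causal` (default 1, matching the single-signal
finding; a guard caps enumeration at 1e6 configurations), scores each by
`prior × BF` with an independent-inclusion prior (default `1/m` per
variant), and marginalizes. Binary annotations act as fixed
multiplicative prior-odds factors; estimating annotation weights is out
of scope. The enumeration posterior is checked against a brute-force
oracle that evaluates the normal densities directly (agreement to 1e-12),
and on simulated single-causal regions (n = 2000, m = 50, block LD) the
causal variant carries the top PIP in ≥ 80% of regions.

## Additive Bayesian network

Each node's conditional distribution is a GLM of the node on its parents:
identity link for continuous nodes, logit for binary ones. The network
score is the sum of BIC-penalized node log-likelihoods
(`logLik − (k/2)·log n`; for gaussian nodes `k` counts the variance).
Dedicated ABN implementations default to an exact marginal likelihood;
BIC is its large-n approximation and keeps every node score closed-form
and testable — a documented deviation. `search_once()` hill-climbs over
add/delete/reverse moves from a random, seed-derived starting DAG under
acyclicity, `max_parents` (default 4) and structural constraints; the
genotype node is constrained parentless (fixed at conception), which also
prevents the search from "explaining" the variant by its descendants.
`consensus()` repeats the search (200 by default in desk runs; the
full-scale convention is 20,000) and keeps directed edges present in at
least 50% of the locally optimal networks. Node scores are memoized
across searches — with 7 nodes and `max_parents = 4` there are only a few
hundred distinct (child, parent-set) fits, which is what makes hundreds
of restarts cheap. Collinear parents are dropped by the fit and flagged;
complete separation in a logistic node yields a finite, flagged score.

## Mendelian randomization

`first_stage()` regresses the exposure on instrument dosage plus
covariates and reports the partial F (1 df) and partial R² for the
instrument — the F > 10 convention is the strength rule. `second_stage()`
regresses the binary outcome on the fitted exposure by logistic
regression: the coefficient is the causal log-odds estimate, matching
practice in which the second-stage coefficient is reported with a Wald CI
on the log-odds scale. The plug-in ML standard error ignores first-stage
uncertainty and is therefore anti-conservative; `mr_study()` optionally
adds a joint two-stage bootstrap SE, and both are reported. Two caveats
are worth stating plainly:

* a logistic second stage estimates a *non-collapsible* quantity: the
  unmodelled exposure variation and any outcome-side heterogeneity enter
  the residual and attenuate the coefficient relative to the
  conditional log-OR. In the package's own experiments at the default
  architecture the attenuation is mild (the 95% CI covers the generative
  per-SD log-OR in > 90% of confounded cohorts while naive regression
  covers it in < 10%), but it is a property of the estimand, not a bug;
* `exclusion_check()` (outcome on instrument adjusting for exposure and
  covariates) conditions on a mediator. When a confounder affects both
  exposure and outcome this opens the collider path Z → X ← U → Y and
  the diagnostic slightly undercovers OR = 1 even for a perfectly valid
  instrument (about 86/100 at the default loadings versus the nominal
  95). Its calibration is therefore asserted in the unconfounded
  scenario, and its rejection under true pleiotropy is tested
  separately.

`ivw_meta()` is the fixed-effect inverse-variance combination with
Cochran's Q and I². `mr_power_binary()` evaluates the asymptotic
non-centrality form for a binary outcome: the two-stage z-statistic has
non-centrality `sqrt(n·R²·K(1−K))·|log OR|` (equivalently the
case/control-ratio form `ratio/(1+ratio)²`), giving two-sided power
`Φ(ncp − z_{1−α/2}) + Φ(−ncp − z_{1−α/2})`, which tends to α as R² → 0.
The formula is validated against a 2000-replicate simulation oracle at a
mid-power design (agreement within ±0.03).

## Orchestration and reproducibility

The numbered scripts under `analysis/` run the stages in order —
simulate, descriptive table, GWAS + conditional scan, fine mapping,
heritability, network, MR + meta + power — writing plain-text outputs
under `results/`. `run_demo_pipeline()` wraps the same computation into a
single call with a reproducibility manifest: configuration snapshot,
seeds, per-stage wall time and MD5 digests of every output; a re-run with
unchanged digests skips completed stages. All randomness flows from the
single seed in `sim_config()`; identical configurations give
byte-identical outputs.

## Problem sizes

The default demonstration cohort is 1500 samples × 5000 variants, which
runs the full pipeline in well under ten minutes on one core. The test
suite sizes its simulations to the smallest scale at which each property
is informative: e.g. heritability recovery uses 20 cohorts of
2000 × 4000; the null association scan uses 500 samples × 5000 variants;
type-I calibration of the mixed model uses 12,000 null variant tests
against a trait with 200 sibling pairs; fine-mapping recovery uses 100
regions of 50 variants. These are the package's own choices of scale,
stated here so that readers know exactly what the green suite does and
does not demonstrate.

## Known limitations

* Single variance component; no partitioned or bivariate heritability.
* Exact per-variant REML (as opposed to the EMMAX approximation) is not
  implemented; score tests are not offered.
* Fine mapping is exhaustive enumeration, suited to `max_causal ≤ 3` on
  regions of tens of variants; no stochastic search or credible-set
  machinery.
* MR is single-instrument, one-sample, individual-level; no Egger,
  weighted-median, or summary-statistic two-sample variants.
* The generator's LD is exchangeable within blocks — adequate for
  methods consuming an LD matrix, wrong for haplotype-based methods.
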