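---
title: "Phenome-wide mendelian randomization: models, defaults and design choices"
author: "pwmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenome-wide mendelian randomization: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmr)
```

## The analysis in one paragraph

`pwmr` asks a single question many times over: does a genetic proxy for a
continuous exposure (a weighted risk score, GRS) associate with each of the
diseases recorded in a biobank's ICD-coded medical records, and where it
does, is the association causal or an artifact of pleiotropy? The pipeline
runs five linked analyses: (1) score construction with allele
harmonization; (2) a phenome-wide scan (PheWAS) over phecode-defined
case/control groups with false-discovery-rate control; (3) a Bayesian scan
of the ICD-10 classification tree in which a discretized genetic
coefficient evolves down the hierarchy under a Markov process; (4)
two-sample mendelian randomization (MR) against an independent cohort's
summary statistics, with heterogeneity and directional-pleiotropy
diagnostics; and (5) a pleiotropy dissection that re-runs the phenome scan
with stratified and leave-group-out scores.

## The weighted genetic risk score

For person $i$ with dosages $g_{ij} \in [0,2]$ and published per-allele
effects $\beta_j$ on the exposure,

$$\mathrm{GRS}_i = \sum_j \beta_j\, g_{ij},$$

after harmonizing each instrument variant to the genotype file's counted
allele. A swapped encoding contributes $\beta_j (2 - g_{ij})$, so the score
always counts exposure-increasing alleles; the score is deliberately left
in the exposure's units (mg/dL-equivalent for a urate-like exposure)
rather than standardized, so association log-odds are per unit of
genetically proxied exposure. Palindromic variants (A/T, C/G) cannot be
oriented by allele letters; they are aligned by allele frequency when both
sides have $|\mathrm{EAF} - 0.5| > 0.08$ (a common two-sample
harmonization default) and dropped as ambiguous otherwise. Missing dosages
are imputed by their expectation $2\,\mathrm{EAF}_j$, which preserves the
score's mean and is the natural choice when the source data do not state
how missingness was handled.

Candidate confounders are screened by their association with the score
itself: Pearson correlation for continuous candidates, one-way ANOVA
across levels for categorical ones, selection at $p < 0.05$. Only
covariates correlated with the instrument can confound score-phenotype
associations, which is why screening is against the score and not the
phenotypes. Note the screen is itself a multiple-testing procedure run at
the nominal level: with $k$ truly independent candidates, each has a 5%
chance of selection, so occasional false inclusions are expected (and
harmless — they only add a covariate).

## The phecode phenome

ICD codes are normalized (uppercased, dots stripped) and mapped to
phecodes by longest-prefix match, so `I21.0` falls back to a map entry for
`I21` when no more specific entry exists. Each assigned phecode also
assigns its dotted ancestors (`411.2` rolls up to `411`); this mirrors how
published phenome scans report both a specific disease and its parent
group with overlapping counts. Controls for a phecode are all persons with
no assignment inside that phecode's exclusion range, so similar or
overlapping disease states never contaminate the control pool; an
ancestor phecode without its own map row inherits the union of its
descendants' ranges. Case/control sets with fewer than `min_cases = 20`
cases are excluded from the scan — below that, logistic estimates are
unstable and a single miscoded record can flip the result.

Each eligible set is fitted by maximum-likelihood logistic regression of
case status on the score plus screened covariates. The fit is iteratively
reweighted least squares (Fisher scoring) with the normal-equations solve
in compiled code, convergence on relative deviance change below $10^{-8}$
within 25 iterations, Wald standard errors from the observed information,
and two-sided normal p-values; odds ratios are $e^\beta$ with
$e^{\beta \pm 1.96\,\mathrm{SE}}$ intervals, displayed at 2 decimals with
full precision retained internally. Perfectly separated data (deviance
numerically zero) or runaway coefficients ($|\beta| > 15$) are reported
with `converged = FALSE` and estimates withheld rather than as spurious
numbers; non-converged fits are excluded from the FDR family since they
carry no valid p-value. Multiplicity is controlled by the
Benjamini–Hochberg step-up at $q = 0.05$; the reported significance
threshold is the largest discovered p-value, which is how phenome scans
conventionally quote their adjusted threshold. BH is used rather than
Bonferroni because rolled-up phecodes are nested, hence strongly
positively dependent, and Bonferroni would be needlessly conservative.

## The tree-structured Bayesian scan

The ICD-10 hierarchy (chapter → block → 3-character → 4-character code) is
treated as a tree over the observed codes and their ancestors, capped at
4-character depth. The genetic coefficient at each node is a random
variable on a finite grid containing 0. The root draws from the prior
$\rho$: zero with probability $1-\pi$, otherwise uniform over the nonzero
grid. Each child copies its parent with probability $1-\theta$ and
redraws from $\rho$ with probability $\theta$. This "redraw-from-root"
switch makes the chain exchangeable along any path: the marginal prior is
$\rho$ at every depth, which gives a clean sanity check (with flat
likelihoods the posterior probability of association is exactly $\pi$
everywhere — this is property-tested).

Evidence enters through a Gaussian working likelihood
$\mathcal{N}(\hat b_v \mid b, \hat{se}_v^2)$ built from the per-node
logistic fit, attached at **leaf nodes only**: an internal node's case set
is the union of its descendants', so attaching likelihood at internal
nodes would count the same persons twice. Internal nodes are inferred
purely through the Markov prior. Nodes with fewer than `min_cases` cases
get a flat likelihood. Exact per-node marginals come from upward
(collect) and downward (distribute) sum-product passes in log space with
max-subtraction; the implementation is validated against exhaustive
enumeration over all state assignments on small random trees to $10^{-10}$.

Defaults, all overridable: $\pi = 0.001$ (associations are rare across a
phenome), $\theta = 1/3$ (a child keeps its parent's coefficient twice as
often as not, encoding that disease sub-types usually share their parent's
genetic effect), and a grid of 0 plus 20 points over $\pm 4 \times$
(median informative-leaf SE $\times \sqrt{\text{leaf count}}$) — wide
enough to contain any plausible pooled effect, fine enough that the
Gaussian likelihood spans several grid points. Reporting uses posterior
probability of a nonzero coefficient, thresholded at 0.95. The MAP effect
and its 95% credible interval are both computed on the renormalized
nonzero posterior mass — i.e. conditional on association — so the MAP
always lies inside its own interval; reporting the unconditional argmax
would return 0 for borderline nodes, outside the conditional interval,
which is incoherent in a table of "effect estimates given association".

## Two-sample MR and the estimator ladder

Per SNP, the Wald ratio $\hat\beta_Y/\hat\beta_X$ with first-order SE
$se_Y/|\hat\beta_X|$. The estimators:

* **IVW** (fixed-effect): $\hat\tau = \sum w_j r_j / \sum w_j$ with
  $w_j = \hat\beta_{X j}^2 / se_{Y j}^2$ — algebraically both the
  inverse-variance meta-analysis of Wald ratios and weighted least squares
  of $\hat\beta_Y$ on $\hat\beta_X$ through the origin. Cochran's $Q$
  against the pooled estimate quantifies heterogeneity. The fixed-effect
  form is the default (it is the simplest IVW); a multiplicative
  random-effect SE is a toggle.
* **Egger**: weighted regression with intercept, after orienting every SNP
  to its exposure-increasing allele (without that orientation the
  intercept is not even well-defined, and orientation also buys invariance
  to per-SNP sign flips). The intercept's p-value is the directional
  horizontal pleiotropy test; SEs are fixed-effect to match the IVW
  convention. With all $\hat\beta_X$ equal the design is collinear and the
  fit is refused rather than silently regularized.
* **Weighted median**: inverse-variance-weighted median of Wald ratios
  with linear interpolation of the cumulative weight at 0.5; robust to up
  to half the weight being invalid.
* **Mode-based**: mode of the inverse-variance-weighted Gaussian kernel
  density of the ratios, Silverman-style bandwidth times a factor
  (default 1); robust when the largest cluster of agreeing instruments is
  valid. Median and mode SEs come from a seeded parametric bootstrap
  (default 1,000 draws) for determinism.

The reported estimate is chosen by a transparent, deterministic ladder:
one SNP → Wald ratio; Egger intercept $p < 0.05$ → mode-based (directional
pleiotropy biases both IVW and, less severely, the median); else Cochran
$Q$ $p < 0.05$ → weighted median (heterogeneity without direction); else
IVW. A trained model-selection framework for the same decision exists in
the literature but is not reproducible from its description; the ladder
preserves its role (pick the estimator whose assumptions the diagnostics
have not rejected) with auditable behavior, and the chosen rule is part of
the output.

## Pleiotropy dissection

A locus is called pleiotropic for a category (obesity, blood pressure,
lipids, glucose) when any trait in that category's GWAS lookup reports
$p < \alpha/m$ with $\alpha = 0.05$ and $m$ the instrument size (31 for
the packaged set, giving $1.61 \times 10^{-3}$). Missing lookups count as
non-significant — consortium supplements typically report only the
associations that reached significance. Categories may overlap; a locus
with no flag is exposure-specific. The stratified score set comprises the
full score, the exposure-specific score, one score per category, a
leave-category-out score per category (a locus is removed if it carries
the removed flag, regardless of its other flags), and — when a
renal-handling annotation is supplied — that subset and its complement.
Renal membership is an annotation (gene assignments), never computed. The
phenome scan is re-run per score; the phenotype × score discovery matrix
is the network-plot analogue of the dissection.

## What the synthetic biobank emulates — and what it does not

The generator exists so every layer of the pipeline can be exercised, and
calibrated, without access-controlled biobank data. It emulates: 31
independent biallelic variants whose true per-allele effects jointly
explain a target 7% of the exposure's variance (the noise SD is set from
the realized score variance, so the realized $R^2$ lands on target —
verified to fall in [0.06, 0.08] at $n = 50{,}000$); four mediator traits
(obesity-, blood-pressure-, lipid- and glucose-like) fed by overlapping
variant subsets of sizes 10/10/6/3 with 14 variants exposure-specific and
7 flagged renal; liability-threshold diseases emitting 4-character ICD-10
codes, with the two gout-like codes driven by the exposure itself and
every cardiometabolic code driven **only** by mediators, so any score
association with them is purely pleiotropic (each category's indicator
disease is mediated by that category alone, which is what makes the
leave-category-out logic decisive); small correlations of assessment
center and the first PC-like covariate with the true score, so covariate
screening has real signal; and an independent outcome cohort's summary
statistics with a configurable causal effect and optional per-SNP direct
effects. Liability thresholds are set on the standardized liability at the
configured prevalence quantile, so observed prevalences track their
targets within binomial error.

Deliberately not modelled: linkage disequilibrium (the instrument is
treated as independent loci, as the analysis assumes), relatedness,
population structure beyond linear covariates, age-dependent incidence,
repeat hospital episodes (one record per prevalent case), and diagnostic
misclassification. Passing tests on this generator therefore demonstrate
the statistical machinery under the assumed model — they do not
demonstrate robustness to LD-contaminated instruments or EHR coding noise,
which is exactly the caveat that applies to the corresponding real-data
analyses.

Since per-locus effect sizes for the real instrument are not published in
machine-readable form, the packaged effects are synthetic: two large
transporter-like loci and 29 small ones, scaled only to the aggregate 7%
target. The lipid-flagged loci carry moderately large exposure effects so
the lipid subscore retains power on the exposure-driven disease — the
qualitative pattern (every pleiotropic subscore also associates with the
gout-like code) mirrors the dissection figure the sensitivity analysis is
meant to reproduce.

## Numerical and testing choices

* All randomness flows through explicit seeds; the pipeline fans one
  master seed into named per-stage streams (`seed_streams`), so stages
  rerun in isolation reproduce their in-pipeline results, and reruns are
  byte-identical.
* Belief propagation runs in log space with max-subtraction; posteriors
  renormalize to 1 within $10^{-10}$ (asserted).
* The logistic IRLS core is compiled (RcppArmadillo) because the
  calibration suites refit on the order of $10^4$ phenome scans'
  worth of regressions; it is cross-checked against `stats::glm` to
  $10^{-6}$ on fuzzed datasets and to $10^{-13}$ in spot checks.
* Problem sizes used by the test and acceptance suites: cohorts of
  50,000 (the packaged default), 1,000 Egger-calibration replicates, 500
  permutation replicates for the BH global-null check, 50 replicates for
  the dissection-recovery rates, and 200 random trees for the
  enumeration oracle. These sizes put Monte-Carlo error comfortably below
  the decision margins being tested.
* Ties and degenerate inputs: zero-exposure-effect SNPs are excluded from
  Wald ratios with a warning; empty categories are skipped with a warning;
  constant covariates are dropped with a warning; an empty diagnosis file
  is a warning, not an error; a cyclic "tree" and an all-dropped
  instrument set are hard errors.

## Known limitations

The Gaussian working likelihood at tree leaves is a summary-statistic
approximation; with very few cases per leaf the exact logistic profile
likelihood would differ (such leaves are flat here). $\pi$ and $\theta$
are fixed, not estimated by empirical Bayes. The Egger intercept test
inherits its known sensitivity to exposure-side measurement error (weak
instruments), which can push its finite-sample size toward the upper end
of its nominal band. Phecode sex-specific restrictions and oncology
coding are out of scope, and the packaged phecode map is a miniature for
the synthetic code alphabet — real analyses should supply the full public
map as input.
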