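# pwmr — phenome-wide mendelian randomization

`pwmr` is an R toolkit for asking, at biobank scale, which diseases are
associated with a genetically proxied continuous exposure — and which of
those associations are causal rather than artifacts of pleiotropy. It was
built around the urate → cardiovascular/metabolic disease problem: serum
urate is observationally linked to gout, hypertension, heart disease and
dyslipidemia, but the instrument loci for urate are heavily pleiotropic on
metabolic traits, so naive scans and naive MR both mislead. The intended
users are genetic epidemiologists running PheWAS/MR workflows on cohorts
with ICD-coded medical records.

## What it computes

1. **Weighted genetic risk score.** `GRS_i = Σ_j β_j g_ij` over a
   harmonized instrument set (allele matching, strand-ambiguous variants
   resolved by frequency or dropped, missing dosages imputed by `2·EAF`),
   plus screening of candidate covariates against the score.
2. **Phecode phenome + PheWAS.** ICD-9/10 records → phecode case/control
   groups with hierarchical rollup and control-exclusion ranges; per-phecode
   logistic regression of case status on the GRS (compiled IRLS, Wald
   inference); Benjamini–Hochberg FDR at q = 0.05 over groups with ≥ 20
   cases; odds ratios as `exp(β)` with `exp(β ± 1.96·SE)` intervals.
3. **Tree-structured Bayesian scan.** A discretized genetic coefficient
   evolves down the ICD-10 hierarchy under a Markov process (root prior:
   nonzero with probability π = 0.001; children copy their parent with
   probability 1 − θ = 2/3, else redraw). Gaussian working likelihoods at
   leaves; exact marginal posteriors by sum-product message passing;
   nodes reported at posterior probability ≥ 0.95 with conditional MAP
   effect and 95% credible interval.
4. **Two-sample MR suite.** Wald ratios, fixed-effect IVW with Cochran Q,
   MR-Egger with the intercept test for directional pleiotropy, weighted
   median, and a mode-based estimator; a deterministic rule ladder picks
   the estimate to report (Egger intercept p < 0.05 → mode-based; else
   Q p < 0.05 → weighted median; else IVW).
5. **Pleiotropy dissection.** Loci classified by cross-trait GWAS lookups
   at the Bonferroni threshold α/m (0.05/31 = 1.61 × 10⁻³ for the packaged
   instrument), stratified and leave-category-out GRSs (plus a
   renal-handling subset and its complement), and a PheWAS rerun per score.

A synthetic biobank generator (`default_sim_config()`, `simulate_cohort()`)
provides genotypes, a 7%-heritability-by-instrument exposure, pleiotropic
mediators, liability-threshold diseases emitting ICD-10 codes, and an
independent outcome cohort's summary statistics, so the whole pipeline is
testable end to end without access-controlled data.

## Worked example

```r
library(pwmr)

cfg    <- default_sim_config(n_individuals = 20000, seed = 7)
cohort <- simulate_cohort(cfg)
grs    <- compute_grs(cohort$genotypes, config_weights(cfg))
grs
#> grs_vector: 20000 persons, 31 variants used (0 dropped); mean 2.470, sd 0.360

cands <- cohort$traits[c("person_id","sex","age","bmi","center", paste0("PC",1:5))]
sel   <- screen_covariates(grs, cands)        # -> "center" "PC1" "PC4"

asg  <- map_to_phecodes(cohort$diagnoses, pwmr_phecode_map())
phen <- build_phenome(asg, pwmr_phecode_map(), cohort$genotypes$person_ids)
scan <- run_phewas(phen, grs, cands[c("person_id", sel)])
scan
#> phewas_report: 19 phenotypes tested, 13 discoveries at q = 0.05 (p <= 0.000128)
scan$results[order(scan$results$p)[1:3], c("id","n_cases","beta","se","or_point","p")]
#>      id n_cases beta    se or_point        p
#>   274.1     544 1.45 0.130     4.28 4.08e-29
#>     274     544 1.45 0.130     4.28 4.08e-29
#>  274.11     397 1.46 0.151     4.29 6.09e-22

set <- simulate_summary_stats(cfg, n_outcome = 50000, tau = 0.3, seed = 11)
run_mr(set, seed = 5)
#> mr_suite (31 SNPs); selected: ivw [no pleiotropy or heterogeneity flagged: ivw]
#>   ivw              beta   0.302  se  0.013  OR 1.35 (1.32-1.39)  p 3.43e-128
#>   egger            beta   0.286  se  0.020  OR 1.33 (1.28-1.38)  p 9.21e-46  p_pleio 0.306
#>   weighted_median  beta   0.287  se  0.019  OR 1.33 (1.29-1.38)  p 1.93e-54
#>   mode_based       beta   0.300  se  0.016  OR 1.35 (1.31-1.39)  p 4.29e-74
```

The gout-like phecode (274.1, driven by the exposure in the generator) is
recovered with OR ≈ 4.3 per mg/dL-equivalent of score; the MR suite
recovers the simulated causal effect τ = 0.3 (IVW 0.302 ± 0.013) and the
clean instrument set correctly leaves IVW selected. `run_pipeline()` runs
all five stages (including the tree scan and the pleiotropy dissection)
from one config and writes per-stage TSVs; `inst/cli/pwmr` wraps
`simulate` and `run-all` for shell use.

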