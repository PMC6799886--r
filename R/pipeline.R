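# End-to-end orchestration: simulate or load a cohort, build the score and
# the phenome, run the phenome scan, the tree scan, the two-sample MR suite
# and the pleiotropy dissection, and write per-stage TSV reports with a
# fixed seed fan-out so each stage is reproducible in isolation.

#' Build a pipeline configuration
#'
#' @param q Phenome-scan false discovery rate (default 0.05).
#' @param min_cases Minimum cases per analyzable phenotype (default 20).
#' @param pp_threshold Tree-scan posterior-probability report cutoff
#'   (default 0.95).
#' @param alpha_pleiotropy Family-wise level for the pleiotropy
#'   classification threshold (default 0.05).
#' @param mr_tau True causal effect used when the outcome-side summary
#'   statistics are simulated (default 0.3).
#' @param mr_n_outcome Outcome-cohort size for simulated summary statistics.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(q = 0.05, min_cases = 20, pp_threshold = 0.95,
                            alpha_pleiotropy = 0.05, mr_tau = 0.3,
                            mr_n_outcome = 50000, seed = 1L) {
  if (!(q >= 0 && q <= 1)) {   # q = 0 is a legal degenerate FDR (no discoveries)
    stop_pwmr("pipeline config: q must lie in [0, 1]", class = "pwmr_config_error")
  }
  for (val in c(pp_threshold, alpha_pleiotropy)) {
    if (!(val > 0 && val <= 1)) {
      stop_pwmr("pipeline config: thresholds must lie in (0, 1]",
                class = "pwmr_config_error")
    }
  }
  structure(list(q = q, min_cases = min_cases, pp_threshold = pp_threshold,
                 alpha_pleiotropy = alpha_pleiotropy, mr_tau = mr_tau,
                 mr_n_outcome = mr_n_outcome, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_pwmr("pipeline stage '%s' failed: %s", name, conditionMessage(e),
              class = "pwmr_pipeline_error")
  })
}

#' Run the full phenome-wide mendelian randomization pipeline
#'
#' Stages: risk score (harmonization, scoring, covariate screening) ->
#' phenome (phecode case/control sets and ICD-10 tree) -> phenome scan with
#' FDR -> tree scan -> two-sample MR suite on an independent simulated
#' outcome cohort -> pleiotropy classification and stratified-score
#' sensitivity scans. Writes one TSV per stage plus a manifest when
#' `out_dir` is given.
#'
#' @param config A `pipeline_config`.
#' @param cohort A `cohort_data` (default: simulated from
#'   [default_sim_config()] with the config's seed).
#' @param out_dir Optional output directory for the per-stage TSVs.
#' @return List of class `pipeline_result` with elements `grs`,
#'   `covariates_selected`, `phenome`, `phewas`, `treewas`,
#'   `treewas_reported`, `mr`, `pleiotropy` (categories, reports,
#'   discovery matrix), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  seeds <- seed_streams(config$seed, c("cohort", "mr", "pvalues", "boot"))
  if (is.null(cohort)) {
    cohort <- stage("simulate",
                    simulate_cohort(default_sim_config(seed = seeds[["cohort"]])))
  }
  sim <- cohort$config
  weights <- config_weights(sim)

  grs <- stage("grs", {
    hz <- harmonize(weights, data.frame(rsid = weights$rsid,
                                        counted_allele = weights$effect_allele,
                                        other_allele = weights$other_allele,
                                        observed_af = weights$eaf))
    compute_grs(cohort$genotypes, hz)
  })
  candidates <- cohort$traits[c("person_id", "sex", "age", "bmi", "center",
                                paste0("PC", 1:5))]
  selected <- stage("covariates", screen_covariates(grs, candidates))
  covars <- candidates[c("person_id", selected)]

  phenome <- stage("phenome", {
    assignments <- map_to_phecodes(cohort$diagnoses, pwmr_phecode_map())
    build_phenome(assignments, pwmr_phecode_map(), cohort$genotypes$person_ids,
                  min_cases = config$min_cases)
  })
  phewas <- stage("phewas", run_phewas(phenome, grs, covars, q = config$q))

  treewas <- stage("treewas", {
    tree <- build_icd_tree(unique(cohort$diagnoses$code[cohort$diagnoses$system == "ICD10"]))
    tree <- propagate_cases(tree, cohort$diagnoses, cohort$genotypes$person_ids)
    run_treewas(tree, grs, covars, min_cases = config$min_cases)
  })
  treewas_reported <- report_associated(treewas, config$pp_threshold)

  mr <- stage("mr", {
    set <- simulate_summary_stats(sim, n_outcome = config$mr_n_outcome,
                                  tau = config$mr_tau, seed = seeds[["mr"]])
    run_mr(set, seed = seeds[["boot"]])
  })

  pleiotropy <- stage("pleiotropy", {
    pvals <- simulate_trait_pvalues(sim, seed = seeds[["pvalues"]])
    thr <- bonferroni_threshold(config$alpha_pleiotropy, nrow(sim$variants))
    cats <- classify_loci(pvals, threshold = thr,
                          renal = sim$variants$rsid[sim$variants$renal])
    grs_set <- build_stratified_grs(cats, weights, cohort$genotypes)
    sens <- run_sensitivity(grs_set, phenome, covars, q = config$q)
    list(threshold = thr, categories = cats, reports = sens$reports,
         discovery_matrix = sens$discovery_matrix)
  })

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(grs = "grs.tsv", phewas = "phewas.tsv", treewas = "treewas.tsv",
               mr = "mr.tsv", categories = "pleiotropy_categories.tsv",
               discoveries = "sensitivity_discoveries.tsv")
    write_grs(grs, file.path(out_dir, paths["grs"]))
    write_phewas_report(phewas, file.path(out_dir, paths["phewas"]))
    write_treewas_result(treewas, file.path(out_dir, paths["treewas"]))
    write_mr_suite(mr, file.path(out_dir, paths["mr"]))
    utils::write.table(as.data.frame(pleiotropy$categories),
                       file.path(out_dir, paths["categories"]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- data.frame(phecode = rownames(pleiotropy$discovery_matrix),
                     pleiotropy$discovery_matrix, check.names = FALSE)
    utils::write.table(dm, file.path(out_dir, paths["discoveries"]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- data.frame(stage = names(paths), file = unname(paths))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(grs = grs, covariates_selected = selected, phenome = phenome,
                 phewas = phewas, treewas = treewas,
                 treewas_reported = treewas_reported, mr = mr,
                 pleiotropy = pleiotropy, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  covariates adjusted: %s\n",
              paste(x$covariates_selected, collapse = ", ")))
  cat(sprintf("  phenome-scan discoveries (q = %g): %s\n", x$phewas$fdr_q,
              paste(x$phewas$discoveries, collapse = ", ")))
  cat(sprintf("  tree nodes at PP >= threshold: %s\n",
              paste(x$treewas_reported$node, collapse = ", ")))
  cat(sprintf("  MR selected estimator: %s (beta %.3f, se %.3f)\n",
              x$mr$selected$method, x$mr$selected$beta, x$mr$selected$se))
  invisible(x)
}
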