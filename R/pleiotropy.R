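# Pleiotropy dissection of the instrument set: classify loci by cross-trait
# associations at a Bonferroni threshold, build stratified and
# leave-group-out risk scores (plus the renal-handling subset), and rerun
# the phenome scan per score to separate exposure-driven from
# mediator-driven disease associations.

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of tests (for the packaged instrument set, the 31 loci).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, is_count(m))
  alpha / m
}

#' Classify instrument loci by cross-trait pleiotropy
#'
#' A locus carries a category flag (obesity, bp, lipid, glucose) when any
#' trait in that category's group reports an association below `threshold`
#' in the cross-trait p-value lookup. Loci with no flag are
#' exposure-specific. Missing p-values (associations the consortium did not
#' report) are treated as non-significant with a warning.
#'
#' @param pvalues Data frame: `rsid` plus one p-value column per trait.
#' @param groups Named character vector trait -> category, as from
#'   [trait_groups()].
#' @param threshold Per-test significance threshold, e.g.
#'   [bonferroni_threshold()].
#' @param renal Optional character vector of rsids annotated as the
#'   renal-handling subset (gene-level annotation supplied by the user, not
#'   computed).
#' @return Data frame of class `locus_categories`: `rsid`, one logical
#'   column per category, `urate_specific`, and `renal` when supplied.
#' @export
classify_loci <- function(pvalues, groups = trait_groups(), threshold,
                          renal = NULL) {
  traits <- setdiff(names(pvalues), "rsid")
  unknown <- setdiff(traits, names(groups))
  if (length(unknown)) {
    stop_pwmr("classify_loci: unknown trait(s) %s", paste(unknown, collapse = ", "),
              class = "pwmr_validation_error")
  }
  if (anyNA(pvalues[traits])) {
    warn_pwmr("classify_loci: %d missing p-value(s) treated as non-significant",
              sum(is.na(pvalues[traits])))
  }
  out <- data.frame(rsid = pvalues$rsid)
  for (cat in unique(unname(groups))) {
    cols <- intersect(traits, names(groups)[groups == cat])
    hit <- if (length(cols)) {
      apply(pvalues[cols] < threshold, 1, any, na.rm = TRUE)
    } else rep(FALSE, nrow(pvalues))
    out[[cat]] <- as.logical(hit)
  }
  cats <- setdiff(names(out), "rsid")
  out$urate_specific <- rowSums(out[cats]) == 0
  if (!is.null(renal)) out$renal <- out$rsid %in% renal
  class(out) <- c("locus_categories", "data.frame")
  out
}

#' Build the stratified and leave-group-out risk score set
#'
#' Emits: the full score; the exposure-specific score; one score per
#' pleiotropy category; a leave-one-category-out score per category (a locus
#' is removed if it carries the removed flag, regardless of other flags);
#' and, when the classification carries a `renal` flag, the renal-handling
#' subset score and its complement. Empty subsets are skipped with a
#' warning.
#'
#' @param categories A `locus_categories` table.
#' @param weights A [variant_weights] table covering the classified rsids.
#' @param genotypes A [genotype_matrix].
#' @return Named list of `grs_vector`s.
#' @export
build_stratified_grs <- function(categories, weights, genotypes) {
  cats <- setdiff(names(categories), c("rsid", "urate_specific", "renal"))
  subsets <- list(full = categories$rsid,
                  urate_specific = categories$rsid[categories$urate_specific])
  for (cat in cats) {
    subsets[[cat]] <- categories$rsid[categories[[cat]]]
    subsets[[paste0("leave_out_", cat)]] <- categories$rsid[!categories[[cat]]]
  }
  if ("renal" %in% names(categories)) {
    subsets$renal <- categories$rsid[categories$renal]
    subsets$renal_complement <- categories$rsid[!categories$renal]
  }
  out <- list()
  for (nm in names(subsets)) {
    rsids <- subsets[[nm]]
    if (!length(rsids)) {
      warn_pwmr("build_stratified_grs: subset '%s' is empty, skipped", nm)
      next
    }
    w <- weights[weights$rsid %in% rsids, , drop = FALSE]
    class(w) <- class(weights)
    out[[nm]] <- compute_grs(genotypes, w)
  }
  out
}

#' Rerun the phenome scan for each stratified risk score
#'
#' @param grs_set Named list of `grs_vector`s from [build_stratified_grs()].
#' @param phenome A `phenome`.
#' @param covariates Optional covariate data frame.
#' @param q Target FDR per scan (default 0.05).
#' @return List of class `sensitivity_report`: `reports` (named list of
#'   `phewas_report`) and `discovery_matrix` (phenotype x score logical
#'   matrix of FDR discoveries, the network-plot analogue).
#' @export
run_sensitivity <- function(grs_set, phenome, covariates = NULL, q = 0.05) {
  reports <- lapply(grs_set, run_phewas, phenome = phenome,
                    covariates = covariates, q = q)
  phecodes <- sort(unique(unlist(lapply(reports, function(r) r$results$id))))
  mat <- vapply(reports, function(r) phecodes %in% r$discoveries,
                logical(length(phecodes)))
  rownames(mat) <- phecodes
  structure(list(reports = reports, discovery_matrix = mat),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity_report: %d scores x %d phenotypes; discoveries per score:\n",
              ncol(x$discovery_matrix), nrow(x$discovery_matrix)))
  print(colSums(x$discovery_matrix))
  invisible(x)
}
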