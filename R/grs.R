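# Weighted genetic risk score: harmonize published instrument weights
# against the genotype file's counted alleles, sum weighted dosages, and
# screen candidate covariates for correlation with the score.

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize instrument weights to the genotype file's counted alleles
#'
#' For each instrument variant matched by rsid: if the genotype file counts
#' the effect allele the weight is kept; if the alleles are swapped the
#' contribution is recoded to `2 - dosage` (equivalently the per-dosage beta
#' is negated and a constant `2*beta` is added, so the score still counts
#' exposure-increasing alleles). Palindromic variants (A/T or C/G) cannot be
#' resolved by allele letters and are aligned by allele frequency when both
#' sides are clearly away from 0.5 (|eaf - 0.5| > `eaf_threshold`), else
#' dropped as `palindromic-ambiguous`. Unmatched rsids and incompatible
#' allele pairs are dropped with machine-readable reasons, never silently.
#'
#' @param weights A [variant_weights] table.
#' @param genotype_variants Data frame `rsid`, `counted_allele`,
#'   `other_allele`, `observed_af` (frequency of the counted allele; may be
#'   NA, which forfeits palindromic rescue).
#' @param eaf_threshold Palindromic frequency-distance threshold (default
#'   0.08, the common two-sample harmonization default).
#' @return List of class `harmonized_weights`: `aligned` (data frame `rsid`,
#'   `beta_dosage` per counted-allele dosage, `offset` constant, `eaf`
#'   aligned to the counted allele, `flipped`) and `dropped` (data frame
#'   `rsid`, `reason`).
#' @export
harmonize <- function(weights, genotype_variants, eaf_threshold = 0.08) {
  gv <- genotype_variants
  stopifnot(!anyDuplicated(weights$rsid), !anyDuplicated(gv$rsid))
  gv$counted_allele <- toupper(as.character(gv$counted_allele))
  gv$other_allele <- toupper(as.character(gv$other_allele))
  if (is.null(gv$observed_af)) gv$observed_af <- NA_real_

  aligned <- list()
  dropped <- list()
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    j <- match(w$rsid, gv$rsid)
    if (is.na(j)) {
      dropped[[length(dropped) + 1L]] <- data.frame(rsid = w$rsid, reason = "unmatched")
      next
    }
    g <- gv[j, ]
    pal <- is_palindromic(w$effect_allele, w$other_allele)
    if (pal) {
      if (!is_palindromic(g$counted_allele, g$other_allele) ||
          !setequal(c(g$counted_allele, g$other_allele),
                    c(w$effect_allele, w$other_allele))) {
        dropped[[length(dropped) + 1L]] <- data.frame(rsid = w$rsid, reason = "allele-mismatch")
        next
      }
      if (is.na(g$observed_af) || abs(w$eaf - 0.5) <= eaf_threshold ||
          abs(g$observed_af - 0.5) <= eaf_threshold) {
        dropped[[length(dropped) + 1L]] <- data.frame(rsid = w$rsid,
                                                      reason = "palindromic-ambiguous")
        next
      }
      # Frequencies on the same side of 0.5 => counted allele is the effect
      # allele; opposite sides => swapped encoding.
      swapped <- (w$eaf < 0.5) != (g$observed_af < 0.5)
    } else if (g$counted_allele == w$effect_allele && g$other_allele == w$other_allele) {
      swapped <- FALSE
    } else if (g$counted_allele == w$other_allele && g$other_allele == w$effect_allele) {
      swapped <- TRUE
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(rsid = w$rsid, reason = "allele-mismatch")
      next
    }
    aligned[[length(aligned) + 1L]] <- data.frame(
      rsid = w$rsid,
      beta_dosage = if (swapped) -w$beta else w$beta,
      offset = if (swapped) 2 * w$beta else 0,
      eaf = if (swapped) 1 - w$eaf else w$eaf,
      flipped = swapped)
  }
  empty_aligned <- data.frame(rsid = character(), beta_dosage = numeric(),
                              offset = numeric(), eaf = numeric(),
                              flipped = logical())
  empty_dropped <- data.frame(rsid = character(), reason = character())
  structure(list(aligned = if (length(aligned)) do.call(rbind, aligned) else empty_aligned,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else empty_dropped),
            class = "harmonized_weights")
}

#' Compute the weighted genetic risk score
#'
#' `score_i = sum_j beta_j * dosage_ij` over the harmonized instrument set,
#' on the counted-allele encoding (flipped variants contribute
#' `beta_j * (2 - dosage_ij)`). Missing dosages are imputed by their
#' expectation `2 * eaf_j`, which preserves the score's mean. Units are those
#' of the instrument betas (mg/dL-equivalent exposure for the packaged set);
#' the score is deliberately not standardized.
#'
#' @param genotypes A [genotype_matrix].
#' @param harmonized A `harmonized_weights` object from [harmonize()] (or a
#'   [variant_weights] table, which is auto-harmonized assuming the counted
#'   allele is the effect allele).
#' @return List of class `grs_vector`: `person_ids`, `score`,
#'   `n_variants_used`, `variants_dropped`.
#' @export
compute_grs <- function(genotypes, harmonized) {
  if (inherits(harmonized, "variant_weights")) {
    harmonized <- harmonize(harmonized,
      data.frame(rsid = harmonized$rsid,
                 counted_allele = harmonized$effect_allele,
                 other_allele = harmonized$other_allele,
                 observed_af = harmonized$eaf))
  }
  al <- harmonized$aligned
  present <- al$rsid %in% genotypes$variant_ids
  dropped <- harmonized$dropped
  if (any(!present)) {
    dropped <- rbind(dropped, data.frame(rsid = al$rsid[!present],
                                         reason = "absent-from-genotypes"))
    al <- al[present, , drop = FALSE]
  }
  if (nrow(al) == 0) {
    stop_pwmr("compute_grs: no instrument variants usable after harmonization",
              class = "pwmr_grs_error")
  }
  idx <- match(al$rsid, genotypes$variant_ids)
  dos <- genotypes$dosage[, idx, drop = FALSE]
  if (anyNA(dos)) {
    imp <- rep(2 * al$eaf, each = nrow(dos))
    dos[is.na(dos)] <- imp[is.na(dos)]
  }
  score <- unname(drop(dos %*% al$beta_dosage)) + sum(al$offset)
  structure(list(person_ids = genotypes$person_ids, score = score,
                 n_variants_used = nrow(al), variants_dropped = dropped),
            class = "grs_vector")
}

#' @export
print.grs_vector <- function(x, ...) {
  cat(sprintf("grs_vector: %d persons, %d variants used (%d dropped); mean %.3f, sd %.3f\n",
              length(x$person_ids), x$n_variants_used, nrow(x$variants_dropped),
              mean(x$score), stats::sd(x$score)))
  invisible(x)
}

#' Write a GRS to TSV (person_id, score)
#' @param grs A `grs_vector`.
#' @param path Output path.
#' @export
write_grs <- function(grs, path) {
  utils::write.table(data.frame(person_id = grs$person_ids,
                                score = sprintf("%.6f", grs$score)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen candidate covariates for correlation with the risk score
#'
#' Continuous candidates are tested by Pearson correlation with the score;
#' categorical candidates by one-way analysis of variance of the score
#' across levels. Candidates with p below `alpha` are returned and should be
#' adjusted for in the association models (they are correlated with the
#' instrument and therefore potential confounders of the score-phenotype
#' associations).
#'
#' @param grs A `grs_vector`.
#' @param candidates Data frame of candidate covariates, rows aligned to
#'   `grs$person_ids` (a `person_id` column, if present, is used to align).
#' @param alpha Selection level (default 0.05).
#' @return Character vector of selected covariate names.
#' @export
screen_covariates <- function(grs, candidates, alpha = 0.05) {
  if ("person_id" %in% names(candidates)) {
    idx <- match(grs$person_ids, candidates$person_id)
    if (anyNA(idx)) stop_pwmr("screen_covariates: persons missing from candidate table",
                              class = "pwmr_validation_error")
    candidates <- candidates[idx, setdiff(names(candidates), "person_id"), drop = FALSE]
  }
  selected <- character()
  for (nm in names(candidates)) {
    x <- candidates[[nm]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warn_pwmr("screen_covariates: '%s' is constant, skipped", nm)
      next
    }
    p <- if (is.numeric(x)) {
      stats::cor.test(grs$score, x)$p.value
    } else {
      stats::anova(stats::lm(grs$score ~ factor(x)))[["Pr(>F)"]][1]
    }
    if (is.finite(p) && p < alpha) selected <- c(selected, nm)
  }
  selected
}
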