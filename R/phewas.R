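# Per-phecode logistic regression of case status on the risk score with
# screened covariates, Benjamini-Hochberg FDR over the phenome, and the
# odds-ratio / Wald-interval transform used in all reports.

#' Odds ratio with 95% Wald interval from a log-odds estimate
#'
#' `exp(beta)` with interval `exp(beta -/+ 1.96 se)`. Full precision is
#' returned; `display` carries the conventional 2-decimal report string.
#'
#' @param beta Log-odds estimate.
#' @param se Standard error (> 0).
#' @return List: `or_point`, `ci_low`, `ci_high` (full precision), `display`.
#' @export
or_from_beta <- function(beta, se) {
  stopifnot(se > 0)
  or <- exp(beta)
  lo <- exp(beta - 1.96 * se)
  hi <- exp(beta + 1.96 * se)
  list(or_point = or, ci_low = lo, ci_high = hi,
       display = sprintf("%.2f (%.2f-%.2f)", round2(or), round2(lo), round2(hi)))
}

# Expand a covariate data frame into a numeric design block (no intercept),
# aligned to person_ids when a person_id column is present. Constant columns
# are dropped with a warning.
covariate_design <- function(covariates, person_ids) {
  if (is.null(covariates) || ncol(covariates) == 0) {
    return(matrix(numeric(0), nrow = length(person_ids), ncol = 0))
  }
  if ("person_id" %in% names(covariates)) {
    idx <- match(person_ids, covariates$person_id)
    if (anyNA(idx)) stop_pwmr("covariates: persons missing from covariate table",
                              class = "pwmr_validation_error")
    covariates <- covariates[idx, setdiff(names(covariates), "person_id"), drop = FALSE]
  } else if (nrow(covariates) != length(person_ids)) {
    stop_pwmr("covariates: %d rows for %d persons and no person_id column",
              nrow(covariates), length(person_ids), class = "pwmr_validation_error")
  }
  keep <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) > 1, logical(1))
  if (any(!keep)) {
    warn_pwmr("covariates: dropping constant column(s) %s",
              paste(names(covariates)[!keep], collapse = ", "))
  }
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) {
    return(matrix(numeric(0), nrow = length(person_ids), ncol = 0))
  }
  stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
}

# Core maximum-likelihood logistic fit: iteratively reweighted least squares
# (Fisher scoring) with the normal-equations solve done on the small p x p
# cross-product in compiled code, which keeps a phenome-wide scan of large
# cohorts cheap. Convergence on relative deviance change < 1e-8 within 25
# iterations; Wald covariance from the observed information (X' W X)^-1 at
# the optimum. Rank deficiency, separation (runaway coefficients) or
# non-convergence are reported as converged = FALSE.
irls_logistic <- function(y, X, epsilon = 1e-8, maxit = 25L) {
  fit <- irls_logistic_cpp(X, as.numeric(y), epsilon, as.integer(maxit))
  names(fit$coefficients) <- colnames(X)
  fit
}

fit_logistic_raw <- function(y, X) {
  fit <- irls_logistic(y, X)
  k <- match("grs", colnames(X))
  beta <- unname(fit$coefficients[k])
  # A (near-)zero deviance means the data are perfectly separated and the
  # MLE does not exist; runaway coefficients catch quasi-separation.
  ok <- fit$converged && is.finite(beta) && abs(beta) < 15 &&
    fit$deviance > 1e-6
  se <- if (ok) sqrt(fit$cov[k, k]) else NA_real_
  ok <- ok && is.finite(se) && se > 0
  list(beta = beta, se = se, converged = ok)
}

#' Logistic association of one case/control set with the risk score
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, deviance tolerance 1e-8, at most 25 iterations) of case status
#' on the score plus covariates; Wald standard error from the observed
#' information and a two-sided normal p-value. Separation or
#' non-convergence yields `converged = FALSE` with estimates withheld; the
#' phenotype is still reported.
#'
#' @param set A `case_control_set`, or a 0/1 vector aligned to
#'   `grs$person_ids`.
#' @param grs A `grs_vector`.
#' @param covariates Optional covariate data frame (see
#'   [screen_covariates()]); aligned by `person_id` column if present.
#' @return One-row data frame of class `association_result`: `id`,
#'   `n_cases`, `n_controls`, `beta`, `se`, `or_point`, `ci_low`, `ci_high`,
#'   `p`, `converged`.
#' @export
fit_logistic <- function(set, grs, covariates = NULL) {
  if (inherits(set, "case_control_set")) {
    persons <- c(set$case_ids, set$control_ids)
    y <- rep(c(1, 0), c(set$n_cases, set$n_controls))
    id <- set$phecode
    idx <- match(persons, grs$person_ids)
    if (anyNA(idx)) stop_pwmr("fit_logistic: persons missing from the GRS",
                              class = "pwmr_validation_error")
  } else {
    y <- as.numeric(set)
    stopifnot(length(y) == length(grs$person_ids), all(y %in% c(0, 1)))
    idx <- seq_along(y)
    persons <- grs$person_ids
    id <- "phenotype"
  }
  Z <- covariate_design(covariates, grs$person_ids)[idx, , drop = FALSE]
  X <- cbind("(Intercept)" = 1, grs = grs$score[idx], Z)
  res <- fit_logistic_raw(y, X)
  association_result(id, n_cases = sum(y == 1), n_controls = sum(y == 0),
                     beta = res$beta, se = res$se, converged = res$converged)
}

association_result <- function(id, n_cases, n_controls, beta, se, converged) {
  if (converged) {
    orci <- or_from_beta(beta, se)
    p <- z_p(beta / se)
    p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  } else {
    beta <- se <- p <- NA_real_
    orci <- list(or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  }
  out <- data.frame(id = id, n_cases = n_cases, n_controls = n_controls,
                    beta = beta, se = se, or_point = orci$or_point,
                    ci_low = orci$ci_low, ci_high = orci$ci_high, p = p,
                    converged = converged)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up threshold
#'
#' Sort the m p-values ascending and find the largest k with
#' `p(k) <= k q / m`; every p-value at or below `p(k)` is a discovery and
#' `p(k)` is the reported significance threshold. With no discoveries the
#' threshold is 0 (below any valid p).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return List: `threshold`, `discoveries` (logical, same order as `p`).
#' @export
fdr_threshold <- function(p, q = 0.05) {
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  if (!length(k)) {
    return(list(threshold = 0, discoveries = rep(FALSE, m)))
  }
  thr <- ps[max(k)]
  list(threshold = thr, discoveries = p <= thr)
}

#' Phenome-wide association scan of a risk score
#'
#' Fits [fit_logistic()] for every eligible (unfiltered) phecode set and
#' applies the BH false-discovery-rate step-up over the converged fits.
#'
#' @param phenome A `phenome` from [build_phenome()].
#' @param grs A `grs_vector`.
#' @param covariates Optional covariate data frame.
#' @param q Target FDR (default 0.05).
#' @return List of class `phewas_report`: `results` (data frame, one row per
#'   eligible phecode), `fdr_q`, `significance_threshold` (largest p among
#'   discoveries), `discoveries` (character vector of phecodes).
#' @export
run_phewas <- function(phenome, grs, covariates = NULL, q = 0.05) {
  eligible <- Filter(function(s) !s$filtered, phenome$sets)
  if (!length(eligible)) {
    stop_pwmr("run_phewas: no phecode has at least %d cases", phenome$min_cases,
              class = "pwmr_phewas_error")
  }
  Z_all <- covariate_design(covariates, grs$person_ids)
  rows <- lapply(eligible, function(s) {
    idx <- match(c(s$case_ids, s$control_ids), grs$person_ids)
    if (anyNA(idx)) stop_pwmr("run_phewas: persons missing from the GRS",
                              class = "pwmr_validation_error")
    y <- rep(c(1, 0), c(s$n_cases, s$n_controls))
    X <- cbind("(Intercept)" = 1, grs = grs$score[idx], Z_all[idx, , drop = FALSE])
    res <- fit_logistic_raw(y, X)
    association_result(s$phecode, s$n_cases, s$n_controls,
                       res$beta, res$se, res$converged)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  conv <- results$converged
  thr <- 0
  disc <- character()
  if (any(conv)) {
    bh <- fdr_threshold(results$p[conv], q)
    thr <- bh$threshold
    disc <- results$id[conv][bh$discoveries]
  }
  if (any(!conv)) {
    warn_pwmr("run_phewas: %d non-converged fit(s) excluded from FDR", sum(!conv))
  }
  structure(list(results = results, fdr_q = q, significance_threshold = thr,
                 discoveries = disc),
            class = "phewas_report")
}

#' @export
print.phewas_report <- function(x, ...) {
  cat(sprintf("phewas_report: %d phenotypes tested, %d discoveries at q = %g (p <= %.3g)\n",
              nrow(x$results), length(x$discoveries), x$fdr_q,
              x$significance_threshold))
  invisible(x)
}

#' Write a PheWAS report to TSV in the standard table layout
#'
#' Columns: phecode, n_cases, n_controls, beta, SE, OR (95% CI), p-value,
#' discovery flag. Numeric columns carry 6 decimals; the OR column is the
#' 2-decimal display form.
#'
#' @param report A `phewas_report`.
#' @param path Output path.
#' @export
write_phewas_report <- function(report, path) {
  r <- report$results
  orci <- ifelse(r$converged,
                 sprintf("%.2f (%.2f-%.2f)", round2(r$or_point),
                         round2(r$ci_low), round2(r$ci_high)), "NA")
  out <- data.frame(phecode = r$id, n_cases = r$n_cases,
                    n_controls = r$n_controls,
                    beta = sprintf("%.6f", r$beta), se = sprintf("%.6f", r$se),
                    `OR (95% CI)` = orci,
                    p = sprintf("%.6g", r$p),
                    discovery = r$id %in% report$discoveries,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
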