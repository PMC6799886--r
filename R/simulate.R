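# Synthetic biobank generator. Emulates the statistical structure the
# analysis pipeline assumes: independent biallelic instrument variants, a
# continuous exposure (urate-like, mg/dL) with a fixed fraction of variance
# explained by the instruments, pleiotropic mediator traits fed by variant
# subsets, liability-threshold diseases emitting hierarchical ICD-10 codes,
# and an independent cohort's GWAS summary statistics for two-sample MR.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

MEDIATOR_NAMES <- c("obesity", "bp", "lipid", "glucose")

#' Trait-to-category map for pleiotropy classification
#'
#' The metabolic traits screened for instrument pleiotropy, grouped into the
#' four mediator categories: obesity (BMI, waist-to-hip ratio), blood
#' pressure (SBP, DBP), lipids (total, LDL and HDL cholesterol) and glucose
#' (fasting, 2-hour, glycoproteins).
#'
#' @return Named character vector mapping trait name to category.
#' @export
trait_groups <- function() {
  c(BMI = "obesity", WHR = "obesity",
    SBP = "bp", DBP = "bp",
    TC = "lipid", LDL = "lipid", HDL = "lipid",
    FG = "glucose", Glu2h = "glucose", GlycP = "glucose")
}

#' Build a validated simulation configuration
#'
#' @param n_individuals Cohort size.
#' @param variants Data frame `rsid`, `eaf`, `beta_urate` (per-allele effect
#'   on the exposure, mg/dL), plus logical flags `obesity`, `bp`, `lipid`,
#'   `glucose`, `renal` used by the pleiotropy machinery.
#' @param target_r2 Fraction of exposure variance explained by the variants
#'   jointly (default 0.07).
#' @param pleiotropy_map Data frame `rsid`, `mediator`, `gamma`: per-allele
#'   effect of a variant on a mediator trait.
#' @param mediators Data frame `name`, `noise_sd`.
#' @param diseases Data frame `icd10_code`, `prevalence`, `w_exposure` and one
#'   `w_<mediator>` column per mediator: liability weights on the
#'   standardized exposure/mediators.
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals, variants, target_r2 = 0.07,
                       pleiotropy_map, mediators, diseases, seed = 1L) {
  stopifnot(is_count(n_individuals))
  if (!(target_r2 > 0 && target_r2 < 1)) {
    stop_pwmr("sim config: target_r2 must lie in (0,1)", class = "pwmr_config_error")
  }
  if (any(variants$eaf <= 0 | variants$eaf >= 1)) {
    stop_pwmr("sim config: eafs must lie in (0,1)", class = "pwmr_config_error")
  }
  if (any(diseases$prevalence <= 0 | diseases$prevalence >= 1)) {
    stop_pwmr("sim config: prevalences must lie in (0,1)", class = "pwmr_config_error")
  }
  stopifnot(!anyDuplicated(variants$rsid),
            all(pleiotropy_map$mediator %in% mediators$name),
            all(pleiotropy_map$rsid %in% variants$rsid))
  w_cols <- c("w_exposure", paste0("w_", mediators$name))
  missing_w <- setdiff(w_cols, names(diseases))
  if (length(missing_w)) {
    stop_pwmr("sim config: diseases table lacks weight column(s) %s",
              paste(missing_w, collapse = ", "), class = "pwmr_config_error")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 variants = as.data.frame(variants),
                 target_r2 = target_r2,
                 pleiotropy_map = as.data.frame(pleiotropy_map),
                 mediators = as.data.frame(mediators),
                 diseases = as.data.frame(diseases),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' The packaged default simulation configuration
#'
#' 31 independent instrument variants jointly explaining about 7% of the
#' exposure variance. 14 loci are exposure-specific; the other 17 carry
#' pleiotropic effects on four mediator traits with overlapping category
#' membership (10 obesity, 10 blood pressure, 6 lipid, 3 glucose). Seven loci
#' are flagged as a renal-handling subset. Eleven liability-threshold
#' diseases emit 4-character ICD-10 codes: two gout-like codes driven by the
#' exposure itself, cardiometabolic codes driven only by mediators (no direct
#' exposure path, so any risk-score association with them is purely
#' pleiotropic), and two null codes.
#'
#' @param n_individuals Cohort size (default 50000).
#' @param seed Master seed stored in the config.
#' @return A [sim_config].
#' @export
default_sim_config <- function(n_individuals = 50000, seed = 1L) {
  rsid <- sprintf("rs%04d", 1:31)
  eaf <- c(0.77, 0.53, 0.31, 0.45, 0.62, 0.26, 0.70, 0.38, 0.55, 0.18,
           0.42, 0.66, 0.29, 0.50, 0.35, 0.58, 0.22, 0.47, 0.73, 0.40,
           0.61, 0.33, 0.52, 0.27, 0.68, 0.44, 0.57, 0.36, 0.49, 0.64, 0.30)
  # Two large-effect loci (transporter-like), the rest small; lipid-flagged
  # loci get moderately large exposure effects so their subscore retains
  # power on the exposure-driven disease.
  beta <- c(0.373, 0.217, 0.060, 0.055, 0.050, 0.048, 0.045, 0.058, 0.052, 0.047,
            0.044, 0.042, 0.055, 0.050,
            0.120, 0.100, 0.090, 0.100, 0.050, 0.048,
            0.046, 0.055, 0.052, 0.050, 0.085, 0.080,
            0.080, 0.075, 0.095, 0.052, 0.048)
  flags <- function(idx) seq_along(rsid) %in% idx
  variants <- data.frame(rsid = rsid, eaf = eaf, beta_urate = beta,
                         obesity = flags(15:24), bp = flags(22:31),
                         lipid = flags(c(15, 16, 17, 25, 26, 27)),
                         glucose = flags(c(18, 28, 29)),
                         renal = flags(1:7))
  med_of <- list(obesity = 15:24, bp = 22:31,
                 lipid = c(15, 16, 17, 25, 26, 27), glucose = c(18, 28, 29))
  pleio <- do.call(rbind, lapply(names(med_of), function(m) {
    data.frame(rsid = rsid[med_of[[m]]], mediator = m, gamma = 0.15)
  }))
  mediators <- data.frame(name = MEDIATOR_NAMES, noise_sd = 1)
  d <- function(code, prev, e = 0, o = 0, b = 0, l = 0, g = 0) {
    data.frame(icd10_code = code, prevalence = prev, w_exposure = e,
               w_obesity = o, w_bp = b, w_lipid = l, w_glucose = g)
  }
  diseases <- rbind(
    d("M10.0", 0.020, e = 1.5),             # gout, exposure-driven
    d("M10.9", 0.010, e = 1.2),             # gout unspecified
    d("I10",   0.100, b = 0.9),             # essential hypertension
    d("I21.0", 0.020, b = 0.4, l = 0.6),    # acute myocardial infarction
    d("I25.1", 0.030, l = 0.8),             # atherosclerotic heart disease
    d("I50.1", 0.015, b = 0.7),             # left ventricular failure
    d("E78.0", 0.050, l = 1.0),             # hypercholesterolemia
    d("E11.9", 0.040, g = 0.9),             # type 2 diabetes, glucose-mediated
    d("E66.9", 0.050, o = 1.0),             # obesity
    d("J45.9", 0.050),                      # asthma: null
    d("N39.0", 0.030))                      # urinary tract infection: null
  sim_config(n_individuals, variants, target_r2 = 0.07,
             pleiotropy_map = pleio, mediators = mediators,
             diseases = diseases, seed = seed)
}

#' Instrument weight table implied by a simulation config
#'
#' The "published" exposure GWAS weights for the simulated instrument set:
#' true per-allele effects with standard errors at a reference-study sample
#' size. Effect allele is the counted (ALT-like) allele.
#'
#' @param config A [sim_config].
#' @param n_ref Reference exposure-GWAS sample size used for the SEs.
#' @return A [variant_weights] data frame.
#' @export
config_weights <- function(config, n_ref = 110000) {
  v <- config$variants
  sd_exp <- exposure_sd(config)
  se <- sd_exp / sqrt(2 * v$eaf * (1 - v$eaf) * n_ref)
  variant_weights(data.frame(rsid = v$rsid, effect_allele = "A",
                             other_allele = "G", beta = v$beta_urate,
                             se = se, eaf = v$eaf))
}

# Exposure genetic variance under Hardy-Weinberg and the implied total SD.
genetic_variance <- function(config) {
  v <- config$variants
  sum(v$beta_urate^2 * 2 * v$eaf * (1 - v$eaf))
}

exposure_sd <- function(config) {
  sqrt(genetic_variance(config) / config$target_r2)
}

#' Simulate instrument genotypes
#'
#' Independent biallelic variants, dosage ~ Binomial(2, eaf); no LD.
#'
#' @param config A [sim_config].
#' @param seed Seed (default: config seed).
#' @return A [genotype_matrix].
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  v <- config$variants
  n <- config$n_individuals
  with_seed(seed, {
    dosage <- vapply(v$eaf, function(p) stats::rbinom(n, 2L, p), numeric(n))
    genotype_matrix(dosage, sprintf("P%06d", seq_len(n)), v$rsid)
  })
}

true_score <- function(genotypes, config) {
  idx <- match(config$variants$rsid, genotypes$variant_ids)
  drop(genotypes$dosage[, idx, drop = FALSE] %*% config$variants$beta_urate)
}

#' Simulate the trait table for a cohort
#'
#' The exposure is the true weighted allele score plus Gaussian noise scaled
#' so the score explains `target_r2` of the exposure variance. Each mediator
#' is the gamma-weighted dosage sum of its pleiotropic variants plus noise.
#' Covariates: sex, age, BMI (independent of the score) and assessment
#' center plus 5 principal-component-like scores, of which center and PC1
#' are given small correlations with the true score so covariate screening
#' has real signal.
#'
#' @param genotypes A [genotype_matrix] from [simulate_genotypes()].
#' @param config A [sim_config].
#' @param seed Seed (default: config seed + 1).
#' @return Data frame keyed by `person_id` with columns `exposure`, one per
#'   mediator, `sex`, `age`, `bmi`, `center`, `PC1`..`PC5`.
#' @export
simulate_traits <- function(genotypes, config, seed = config$seed + 1L) {
  n <- length(genotypes$person_ids)
  score <- true_score(genotypes, config)
  var_g <- stats::var(score)
  if (var_g <= 0) {
    stop_pwmr("simulate_traits: zero genetic variance, target_r2 unattainable",
              class = "pwmr_config_error")
  }
  noise_sd <- sqrt(var_g * (1 - config$target_r2) / config$target_r2)
  with_seed(seed, {
    exposure <- score + stats::rnorm(n, 0, noise_sd)
    med <- matrix(0, n, nrow(config$mediators),
                  dimnames = list(NULL, config$mediators$name))
    for (k in seq_len(nrow(config$mediators))) {
      m <- config$mediators$name[k]
      pm <- config$pleiotropy_map[config$pleiotropy_map$mediator == m, , drop = FALSE]
      if (nrow(pm)) {
        idx <- match(pm$rsid, genotypes$variant_ids)
        med[, k] <- drop(genotypes$dosage[, idx, drop = FALSE] %*% pm$gamma)
      }
      med[, k] <- med[, k] + stats::rnorm(n, 0, config$mediators$noise_sd[k])
    }
    score_std <- (score - mean(score)) / stats::sd(score)
    center_latent <- 0.08 * score_std + stats::rnorm(n)
    center <- cut(center_latent, breaks = stats::quantile(center_latent, c(0, 1/3, 2/3, 1)),
                  labels = c("C1", "C2", "C3"), include.lowest = TRUE)
    pcs <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
    pcs[, 1] <- pcs[, 1] + 0.06 * score_std
    out <- data.frame(person_id = genotypes$person_ids, exposure = exposure,
                      med,
                      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.54, 0.46)),
                      age = round(pmin(pmax(stats::rnorm(n, 56.87, 7.99), 40), 69)),
                      bmi = stats::rnorm(n, 27.4, 4.76),
                      center = as.character(center),
                      pcs, check.names = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate diagnosis records under a liability-threshold disease model
#'
#' Per disease: liability = weighted sum of the standardized exposure and
#' mediators plus standard normal noise; persons above the liability quantile
#' implied by the configured prevalence become cases and emit one hospital
#' record of the configured ICD-10 code (one record per prevalent case).
#'
#' @param traits Trait table from [simulate_traits()].
#' @param config A [sim_config].
#' @param hierarchy ICD-10 hierarchy table (see [read_icd_hierarchy()]);
#'   every configured code must resolve in it.
#' @param seed Seed (default: config seed + 2).
#' @return A `diagnosis_records` data frame.
#' @export
simulate_diagnoses <- function(traits, config,
                               hierarchy = pwmr_icd_hierarchy(),
                               seed = config$seed + 2L) {
  codes3 <- substr(normalize_icd_code(config$diseases$icd10_code), 1, 3)
  missing <- setdiff(codes3, hierarchy$code3)
  if (length(missing)) {
    stop_pwmr("simulate_diagnoses: disease code(s) %s absent from the ICD-10 hierarchy",
              paste(missing, collapse = ", "), class = "pwmr_config_error")
  }
  n <- nrow(traits)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  expo_std <- std(traits$exposure)
  med_std <- vapply(config$mediators$name, function(m) std(traits[[m]]),
                    numeric(n))
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(config$diseases)), function(i) {
      di <- config$diseases[i, ]
      liab <- di$w_exposure * expo_std +
        drop(med_std %*% as.numeric(di[paste0("w_", config$mediators$name)])) +
        stats::rnorm(n)
      liab <- (liab - mean(liab)) / stats::sd(liab)
      case <- liab > stats::qnorm(1 - di$prevalence)
      if (!any(case)) return(NULL)
      data.frame(person_id = traits$person_id[case], system = "ICD10",
                 code = normalize_icd_code(di$icd10_code), source = "hospital")
    })
    diagnosis_records(do.call(rbind, c(recs, list(NULL))) %||%
                        data.frame(person_id = character(), system = character(),
                                   code = character(), source = character()))
  })
}

#' Simulate a full synthetic cohort
#'
#' @param config A [sim_config].
#' @return List of class `cohort_data`: `genotypes`, `traits`, `diagnoses`
#'   (all sharing person ids), plus the `config`.
#' @export
simulate_cohort <- function(config = default_sim_config()) {
  genotypes <- simulate_genotypes(config)
  traits <- simulate_traits(genotypes, config)
  diagnoses <- simulate_diagnoses(traits, config)
  structure(list(genotypes = genotypes, traits = traits,
                 diagnoses = diagnoses, config = config),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data: %d persons, %d variants, %d diagnosis records\n",
              length(x$genotypes$person_ids), length(x$genotypes$variant_ids),
              nrow(x$diagnoses)))
  invisible(x)
}

#' Simulate two-sample MR summary statistics from an independent cohort
#'
#' Exposure-side effects are the config's true per-allele effects observed
#' with sampling noise at `n_exposure`; outcome-side effects are
#' `tau * beta_j + alpha_j` (causal path plus any direct pleiotropic effect
#' `alpha_j`) observed with noise at `n_outcome`. SEs follow the usual
#' 1/sqrt(2 p (1-p) n) scaling for a unit-variance continuous outcome.
#'
#' @param config A [sim_config].
#' @param n_outcome Outcome-cohort sample size.
#' @param tau True causal effect of the exposure on the outcome.
#' @param alpha Per-SNP direct (horizontal pleiotropy) effects on the
#'   outcome; scalar or vector, default 0.
#' @param n_exposure Exposure-cohort sample size.
#' @param outcome Outcome trait label.
#' @param seed Seed; defaults to an independent stream from the cohort's.
#' @return An [mr_summary_set].
#' @export
simulate_summary_stats <- function(config, n_outcome, tau, alpha = 0,
                                   n_exposure = 110000,
                                   outcome = "outcome",
                                   seed = config$seed + 1000L) {
  v <- config$variants
  alpha <- rep_len(alpha, nrow(v))
  info <- 2 * v$eaf * (1 - v$eaf)
  se_x <- exposure_sd(config) / sqrt(info * n_exposure)
  se_y <- 1 / sqrt(info * n_outcome)
  with_seed(seed, {
    bx <- stats::rnorm(nrow(v), v$beta_urate, se_x)
    by <- stats::rnorm(nrow(v), tau * v$beta_urate + alpha, se_y)
    mr_summary_set(data.frame(rsid = v$rsid, beta_exposure = bx,
                              se_exposure = se_x, beta_outcome = by,
                              se_outcome = se_y),
                   exposure = "exposure", outcome = outcome)
  })
}

#' Simulate the cross-trait p-value lookup for pleiotropy classification
#'
#' Emulates looking up each instrument locus in the metabolic-trait GWAS
#' consortia: a pleiotropic locus is reported with the p-value of its true
#' mediator association (noncentral at `n_ref`), on the first trait of its
#' category. As in published consortium supplements, associations that were
#' not reported are absent (`NA`); classification treats missing as
#' non-significant. With `report_all = TRUE`, null lookups are filled with
#' draws from the null distribution instead.
#'
#' @param config A [sim_config].
#' @param n_ref Reference GWAS sample size.
#' @param report_all If TRUE, also emit null-distributed p for non-associated
#'   pairs.
#' @param seed Seed.
#' @return Data frame: `rsid` plus one p-value column per trait in
#'   [trait_groups()].
#' @export
simulate_trait_pvalues <- function(config, n_ref = 100000, report_all = FALSE,
                                   seed = config$seed + 2000L) {
  v <- config$variants
  groups <- trait_groups()
  out <- data.frame(rsid = v$rsid)
  for (tr in names(groups)) out[[tr]] <- NA_real_
  with_seed(seed, {
    for (k in seq_len(nrow(config$pleiotropy_map))) {
      pm <- config$pleiotropy_map[k, ]
      i <- match(pm$rsid, v$rsid)
      trait <- names(groups)[groups == pm$mediator][1]
      ncp <- pm$gamma * sqrt(2 * v$eaf[i] * (1 - v$eaf[i]) * n_ref)
      z <- stats::rnorm(1, ncp, 1)
      out[[trait]][i] <- z_p(z)
    }
    if (report_all) {
      for (tr in names(groups)) {
        nulls <- is.na(out[[tr]])
        out[[tr]][nulls] <- z_p(stats::rnorm(sum(nulls)))
      }
    }
  })
  out
}

# ---- packaged reference tables ---------------------------------------------

pwmr_extdata <- function(file) {
  system.file("extdata", file, package = "pwmr", mustWork = TRUE)
}

#' Read an ICD-10 hierarchy edge list
#'
#' TSV columns `code3`, `block`, `chapter`: membership of each 3-character
#' code in its block (e.g. `I21` in `I20-I25`) and chapter.
#'
#' @param path TSV path; defaults to the packaged mini hierarchy.
#' @return Data frame with columns `code3`, `block`, `chapter`.
#' @export
read_icd_hierarchy <- function(path = pwmr_extdata("icd10_hierarchy_mini.tsv")) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  require_columns(df, c("code3", "block", "chapter"), "ICD-10 hierarchy")
  df$code3 <- normalize_icd_code(df$code3)
  df
}

#' The packaged mini ICD-10 hierarchy
#' @return Data frame with columns `code3`, `block`, `chapter`.
#' @export
pwmr_icd_hierarchy <- function() read_icd_hierarchy()

#' The packaged mini phecode map
#'
#' Covers every ICD-10 code the default synthetic generator can emit, plus a
#' few ICD-9 rows, with control-exclusion ranges in the style of the public
#' phecode map.
#'
#' @return A `phecode_map` data frame.
#' @export
pwmr_phecode_map <- function() read_phecode_map(pwmr_extdata("phecode_map_mini.csv"))
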