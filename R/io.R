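# Readers/writers for every external table the pipeline touches. All
# downstream modules consume only the validated objects built here. Formats
# are fixed (UTF-8, tab- or comma-separated as documented per function); no
# dialect sniffing, so a written file re-reads bit-identically.

# ---- code normalisation -----------------------------------------------------

#' Normalize an ICD diagnosis code
#'
#' Uppercases, trims whitespace and strips the dot, so `"i21.0"` becomes
#' `"I210"`. Hospital extracts vary in dot usage; every comparison in the
#' package is done on this normalized form.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @export
normalize_icd_code <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

icd_code_valid <- function(code, system) {
  ok <- rep(FALSE, length(code))
  icd10 <- system == "ICD10"
  ok[icd10] <- grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", code[icd10])
  icd9 <- system == "ICD9"
  ok[icd9] <- grepl("^[VE]?[0-9]{3,5}$", code[icd9])
  ok
}

phecode_valid <- function(phecode) {
  grepl("^[0-9]{1,4}(\\.[0-9]{1,2})?$", phecode)
}

reject_rows <- function(bad, what, reason) {
  if (any(bad)) {
    stop_pwmr("%s: row%s %s %s", what,
              if (sum(bad) > 1) "s" else "",
              paste(which(bad), collapse = ", "), reason,
              class = "pwmr_validation_error")
  }
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_pwmr("%s: missing column%s %s", what,
              if (length(missing) > 1) "s" else "",
              paste(missing, collapse = ", "),
              class = "pwmr_format_error")
  }
}

# ---- variant weights --------------------------------------------------------

#' Construct a validated variant-weight table
#'
#' One row per instrument variant: effect and other allele, per-allele effect
#' (beta) on the exposure in its measurement units (mg/dL urate for the
#' packaged instrument set), its standard error and the effect-allele
#' frequency.
#'
#' @param df Data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `eaf`.
#' @return The validated data frame with class `variant_weights`.
#' @export
variant_weights <- function(df) {
  require_columns(df, c("rsid", "effect_allele", "other_allele", "beta", "se", "eaf"),
                  "variant weights")
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "eaf")) df[[col]] <- as.numeric(df[[col]])
  reject_rows(!df$effect_allele %in% VALID_BASES |
              !df$other_allele %in% VALID_BASES, "variant weights",
              "have an allele outside A/C/G/T")
  reject_rows(df$effect_allele == df$other_allele, "variant weights",
              "have identical effect and other allele")
  reject_rows(!is.finite(df$beta), "variant weights", "have non-finite beta")
  reject_rows(!is.finite(df$se) | df$se <= 0, "variant weights",
              "have se <= 0 or missing")
  reject_rows(!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1,
              "variant weights", "have eaf outside (0,1)")
  if (anyDuplicated(df$rsid)) {
    stop_pwmr("variant weights: duplicate rsid %s",
              paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "),
              class = "pwmr_validation_error")
  }
  rownames(df) <- NULL
  class(df) <- c("variant_weights", "data.frame")
  df
}

#' Read instrument variant weights from TSV
#'
#' @param path TSV file with header
#'   `rsid  effect_allele  other_allele  beta  se  eaf`.
#' @return A [variant_weights] data frame.
#' @export
read_variant_weights <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  variant_weights(df)
}

#' Write instrument variant weights to TSV
#'
#' Full `%.17g` precision so write -> read round-trips bit-identically.
#'
#' @param weights A [variant_weights] data frame.
#' @param path Output path.
#' @export
write_variant_weights <- function(weights, path) {
  out <- as.data.frame(weights)
  for (col in c("beta", "se", "eaf")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- diagnoses --------------------------------------------------------------

#' Read diagnosis records from long TSV
#'
#' Columns `person_id`, `system` (ICD9/ICD10), `code`, `source` (hospital,
#' cancer or death registry). Codes are normalized (dot stripped, uppercased);
#' duplicate rows are retained, since each row is one coded episode.
#'
#' @param path TSV path.
#' @return Data frame of class `diagnosis_records`.
#' @export
read_diagnoses <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  diagnosis_records(df)
}

#' Construct validated diagnosis records
#'
#' @param df Data frame with columns `person_id`, `system`, `code`, `source`.
#' @return The normalized data frame with class `diagnosis_records`.
#' @export
diagnosis_records <- function(df) {
  require_columns(df, c("person_id", "system", "code", "source"), "diagnoses")
  if (nrow(df) == 0) {
    warn_pwmr("diagnoses: empty file, no records read")
    df <- data.frame(person_id = character(), system = character(),
                     code = character(), source = character())
    class(df) <- c("diagnosis_records", "data.frame")
    return(df)
  }
  df$person_id <- as.character(df$person_id)
  df$system <- toupper(gsub("[^A-Za-z0-9]", "", df$system))
  bad_sys <- !df$system %in% c("ICD9", "ICD10")
  if (any(bad_sys)) {
    stop_pwmr("diagnoses: unknown code system '%s' (row %d)",
              df$system[which(bad_sys)[1]], which(bad_sys)[1],
              class = "pwmr_format_error")
  }
  df$code <- normalize_icd_code(df$code)
  df$source <- tolower(as.character(df$source))
  reject_rows(!df$source %in% c("hospital", "cancer", "death"), "diagnoses",
              "have a source other than hospital/cancer/death")
  reject_rows(!icd_code_valid(df$code, df$system), "diagnoses",
              "have a code not matching the declared system's syntax")
  rownames(df) <- NULL
  class(df) <- c("diagnosis_records", "data.frame")
  df
}

#' Write diagnosis records to long TSV
#' @param records A `diagnosis_records` data frame.
#' @param path Output path.
#' @export
write_diagnoses <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- phecode map ------------------------------------------------------------

#' Read a phecode map from CSV
#'
#' Dialect of the public phecodes-to-ICD map: columns `phecode`, `icd`,
#' `system`, `exclude_low`, `exclude_high`. `icd` is a normalized code or
#' prefix; the exclusion bounds delimit the phecode range whose carriers are
#' removed from this phecode's control pool (empty = no exclusion).
#'
#' @param path CSV path.
#' @return Data frame of class `phecode_map`.
#' @export
read_phecode_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  phecode_map(df)
}

#' Construct a validated phecode map
#' @param df Data frame with columns `phecode`, `icd`, `system`,
#'   `exclude_low`, `exclude_high`.
#' @return Validated data frame with class `phecode_map`.
#' @export
phecode_map <- function(df) {
  require_columns(df, c("phecode", "icd", "system", "exclude_low", "exclude_high"),
                  "phecode map")
  df$phecode <- trimws(as.character(df$phecode))
  df$icd <- normalize_icd_code(df$icd)
  df$system <- toupper(gsub("[^A-Za-z0-9]", "", df$system))
  reject_rows(!phecode_valid(df$phecode), "phecode map",
              "have a non-numeric phecode")
  reject_rows(!df$system %in% c("ICD9", "ICD10"), "phecode map",
              "have an unknown code system")
  df$exclude_low <- trimws(df$exclude_low)
  df$exclude_high <- trimws(df$exclude_high)
  has_range <- nzchar(df$exclude_low) | nzchar(df$exclude_high)
  reject_rows(has_range & (!nzchar(df$exclude_low) | !nzchar(df$exclude_high)),
              "phecode map", "have a half-open exclusion range")
  reject_rows(has_range & (!phecode_valid(df$exclude_low) |
                           !phecode_valid(df$exclude_high)), "phecode map",
              "have non-numeric exclusion bounds")
  lo <- suppressWarnings(as.numeric(df$exclude_low))
  hi <- suppressWarnings(as.numeric(df$exclude_high))
  reject_rows(has_range & (lo > hi), "phecode map",
              "have exclusion bounds out of order")
  key <- paste(df$system, df$icd)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conflict <- tapply(df$phecode[dup], key[dup], function(p) length(unique(p)) > 1)
    if (any(conflict)) {
      bad_key <- names(conflict)[conflict][1]
      rows <- which(key == bad_key)
      stop_pwmr("phecode map: code %s maps to conflicting phecodes %s (rows %s)",
                bad_key, paste(unique(df$phecode[rows]), collapse = " vs "),
                paste(rows, collapse = ", "),
                class = "pwmr_validation_error")
    }
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("phecode_map", "data.frame")
  df
}

#' Write a phecode map to CSV
#' @param map A `phecode_map` data frame.
#' @param path Output path.
#' @export
write_phecode_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- genotypes --------------------------------------------------------------

#' Construct a genotype dosage matrix
#'
#' Individuals by variants, dosages in \[0, 2\] with `NA` for missing calls
#' (never 0, which is a valid dosage).
#'
#' @param dosage Numeric matrix, rows = persons, columns = variants.
#' @param person_ids Character vector of unique person ids (row names).
#' @param variant_ids Character vector of variant rsids (column names).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, person_ids, variant_ids) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != length(person_ids) || ncol(dosage) != length(variant_ids)) {
    stop_pwmr("genotype matrix: dimensions (%d x %d) do not match %d persons x %d variants",
              nrow(dosage), ncol(dosage), length(person_ids), length(variant_ids),
              class = "pwmr_validation_error")
  }
  person_ids <- as.character(person_ids)
  if (anyDuplicated(person_ids)) {
    stop_pwmr("genotype matrix: duplicate person ids",
              class = "pwmr_validation_error")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stop_pwmr("genotype matrix: dosages outside [0, 2]",
              class = "pwmr_validation_error")
  }
  dimnames(dosage) <- list(person_ids, as.character(variant_ids))
  structure(list(dosage = dosage, person_ids = person_ids,
                 variant_ids = as.character(variant_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d persons x %d variants (%.2f%% missing)\n",
              length(x$person_ids), length(x$variant_ids),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read a wide dosage matrix from TSV
#'
#' First column `person_id`, remaining columns one per variant rsid; values
#' are dosages in \[0, 2\], missing encoded as `NA`.
#'
#' @param path TSV path.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  require_columns(df, "person_id", "genotypes")
  ids <- as.character(df$person_id)
  mat <- as.matrix(df[, setdiff(names(df), "person_id"), drop = FALSE])
  genotype_matrix(mat, ids, colnames(mat))
}

#' Write a dosage matrix to wide TSV
#' @param genotypes A [genotype_matrix].
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(person_id = genotypes$person_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(genotypes$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a minimal VCF (GT field only)
#'
#' Hard-called diploid genotypes: the dosage is the ALT-allele count in the
#' GT subfield; half-missing or missing calls become `NA`. The counted allele
#' is ALT. Only the GT subfield is interpreted.
#'
#' @param path VCF path (plain text).
#' @return A [genotype_matrix] with an attribute `alleles` (data frame of
#'   rsid, counted ALT allele, other REF allele).
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^##", lines)]
  if (!length(lines) || !grepl("^#CHROM", lines[1])) {
    stop_pwmr("VCF: missing #CHROM header line", class = "pwmr_format_error")
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT")
  samples <- setdiff(header, fixed_cols)
  body <- lines[-1]
  rows <- strsplit(body, "\t", fixed = TRUE)
  n_var <- length(rows)
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = n_var)
  ids <- character(n_var)
  ref <- character(n_var)
  alt <- character(n_var)
  gt_count <- function(field) {
    gt <- strsplit(field, ":", fixed = TRUE)[[1]][1]
    alleles <- strsplit(gt, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  for (i in seq_len(n_var)) {
    row <- rows[[i]]
    ids[i] <- row[match("ID", header)]
    ref[i] <- row[match("REF", header)]
    alt[i] <- row[match("ALT", header)]
    calls <- row[match(samples, header)]
    dosage[, i] <- vapply(calls, gt_count, numeric(1))
  }
  gm <- genotype_matrix(dosage, samples, ids)
  attr(gm, "alleles") <- data.frame(rsid = ids, counted_allele = alt,
                                    other_allele = ref)
  gm
}

# ---- GWAS summary statistics ------------------------------------------------

#' Construct validated GWAS summary-statistic records
#'
#' @param df Data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `eaf` (may be NA), `trait`.
#' @return Validated data frame with class `summary_stats`.
#' @export
summary_stats <- function(df) {
  require_columns(df, c("rsid", "effect_allele", "other_allele", "beta", "se", "trait"),
                  "summary stats")
  if (is.null(df$eaf)) df$eaf <- NA_real_
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "eaf")) df[[col]] <- as.numeric(df[[col]])
  df$trait <- as.character(df$trait)
  reject_rows(!df$effect_allele %in% VALID_BASES |
              !df$other_allele %in% VALID_BASES, "summary stats",
              "have an allele outside A/C/G/T")
  reject_rows(!is.finite(df$beta), "summary stats", "have non-finite beta")
  reject_rows(!is.finite(df$se) | df$se <= 0, "summary stats",
              "have se <= 0 or missing")
  reject_rows(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "summary stats",
              "have eaf outside (0,1)")
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Read GWAS summary statistics from TSV
#' @param path TSV with header rsid/effect_allele/other_allele/beta/se/eaf/trait.
#' @return A [summary_stats] data frame.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  summary_stats(df)
}

#' Write GWAS summary statistics to TSV
#' @param stats A [summary_stats] data frame.
#' @param path Output path.
#' @export
write_summary_stats <- function(stats, path) {
  out <- as.data.frame(stats)
  for (col in c("beta", "se", "eaf")) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
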