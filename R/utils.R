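#' @keywords internal
#' @useDynLib pwmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

VALID_BASES <- c("A", "C", "G", "T")

stop_pwmr <- function(fmt, ..., class = "pwmr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "pwmr_error")))
}

warn_pwmr <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Derive independent sub-stream seeds from one master seed
#'
#' Stage-level reproducibility: the pipeline fans a single seed out to named
#' per-stage seeds so each stage can be rerun in isolation with the same
#' random stream it saw inside the full run. Seeds stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param names Character vector of sub-stream names.
#' @return Named integer vector of seeds, one per name.
#' @export
seed_streams <- function(seed, names) {
  stopifnot(is_count(seed) || seed == 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, length(names))
  names(out) <- names
  out
}

# Round to 2 decimals for report display; full precision kept elsewhere.
round2 <- function(x) round(x, 2)

# Normal two-sided p from a z statistic.
z_p <- function(z) 2 * stats::pnorm(-abs(z))
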