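# Independent oracles and fixture builders shared across the suite.

# Reference maximum-likelihood logistic fit: stats::glm, an implementation
# independent of the package's IRLS core.
oracle_logistic <- function(y, x, covars = NULL) {
  df <- data.frame(y = y, x = x)
  if (!is.null(covars)) df <- cbind(df, covars)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  list(beta = unname(stats::coef(fit)["x"]),
       se = unname(summary(fit)$coefficients["x", "Std. Error"]))
}

# Build a pheno_tree directly from a named parent vector (NA marks the root).
make_tree <- function(parent) {
  nodes <- names(parent)
  root <- nodes[is.na(parent)]
  children <- split(nodes[!is.na(parent)], parent[!is.na(parent)])
  structure(list(nodes = nodes, parent = parent, children = children,
                 root = root), class = "pheno_tree")
}

# Random rooted tree on n nodes: node i's parent is uniform among 1..i-1.
random_tree <- function(n_nodes) {
  nodes <- paste0("n", seq_len(n_nodes))
  parent <- c(NA_character_,
              if (n_nodes > 1) nodes[vapply(2:n_nodes, function(i)
                sample.int(i - 1, 1), integer(1))])
  names(parent) <- nodes
  make_tree(parent)
}

# Exhaustive-enumeration posterior marginals for the coefficient-tree model:
# sums the joint probability over every grid-state assignment. Tractable for
# small trees; completely independent of the message-passing code.
enum_posteriors <- function(tree, summaries, grid) {
  b <- grid$values
  K <- length(b)
  rho <- ifelse(b == 0, 1 - grid$prior_nonzero,
                grid$prior_nonzero / (K - 1))
  theta <- grid$switch_prob
  leaves <- setdiff(tree$nodes, names(tree$children))
  lik <- matrix(1, length(tree$nodes), K, dimnames = list(tree$nodes, NULL))
  for (v in leaves) {
    i <- match(v, summaries$node)
    if (!is.na(i) && isTRUE(summaries$informative[i])) {
      lik[v, ] <- stats::dnorm(summaries$b_hat[i], b, summaries$se_hat[i])
    }
  }
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), length(tree$nodes))))
  colnames(states) <- tree$nodes
  p <- rho[states[, tree$root]]
  for (v in setdiff(tree$nodes, tree$root)) {
    sv <- states[, v]
    sp <- states[, tree$parent[[v]]]
    p <- p * ((1 - theta) * (sv == sp) + theta * rho[sv])
  }
  for (v in tree$nodes) p <- p * lik[v, ][states[, v]]
  post <- vapply(tree$nodes, function(v)
    vapply(seq_len(K), function(k) sum(p[states[, v] == k]), numeric(1)),
    numeric(K))
  t(post) / sum(p)
}

# Flat (uninformative) summaries for every node of a tree.
flat_summaries <- function(tree) {
  data.frame(node = tree$nodes, b_hat = NA_real_, se_hat = NA_real_,
             n_cases = 0L, informative = FALSE)
}

# Random leaf summaries: roughly half the leaves informative by default.
random_summaries <- function(tree, p_informative = 0.8) {
  leaves <- setdiff(tree$nodes, names(tree$children))
  s <- flat_summaries(tree)
  for (v in leaves) {
    if (stats::runif(1) < p_informative) {
      i <- match(v, s$node)
      s$b_hat[i] <- stats::rnorm(1)
      s$se_hat[i] <- stats::runif(1, 0.2, 1)
      s$informative[i] <- TRUE
    }
  }
  s
}

# Small hand-constructed instrument table.
toy_weights <- function(n = 4) {
  variant_weights(data.frame(
    rsid = paste0("rs", seq_len(n)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C"), length.out = n),
    beta = seq(0.1, by = 0.05, length.out = n),
    se = rep(0.01, n),
    eaf = seq(0.2, 0.8, length.out = n)))
}

# Cohort cache: the packaged default configuration is expensive at full
# size, so tests share one realization per (n, seed).
.pwmr_cache <- new.env(parent = emptyenv())

test_cohort <- function(n = 50000, seed = 1) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.pwmr_cache[[key]])) {
    .pwmr_cache[[key]] <- simulate_cohort(default_sim_config(n_individuals = n,
                                                             seed = seed))
  }
  .pwmr_cache[[key]]
}

# Cohort plus score, screened covariates and phenome, cached likewise.
test_bundle <- function(n = 50000, seed = 1) {
  key <- sprintf("bundle_%d_%d", n, seed)
  if (is.null(.pwmr_cache[[key]])) {
    cohort <- test_cohort(n, seed)
    grs <- compute_grs(cohort$genotypes, config_weights(cohort$config))
    candidates <- cohort$traits[c("person_id", "sex", "age", "bmi", "center",
                                  paste0("PC", 1:5))]
    selected <- screen_covariates(grs, candidates)
    assignments <- map_to_phecodes(cohort$diagnoses, pwmr_phecode_map())
    phenome <- build_phenome(assignments, pwmr_phecode_map(),
                             cohort$genotypes$person_ids)
    .pwmr_cache[[key]] <- list(cohort = cohort, grs = grs,
                               covars = candidates[c("person_id", selected)],
                               selected = selected,
                               assignments = assignments, phenome = phenome)
  }
  .pwmr_cache[[key]]
}

# Phecodes of the default generator's disease alphabet, for readability.
GOUT_PHECODE <- "274.1"
HYPERTENSION_PHECODE <- "401.1"
HYPERCHOL_PHECODE <- "272.11"
OBESITY_PHECODE <- "278.1"
T2D_PHECODE <- "250.2"
IHD_PHECODE <- "411.8"
NULL_PHECODES <- c("495", "599")
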