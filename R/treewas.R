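# Bayesian tree-structured association scan. A discretized genetic
# coefficient evolves down the ICD-10 classification tree under a Markov
# process: the root state is 0 with probability 1 - pi, otherwise uniform on
# the nonzero grid; each child copies its parent's state with probability
# 1 - theta and otherwise redraws from the root prior (which makes the
# marginal prior identical at every depth). A Gaussian working likelihood
# N(b_hat | b, se_hat^2) attaches at informative leaves only -- internal
# case sets are unions of their descendants', so attaching likelihood there
# would count the same persons twice. Exact per-node marginal posteriors
# come from upward/downward sum-product passes in log space.

#' Construct the discretized coefficient grid and Markov prior
#'
#' @param values Strictly increasing grid of coefficient values containing
#'   exactly one 0.
#' @param prior_nonzero Prior probability pi that a coefficient drawn from
#'   the root prior is nonzero (default 0.001).
#' @param switch_prob Probability theta that a child redraws its state from
#'   the root prior instead of copying its parent (default 1/3).
#' @return List of class `coefficient_grid`.
#' @export
coefficient_grid <- function(values, prior_nonzero = 0.001, switch_prob = 1/3) {
  values <- as.numeric(values)
  if (sum(values == 0) != 1) {
    stop_pwmr("coefficient grid: values must contain exactly one 0",
              class = "pwmr_config_error")
  }
  if (is.unsorted(values, strictly = TRUE)) {
    stop_pwmr("coefficient grid: values must be strictly increasing",
              class = "pwmr_config_error")
  }
  if (!(prior_nonzero > 0 && prior_nonzero < 1) ||
      !(switch_prob > 0 && switch_prob < 1)) {
    stop_pwmr("coefficient grid: pi and theta must lie in (0,1)",
              class = "pwmr_config_error")
  }
  structure(list(values = values, prior_nonzero = prior_nonzero,
                 switch_prob = switch_prob),
            class = "coefficient_grid")
}

#' Default coefficient grid from leaf summaries
#'
#' 0 plus `size` points equally spaced over +/- 4 times the median
#' informative-leaf standard error scaled by the square root of the leaf
#' count -- wide enough to cover any plausible pooled effect while keeping
#' per-leaf resolution.
#'
#' @param summaries Node summaries from [node_summaries()].
#' @param size Number of nonzero grid points (default 20).
#' @inheritParams coefficient_grid
#' @return A [coefficient_grid].
#' @export
default_grid <- function(summaries, size = 20, prior_nonzero = 0.001,
                         switch_prob = 1/3) {
  se <- summaries$se_hat[summaries$informative]
  if (!length(se)) {
    stop_pwmr("default_grid: no informative leaf summaries",
              class = "pwmr_config_error")
  }
  half_width <- 4 * stats::median(se) * sqrt(length(se))
  pts <- seq(-half_width, half_width, length.out = size)
  coefficient_grid(sort(unique(c(0, pts))), prior_nonzero, switch_prob)
}

#' Per-node association summaries for the tree scan
#'
#' At every tree node with at least `min_cases` cases the case indicator is
#' regressed on the score (plus covariates) with the same logistic machinery
#' as the phenome scan, yielding the Gaussian working likelihood
#' (b_hat, se_hat). Nodes below the case floor, without variation, or with
#' non-converged fits get an uninformative (flat-likelihood) summary.
#'
#' @param tree A `pheno_tree` with case indicators ([propagate_cases()]).
#' @param grs A `grs_vector`.
#' @param covariates Optional covariate data frame.
#' @param min_cases Minimum case count for an informative node (default 20).
#' @return Data frame: `node`, `b_hat`, `se_hat`, `n_cases`, `informative`.
#' @export
node_summaries <- function(tree, grs, covariates = NULL, min_cases = 20) {
  if (is.null(tree$case_ids)) {
    stop_pwmr("node_summaries: tree has no case indicators; run propagate_cases()",
              class = "pwmr_validation_error")
  }
  Z_all <- covariate_design(covariates, grs$person_ids)
  n <- length(grs$person_ids)
  rows <- lapply(tree$nodes, function(v) {
    cases <- tree$case_ids[[v]]
    nc <- length(cases)
    if (nc < min_cases || nc > n - min_cases) {
      return(data.frame(node = v, b_hat = NA_real_, se_hat = NA_real_,
                        n_cases = nc, informative = FALSE))
    }
    y <- as.numeric(grs$person_ids %in% cases)
    X <- cbind("(Intercept)" = 1, grs = grs$score, Z_all)
    res <- fit_logistic_raw(y, X)
    data.frame(node = v, b_hat = res$beta, se_hat = res$se, n_cases = nc,
               informative = res$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

tree_depth_order <- function(tree) {
  depth <- stats::setNames(rep(NA_real_, length(tree$nodes)), tree$nodes)
  depth[tree$root] <- 0
  frontier <- tree$root
  while (length(frontier)) {
    kids <- unlist(tree$children[frontier], use.names = FALSE)
    depth[kids] <- depth[frontier[match(tree$parent[kids], frontier)]] + 1
    frontier <- kids
  }
  if (anyNA(depth)) {
    stop_pwmr("tree_posteriors: input graph is not a rooted tree (cycle or orphan)",
              class = "pwmr_validation_error")
  }
  names(sort(depth))
}

#' Exact marginal posteriors on the coefficient tree
#'
#' Upward (collect) then downward (distribute) sum-product message passing
#' in log space, with the Gaussian working likelihood attached at
#' informative leaf nodes only. Per node: the marginal posterior over grid
#' states, the posterior probability of a nonzero coefficient, the MAP
#' state, and the central 95% credible interval of the renormalized nonzero
#' posterior mass.
#'
#' @param tree A `pheno_tree`.
#' @param summaries Node summaries from [node_summaries()].
#' @param grid A [coefficient_grid].
#' @return Data frame of class `treewas_result`: `node`, `n_cases`,
#'   `pp_nonzero`, `map_estimate`, `ci_low`, `ci_high`; the full posterior
#'   matrix (nodes x states) is attached as attribute `posterior`.
#' @export
tree_posteriors <- function(tree, summaries, grid) {
  stopifnot(inherits(grid, "coefficient_grid"))
  b <- grid$values
  K <- length(b)
  zero <- which(b == 0)
  pi0 <- grid$prior_nonzero
  theta <- grid$switch_prob
  log_rho <- log(ifelse(b == 0, 1 - pi0, pi0 / (K - 1)))
  # Transition matrix T[s_parent, s_child].
  Tm <- matrix(rep(theta * exp(log_rho), each = K), K, K)
  diag(Tm) <- diag(Tm) + (1 - theta)
  log_T <- log(Tm)

  ord <- tree_depth_order(tree)          # root first
  leaves <- setdiff(tree$nodes, names(tree$children))
  s <- summaries[match(tree$nodes, summaries$node), ]
  log_lik <- matrix(0, length(tree$nodes), K,
                    dimnames = list(tree$nodes, NULL))
  for (v in leaves) {
    i <- match(v, s$node)
    if (isTRUE(s$informative[i])) {
      log_lik[v, ] <- stats::dnorm(s$b_hat[i], b, s$se_hat[i], log = TRUE)
    }
  }

  # Upward: message from each node to its parent.
  up <- matrix(0, length(tree$nodes), K, dimnames = list(tree$nodes, NULL))
  for (v in rev(ord)) {
    kids <- tree$children[[v]] %||% character()
    phi <- log_lik[v, ] + if (length(kids)) colSums(up[kids, , drop = FALSE]) else 0
    if (v != tree$root) {
      up[v, ] <- apply(log_T + rep(phi, each = K), 1, log_sum_exp)
    } else {
      up[v, ] <- phi   # stored as the root's collected evidence
    }
  }

  # Downward: prior-side message d_v(s_v); at the root it is the root prior.
  down <- matrix(0, length(tree$nodes), K, dimnames = list(tree$nodes, NULL))
  down[tree$root, ] <- log_rho
  for (v in ord) {
    kids <- tree$children[[v]] %||% character()
    if (!length(kids)) next
    kid_sum <- colSums(up[kids, , drop = FALSE])
    base_v <- down[v, ] + log_lik[v, ] + kid_sum
    for (c in kids) {
      q <- base_v - up[c, ]   # evidence at v excluding c's subtree
      down[c, ] <- apply(log_T + rep(q, times = K), 2, log_sum_exp)
    }
  }

  post <- matrix(NA_real_, length(tree$nodes), K,
                 dimnames = list(tree$nodes, NULL))
  for (v in tree$nodes) {
    kids <- tree$children[[v]] %||% character()
    lp <- down[v, ] + log_lik[v, ] +
      if (length(kids)) colSums(up[kids, , drop = FALSE]) else 0
    post[v, ] <- exp(lp - log_sum_exp(lp))
  }

  res <- lapply(tree$nodes, function(v) {
    pv <- post[v, ]
    pp <- 1 - pv[zero]
    # MAP and credible interval are conditional on a nonzero coefficient,
    # i.e. computed on the renormalized nonzero posterior mass, so the MAP
    # always lies inside its own interval.
    nz <- pv[-zero] / sum(pv[-zero])
    bnz <- b[-zero]
    map <- bnz[which.max(nz)]
    cum <- cumsum(nz)
    ci_low <- bnz[which(cum >= 0.025)[1]]
    ci_high <- bnz[which(cum >= 0.975)[1]]
    data.frame(node = v, n_cases = s$n_cases[match(v, s$node)],
               pp_nonzero = pp, map_estimate = map,
               ci_low = ci_low, ci_high = ci_high)
  })
  out <- do.call(rbind, res)
  out <- out[match(ord, out$node), ]
  rownames(out) <- NULL
  attr(out, "posterior") <- post
  class(out) <- c("treewas_result", "data.frame")
  out
}

#' Report tree nodes with high posterior probability of association
#'
#' @param results A `treewas_result`.
#' @param pp_threshold Posterior-probability cutoff (default 0.95).
#' @return The rows with `pp_nonzero >= pp_threshold`, in tree order.
#' @export
report_associated <- function(results, pp_threshold = 0.95) {
  out <- results[results$pp_nonzero >= pp_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full tree-structured scan
#'
#' Convenience wrapper: per-node summaries, default grid, exact posteriors.
#'
#' @inheritParams node_summaries
#' @param grid Optional [coefficient_grid]; default built by [default_grid()].
#' @param prior_nonzero,switch_prob Passed to [default_grid()] when `grid`
#'   is NULL.
#' @param grid_size Nonzero grid points for the default grid.
#' @return A `treewas_result`.
#' @export
run_treewas <- function(tree, grs, covariates = NULL, min_cases = 20,
                        grid = NULL, prior_nonzero = 0.001, switch_prob = 1/3,
                        grid_size = 20) {
  summaries <- node_summaries(tree, grs, covariates, min_cases)
  if (is.null(grid)) {
    leaf <- summaries[summaries$node %in% setdiff(tree$nodes, names(tree$children)), ]
    grid <- default_grid(leaf, size = grid_size, prior_nonzero = prior_nonzero,
                         switch_prob = switch_prob)
  }
  tree_posteriors(tree, summaries, grid)
}

#' Write tree-scan results to TSV (node, n_cases, PP, MAP, 95% CrI)
#' @param results A `treewas_result`.
#' @param path Output path.
#' @export
write_treewas_result <- function(results, path) {
  out <- data.frame(node = results$node, n_cases = results$n_cases,
                    pp_nonzero = sprintf("%.6f", results$pp_nonzero),
                    map = sprintf("%.6f", results$map_estimate),
                    ci_low = sprintf("%.6f", results$ci_low),
                    ci_high = sprintf("%.6f", results$ci_high))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
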