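grid5 <- coefficient_grid(c(-0.4, -0.2, 0, 0.2, 0.4),
                          prior_nonzero = 0.1, switch_prob = 1/3)

test_that("message-passing marginals equal exhaustive enumeration (3-node chain)", {
  tree <- make_tree(c(a = NA, b = "a", c = "b"))
  s <- data.frame(node = c("a", "b", "c"),
                  b_hat = c(NA, NA, 0.25), se_hat = c(NA, NA, 0.1),
                  n_cases = 0L, informative = c(FALSE, FALSE, TRUE))
  res <- tree_posteriors(tree, s, grid5)
  post <- attr(res, "posterior")
  ref <- enum_posteriors(tree, s, grid5)
  expect_equal(post[tree$nodes, ], ref[tree$nodes, ], tolerance = 1e-10)
  expect_equal(unname(rowSums(post)), rep(1, 3), tolerance = 1e-10)
})

test_that("message passing equals enumeration on random trees (property)", {
  set.seed(314)
  for (rep in 1:40) {
    tree <- random_tree(sample(2:6, 1))
    K <- sample(3:7, 1)
    vals <- sort(c(0, runif(K - 1, -1, 1)))
    grid <- coefficient_grid(vals, prior_nonzero = runif(1, 0.01, 0.5),
                             switch_prob = runif(1, 0.05, 0.9))
    s <- random_summaries(tree)
    res <- tree_posteriors(tree, s, grid)
    post <- attr(res, "posterior")
    ref <- enum_posteriors(tree, s, grid)
    expect_equal(post[tree$nodes, ], ref[tree$nodes, ], tolerance = 1e-10)
    expect_equal(unname(rowSums(post)), rep(1, length(tree$nodes)),
                 tolerance = 1e-10)
  }
})

test_that("switch probability near 0 pools all nodes into one posterior", {
  tree <- make_tree(c(r = NA, l1 = "r", l2 = "r", l3 = "r"))
  s <- data.frame(node = tree$nodes,
                  b_hat = c(NA, 0.3, 0.25, 0.35),
                  se_hat = c(NA, 0.1, 0.15, 0.1),
                  n_cases = 0L, informative = c(FALSE, TRUE, TRUE, TRUE))
  grid <- coefficient_grid(grid5$values, prior_nonzero = 0.1,
                           switch_prob = 1e-9)
  post <- attr(tree_posteriors(tree, s, grid), "posterior")
  b <- grid$values
  rho <- ifelse(b == 0, 0.9, 0.1 / 4)
  pooled <- rho
  for (i in 2:4) pooled <- pooled * dnorm(s$b_hat[i], b, s$se_hat[i])
  pooled <- pooled / sum(pooled)
  for (v in tree$nodes) expect_equal(unname(post[v, ]), pooled, tolerance = 1e-6)
})

test_that("switch probability near 1 decouples leaves into standalone posteriors", {
  tree <- make_tree(c(r = NA, l1 = "r", l2 = "r", l3 = "r"))
  s <- data.frame(node = tree$nodes,
                  b_hat = c(NA, 0.3, -0.1, 0.05),
                  se_hat = c(NA, 0.1, 0.2, 0.15),
                  n_cases = 0L, informative = c(FALSE, TRUE, TRUE, TRUE))
  grid <- coefficient_grid(grid5$values, prior_nonzero = 0.1,
                           switch_prob = 1 - 1e-9)
  post <- attr(tree_posteriors(tree, s, grid), "posterior")
  b <- grid$values
  rho <- ifelse(b == 0, 0.9, 0.1 / 4)
  for (i in 2:4) {
    single <- rho * dnorm(s$b_hat[i], b, s$se_hat[i])
    single <- single / sum(single)
    expect_equal(unname(post[tree$nodes[i], ]), single, tolerance = 1e-6)
  }
})

test_that("flat likelihoods reproduce the prior nonzero mass at every depth", {
  tree <- make_tree(c(a = NA, b = "a", c = "b", d = "c"))
  res <- tree_posteriors(tree, flat_summaries(tree), grid5)
  # the redraw-from-root-prior switch makes the marginal prior depth-free
  expect_equal(res$pp_nonzero, rep(grid5$prior_nonzero, 4), tolerance = 1e-10)
})

test_that("stronger leaf evidence never lowers that leaf's posterior probability", {
  tree <- make_tree(c(r = NA, l1 = "r", l2 = "r"))
  pps <- vapply(c(0.5, 1, 2, 4), function(scale) {
    s <- data.frame(node = tree$nodes, b_hat = c(NA, 0.1 * scale, 0),
                    se_hat = c(NA, 0.1, 0.1), n_cases = 0L,
                    informative = c(FALSE, TRUE, TRUE))
    res <- tree_posteriors(tree, s, grid5)
    res$pp_nonzero[res$node == "l1"]
  }, numeric(1))
  expect_true(all(diff(pps) >= -1e-12))
})

test_that("credible intervals bracket the conditional MAP", {
  b <- test_bundle()
  co <- b$cohort
  tree <- build_icd_tree(unique(co$diagnoses$code))
  tree <- propagate_cases(tree, co$diagnoses, co$genotypes$person_ids)
  res <- run_treewas(tree, b$grs, b$covars)
  expect_true(all(res$pp_nonzero >= 0 & res$pp_nonzero <= 1))
  expect_true(all(res$ci_low <= res$map_estimate + 1e-12))
  expect_true(all(res$map_estimate <= res$ci_high + 1e-12))
  # the exposure-driven branch is reported; null leaves are not
  hits <- report_associated(res, 0.95)
  expect_true(all(c("M10", "M100") %in% hits$node))
  expect_false("J459" %in% hits$node)
  expect_false("N390" %in% hits$node)
})

test_that("report filtering respects the threshold at both extremes", {
  res <- data.frame(node = c("a", "b"), n_cases = 1:2,
                    pp_nonzero = c(0.5, 0.5), map_estimate = 0,
                    ci_low = -1, ci_high = 1)
  class(res) <- c("treewas_result", "data.frame")
  expect_equal(nrow(report_associated(res, 0.95)), 0)
  expect_equal(nrow(report_associated(res, 0)), 2)
})

test_that("node summaries agree with the standalone logistic fit", {
  b <- test_bundle()
  co <- b$cohort
  tree <- build_icd_tree(unique(co$diagnoses$code))
  tree <- propagate_cases(tree, co$diagnoses, co$genotypes$person_ids)
  s <- node_summaries(tree, b$grs, b$covars)
  v <- "M100"
  y <- as.numeric(b$grs$person_ids %in% tree$case_ids[[v]])
  ref <- fit_logistic(y, b$grs, b$covars)
  i <- match(v, s$node)
  expect_equal(s$b_hat[i], ref$beta, tolerance = 1e-10)
  expect_equal(s$se_hat[i], ref$se, tolerance = 1e-10)
  # a node with too few cases carries the flat-likelihood flag
  tree$case_ids[["I501"]] <- tree$case_ids[["I501"]][1:5]
  s2 <- node_summaries(tree, b$grs, b$covars)
  expect_false(s2$informative[s2$node == "I501"])
})

test_that("a cyclic graph is rejected", {
  bad <- make_tree(c(a = NA, b = "c", c = "b"))
  expect_error(tree_posteriors(bad, flat_summaries(bad), grid5),
               "not a rooted tree", class = "pwmr_validation_error")
})

test_that("grid validation rejects malformed grids", {
  expect_error(coefficient_grid(c(-1, 1)), "exactly one 0",
               class = "pwmr_config_error")
  expect_error(coefficient_grid(c(0, 1, 1)), "strictly increasing",
               class = "pwmr_config_error")
  expect_error(coefficient_grid(c(0, 1), prior_nonzero = 0),
               "pi and theta", class = "pwmr_config_error")
})
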