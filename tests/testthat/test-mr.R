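mk_set <- function(bx, by, sx = 0.02, sy = 0.05) {
  n <- length(bx)
  mr_summary_set(data.frame(rsid = paste0("rs", seq_len(n)),
                            beta_exposure = bx, se_exposure = rep_len(sx, n),
                            beta_outcome = by, se_outcome = rep_len(sy, n)))
}

test_that("the Wald ratio is beta_outcome/beta_exposure with first-order SE", {
  r <- wald_ratio(mk_set(0.5, 0.25, sy = 0.1))
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(wald_ratio(mk_set(0.5, 0))$beta, 0)
  expect_error(wald_ratio(mk_set(0, 0.1)), "beta_exposure = 0",
               class = "pwmr_mr_error")
  # one SNP: IVW delegates to the Wald ratio
  one <- mk_set(0.5, 0.25, sy = 0.1)
  expect_equal(ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(ivw(one)$method, "wald_ratio")
})

test_that("IVW equals the inverse-variance meta-analysis of Wald ratios", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(2:31, 1)
    set <- mk_set(runif(n, 0.05, 0.5) * sample(c(-1, 1), n, TRUE),
                  rnorm(n, 0, 0.2), sy = runif(n, 0.01, 0.2))
    est <- ivw(set)
    ratio <- set$beta_outcome / set$beta_exposure
    w <- set$beta_exposure^2 / set$se_outcome^2
    expect_equal(est$beta, sum(w * ratio) / sum(w), tolerance = 1e-10)
    expect_equal(est$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
    # and the WLS-through-origin identity
    ref <- lm(beta_outcome ~ 0 + beta_exposure, data = set,
              weights = 1 / set$se_outcome^2)
    expect_equal(est$beta, unname(coef(ref)), tolerance = 1e-10)
  }
})

test_that("two SNPs with identical ratios give that ratio", {
  set <- mk_set(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(ivw(set)$beta, 0.5, tolerance = 1e-12)
  expect_equal(ivw(set)$q_stat, 0, tolerance = 1e-20)
})

test_that("Egger recovers a constant directional pleiotropy offset", {
  set.seed(66)
  n <- 31
  bx <- runif(n, 0.05, 0.4)
  delta <- 0.03
  sy <- 0.01
  by <- 0.3 * bx + delta + rnorm(n, 0, sy)
  est <- egger(mk_set(bx, by, sy = sy))
  # intercept estimate ~ delta: slope unbiased despite the offset
  expect_lt(abs(est$beta - 0.3), 2.5 * est$se)
  expect_lt(est$p_pleiotropy, 0.05)
  # IVW on the same set is biased upward by the offset
  expect_gt(ivw(mk_set(bx, by, sy = sy))$beta, 0.3)
})

test_that("Egger with equal exposure effects is unidentifiable", {
  expect_error(egger(mk_set(rep(0.2, 4), c(0.1, 0.12, 0.08, 0.1))),
               "unidentifiable", class = "pwmr_mr_error")
  expect_error(egger(mk_set(c(0.1, 0.2), c(0.05, 0.1))), "3 SNPs",
               class = "pwmr_mr_error")
})

test_that("weighted median interpolates the cumulative weight at one half", {
  est <- weighted_median(mk_set(c(1, 1, 1), c(1, 2, 3)), n_boot = 50)
  expect_equal(est$beta, 2)              # equal weights: plain median
  # 60% of weight consistent at tau, 40% outliers
  set.seed(88)
  n <- 30
  bx <- runif(n, 0.1, 0.4)
  by <- 0.3 * bx
  by[1:12] <- by[1:12] + runif(12, 0.1, 0.3)   # 40% invalid, upward biased
  est2 <- weighted_median(mk_set(bx, by, sy = 0.02), n_boot = 100)
  expect_lt(abs(est2$beta - 0.3), 0.05)
  expect_gt(ivw(mk_set(bx, by, sy = 0.02))$beta, est2$beta)  # IVW dragged up
})

test_that("mode-based estimate finds the heavier consistent cluster", {
  est <- mode_based(mk_set(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4) * 0.7),
                    n_boot = 50)
  expect_equal(est$beta, 0.7, tolerance = 1e-6)  # all ratios equal
  set.seed(99)
  n <- 30
  bx <- runif(n, 0.1, 0.4)
  by <- 0.3 * bx
  by[1:10] <- 0.9 * bx[1:10]             # minority cluster at 0.9
  est2 <- mode_based(mk_set(bx, by, sy = 0.005), n_boot = 100)
  expect_lt(abs(est2$beta - 0.3), 0.05)
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  set.seed(111)
  n <- 12
  set <- mk_set(runif(n, 0.05, 0.4), rnorm(n, 0.1, 0.1),
                sy = runif(n, 0.02, 0.1))
  perm <- set[sample(n), ]
  class(perm) <- class(set)
  flip <- set
  flip$beta_exposure[1:4] <- -flip$beta_exposure[1:4]
  flip$beta_outcome[1:4] <- -flip$beta_outcome[1:4]
  for (f in list(ivw, egger)) {
    expect_equal(f(perm)$beta, f(set)$beta, tolerance = 1e-10)
    expect_equal(f(flip)$beta, f(set)$beta, tolerance = 1e-10)
  }
  expect_equal(weighted_median(perm, n_boot = 10)$beta,
               weighted_median(set, n_boot = 10)$beta, tolerance = 1e-10)
  expect_equal(mode_based(flip, n_boot = 10)$beta,
               mode_based(set, n_boot = 10)$beta, tolerance = 1e-10)
})

test_that("the selection ladder picks the documented estimator", {
  cfg <- default_sim_config(seed = 42)
  clean <- simulate_summary_stats(cfg, n_outcome = 50000, tau = 0.3, seed = 1)
  suite <- run_mr(clean, n_boot = 100, seed = 2)
  expect_equal(suite$selected$method, "ivw")

  dirty <- simulate_summary_stats(cfg, n_outcome = 50000, tau = 0.3,
                                  alpha = 0.03, seed = 1)
  suite2 <- run_mr(dirty, n_boot = 100, seed = 2)
  expect_equal(suite2$selected$method, "mode_based")

  single <- clean[1, ]
  class(single) <- class(clean)
  suite3 <- run_mr(single, n_boot = 10, seed = 2)
  expect_equal(suite3$selected$method, "wald_ratio")
})

test_that("summary-stat harmonization aligns, flips and drops like the score side", {
  ex <- summary_stats(data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                                 effect_allele = c("A", "A", "A", "A"),
                                 other_allele = c("G", "G", "T", "T"),
                                 beta = c(0.2, 0.3, 0.1, 0.1),
                                 se = 0.02,
                                 eaf = c(0.3, 0.3, 0.2, 0.45),
                                 trait = "urate"))
  out <- summary_stats(data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                                  effect_allele = c("A", "G", "T", "A"),
                                  other_allele = c("G", "A", "A", "T"),
                                  beta = c(0.1, 0.1, 0.1, 0.1),
                                  se = 0.05,
                                  eaf = c(0.3, 0.7, 0.8, 0.44),
                                  trait = "chd"))
  h <- harmonize_mr(ex, out)
  expect_equal(h$set$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(h$set$beta_outcome, c(0.1, -0.1, -0.1))
  expect_equal(h$dropped$reason, "palindromic-ambiguous")
})
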