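gv <- function(rsid, counted, other, af = NA_real_) {
  data.frame(rsid = rsid, counted_allele = counted, other_allele = other,
             observed_af = af)
}

test_that("allele harmonization keeps, swaps and drops correctly", {
  w <- variant_weights(data.frame(rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                                  effect_allele = c("A", "A", "A", "A", "A"),
                                  other_allele = c("G", "G", "T", "T", "C"),
                                  beta = c(0.3, 0.2, 0.1, 0.1, 0.1),
                                  se = rep(0.01, 5),
                                  eaf = c(0.3, 0.3, 0.10, 0.48, 0.3)))
  g <- rbind(gv("rs1", "A", "G", 0.3),    # direct match
             gv("rs2", "G", "A", 0.7),    # swapped letters
             gv("rs3", "A", "T", 0.11),   # palindromic, clear frequency
             gv("rs4", "A", "T", 0.48),   # palindromic, ambiguous
             gv("rs5", "C", "T", 0.3))    # incompatible alleles
  h <- harmonize(w, g)
  expect_equal(h$aligned$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(h$aligned$beta_dosage, c(0.3, -0.2, 0.1))
  expect_equal(h$aligned$offset, c(0, 0.4, 0))
  expect_equal(h$aligned$eaf, c(0.3, 0.7, 0.10))
  expect_equal(h$dropped$reason[h$dropped$rsid == "rs4"], "palindromic-ambiguous")
  expect_equal(h$dropped$reason[h$dropped$rsid == "rs5"], "allele-mismatch")

  # palindromic with frequencies on opposite sides of 0.5 => swapped
  h2 <- harmonize(w[3, ], gv("rs3", "A", "T", 0.89))
  expect_true(h2$aligned$flipped)
  expect_equal(h2$aligned$eaf, 0.9)
})

test_that("the allele-swap identity 2 - d reproduces the same score", {
  w <- toy_weights(3)
  dos <- matrix(c(2, 1, 0,
                  0, 2, 1,
                  1, 1, 2), 3, 3, byrow = TRUE)
  gm_fwd <- genotype_matrix(dos, paste0("p", 1:3), w$rsid)
  gm_rev <- genotype_matrix(2 - dos, paste0("p", 1:3), w$rsid)
  g_fwd <- compute_grs(gm_fwd, harmonize(w, gv(w$rsid, w$effect_allele,
                                               w$other_allele, w$eaf)))
  g_rev <- compute_grs(gm_rev, harmonize(w, gv(w$rsid, w$other_allele,
                                               w$effect_allele, 1 - w$eaf)))
  expect_equal(g_fwd$score, g_rev$score, tolerance = 1e-12)
})

test_that("the score is the weighted dosage sum, matching a naive loop", {
  w3 <- variant_weights(data.frame(rsid = paste0("rs", 1:3),
                                   effect_allele = "A", other_allele = "G",
                                   beta = c(0.3, 0.2, 0.1), se = 0.01,
                                   eaf = 0.5))
  gm <- genotype_matrix(matrix(c(2, 1, 0), 1, 3), "p1", w3$rsid)
  expect_equal(compute_grs(gm, w3)$score, 0.8)

  w0 <- w3
  w0$beta <- c(0, 0, 0)
  expect_equal(compute_grs(gm, w0)$score, 0)

  set.seed(17)
  w <- toy_weights(4)
  dos <- matrix(sample(0:2, 20, TRUE), 5, 4)
  gm <- genotype_matrix(dos, paste0("p", 1:5), w$rsid)
  g <- compute_grs(gm, w)
  naive <- vapply(1:5, function(i) {
    s <- 0
    for (j in 1:4) s <- s + w$beta[j] * dos[i, j]
    s
  }, numeric(1))
  expect_equal(g$score, naive, tolerance = 1e-12)
})

test_that("missing dosages are imputed by 2*eaf, preserving the mean", {
  w <- toy_weights(2)
  dos <- matrix(c(NA, 1, 2, NA), 2, 2)
  gm <- genotype_matrix(dos, c("p1", "p2"), w$rsid)
  g <- compute_grs(gm, w)
  expect_equal(g$score[1], w$beta[1] * 2 * w$eaf[1] + w$beta[2] * 2)
  expect_equal(g$score[2], w$beta[1] * 1 + w$beta[2] * 2 * w$eaf[2])
})

test_that("scores are linear in weight sets and invariant to variant order", {
  set.seed(23)
  w <- toy_weights(4)
  gm <- genotype_matrix(matrix(sample(0:2, 24, TRUE), 6, 4),
                        paste0("p", 1:6), w$rsid)
  g_all <- compute_grs(gm, w)
  half1 <- w[1:2, ]; class(half1) <- class(w)
  half2 <- w[3:4, ]; class(half2) <- class(w)
  expect_equal(compute_grs(gm, half1)$score + compute_grs(gm, half2)$score,
               g_all$score, tolerance = 1e-12)

  perm <- w[c(3, 1, 4, 2), ]; class(perm) <- class(w)
  expect_equal(compute_grs(gm, perm)$score, g_all$score, tolerance = 1e-12)
})

test_that("all variants dropped is a hard error", {
  w <- toy_weights(2)
  gm <- genotype_matrix(matrix(1, 2, 2), c("p1", "p2"), c("rsX", "rsY"))
  expect_error(compute_grs(gm, w), "no instrument variants",
               class = "pwmr_grs_error")
})

test_that("covariate screening finds correlated candidates and skips constants", {
  set.seed(31)
  n <- 5000
  grs <- structure(list(person_ids = paste0("p", 1:n), score = rnorm(n),
                        n_variants_used = 1L,
                        variants_dropped = data.frame()), class = "grs_vector")
  cands <- data.frame(self = grs$score,
                      indep = rnorm(n),
                      const = rep(1, n))
  expect_warning(sel <- screen_covariates(grs, cands), "constant")
  expect_true("self" %in% sel)

  # a categorical candidate whose levels differ in mean score is selected
  lv <- cut(grs$score + rnorm(n, 0, 2), 3)
  expect_true("grp" %in% screen_covariates(grs, data.frame(grp = as.character(lv))))
})

test_that("a null candidate is selected at about the nominal 5% rate", {
  set.seed(47)
  n <- 2000
  hits <- 0
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    score <- rnorm(n)
    grs <- structure(list(person_ids = paste0("p", 1:n), score = score,
                          n_variants_used = 1L,
                          variants_dropped = data.frame()), class = "grs_vector")
    hits <- hits + ("x" %in% screen_covariates(grs, data.frame(x = rnorm(n))))
  }
  rate <- hits / n_rep
  mc <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - mc)
  expect_lt(rate, 0.05 + mc)
})

test_that("screening on the packaged cohort recovers the confounded covariates", {
  b <- test_bundle()
  expect_true(all(c("center", "PC1") %in% b$selected))
  # unconfounded candidates are selected only at the nominal error rate
  nulls <- setdiff(b$selected, c("center", "PC1"))
  expect_lte(length(nulls), 2)
})
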