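mini_map <- function() {
  phecode_map(data.frame(phecode = c("411.2", "411.8", "274.1"),
                         icd = c("I21", "I25", "M10"),
                         system = "ICD10",
                         exclude_low = c("410", "410", "274"),
                         exclude_high = c("414.99", "414.99", "274.99")))
}

diag_df <- function(...) {
  rows <- list(...)
  diagnosis_records(data.frame(person_id = vapply(rows, `[[`, "", 1),
                               system = "ICD10",
                               code = vapply(rows, `[[`, "", 2),
                               source = "hospital"))
}

test_that("prefix match assigns the phecode and its dotted ancestors", {
  asg <- map_to_phecodes(diag_df(c("p1", "I21.0")), mini_map())
  expect_setequal(asg$phecode[asg$person_id == "p1"], c("411.2", "411"))

  # longest-prefix: a more specific map entry wins
  m2 <- phecode_map(data.frame(phecode = c("411.2", "411.21"),
                               icd = c("I21", "I210"), system = "ICD10",
                               exclude_low = "", exclude_high = ""))
  asg2 <- map_to_phecodes(diag_df(c("p1", "I21.0"), c("p2", "I21.9")), m2)
  expect_setequal(asg2$phecode[asg2$person_id == "p1"],
                  c("411.21", "411.2", "411"))
  expect_setequal(asg2$phecode[asg2$person_id == "p2"], c("411.2", "411"))
})

test_that("unmappable codes are counted, not fatal", {
  expect_warning(asg <- map_to_phecodes(diag_df(c("p1", "Z99.9")), mini_map()),
                 "unmapped")
  expect_equal(nrow(asg), 0)
  expect_equal(attr(asg, "n_unmapped_codes"), 1)
})

test_that("mapping is idempotent on its own output", {
  d <- diag_df(c("p1", "I21.0"), c("p2", "M10.0"), c("p2", "I25.1"))
  a1 <- map_to_phecodes(d, mini_map())
  a2 <- map_to_phecodes(d, mini_map())
  expect_identical(a1[order(a1$person_id, a1$phecode), ],
                   a2[order(a2$person_id, a2$phecode), ])
})

test_that("exclusion ranges remove overlapping disease states from controls", {
  persons <- paste0("p", 1:10)
  # p1 has I21.0 (-> 411.2); p2 has I25.1 (-> 411.8, inside [410, 414.99])
  asg <- map_to_phecodes(diag_df(c("p1", "I21.0"), c("p2", "I25.1")), mini_map())
  cc <- build_case_control("411.2", asg, mini_map(), persons, min_cases = 1)
  expect_equal(cc$case_ids, "p1")
  expect_false("p2" %in% cc$control_ids)   # excluded, not control
  expect_equal(cc$n_controls, 8)
  expect_length(intersect(cc$case_ids, cc$control_ids), 0)

  cc_roll <- build_case_control("411", asg, mini_map(), persons, min_cases = 1)
  expect_setequal(cc_roll$case_ids, c("p1", "p2"))  # rollup: both are 411 cases
  expect_equal(cc_roll$n_controls, 8)
})

test_that("sets below the case floor are marked filtered", {
  persons <- paste0("p", 1:100)
  rows <- lapply(paste0("p", 1:19), function(p) c(p, "M10.0"))
  asg <- map_to_phecodes(do.call(diag_df, rows), mini_map())
  cc <- build_case_control("274.1", asg, mini_map(), persons, min_cases = 20)
  expect_true(cc$filtered)
  expect_equal(cc$n_cases, 19)
  cc2 <- build_case_control("274.1", asg, mini_map(), persons, min_cases = 19)
  expect_false(cc2$filtered)
})

test_that("toy cohort case/control counts match hand enumeration", {
  persons <- paste0("p", 1:10)
  d <- diag_df(c("p1", "I21.0"), c("p2", "I21.9"), c("p3", "I25.1"),
               c("p4", "M10.0"), c("p5", "I21.0"), c("p5", "M10.0"))
  asg <- map_to_phecodes(d, mini_map())
  ph <- build_phenome(asg, mini_map(), persons, min_cases = 1)
  # hand enumeration: 411.2 cases {p1,p2,p5}; excluded {p3}; controls 6
  expect_equal(ph$sets[["411.2"]]$n_cases, 3)
  expect_equal(ph$sets[["411.2"]]$n_controls, 6)
  # 411 cases {p1,p2,p3,p5}; controls {p4,p6..p10} = 6
  expect_equal(ph$sets[["411"]]$n_cases, 4)
  expect_equal(ph$sets[["411"]]$n_controls, 6)
  # 274.1 cases {p4,p5}; exclusion [274,274.99] adds nobody else
  expect_equal(ph$sets[["274.1"]]$n_cases, 2)
  expect_equal(ph$sets[["274.1"]]$n_controls, 8)
})

test_that("rollup case counts are monotone: parent >= child", {
  b <- test_bundle()
  for (p in names(b$phenome$sets)) {
    for (anc in phecode_ancestors(p)) {
      if (anc %in% names(b$phenome$sets)) {
        expect_gte(b$phenome$sets[[anc]]$n_cases, b$phenome$sets[[p]]$n_cases)
      }
    }
  }
})

test_that("ICD tree over observed codes has the expected skeleton", {
  tree <- build_icd_tree(c("I21.0", "I21.9", "I50.1"))
  leaves <- setdiff(tree$nodes, names(tree$children))
  expect_setequal(leaves, c("I210", "I219", "I501"))
  expect_true(all(c("I21", "I50", "I20-I25", "I30-I52", "IX", "ROOT") %in%
                  tree$nodes))
  expect_equal(unname(tree$parent[["I21"]]), "I20-I25")
  expect_equal(unname(tree$parent[["I20-I25"]]), "IX")
  # single root, one parent each
  expect_equal(sum(is.na(tree$parent)), 1)

  chain <- build_icd_tree("M10.0")
  expect_equal(length(chain$nodes), 5)   # ROOT, XIII, M05-M14, M10, M100

  expect_error(build_icd_tree("Q99.9"), "Q99",
               class = "pwmr_validation_error")
})

test_that("case propagation marks ancestors and matches a raw recount", {
  d <- diag_df(c("p1", "I21.0"), c("p2", "M10.0"))
  tree <- build_icd_tree(unique(d$code))
  tree <- propagate_cases(tree, d, paste0("p", 1:5))
  for (v in c("I210", "I21", "I20-I25", "IX", "ROOT")) {
    expect_true("p1" %in% tree$case_ids[[v]], info = v)
  }
  expect_false("p2" %in% tree$case_ids[["I21"]])
  expect_setequal(tree$case_ids[["ROOT"]], c("p1", "p2"))

  # internal node case set equals the union of its children's
  b <- test_bundle()
  co <- b$cohort
  big <- build_icd_tree(unique(co$diagnoses$code))
  big <- propagate_cases(big, co$diagnoses, co$genotypes$person_ids)
  for (v in names(big$children)) {
    kids <- big$children[[v]]
    expect_setequal(big$case_ids[[v]],
                    unique(unlist(big$case_ids[kids], use.names = FALSE)))
  }
  # and matches an independent recount from the raw diagnosis records
  i21 <- unique(co$diagnoses$person_id[startsWith(co$diagnoses$code, "I21")])
  expect_setequal(big$case_ids[["I21"]], i21)
})
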