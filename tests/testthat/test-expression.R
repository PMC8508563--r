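test_that("signed fold convention is monotone and involution-consistent", {
  expect_equal(signed_fold(2), 2)
  expect_equal(signed_fold(1), 1)
  expect_equal(signed_fold(0.917), -1 / 0.917)
  expect_equal(signed_fold(0.917), -1.0905, tolerance = 1e-4)
  set.seed(71)
  r <- exp(rnorm(100))
  r <- r[abs(r - 1) > 1e-6]
  expect_equal(signed_fold(1 / r), -signed_fold(r), tolerance = 1e-12)
  expect_true(all(abs(signed_fold(r)) >= 1))
  expect_error(signed_fold(-2), "positive")
})

test_that("paired fold changes back-transform the log2 differences", {
  sheet <- make_sheet(2, 3)
  # no change anywhere: fold 1, CI contains 1
  ex <- matrix(8, 2, nrow(sheet),
               dimnames = list(c("pr1", "pr2"), sheet$sample_id))
  fc <- paired_fold_change(ex, sheet)
  expect_equal(fc$fold, c(1, 1))
  expect_true(all(fc$ci_low <= 1 & fc$ci_high >= 1))

  # exact planted 1.399-fold with zero spread: degenerate CI at the value
  ex2 <- ex
  ex2[, sheet$tissue == "tumor"] <- 8 + log2(1.399)
  fc2 <- paired_fold_change(ex2, sheet)
  expect_equal(fc2$fold, c(1.399, 1.399), tolerance = 1e-12)
  expect_identical(unique(fc2$flag), "degenerate_ci")

  # downregulation maps through the signed convention, bounds included
  ex3 <- ex
  ex3[, sheet$tissue == "tumor"] <- 8 + log2(0.917)
  fc3 <- paired_fold_change(ex3, sheet)
  expect_equal(fc3$fold, rep(-1 / 0.917, 2), tolerance = 1e-12)

  one_pair <- make_sheet(0, 1)
  exs <- matrix(8, 1, 2, dimnames = list("pr1", one_pair$sample_id))
  expect_identical(paired_fold_change(exs, one_pair)$flag,
                   "insufficient_pairs")
})

test_that("t-interval coverage of the true fold is near nominal", {
  sheet <- simulate_cohort(cohort_config(n_persons = 30, n_msi = 30,
                                         p_right_given_msi = 0.5, seed = 72))
  true_fold <- 1.2
  ge <- data.frame(probe_id = "pr1", gene = "G1", baseline_log2 = 8,
                   fold_msi = true_fold, fold_mss = 1)
  covered <- vapply(1:1000, function(i) {
    ex <- simulate_expression(sheet, ge, noise_spec(0, 0.3), seed = 7000 + i)
    fc <- paired_fold_change(ex, sheet, group = "MSI")
    fc$ci_low <= true_fold && fc$ci_high >= true_fold
  }, TRUE)
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("expression interaction scan detects MSI-specific folds and is calibrated", {
  sheet <- simulate_cohort(cohort_config(seed = 73))
  # null probes: detection rate compatible with the 5% nominal level
  ge_null <- data.frame(probe_id = sprintf("pr%04d", 1:2000), gene = "G",
                        baseline_log2 = 8, fold_msi = 1, fold_mss = 1)
  ex <- simulate_expression(sheet, ge_null, noise_spec(0, 0.3), seed = 74)
  sc <- expression_interaction_scan(ex, sheet)
  hits <- sum(sc$significant)
  expect_gte(hits, qbinom(0.005, 2000, 0.05))
  expect_lte(hits, qbinom(0.995, 2000, 0.05))

  # constant matrix: degenerate, nothing called significant
  const <- matrix(5, 3, nrow(sheet),
                  dimnames = list(paste0("c", 1:3), sheet$sample_id))
  sc0 <- expression_interaction_scan(const, sheet)
  expect_true(all(nzchar(sc0$flags)))
  expect_false(any(sc0$significant))
})

test_that("gene-set average fold pools probe-level paired differences", {
  sheet <- make_sheet(2, 2)
  ex <- matrix(8, 3, nrow(sheet),
               dimnames = list(paste0("pr", 1:3), sheet$sample_id))
  ex[, sheet$tissue == "tumor"] <- 8 + log2(1.09)
  gs <- geneset_average_fold(ex, paste0("pr", 1:3), sheet)
  expect_equal(gs$fold, 1.09, tolerance = 1e-12)

  # a single-probe set reduces to the per-probe fold change
  set.seed(75)
  ex2 <- matrix(rnorm(nrow(sheet), 8, 1), 1, nrow(sheet),
                dimnames = list("pr1", sheet$sample_id))
  gs1 <- geneset_average_fold(ex2, "pr1", sheet)
  fc1 <- paired_fold_change(ex2, sheet)
  expect_equal(gs1$fold, fc1$fold, tolerance = 1e-12)
  expect_equal(gs1$ci_low, fc1$ci_low, tolerance = 1e-12)

  expect_error(geneset_average_fold(ex, character(0), sheet), "empty")
  expect_error(geneset_average_fold(ex, "nope", sheet), "not in expression")

  # recovery: planted uniform 1.09-fold over 15 probes, 30 pairs, sigma 0.2
  sheet30 <- simulate_cohort(cohort_config(n_persons = 30, n_msi = 30,
                                           p_right_given_msi = 0.5,
                                           seed = 76))
  ge <- data.frame(probe_id = sprintf("pr%02d", 1:15),
                   gene = sprintf("G%02d", 1:15), baseline_log2 = 8,
                   fold_msi = 1.09, fold_mss = 1.09)
  est <- vapply(1:200, function(i) {
    exs <- simulate_expression(sheet30, ge, noise_spec(0, 0.2),
                               seed = 9000 + i)
    geneset_average_fold(exs, ge$probe_id, sheet30, group = "MSI")$fold
  }, 0)
  expect_lt(abs(mean(est) - 1.09), 0.03)
})
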