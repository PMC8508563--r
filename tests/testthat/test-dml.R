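test_that("BH q-values equal the definitional step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)

  set.seed(41)
  for (i in 1:60) {
    m <- sample(1:12, 1)
    p <- round(runif(m), sample(1:3, 1))   # rounding forces ties
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # missing p-values propagate without counting as tests
  p <- c(0.01, NA, 0.04)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_brute(c(0.01, 0.04)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DML calling combines the FDR and magnitude criteria", {
  res <- data.frame(locus_id = c("a", "b", "c"),
                    q_msi = c(5e-4, 5e-4, 0.01),
                    delta_msi = c(0.25, 0.15, 0.30))
  called <- call_dml(res, "msi", dml_thresholds())
  expect_identical(called$locus_id, "a")       # b fails magnitude, c fails FDR
  expect_identical(called$direction, "hyper")
  res$delta_msi[1] <- -0.25
  expect_identical(call_dml(res, "msi")$direction, "hypo")
})

test_that("interaction categories follow the three-set membership rules", {
  universe <- paste0("L", 1:8)
  # all 8 membership patterns, one locus each:
  # (msi, mss, interaction) in binary order L1=000 ... L8=111
  msi <- universe[c(5, 6, 7, 8)]
  mss <- universe[c(3, 4, 7, 8)]
  int <- universe[c(2, 4, 6, 8)]
  cat <- classify_interaction(msi, mss, int, universe)
  expected <- c(L1 = "none", L2 = "none", L3 = "none", L4 = "D",
                L5 = "none", L6 = "B", L7 = "A", L8 = "C")
  expect_identical(as.character(cat), unname(expected))
  # every locus gets exactly one label; A+B+C+D matches the set identity
  # |(MSI u MSS) n (INT u (MSI n MSS))|
  set.seed(42)
  for (i in 1:25) {
    u <- paste0("x", 1:30)
    s_msi <- sample(u, sample(0:30, 1))
    s_mss <- sample(u, sample(0:30, 1))
    s_int <- sample(u, sample(0:30, 1))
    cc <- classify_interaction(s_msi, s_mss, s_int, u)
    lhs <- sum(cc != "none")
    rhs <- length(intersect(union(s_msi, s_mss),
                            union(s_int, intersect(s_msi, s_mss))))
    expect_equal(lhs, rhs)
  }
  expect_error(classify_interaction(c("zz"), character(0), character(0),
                                    universe),
               "outside the universe")
})

test_that("Venn arithmetic is conserved", {
  v <- venn_counts(paste0("a", 1:5), paste0("a", 4:9))
  expect_equal(unname(v), c(3, 4, 2))
  expect_equal(unname(venn_counts(c("x"), c("y"))), c(1, 1, 0))
  expect_equal(unname(venn_counts(c("x", "y"), c("y", "x"))), c(0, 0, 2))
  expect_equal(unname(venn_from_totals(10, 7, 4)), c(6, 3, 4))
  expect_error(venn_from_totals(5, 3, 4), "invalid")
})

test_that("region tabulation conserves counts and percentages", {
  ann <- data.frame(locus_id = paste0("cg", 1:60), gene_symbols = "",
                    region = rep(c("Island", "N_Shore", "OpenSea"), 20),
                    promoter_associated = FALSE, stringsAsFactors = FALSE)
  ann$region <- msimeth:::normalize_region(ann$region)
  ids <- paste0("cg", 1:30)
  dirs <- rep(c("hyper", "hypo"), 15)
  chip <- c(Island = 300, N_Shelf = 50, N_Shore = 125, S_Shelf = 45,
            S_Shore = 100, OpenSea = 380)
  tab <- tabulate_regions(ids, dirs, ann, chip_totals = chip)
  body <- tab[tab$region != "Total", ]
  expect_equal(body$hypo + body$hyper, body$total)
  expect_equal(sum(body$total), 30)
  expect_equal(tab$total[tab$region == "Total"], 30)
  expect_equal(body$pct_dml[body$region == "Island"],
               round(100 * 10 / 30, 2))
  expect_equal(body$pct_chip[body$region == "Island"], 30)

  # empty DML set: all zeros, no division error
  tab0 <- tabulate_regions(character(0), character(0), ann,
                           chip_totals = chip)
  expect_true(all(tab0$total == 0))
  # unannotated loci are an error listing the IDs
  expect_error(tabulate_regions("cg999", "hyper", ann, chip), "cg999")
})

test_that("promoter-island filter applies the Bonferroni rule to its universe", {
  ann <- data.frame(
    locus_id = paste0("cg", 1:120), gene_symbols = paste0("G", 1:120),
    region = c(rep("Island", 110), rep("N_Shore", 10)),
    promoter_associated = c(rep(TRUE, 100), rep(FALSE, 10), rep(TRUE, 10)),
    stringsAsFactors = FALSE)
  ann$region <- msimeth:::normalize_region(ann$region)
  res <- data.frame(locus_id = paste0("cg", 1:120),
                    p_interaction = rep(0.5, 120),
                    delta_all = 0.3, stringsAsFactors = FALSE)
  res$p_interaction[1] <- 1e-5    # inside universe, passes 0.05/100 = 5e-4
  res$p_interaction[2] <- 1e-3    # inside universe, above threshold
  res$p_interaction[111] <- 1e-9  # island but not promoter: outside universe
  out <- promoter_island_filter(res, ann, dml_thresholds())
  expect_equal(attr(out, "n_universe"), 100L)
  expect_equal(attr(out, "threshold"), 5e-4)
  expect_identical(out$locus_id, "cg1")
  expect_identical(out$direction, "hyper")

  empty_ann <- ann
  empty_ann$promoter_associated <- FALSE
  expect_warning(out0 <- promoter_island_filter(res, empty_ann),
                 "empty")
  expect_equal(nrow(out0), 0L)
})

test_that("planted strong promoter-island interactions are recovered", {
  sheet <- simulate_cohort(cohort_config(seed = 43))
  eff <- rbind(
    locus_effects(10, "msi_only", 0.4, 0, baseline = 0.3,
                  locus_id = sprintf("hit%02d", 1:10)),
    locus_effects(40, "null", baseline = 0.3,
                  locus_id = sprintf("bg%02d", 1:40))
  )
  sim <- simulate_beta_matrix(sheet, eff, noise_spec(), seed = 44)
  res <- dml_scan_results(sim$beta, sheet)
  ann <- data.frame(locus_id = eff$locus_id,
                    gene_symbols = paste0("G", seq_len(nrow(eff))),
                    region = "Island", promoter_associated = TRUE,
                    stringsAsFactors = FALSE)
  ann$region <- msimeth:::normalize_region(ann$region)
  names(res)[names(res) == "delta_all"] <- "delta_all"
  out <- promoter_island_filter(res, ann)
  expect_setequal(out$locus_id, sprintf("hit%02d", 1:10))
})

test_that("the DML catalog is consistent with its member sets", {
  sheet <- simulate_cohort(cohort_config(n_persons = 40, n_msi = 15,
                                         seed = 45))
  eff <- rbind(locus_effects(20, "null", baseline = 0.35),
               locus_effects(5, "msi_only", 0.35, 0, 0.3,
                             locus_id = sprintf("mi%d", 1:5)))
  sim <- simulate_beta_matrix(sheet, eff, noise_spec(), seed = 46)
  res <- dml_scan_results(sim$beta, sheet)
  cat <- build_dml_catalog(res)
  expect_equal(nrow(cat), 25L)
  # category is a pure function of the membership triple
  expect_true(all((cat$category == "B") ==
                  (cat$in_msi_dml & !cat$in_mss_dml & cat$in_interaction)))
  expect_true(all((cat$category == "A") ==
                  (cat$in_msi_dml & cat$in_mss_dml & !cat$in_interaction)))
})
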