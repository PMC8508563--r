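test_that("paired model equals the paired t-test", {
  sheet <- make_sheet(0, 2)
  y <- sheet_values(sheet, tumor = c(0.5, 0.6), normal = c(0.3, 0.3))
  fit <- fit_paired_model(y, sheet)
  expect_equal(fit$deltas[["all"]], 0.25)
  expect_equal(fit$table$f[fit$table$term == "tumor"], 25, tolerance = 1e-10)
  expect_equal(fit$table$p[fit$table$term == "tumor"], 0.1256659,
               tolerance = 1e-6)

  # F_tumor = paired-t^2 over random small datasets
  set.seed(31)
  for (i in 1:500) {
    n <- sample(3:10, 1)
    sh <- make_sheet(0, n)
    yt <- runif(n); yn <- runif(n)
    yy <- sheet_values(sh, yt, yn)
    f <- fit_paired_model(yy, sh)
    tt <- t.test(yt, yn, paired = TRUE)
    expect_equal(f$table$f[f$table$term == "tumor"], unname(tt$statistic)^2,
                 tolerance = 1e-8)
    expect_equal(f$table$p[f$table$term == "tumor"], tt$p.value,
                 tolerance = 1e-8)
  }

  # degenerate: tumor == normal everywhere -> F 0, p 1
  sh <- make_sheet(0, 4)
  v <- runif(4)
  f0 <- fit_paired_model(sheet_values(sh, v, v), sh)
  expect_equal(f0$table$f[f0$table$term == "tumor"], 0)
  expect_equal(f0$table$p[f0$table$term == "tumor"], 1)
  # a single pair is insufficient and flagged, not thrown
  f1 <- fit_paired_model(sheet_values(make_sheet(0, 1), 0.5, 0.3),
                         make_sheet(0, 1))
  expect_true("insufficient_data" %in% f1$flags)
  expect_null(f1$table)
})

test_that("paired t-test handles degenerate spread", {
  tt <- paired_t_test(c(0.2, 0.3))
  expect_equal(tt$t, 5)
  expect_equal(tt$p, 0.1256659, tolerance = 1e-6)
  expect_equal(paired_t_test(rep(0, 5))[c("t", "p")], list(t = 0, p = 1))
  deg <- paired_t_test(rep(0.1, 5))
  expect_identical(deg$flag, "degenerate")
  expect_equal(deg$p, 0)
})

test_that("method-of-moments person component is truncated and recovers truth", {
  # raw estimate can be negative; reported component is truncated at 0
  sh <- make_sheet(0, 3)
  set.seed(32)
  found_negative <- FALSE
  for (i in 1:50) {
    f <- fit_paired_model(sheet_values(sh, runif(3), runif(3)), sh)
    expect_gte(f$sigma2_person, 0)
    if (f$sigma2_person_raw < 0) found_negative <- TRUE
  }
  expect_true(found_negative)

  # averaged over 2000 loci at 125 pairs the component recovers the
  # generating person variance within 10% (fit on the logit scale, where
  # the generating model is exactly linear)
  sheet <- simulate_cohort(cohort_config(seed = 33))
  eff <- locus_effects(2000, "null", baseline = 0.5)
  sim <- simulate_beta_matrix(sheet, eff, noise_spec(0.3, 0.3), seed = 34)
  s <- genomewide_scan(qlogis(sim$beta), sheet, model = "paired")
  expect_lt(abs(mean(s$sigma2_person) - 0.09) / 0.09, 0.10)
})

test_that("interaction model reproduces the balanced 2x2 hand computation", {
  sh <- make_sheet(2, 2)
  # MSS cells 0.2 -> 0.3, MSI cells 0.2 -> 0.6, no within-cell spread
  y <- sheet_values(sh, tumor = c(0.6, 0.6, 0.3, 0.3),
                    normal = c(0.2, 0.2, 0.2, 0.2))
  fit <- fit_interaction_model(y, sh)
  expect_equal(fit$table$ss[fit$table$term == "tumor:msi"], 0.045,
               tolerance = 1e-12)
  expect_equal(fit$table$ss[fit$table$term == "error"], 0, tolerance = 1e-12)

  # equal deltas in both groups kill the interaction contrast
  y2 <- sheet_values(sh, tumor = c(0.5, 0.5, 0.4, 0.4),
                     normal = c(0.3, 0.3, 0.2, 0.2))
  fit2 <- fit_interaction_model(y2, sh)
  expect_equal(fit2$table$ss[fit2$table$term == "tumor:msi"], 0,
               tolerance = 1e-12)

  # an empty cell is flagged, not thrown
  sh_no_msi_t <- sh[!(sh$msi_status == "MSI" & sh$tissue == "tumor"), ]
  fit3 <- fit_interaction_model(y[sh_no_msi_t$sample_id], sh_no_msi_t)
  expect_true("inestimable_interaction" %in% fit3$flags)
})

test_that("Type III tests match the regression oracles on unbalanced designs", {
  library(car)
  set.seed(35)
  for (i in 1:20) {
    n_msi <- sample(2:4, 1)
    n_mss <- sample(3:6, 1)
    sh <- make_sheet(n_msi, n_mss)
    y <- runif(nrow(sh))
    names(y) <- sh$sample_id
    fit <- fit_interaction_model(y, sh)
    d <- data.frame(y = y,
                    tumor = factor(sh$tissue, c("normal", "tumor")),
                    msi = factor(sh$msi_status, c("MSS", "MSI")))
    m <- lm(y ~ tumor * msi, data = d,
            contrasts = list(tumor = "contr.sum", msi = "contr.sum"))
    a3 <- car::Anova(m, type = 3)
    for (term in c("tumor", "msi", "tumor:msi")) {
      expect_equal(fit$table$f[fit$table$term == term],
                   a3[term, "F value"], tolerance = 1e-8)
    }
    # interaction F also equals the model-comparison (full vs dropped) F
    m_red <- lm(y ~ tumor + msi, data = d,
                contrasts = list(tumor = "contr.sum", msi = "contr.sum"))
    cmp <- anova(m_red, m)
    expect_equal(fit$table$f[fit$table$term == "tumor:msi"], cmp$F[2],
                 tolerance = 1e-8)
  }
})

test_that("location model adjusts the interaction and degrades gracefully", {
  # constant location: model reduces to the two-factor interaction model
  sh <- make_sheet(2, 3, location = "left")
  set.seed(36)
  y <- runif(nrow(sh)); names(y) <- sh$sample_id
  fl <- fit_location_model(y, sh)
  fi <- fit_interaction_model(y, sh)
  expect_true(any(grepl("dropped:location", fl$flags)))
  expect_equal(fl$table$f[fl$table$term == "tumor:msi"],
               fi$table$f[fi$table$term == "tumor:msi"], tolerance = 1e-8)

  # zero-noise data with only a tumor-by-location effect: no tumor:msi SS
  sh2 <- make_sheet(2, 2, location = c("left", "right", "left", "right"))
  y2 <- ifelse(sh2$tissue == "tumor" & sh2$location == "right", 0.6, 0.3)
  names(y2) <- sh2$sample_id
  f2 <- fit_location_model(y2, sh2)
  expect_equal(f2$table$ss[f2$table$term == "tumor:msi"], 0,
               tolerance = 1e-12)
  expect_gt(f2$table$ss[f2$table$term == "tumor:location"], 0)

  # planted MSI-only effect independent of location: tumor:msi significant,
  # tumor:location not
  sheet <- simulate_cohort(cohort_config(seed = 37))
  eff <- locus_effects(1, "msi_only", 0.3, 0, baseline = 0.3)
  sim <- simulate_beta_matrix(sheet, eff, noise_spec(), seed = 38)
  f3 <- fit_location_model(sim$beta[1, ], sheet)
  expect_lt(f3$table$p[f3$table$term == "tumor:msi"], 1e-4)
  expect_gt(f3$table$p[f3$table$term == "tumor:location"], 0.01)
})

test_that("variance decomposition shares sum to one and flag degeneracy", {
  sh <- make_sheet(0, 4)
  # person effects only, tumor == normal: person share is 1
  v <- c(0.2, 0.4, 0.6, 0.8)
  f <- fit_paired_model(sheet_values(sh, v, v), sh)
  dec <- variance_decomposition(f)
  expect_equal(sum(dec$share), 1, tolerance = 1e-12)
  expect_equal(dec$share[dec$term == "person"], 1, tolerance = 1e-12)

  # constant response is degenerate
  f0 <- fit_paired_model(sheet_values(sh, 0.5, 0.5), sh)
  dec0 <- variance_decomposition(f0)
  expect_true(attr(dec0, "degenerate"))
  expect_true(all(dec0$share == 0))
})

test_that("genome-wide scan honours subsetting, ordering and flags", {
  sheet <- simulate_cohort(cohort_config(n_persons = 20, n_msi = 8,
                                         seed = 39))
  eff <- locus_effects(30, "null", baseline = 0.4)
  sim <- simulate_beta_matrix(sheet, eff, noise_spec(), seed = 40)
  mat <- sim$beta
  mat[3, 1:2] <- NA            # partial missingness -> per-locus refit
  s_all <- genomewide_scan(mat, sheet, model = "paired")
  expect_identical(s_all$locus_id, rownames(mat))
  expect_equal(s_all$n_eff[1], 20L)

  s_msi <- genomewide_scan(mat, sheet, model = "paired", stratum = "MSI")
  expect_equal(s_msi$n_eff[1], 8L)

  # permutation equivariance: permuting rows permutes results identically
  perm <- sample(nrow(mat))
  s_perm <- genomewide_scan(mat[perm, ], sheet, model = "paired")
  expect_equal(as.data.frame(s_perm), as.data.frame(s_all)[perm, ],
               ignore_attr = TRUE)

  # a locus missing in every tumor sample cannot be paired
  mat[5, sheet$sample_id[sheet$tissue == "tumor"]] <- NA
  s2 <- genomewide_scan(mat, sheet, model = "paired")
  expect_match(s2$flags[5], "insufficient_data")
  expect_false(any(is.na(s2$p_tumor[-5])))

  # matrix lacking design samples is a configuration error
  expect_error(genomewide_scan(mat[, 1:10], sheet, model = "paired"),
               "lacks sample column")
})
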