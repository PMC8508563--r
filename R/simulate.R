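# Synthetic-data generator emulating the paired tumor/normal 450K design:
# 125 persons each contributing one tumor and one matched normal sample, an
# MSI subgroup, person-level random intercepts dominating the variation, and
# loci belonging to planted effect classes.

#' Cohort configuration for the paired-design simulator
#'
#' Defaults reproduce the study design this package targets: 125 persons of
#' whom 30 are MSI, right-sided tumors in 13/30 of the MSI and 11/95 of the
#' MSS persons, 72/125 males, ages around 46, and stages I/II/III in
#' proportions 25/33/67.
#'
#' @param n_persons number of persons (each contributes a tumor/normal pair).
#' @param n_msi number of MSI persons (`0 <= n_msi <= n_persons`).
#' @param p_right_given_msi probability a tumor is right-sided given MSI.
#' @param p_right_given_mss probability a tumor is right-sided given MSS.
#' @param sex_split probability a person is male.
#' @param age_mean,age_sd age distribution (years), truncated at 18.
#' @param stage_probs probabilities for stages 1, 2, 3.
#' @param seed integer seed for `simulate_cohort()`; `NULL` uses the current
#'   RNG state.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_persons = 125, n_msi = 30,
                          p_right_given_msi = 13 / 30,
                          p_right_given_mss = 11 / 95,
                          sex_split = 72 / 125,
                          age_mean = 46, age_sd = 14,
                          stage_probs = c(25, 33, 67) / 125,
                          seed = NULL) {
  if (n_persons < 0 || n_msi < 0 || n_msi > n_persons) {
    stopf("invalid config: need 0 <= n_msi <= n_persons")
  }
  probs <- c(p_right_given_msi, p_right_given_mss, sex_split)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  if (length(stage_probs) != 3L || abs(sum(stage_probs) - 1) > 1e-9) {
    stopf("stage_probs must be three probabilities summing to 1")
  }
  structure(list(n_persons = as.integer(n_persons),
                 n_msi = as.integer(n_msi),
                 p_right_given_msi = p_right_given_msi,
                 p_right_given_mss = p_right_given_mss,
                 sex_split = sex_split, age_mean = age_mean, age_sd = age_sd,
                 stage_probs = stage_probs, seed = seed),
            class = "cohort_config")
}

#' Noise model for the beta-value simulator
#'
#' Gaussian noise on the logit (log-odds) scale: a person-level random
#' intercept shared by a person's tumor and normal sample, plus an
#' independent per-sample residual. The defaults (`sigma_person = 0.2`,
#' `sigma_error = 0.35`) make the person term account for about 62% of the
#' paired-model sum of squares at 125 pairs; see `calibrate_person_sd()`.
#'
#' @param sigma_person SD of the person random intercept (logit scale, >= 0).
#' @param sigma_error SD of the per-sample residual (logit scale, >= 0).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_person = 0.2, sigma_error = 0.35) {
  if (sigma_person < 0 || sigma_error < 0) stopf("noise SDs must be >= 0")
  structure(list(sigma_person = sigma_person, sigma_error = sigma_error),
            class = "noise_spec")
}

#' Person-intercept SD yielding a target person sum-of-squares share
#'
#' In the paired model (tumor + random person), the expected share of the
#' total sum of squares attributable to the person term at `n_pairs` pairs is
#' `A(2*sp^2 + se^2) / (se^2 + A(2*sp^2 + 2*se^2))` with `A = n_pairs - 1`
#' (null locus). This inverts that relation: given the residual SD and a
#' target share, it returns the person SD that attains it in expectation.
#'
#' @param share target person SS share in (0, 1).
#' @param sigma_error residual SD (logit scale).
#' @param n_pairs number of tumor/normal pairs.
#' @return the person-intercept SD.
#' @export
calibrate_person_sd <- function(share, sigma_error, n_pairs = 125) {
  if (share <= 0 || share >= 1) stopf("share must be in (0,1)")
  a <- n_pairs - 1
  num <- sigma_error^2 * (share * (1 + 2 * a) - a)
  if (num <= 0) {
    stopf("share %.3f is below the floor attainable with sigma_person = 0",
          share)
  }
  sqrt(num / (2 * a * (1 - share)))
}

#' Planted per-locus effect specifications
#'
#' Builds the effect table consumed by `simulate_beta_matrix()`. Each locus
#' has a baseline mean beta and a tumor-minus-normal difference (on the beta
#' scale) per MSI stratum, constrained by its effect class:
#' `null` (no difference), `shared` (same difference in MSI and MSS),
#' `msi_only`, `mss_only`, and `both_diff` (both nonzero, different
#' magnitude).
#'
#' @param n number of loci (each argument is recycled to length `n`).
#' @param effect_class one of `"null"`, `"shared"`, `"msi_only"`,
#'   `"mss_only"`, `"both_diff"`.
#' @param delta_msi,delta_mss tumor-minus-normal difference in mean beta per
#'   stratum.
#' @param baseline mean beta of the normal tissue, strictly inside (0, 1).
#' @param locus_id optional locus identifiers.
#' @return data frame with one row per locus.
#' @export
locus_effects <- function(n, effect_class = "null", delta_msi = 0,
                          delta_mss = 0, baseline = 0.3, locus_id = NULL) {
  classes <- c("null", "shared", "msi_only", "mss_only", "both_diff")
  eff <- data.frame(
    locus_id = locus_id %||% sprintf("cg%06d", seq_len(n)),
    effect_class = rep_len(as.character(effect_class), n),
    delta_msi = rep_len(delta_msi, n),
    delta_mss = rep_len(delta_mss, n),
    baseline = rep_len(baseline, n),
    stringsAsFactors = FALSE
  )
  bad <- !(eff$effect_class %in% classes)
  if (any(bad)) stopf("unknown effect_class '%s'", eff$effect_class[bad][1L])
  chk <- function(cls, cond, msg) {
    viol <- eff$effect_class == cls & !cond
    if (any(viol)) stopf("effect_class '%s' requires %s (locus %s)",
                         cls, msg, eff$locus_id[viol][1L])
  }
  chk("null", eff$delta_msi == 0 & eff$delta_mss == 0, "zero deltas")
  chk("shared", eff$delta_msi == eff$delta_mss, "delta_msi == delta_mss")
  chk("msi_only", eff$delta_mss == 0 & eff$delta_msi != 0,
      "delta_mss == 0 and delta_msi != 0")
  chk("mss_only", eff$delta_msi == 0 & eff$delta_mss != 0,
      "delta_msi == 0 and delta_mss != 0")
  chk("both_diff",
      eff$delta_msi != 0 & eff$delta_mss != 0 &
        eff$delta_msi != eff$delta_mss,
      "two distinct nonzero deltas")
  eff
}

#' Simulate a paired tumor/normal cohort
#'
#' Generates a sample sheet with exactly two rows (one tumor, one normal)
#' per person. MSI status, tumor location, sex and age are person-level
#' attributes; tumor location depends on MSI status through
#' `p_right_given_msi` / `p_right_given_mss`. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a `cohort_config`.
#' @return sample-sheet data frame (see `read_sample_sheet()`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_persons
  if (n == 0L) {
    sheet <- data.frame(sample_id = character(0), person_id = character(0),
                        tissue = character(0), msi_status = character(0),
                        location = character(0), sex = character(0),
                        age = numeric(0), stage = integer(0),
                        stringsAsFactors = FALSE)
    return(sheet)
  }
  with_seed(sub_seed(config$seed, 1L), {
    person <- sprintf("P%03d", seq_len(n))
    msi <- rep("MSS", n)
    if (config$n_msi > 0L) msi[sample.int(n, config$n_msi)] <- "MSI"
    p_right <- ifelse(msi == "MSI", config$p_right_given_msi,
                      config$p_right_given_mss)
    location <- ifelse(stats::runif(n) < p_right, "right", "left")
    sex <- ifelse(stats::runif(n) < config$sex_split, "male", "female")
    age <- pmax(18, round(stats::rnorm(n, config$age_mean, config$age_sd), 1))
    stage <- sample(1:3, n, replace = TRUE, prob = config$stage_probs)
    sheet <- data.frame(
      sample_id = c(paste0(person, "_T"), paste0(person, "_N")),
      person_id = c(person, person),
      tissue = rep(c("tumor", "normal"), each = n),
      msi_status = c(msi, msi), location = c(location, location),
      sex = c(sex, sex), age = c(age, age), stage = c(stage, stage),
      stringsAsFactors = FALSE
    )
    sheet <- sheet[order(sheet$person_id, sheet$tissue, decreasing = c(FALSE, TRUE),
                         method = "radix"), ]
    rownames(sheet) <- NULL
    validate_sample_sheet(sheet)
  })
}

#' Simulate a beta-value matrix with planted effects
#'
#' Values are generated on the logit scale and back-transformed, which keeps
#' every beta strictly inside (0, 1):
#' `beta = plogis(qlogis(baseline) + tumor * delta_logit + person + resid)`,
#' where `delta_logit = qlogis(baseline + delta) - qlogis(baseline)` for the
#' person's MSI stratum, so that with zero noise the tumor-minus-normal
#' difference on the beta scale equals the planted delta exactly. The person
#' intercept is shared by a person's two samples, as the paired model
#' assumes.
#'
#' @param sheet sample sheet (nonempty, complete pairs).
#' @param effects effect table from `locus_effects()` (rows may be
#'   concatenated with `rbind`).
#' @param noise a `noise_spec`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `beta` (loci x samples matrix) and `truth` (data frame:
#'   `locus_id`, `effect_class`, `true_delta_msi`, `true_delta_mss`,
#'   `true_person_variance_fraction` — the expected person SS share in the
#'   paired model at this cohort size).
#' @export
simulate_beta_matrix <- function(sheet, effects, noise = noise_spec(),
                                 seed = NULL) {
  validate_sample_sheet(sheet)
  if (nrow(sheet) == 0L) stopf("sample sheet is empty")
  stopifnot(inherits(noise, "noise_spec"))
  if (any(effects$baseline <= 0 | effects$baseline >= 1)) {
    stopf("baselines must lie strictly inside (0,1)")
  }
  tgt_msi <- effects$baseline + effects$delta_msi
  tgt_mss <- effects$baseline + effects$delta_mss
  if (any(tgt_msi <= 0 | tgt_msi >= 1 | tgt_mss <= 0 | tgt_mss >= 1)) {
    stopf("baseline + delta must lie strictly inside (0,1)")
  }
  n_loci <- nrow(effects)
  n_samp <- nrow(sheet)
  persons <- unique(sheet$person_id)
  p_idx <- match(sheet$person_id, persons)
  is_tum <- sheet$tissue == "tumor"
  is_msi <- sheet$msi_status == "MSI"

  base_l <- stats::qlogis(effects$baseline)
  dl_msi <- stats::qlogis(tgt_msi) - base_l
  dl_mss <- stats::qlogis(tgt_mss) - base_l

  with_seed(sub_seed(seed, 2L), {
    person_int <- matrix(stats::rnorm(n_loci * length(persons), 0,
                                      noise$sigma_person),
                         nrow = n_loci)
    resid <- matrix(stats::rnorm(n_loci * n_samp, 0, noise$sigma_error),
                    nrow = n_loci)
    shift <- outer(dl_msi, as.numeric(is_tum & is_msi)) +
      outer(dl_mss, as.numeric(is_tum & !is_msi))
    lv <- base_l + shift + person_int[, p_idx, drop = FALSE] + resid
    beta <- stats::plogis(lv)
    dimnames(beta) <- list(effects$locus_id, sheet$sample_id)
    n_pairs <- length(persons)
    truth <- data.frame(
      locus_id = effects$locus_id,
      effect_class = effects$effect_class,
      true_delta_msi = effects$delta_msi,
      true_delta_mss = effects$delta_mss,
      true_person_variance_fraction =
        expected_person_share(noise$sigma_person, noise$sigma_error, n_pairs),
      stringsAsFactors = FALSE
    )
    list(beta = beta, truth = truth)
  })
}

# Expected person SS share in the paired model at n_pairs pairs (null locus).
expected_person_share <- function(sigma_person, sigma_error, n_pairs) {
  sp2 <- sigma_person^2
  se2 <- sigma_error^2
  if (sp2 + se2 == 0) return(0)
  a <- n_pairs - 1
  a * (2 * sp2 + se2) / (se2 + a * (2 * sp2 + 2 * se2))
}

#' Simulate a locus annotation table
#'
#' Assigns each locus one CpG-island relation category (by default in the
#' 450K chip proportions), a promoter flag, and zero or more synthetic gene
#' symbols.
#'
#' @param n_loci number of loci.
#' @param region_proportions named probabilities over the six region
#'   categories, summing to 1.
#' @param promoter_rate probability a locus is promoter-associated. The
#'   default 0.4 combined with the chip island share puts about 12.4% of
#'   loci in the promoter-island universe.
#' @param genes_per_locus probabilities that a locus maps to 0, 1, 2, ...
#'   gene symbols.
#' @param n_genes size of the synthetic gene universe symbols are drawn from.
#' @param locus_id optional locus identifiers.
#' @param seed integer seed.
#' @return annotation data frame (see `read_annotation()`).
#' @export
simulate_annotation <- function(n_loci,
                                region_proportions =
                                  chip450k_region_counts /
                                  sum(chip450k_region_counts),
                                promoter_rate = 0.4,
                                genes_per_locus = c(0.1, 0.7, 0.2),
                                n_genes = max(50L, ceiling(n_loci / 15)),
                                locus_id = NULL, seed = NULL) {
  if (abs(sum(region_proportions) - 1) > 1e-9) {
    stopf("region proportions must sum to 1")
  }
  regions <- normalize_region(names(region_proportions))
  if (anyNA(regions)) stopf("region proportions must be named by category")
  with_seed(sub_seed(seed, 3L), {
    region <- sample(as.character(regions), n_loci, replace = TRUE,
                     prob = region_proportions)
    promoter <- stats::runif(n_loci) < promoter_rate
    n_g <- sample(seq_along(genes_per_locus) - 1L, n_loci, replace = TRUE,
                  prob = genes_per_locus)
    universe <- sprintf("GENE%04d", seq_len(n_genes))
    genes <- vapply(n_g, function(k) {
      paste(sample(universe, k), collapse = ";")
    }, character(1))
    data.frame(locus_id = locus_id %||% sprintf("cg%06d", seq_len(n_loci)),
               gene_symbols = genes,
               region = factor(region, levels = region_levels()),
               promoter_associated = promoter, stringsAsFactors = FALSE)
  })
}

#' Simulate a log2 expression matrix with planted fold changes
#'
#' Generates log2-scale expression values for the samples in `sheet` with a
#' planted tumor/normal fold change per MSI stratum: the paired
#' tumor-minus-normal difference equals `log2(fold)` in expectation. Noise
#' follows the same person-intercept-plus-residual structure as the beta
#' simulator, on the log2 scale.
#'
#' @param sheet sample sheet (nonempty).
#' @param gene_effects data frame with columns `probe_id`, `gene`,
#'   `baseline_log2`, `fold_msi`, `fold_mss` (folds > 0; 1 means no change).
#' @param noise a `noise_spec` (SDs on the log2 scale).
#' @param seed integer seed.
#' @return numeric matrix, probes x samples.
#' @export
simulate_expression <- function(sheet, gene_effects,
                                noise = noise_spec(sigma_person = 0.25,
                                                   sigma_error = 0.3),
                                seed = NULL) {
  validate_sample_sheet(sheet)
  if (nrow(sheet) == 0L) stopf("sample sheet is empty")
  if (any(gene_effects$fold_msi <= 0 | gene_effects$fold_mss <= 0)) {
    stopf("fold changes must be positive")
  }
  n_p <- nrow(gene_effects)
  n_s <- nrow(sheet)
  persons <- unique(sheet$person_id)
  p_idx <- match(sheet$person_id, persons)
  is_tum <- sheet$tissue == "tumor"
  is_msi <- sheet$msi_status == "MSI"
  with_seed(sub_seed(seed, 4L), {
    person_int <- matrix(stats::rnorm(n_p * length(persons), 0,
                                      noise$sigma_person), nrow = n_p)
    resid <- matrix(stats::rnorm(n_p * n_s, 0, noise$sigma_error), nrow = n_p)
    shift <- outer(log2(gene_effects$fold_msi), as.numeric(is_tum & is_msi)) +
      outer(log2(gene_effects$fold_mss), as.numeric(is_tum & !is_msi))
    expr <- gene_effects$baseline_log2 + shift +
      person_int[, p_idx, drop = FALSE] + resid
    dimnames(expr) <- list(gene_effects$probe_id, sheet$sample_id)
    expr
  })
}
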