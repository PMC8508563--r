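# Cohort characteristic statistics: subgroup proportions, contingency-table
# association tests, and one-way ANOVA for continuous variables.

#' Proportion of a subgroup meeting a condition
#'
#' Computes `100 * sum(condition & subgroup) / sum(subgroup)`. The full
#' precision value is kept; a display value rounded half-up to
#' `display_digits` digits is attached (cohort percentages are convention-
#' ally printed at integer precision).
#'
#' @param condition logical vector (NAs treated as FALSE).
#' @param subgroup logical vector selecting the denominator; default all.
#' @param display_digits digits for the rounded display value.
#' @return list with `pct` (full precision), `display` (rounded half-up),
#'   `n_condition`, `n_subgroup` and `flag` (`"empty_subgroup"` when the
#'   denominator is empty, with NA percentages).
#' @export
group_proportion <- function(condition, subgroup = NULL,
                             display_digits = 0) {
  condition <- condition %in% TRUE
  subgroup <- if (is.null(subgroup)) rep(TRUE, length(condition)) else
    subgroup %in% TRUE
  stopifnot(length(condition) == length(subgroup))
  n_sub <- sum(subgroup)
  if (n_sub == 0L) {
    return(list(pct = NA_real_, display = NA_real_, n_condition = 0L,
                n_subgroup = 0L, flag = "empty_subgroup"))
  }
  n_cond <- sum(condition & subgroup)
  pct <- 100 * n_cond / n_sub
  list(pct = pct, display = round_half_up(pct, display_digits),
       n_condition = n_cond, n_subgroup = n_sub, flag = "")
}

#' Association test for a contingency table
#'
#' @param table matrix of nonnegative integer counts (at least 2x2).
#' @param method `"pearson"` (uncorrected chi-square, the default),
#'   `"yates"` (continuity-corrected chi-square, 2x2 only) or `"fisher"`
#'   (exact test, 2x2 only).
#' @return list with `statistic` (NA for fisher), `p`, `df` (chi-square
#'   methods), `method` and `flag` (`"degenerate"` for tables with a zero
#'   margin, where the chi-square statistic is undefined).
#' @export
association_test <- function(table, method = c("pearson", "yates",
                                               "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stopf("counts must be nonnegative integers")
  }
  if (nrow(table) < 2L || ncol(table) < 2L || sum(table) == 0) {
    stopf("need at least a 2x2 table with positive total")
  }
  if (method %in% c("yates", "fisher") &&
      (nrow(table) != 2L || ncol(table) != 2L)) {
    stopf("method '%s' supports 2x2 tables only", method)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, df = NA_integer_,
                method = method, flag = "degenerate"))
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(table)
    return(list(statistic = NA_real_, p = ft$p.value, df = NA_integer_,
                method = method, flag = ""))
  }
  ct <- suppressWarnings(stats::chisq.test(table,
                                           correct = (method == "yates")))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), method = method, flag = "")
}

#' One-way ANOVA across groups for a continuous variable
#'
#' Standard one-way analysis of variance; with two groups the F statistic
#' equals the square of the pooled-variance two-sample t statistic.
#'
#' @param values numeric vector.
#' @param group grouping vector (coerced to factor).
#' @return list with `f`, `p`, `df1`, `df2`, per-group `means` and `sds`,
#'   and `flag` (`"small_group"` when some group has fewer than 2 values).
#' @export
continuous_group_test <- function(values, group) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- factor(group[ok])
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  sizes <- table(group)
  flag <- if (any(sizes < 2L)) "small_group" else ""
  fit <- stats::anova(stats::lm(values ~ group))
  list(f = fit$`F value`[1L], p = fit$`Pr(>F)`[1L], df1 = fit$Df[1L],
       df2 = fit$Df[2L],
       means = tapply(values, group, mean), sds = tapply(values, group, sd),
       flag = flag)
}

#' Cohort characteristics table
#'
#' Patient-characteristics summary comparing MSS and MSI persons:
#' counts per category for the categorical variables (sex, location,
#' stage), mean (SD) for age, with an association p-value per
#' characteristic (Pearson chi-square for categorical rows, one-way ANOVA
#' for age).
#'
#' @param sheet sample-sheet data frame (one row per sample; person-level
#'   rows are deduplicated internally).
#' @param method association test method for the categorical rows.
#' @return data frame with columns `characteristic`, `category`, `mss`,
#'   `msi`, `p`.
#' @export
cohort_table <- function(sheet, method = "pearson") {
  validate_sample_sheet(sheet)
  per <- sheet[!duplicated(sheet$person_id), , drop = FALSE]
  msi <- factor(per$msi_status, levels = c("MSS", "MSI"))
  rows <- list()
  for (var in c("sex", "location", "stage")) {
    v <- factor(per[[var]])
    tab <- table(v, msi)
    p <- if (nrow(tab) >= 2L && all(rowSums(tab) > 0)) {
      association_test(tab, method)$p
    } else NA_real_
    for (i in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = var, category = rownames(tab)[i],
        mss = as.integer(tab[i, "MSS"]), msi = as.integer(tab[i, "MSI"]),
        p = if (i == 1L) p else NA_real_, stringsAsFactors = FALSE)
    }
  }
  age <- continuous_group_test(per$age, msi)
  rows[[length(rows) + 1L]] <- data.frame(
    characteristic = "age", category = "mean (SD)",
    mss = round(age$means[["MSS"]], 2), msi = round(age$means[["MSI"]], 2),
    p = age$p, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
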