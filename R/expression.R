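# Paired expression analysis on log2-scale matrices: per-probe fold changes
# with t-based confidence intervals under the signed-fold convention,
# the tumor-by-MSI interaction scan, and gene-set average folds.

#' Signed fold change from a ratio
#'
#' Maps a positive expression ratio `r` to the signed convention used in
#' microarray reporting: `r` itself when `r >= 1`, and `-1/r` (a negative
#' fold of magnitude >= 1) when `r < 1`. Monotone in `r`, so confidence
#' bounds can be mapped through it.
#'
#' @param r positive ratio(s).
#' @return signed fold change(s), `|fold| >= 1`.
#' @export
signed_fold <- function(r) {
  if (any(r <= 0, na.rm = TRUE)) stopf("ratios must be positive")
  ifelse(r >= 1, r, -1 / r)
}

fold_from_log2 <- function(d, se, df, conf_level) {
  if (is.na(se) || se == 0 || df < 1) {
    ci <- c(d, d)
    flag <- if (is.na(se) || df < 1) "insufficient_data" else "degenerate_ci"
  } else {
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- d + c(-1, 1) * tq * se
    flag <- ""
  }
  list(fold = signed_fold(2^d), ci_low = signed_fold(2^ci[1L]),
       ci_high = signed_fold(2^ci[2L]), log2_diff = d, flag = flag)
}

#' Paired tumor/normal fold change with confidence interval
#'
#' For each probe, computes the mean paired log2 difference `d` (tumor minus
#' normal) over complete pairs in the requested group, a t-based
#' `conf_level` interval on `d`, and back-transforms both through
#' [signed_fold()].
#'
#' @param expr numeric matrix of log2 expression values, probes x samples
#'   (sample IDs as column names).
#' @param sheet sample-sheet data frame covering the expression samples;
#'   samples without expression columns are ignored (incomplete pairs are
#'   dropped).
#' @param group `"all"`, `"MSI"` or `"MSS"`.
#' @param conf_level confidence level (default 0.95).
#' @return data frame with one row per probe: `id`, `group`, `n_pairs`,
#'   `fold`, `ci_low`, `ci_high`, `log2_diff`, `flag`. Probes with fewer
#'   than 2 complete pairs are flagged, not dropped.
#' @export
paired_fold_change <- function(expr, sheet, group = c("all", "MSI", "MSS"),
                               conf_level = 0.95) {
  group <- match.arg(group)
  d_mat <- paired_log2_diffs(expr, sheet, group)
  rows <- lapply(seq_len(nrow(d_mat)), function(i) {
    d <- d_mat[i, ]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2L) {
      return(data.frame(id = rownames(d_mat)[i], group = group, n_pairs = n,
                        fold = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, log2_diff = NA_real_,
                        flag = "insufficient_pairs",
                        stringsAsFactors = FALSE))
    }
    fc <- fold_from_log2(mean(d), stats::sd(d) / sqrt(n), n - 1L, conf_level)
    data.frame(id = rownames(d_mat)[i], group = group, n_pairs = n,
               fold = fc$fold, ci_low = fc$ci_low, ci_high = fc$ci_high,
               log2_diff = fc$log2_diff, flag = fc$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Matrix of paired tumor-minus-normal log2 differences (probes x persons)
# for the persons in `group` whose both samples have expression columns.
paired_log2_diffs <- function(expr, sheet, group) {
  validate_sample_sheet(sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(expr), , drop = FALSE]
  if (group != "all") {
    sheet <- sheet[sheet$msi_status == group, , drop = FALSE]
  }
  pairing <- validate_pairing(sheet)
  if (nrow(pairing) == 0L) stopf("no complete pairs in group '%s'", group)
  d <- expr[, pairing$tumor_sample, drop = FALSE] -
    expr[, pairing$normal_sample, drop = FALSE]
  colnames(d) <- pairing$person_id
  if (is.null(rownames(d))) rownames(d) <- as.character(seq_len(nrow(d)))
  d
}

#' Tumor-by-MSI interaction scan on expression data
#'
#' Applies the tumor-by-MSI interaction ANOVA (see [genomewide_scan()]) to a
#' log2 expression matrix and flags probes whose interaction p-value falls
#' below `alpha` (unadjusted).
#'
#' @param expr log2 expression matrix, probes x samples.
#' @param sheet sample-sheet data frame.
#' @param alpha per-probe significance threshold (default 0.05).
#' @return the `meth_scan` data frame with an extra logical column
#'   `significant`.
#' @export
expression_interaction_scan <- function(expr, sheet, alpha = 0.05) {
  sheet <- sheet[sheet$sample_id %in% colnames(expr), , drop = FALSE]
  scan <- genomewide_scan(expr, sheet, model = "interaction")
  scan$significant <- !is.na(scan$p_interaction) & scan$p_interaction < alpha
  scan
}

#' Average fold change of a gene set
#'
#' Pools the paired tumor-minus-normal log2 differences of every probe in
#' the set (equal weights across probes and pairs), forms a t-based
#' confidence interval on the pooled mean, and back-transforms through
#' [signed_fold()].
#'
#' @param expr log2 expression matrix, probes x samples.
#' @param probes character vector of probe IDs in the set (must be
#'   nonempty and present in `expr`).
#' @param sheet sample-sheet data frame.
#' @param group `"all"`, `"MSI"` or `"MSS"`.
#' @param conf_level confidence level.
#' @return one-row data frame like [paired_fold_change()] with `id` set to
#'   `"geneset"` and `n_obs` the number of pooled probe-by-pair
#'   differences.
#' @export
geneset_average_fold <- function(expr, probes, sheet,
                                 group = c("all", "MSI", "MSS"),
                                 conf_level = 0.95) {
  group <- match.arg(group)
  if (length(probes) == 0L) stopf("gene set is empty")
  missing <- setdiff(probes, rownames(expr))
  if (length(missing) > 0L) {
    stopf("probe(s) not in expression matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  d_mat <- paired_log2_diffs(expr[probes, , drop = FALSE], sheet, group)
  d <- as.vector(d_mat)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) {
    return(data.frame(id = "geneset", group = group, n_obs = n,
                      fold = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      log2_diff = NA_real_, flag = "insufficient_pairs",
                      stringsAsFactors = FALSE))
  }
  fc <- fold_from_log2(mean(d), stats::sd(d) / sqrt(n), n - 1L, conf_level)
  data.frame(id = "geneset", group = group, n_obs = n, fold = fc$fold,
             ci_low = fc$ci_low, ci_high = fc$ci_high,
             log2_diff = fc$log2_diff, flag = fc$flag,
             stringsAsFactors = FALSE)
}
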