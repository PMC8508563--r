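# DML calling and classification: BH correction, FDR + magnitude filter,
# the three-set interaction categories, Venn arithmetic, region tabulation
# and the promoter-island Bonferroni filter.

#' Thresholds for DML calling
#'
#' @param q_dml FDR level for the stratified (within-MSI, within-MSS) DML
#'   calls (default 0.001).
#' @param q_interaction FDR level for the tumor-by-MSI interaction term
#'   (default 0.05).
#' @param min_abs_delta minimum absolute tumor-minus-normal delta beta
#'   (default 0.2, i.e. a 20% methylation difference).
#' @param bonferroni_alpha family-wise level for the strong-interaction
#'   promoter-island list (default 0.05).
#' @return object of class `dml_thresholds`.
#' @export
dml_thresholds <- function(q_dml = 0.001, q_interaction = 0.05,
                           min_abs_delta = 0.2, bonferroni_alpha = 0.05) {
  vals <- c(q_dml, q_interaction, min_abs_delta, bonferroni_alpha)
  if (any(vals <= 0 | vals > 1)) stopf("thresholds must lie in (0, 1]")
  structure(list(q_dml = q_dml, q_interaction = q_interaction,
                 min_abs_delta = min_abs_delta,
                 bonferroni_alpha = bonferroni_alpha),
            class = "dml_thresholds")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment. Missing p-values are propagated
#' as missing and do not count toward the number of tests.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!is.numeric(pvals)) stopf("p-values must be numeric")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

#' Combined scan results for DML calling
#'
#' Convenience wrapper running the three scans the DML pipeline consumes:
#' paired scans within the MSI and MSS strata (giving the stratified
#' tumor-vs-normal p-values) and the tumor-by-MSI interaction scan, then
#' attaching BH q-values per contrast across all loci.
#'
#' @param mat beta-value matrix, loci x samples.
#' @param sheet sample-sheet data frame.
#' @param interaction_model `"interaction"` (default) or `"location"`; the
#'   latter adjusts the interaction p-value for tumor location.
#' @return data frame with one row per locus: `locus_id`, `delta_msi`,
#'   `delta_mss`, `delta_all`, `p_msi`, `p_mss`, `p_interaction`, `q_msi`,
#'   `q_mss`, `q_interaction`, `flags`.
#' @export
dml_scan_results <- function(mat, sheet,
                             interaction_model = c("interaction",
                                                   "location")) {
  interaction_model <- match.arg(interaction_model)
  s_msi <- genomewide_scan(mat, sheet, model = "paired", stratum = "MSI")
  s_mss <- genomewide_scan(mat, sheet, model = "paired", stratum = "MSS")
  s_int <- genomewide_scan(mat, sheet, model = interaction_model)
  stopifnot(identical(s_msi$locus_id, s_mss$locus_id),
            identical(s_msi$locus_id, s_int$locus_id))
  flags <- trimws(paste(s_msi$flags, s_mss$flags, s_int$flags))
  data.frame(
    locus_id = s_msi$locus_id,
    delta_msi = s_msi$delta_beta_msi,
    delta_mss = s_mss$delta_beta_mss,
    delta_all = s_int$delta_beta_all,
    p_msi = s_msi$p_tumor, p_mss = s_mss$p_tumor,
    p_interaction = s_int$p_interaction,
    q_msi = bh_fdr(s_msi$p_tumor), q_mss = bh_fdr(s_mss$p_tumor),
    q_interaction = bh_fdr(s_int$p_interaction),
    flags = flags, stringsAsFactors = FALSE
  )
}

#' Call differentially methylated loci in one stratum
#'
#' A locus is a DML when its stratified q-value is at most `q_dml` and the
#' absolute tumor-minus-normal delta beta is at least `min_abs_delta`.
#' Direction is hypermethylated for a positive delta, hypomethylated for a
#' negative one. Loci with missing q or delta (flagged upstream) are
#' excluded.
#'
#' @param results data frame from [dml_scan_results()] (columns `q_msi` /
#'   `delta_msi` etc.).
#' @param stratum `"msi"` or `"mss"`.
#' @param thresholds a [dml_thresholds()] object.
#' @return data frame `locus_id`, `delta`, `q`, `direction` for the called
#'   loci.
#' @export
call_dml <- function(results, stratum = c("msi", "mss"),
                     thresholds = dml_thresholds()) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(thresholds, "dml_thresholds"))
  q <- results[[paste0("q_", stratum)]]
  delta <- results[[paste0("delta_", stratum)]]
  if (is.null(q) || is.null(delta)) {
    stopf("results lack q_%s / delta_%s columns", stratum, stratum)
  }
  keep <- !is.na(q) & !is.na(delta) & q <= thresholds$q_dml &
    abs(delta) >= thresholds$min_abs_delta
  data.frame(locus_id = results$locus_id[keep], delta = delta[keep],
             q = q[keep],
             direction = ifelse(delta[keep] > 0, "hyper", "hypo"),
             stringsAsFactors = FALSE)
}

#' Interaction categories from the three membership sets
#'
#' Partitions the locus universe by membership in the MSI DML set, the MSS
#' DML set, and the interaction-significant set:
#' \describe{
#'   \item{A}{DML in both strata, no interaction — the tumor effect is
#'     shared and of similar magnitude.}
#'   \item{B}{MSI DML with interaction, not an MSS DML — the effect appears
#'     only with MSI.}
#'   \item{C}{DML in both strata with interaction — present in both, with
#'     different magnitude.}
#'   \item{D}{MSS DML with interaction, not an MSI DML — the effect appears
#'     only with MSS.}
#'   \item{none}{everything else.}
#' }
#'
#' @param msi_dml,mss_dml,interaction_set character vectors of locus IDs;
#'   each must be a subset of `universe`.
#' @param universe character vector of all tested locus IDs.
#' @return factor of categories (levels A, B, C, D, none), one per universe
#'   locus, named by locus ID.
#' @export
classify_interaction <- function(msi_dml, mss_dml, interaction_set,
                                 universe) {
  sets <- list(msi_dml = msi_dml, mss_dml = mss_dml,
               interaction = interaction_set)
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], universe)
    if (length(extra) > 0L) {
      stopf("%s contains loci outside the universe (e.g. '%s')", nm,
            extra[1L])
    }
  }
  in_msi <- universe %in% msi_dml
  in_mss <- universe %in% mss_dml
  in_int <- universe %in% interaction_set
  cat <- rep("none", length(universe))
  cat[in_msi & in_mss & !in_int] <- "A"
  cat[in_msi & !in_mss & in_int] <- "B"
  cat[in_msi & in_mss & in_int] <- "C"
  cat[!in_msi & in_mss & in_int] <- "D"
  factor(stats::setNames(cat, universe), levels = c("A", "B", "C", "D",
                                                    "none"))
}

#' Venn counts of two locus sets
#'
#' @param set_a,set_b character vectors.
#' @return named integer vector `only_a`, `only_b`, `shared`.
#' @export
venn_counts <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  c(only_a = length(a) - shared, only_b = length(b) - shared,
    shared = shared)
}

#' Venn arithmetic from printed set totals
#'
#' Recovers the exclusive region sizes of a two-set Venn diagram from the
#' two set sizes and the size of their intersection.
#'
#' @param n_a,n_b set sizes.
#' @param n_shared intersection size (`<= min(n_a, n_b)`).
#' @return named integer vector `only_a`, `only_b`, `shared`.
#' @export
venn_from_totals <- function(n_a, n_b, n_shared) {
  if (n_shared > min(n_a, n_b) || any(c(n_a, n_b, n_shared) < 0)) {
    stopf("invalid Venn totals")
  }
  c(only_a = n_a - n_shared, only_b = n_b - n_shared, shared = n_shared)
}

#' Tabulate DML by relation to CpG island
#'
#' Region table in the style of a chip-composition report: per region
#' category, the number of hypo- and hypermethylated DML, their total, the
#' percentage of all DML (2 decimal places), the number of loci on the chip
#' in that category and the percentage of the chip (2 decimal places). A
#' grand-total row is appended.
#'
#' @param locus_ids character vector of DML locus IDs.
#' @param directions `"hyper"`/`"hypo"` per locus.
#' @param annotation annotation data frame covering every DML locus.
#' @param chip_totals named vector of chip locus counts per region
#'   (default: the 450K composition, [chip450k_region_counts]).
#' @return data frame with columns `region`, `hypo`, `hyper`, `total`,
#'   `pct_dml`, `chip_count`, `pct_chip`.
#' @export
tabulate_regions <- function(locus_ids, directions, annotation,
                             chip_totals = chip450k_region_counts) {
  stopifnot(length(locus_ids) == length(directions))
  if (!all(directions %in% c("hyper", "hypo"))) {
    stopf("directions must be 'hyper' or 'hypo'")
  }
  idx <- match(locus_ids, annotation$locus_id)
  if (anyNA(idx)) {
    stopf("unannotated DML locus/loci: %s",
          paste(utils::head(locus_ids[is.na(idx)], 5), collapse = ", "))
  }
  names(chip_totals) <- as.character(normalize_region(names(chip_totals)))
  regions <- region_levels()
  region <- factor(as.character(annotation$region[idx]), levels = regions)
  hypo <- as.integer(table(region[directions == "hypo"]))
  hyper <- as.integer(table(region[directions == "hyper"]))
  total <- hypo + hyper
  grand <- sum(total)
  chip <- as.integer(chip_totals[regions])
  chip_grand <- sum(chip)
  pct_dml <- if (grand == 0) rep(0, length(regions)) else
    round_half_up(100 * total / grand, 2)
  pct_chip <- round_half_up(100 * chip / chip_grand, 2)
  out <- data.frame(region = c(regions, "Total"),
                    hypo = c(hypo, sum(hypo)), hyper = c(hyper, sum(hyper)),
                    total = c(total, grand),
                    pct_dml = c(pct_dml, if (grand == 0) 0 else 100),
                    chip_count = c(chip, chip_grand),
                    pct_chip = c(pct_chip, 100), stringsAsFactors = FALSE)
  out
}

#' Strong-interaction loci in promoter-associated CpG islands
#'
#' Restricts the tested universe to loci that are in a CpG island and
#' promoter-associated, applies a Bonferroni threshold
#' `bonferroni_alpha / n_filtered` to the interaction p-value over that
#' universe, and returns the surviving loci with their gene symbols and
#' direction of change.
#'
#' @param results data frame with `locus_id`, `p_interaction` and a delta
#'   column (`delta_all`, falling back to the larger-magnitude stratum
#'   delta) used for direction.
#' @param annotation annotation data frame with `region` and
#'   `promoter_associated`.
#' @param thresholds a [dml_thresholds()] object.
#' @return data frame `locus_id`, `p_interaction`, `bonferroni_p`,
#'   `direction`, `gene_symbols`, with attributes `n_universe` and
#'   `threshold`.
#' @export
promoter_island_filter <- function(results, annotation,
                                   thresholds = dml_thresholds()) {
  stopifnot(inherits(thresholds, "dml_thresholds"))
  uni_ids <- annotation$locus_id[annotation$region == "Island" &
                                   annotation$promoter_associated %in% TRUE]
  res <- results[results$locus_id %in% uni_ids, , drop = FALSE]
  m <- nrow(res)
  if (m == 0L) {
    warning("promoter-island universe is empty")
    out <- data.frame(locus_id = character(0), p_interaction = numeric(0),
                      bonferroni_p = numeric(0), direction = character(0),
                      gene_symbols = character(0), stringsAsFactors = FALSE)
    attr(out, "n_universe") <- 0L
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- thresholds$bonferroni_alpha / m
  delta <- res$delta_all
  if (is.null(delta)) {
    delta <- ifelse(abs(res$delta_msi) >= abs(res$delta_mss), res$delta_msi,
                    res$delta_mss)
  }
  keep <- !is.na(res$p_interaction) & res$p_interaction < thr
  ann_idx <- match(res$locus_id[keep], annotation$locus_id)
  out <- data.frame(
    locus_id = res$locus_id[keep],
    p_interaction = res$p_interaction[keep],
    bonferroni_p = pmin(1, res$p_interaction[keep] * m),
    direction = ifelse(delta[keep] > 0, "hyper", "hypo"),
    gene_symbols = annotation$gene_symbols[ann_idx],
    stringsAsFactors = FALSE
  )
  attr(out, "n_universe") <- m
  attr(out, "threshold") <- thr
  out
}

#' Build the full DML catalog
#'
#' Combines the stratified DML calls and the interaction set into the
#' per-locus catalog: membership booleans, per-stratum directions and the
#' interaction category.
#'
#' @param results data frame from [dml_scan_results()].
#' @param thresholds a [dml_thresholds()] object.
#' @return a `dml_catalog` data frame with columns `locus_id`,
#'   `in_msi_dml`, `in_mss_dml`, `in_interaction`, `direction_msi`,
#'   `direction_mss`, `category`, plus the q-value and delta columns.
#' @export
build_dml_catalog <- function(results, thresholds = dml_thresholds()) {
  msi <- call_dml(results, "msi", thresholds)
  mss <- call_dml(results, "mss", thresholds)
  in_int <- !is.na(results$q_interaction) &
    results$q_interaction <= thresholds$q_interaction
  category <- classify_interaction(msi$locus_id, mss$locus_id,
                                   results$locus_id[in_int],
                                   results$locus_id)
  out <- data.frame(
    locus_id = results$locus_id,
    in_msi_dml = results$locus_id %in% msi$locus_id,
    in_mss_dml = results$locus_id %in% mss$locus_id,
    in_interaction = in_int,
    direction_msi = ifelse(is.na(results$delta_msi), NA_character_,
                           ifelse(results$delta_msi > 0, "hyper", "hypo")),
    direction_mss = ifelse(is.na(results$delta_mss), NA_character_,
                           ifelse(results$delta_mss > 0, "hyper", "hypo")),
    category = as.character(category),
    q_msi = results$q_msi, q_mss = results$q_mss,
    q_interaction = results$q_interaction,
    delta_msi = results$delta_msi, delta_mss = results$delta_mss,
    stringsAsFactors = FALSE
  )
  structure(out, thresholds = thresholds,
            class = c("dml_catalog", "data.frame"))
}

#' @export
print.dml_catalog <- function(x, ...) {
  cat(sprintf("DML catalog: %d loci\n", nrow(x)))
  cat(sprintf("MSI DML: %d | MSS DML: %d | interaction: %d\n",
              sum(x$in_msi_dml), sum(x$in_mss_dml), sum(x$in_interaction)))
  print(table(category = x$category))
  invisible(x)
}
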