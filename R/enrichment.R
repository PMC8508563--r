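# Gene-category enrichment: chi-square comparison of a category's share of
# the significant gene list against its share of the chip, scored as
# -log10(p).

#' Chi-square enrichment score per gene category
#'
#' For each category, compares the proportion of significant genes falling
#' in the category with the proportion of chip genes in the category via a
#' 2x2 Pearson chi-square (no continuity correction) on
#' `[sig-in, sig-out; chip-in, chip-out]`. By default the chip background
#' includes the significant genes; set `exclude_sig_from_background` to
#' compare against the non-significant remainder instead. The enrichment
#' score is `-log10(p)`; categories are ranked by descending score.
#'
#' @param sig_genes character vector of significant gene symbols.
#'   Genes outside `chip_universe` are dropped with a warning.
#' @param category_map named list mapping category IDs to character vectors
#'   of gene symbols (intersected with the universe).
#' @param chip_universe character vector of all gene symbols on the chip.
#' @param exclude_sig_from_background logical; see above.
#' @return data frame `category`, `n_sig_in`, `n_sig`, `n_chip_in`,
#'   `n_chip`, `statistic`, `p`, `score`, sorted by `score` descending;
#'   degenerate categories (empty, or spanning the whole chip) carry NA
#'   statistics and a `flag`.
#' @export
enrichment_score <- function(sig_genes, category_map, chip_universe,
                             exclude_sig_from_background = FALSE) {
  chip <- unique(chip_universe)
  sig <- unique(sig_genes)
  outside <- setdiff(sig, chip)
  if (length(outside) > 0L) {
    warning(sprintf("%d significant gene(s) not on the chip were dropped",
                    length(outside)))
    sig <- intersect(sig, chip)
  }
  bg <- if (exclude_sig_from_background) setdiff(chip, sig) else chip
  n_sig <- length(sig)
  n_bg <- length(bg)
  rows <- lapply(names(category_map), function(cat_id) {
    cat_genes <- intersect(unique(category_map[[cat_id]]), chip)
    a <- length(intersect(sig, cat_genes))          # sig in category
    b <- n_sig - a
    cc <- length(intersect(bg, cat_genes))          # background in category
    d <- n_bg - cc
    flag <- ""
    if (n_sig == 0L) flag <- "empty_significant_list"
    else if (length(cat_genes) == 0L) flag <- "empty_category"
    else if (cc == n_bg && a == n_sig) flag <- "category_covers_chip"
    stat <- p <- score <- NA_real_
    if (!nzchar(flag)) {
      tab <- matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
      if (is.nan(stat) || is.na(p)) {
        flag <- "degenerate_table"
        stat <- p <- NA_real_
      } else {
        score <- -log10(max(p, .Machine$double.xmin))
      }
    }
    data.frame(category = cat_id, n_sig_in = a, n_sig = n_sig,
               n_chip_in = cc, n_chip = n_bg, statistic = stat, p = p,
               score = score, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-replace(out$score, is.na(out$score), -Inf), out$category), ,
      drop = FALSE]
}

#' Map significant loci to significant genes
#'
#' A gene is significant when at least one of its annotated loci is in the
#' significant locus list.
#'
#' @param locus_ids character vector of significant locus IDs.
#' @param annotation annotation data frame (`locus_id`, `gene_symbols`).
#' @return character vector of unique gene symbols.
#' @export
genes_for_loci <- function(locus_ids, annotation) {
  idx <- match(locus_ids, annotation$locus_id)
  if (anyNA(idx)) {
    stopf("unannotated locus/loci: %s",
          paste(utils::head(locus_ids[is.na(idx)], 5), collapse = ", "))
  }
  sort(unique(unlist(split_genes(annotation$gene_symbols[idx]))))
}

#' Read a category map from two-column TSV
#'
#' Expects columns `category_id` and `gene` (one gene per row).
#'
#' @param path file path.
#' @return named list of gene-symbol vectors.
#' @export
read_category_map <- function(path) {
  check_no_ragged(path, sep = "\t")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("category_id", "gene") %in% names(df))) {
    stopf("category map needs columns 'category_id' and 'gene'")
  }
  split(df$gene, df$category_id)
}
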