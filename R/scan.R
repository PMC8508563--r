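# Genome-wide per-locus scan: one ANOVA per matrix row, vectorised through
# the shared design projectors. Loci with missing values fall back to a
# per-locus fit with pairwise deletion; loci failing preconditions are
# flagged, never dropped.

scan_result_columns <- c("locus_id", "n_eff", "delta_beta_all",
                         "delta_beta_msi", "delta_beta_mss", "p_tumor",
                         "p_msi", "p_interaction", "p_location",
                         "p_tumor_x_location", "share_person",
                         "sigma2_person", "flags")

#' Genome-wide per-locus ANOVA scan
#'
#' Runs one of the per-locus models (see [locus_anova()]) across every row
#' of a value matrix. The design is shared across loci, so complete loci are
#' fitted by matrix algebra in one pass; loci with missing values are
#' refitted individually under pairwise deletion. Output rows match the
#' input locus order; loci that cannot be fitted carry a flag and NA
#' statistics.
#'
#' @param mat numeric matrix, loci x samples, with sample IDs as column
#'   names covering the samples the design needs.
#' @param sheet sample-sheet data frame.
#' @param model `"paired"`, `"interaction"` or `"location"`.
#' @param stratum optional MSI level restricting the scan to that subgroup's
#'   pairs (typically used with the paired model).
#' @return a `meth_scan` data frame with columns `locus_id`, `n_eff`,
#'   `delta_beta_all`, `delta_beta_msi`, `delta_beta_mss`, `p_tumor`,
#'   `p_msi`, `p_interaction`, `p_location`, `p_tumor_x_location`,
#'   `share_person` (person share of total SS, paired model) and `flags`;
#'   inapplicable columns are NA. Attributes `model` and `stratum` record
#'   the design.
#' @export
genomewide_scan <- function(mat, sheet,
                            model = c("paired", "interaction", "location"),
                            stratum = NULL) {
  model <- match.arg(model)
  validate_sample_sheet(sheet)
  if (!is.null(stratum)) {
    stopifnot(stratum %in% c("MSI", "MSS"))
    sheet <- sheet[sheet$msi_status == stratum, , drop = FALSE]
  }
  if (model == "location" && all(is.na(sheet$location))) {
    stopf("model 'location' needs a location column with values")
  }
  if (model == "paired") {
    pairing <- validate_pairing(sheet)
    sheet <- sheet[sheet$person_id %in% pairing$person_id, , drop = FALSE]
  }
  missing_cols <- setdiff(sheet$sample_id, colnames(mat))
  if (length(missing_cols) > 0L) {
    stopf("matrix lacks sample column(s): %s",
          paste(utils::head(missing_cols, 3), collapse = ", "))
  }
  y_all <- mat[, sheet$sample_id, drop = FALSE]
  n_loci <- nrow(y_all)
  out <- data.frame(
    locus_id = rownames(mat) %||% as.character(seq_len(n_loci)),
    n_eff = NA_integer_, delta_beta_all = NA_real_,
    delta_beta_msi = NA_real_, delta_beta_mss = NA_real_,
    p_tumor = NA_real_, p_msi = NA_real_, p_interaction = NA_real_,
    p_location = NA_real_, p_tumor_x_location = NA_real_,
    share_person = NA_real_, sigma2_person = NA_real_, flags = "",
    stringsAsFactors = FALSE
  )
  if (n_loci == 0L) return(as_meth_scan(out, model, stratum))

  # deltas over complete pairs, vectorised (pairwise deletion per locus)
  pairing_all <- validate_pairing(sheet)
  if (nrow(pairing_all) > 0L) {
    d <- y_all[, pairing_all$tumor_sample, drop = FALSE] -
      y_all[, pairing_all$normal_sample, drop = FALSE]
    msi_p <- sheet$msi_status[match(pairing_all$person_id, sheet$person_id)]
    out$delta_beta_all <- rowMeans(d, na.rm = TRUE)
    if (any(msi_p == "MSI")) {
      out$delta_beta_msi <- rowMeans(d[, msi_p == "MSI", drop = FALSE],
                                     na.rm = TRUE)
    }
    if (any(msi_p == "MSS")) {
      out$delta_beta_mss <- rowMeans(d[, msi_p == "MSS", drop = FALSE],
                                     na.rm = TRUE)
    }
    out$delta_beta_all[is.nan(out$delta_beta_all)] <- NA_real_
    out$delta_beta_msi[is.nan(out$delta_beta_msi)] <- NA_real_
    out$delta_beta_mss[is.nan(out$delta_beta_mss)] <- NA_real_
  }

  fill_p <- function(out, i, pmat) {
    for (col in colnames(pmat)) {
      tgt <- switch(col, tumor = "p_tumor", msi = "p_msi",
                    `tumor:msi` = "p_interaction", location = "p_location",
                    `tumor:location` = "p_tumor_x_location", person = NULL)
      if (!is.null(tgt)) out[[tgt]][i] <- pmat[, col]
    }
    out
  }

  complete <- rowSums(is.na(y_all)) == 0L
  if (any(complete)) {
    data <- build_factors(sheet)
    labels <- model_term_labels(model)
    pr <- prune_terms(labels, data)
    drop_flag <- if (length(pr$dropped) > 0L) {
      paste0("dropped:", pr$dropped, collapse = ";")
    } else ""
    if (!("tumor" %in% pr$kept) ||
        (model == "paired" && nrow(pairing_all) < 2L)) {
      out$flags[complete] <- trimws(paste(drop_flag, "inestimable"), "left")
    } else {
      ps <- projector_set(data, pr$kept)
      res <- project_anova(y_all[complete, , drop = FALSE], ps)
      idx <- which(complete)
      for (col in colnames(res$p)) {
        tgt <- switch(col, tumor = "p_tumor", msi = "p_msi",
                      `tumor:msi` = "p_interaction",
                      location = "p_location",
                      `tumor:location` = "p_tumor_x_location", person = NA)
        if (!is.na(tgt) && !is.null(tgt)) out[[tgt]][idx] <- res$p[, col]
      }
      out$n_eff[idx] <- if (model == "paired") nrow(pairing_all)
                        else nrow(sheet)
      if (model == "paired" && "person" %in% colnames(res$ss)) {
        tot <- res$ss[, "tumor"] + res$ss[, "person"] + res$rss
        out$share_person[idx] <- ifelse(tot < 1e-12, 0,
                                        res$ss[, "person"] / tot)
        df_p <- res$df[["person"]]
        ms_p <- res$ss[, "person"] / df_p
        out$sigma2_person[idx] <- pmax(0, (ms_p - res$ms_error) / 2)
      }
      if (nzchar(drop_flag)) out$flags[idx] <- drop_flag
      zero_rss <- res$rss == 0
      if (any(zero_rss)) {
        out$flags[idx[zero_rss]] <- trimws(paste(out$flags[idx[zero_rss]],
                                                 "zero_residual"), "left")
      }
    }
  }
  for (i in which(!complete)) {
    fit <- locus_anova(y_all[i, ], sheet, model = model)
    if (!is.null(fit$table)) {
      pv <- matrix(fit$table$p[-nrow(fit$table)], nrow = 1L,
                   dimnames = list(NULL, fit$table$term[-nrow(fit$table)]))
      out <- fill_p(out, i, pv)
      if (model == "paired") {
        dec <- variance_decomposition(fit)
        out$share_person[i] <- dec$share[dec$term == "person"]
        out$sigma2_person[i] <- fit$sigma2_person
      }
    }
    out$n_eff[i] <- if (model == "paired") fit$n_pairs else fit$n
    if (length(fit$flags) > 0L) out$flags[i] <- paste(fit$flags,
                                                     collapse = ";")
  }
  as_meth_scan(out, model, stratum)
}

as_meth_scan <- function(df, model, stratum) {
  structure(df, model = model, stratum = stratum %||% "all",
            class = c("meth_scan", "data.frame"))
}

#' @export
print.meth_scan <- function(x, ...) {
  cat(sprintf("Genome-wide scan: %d loci, model '%s', stratum '%s'\n",
              nrow(x), attr(x, "model"), attr(x, "stratum")))
  flagged <- sum(nzchar(x$flags))
  if (flagged > 0L) cat(sprintf("%d flagged loci\n", flagged))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... %d more loci\n", nrow(x) - 10L))
  invisible(x)
}

#' Write scan results as TSV
#'
#' @param scan a `meth_scan` data frame.
#' @param path output file path.
#' @export
write_scan_results <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
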