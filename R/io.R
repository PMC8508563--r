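# Readers and writers for the plain-text interchange formats: beta matrices
# and annotations as TSV, sample sheets as CSV. Missing values are "NA";
# ragged rows are rejected.

check_no_ragged <- function(path, sep) {
  n <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  n <- n[!is.na(n)]
  if (length(unique(n)) > 1L) {
    stopf("ragged rows in '%s': field counts %s", path,
          paste(unique(n), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read and write a beta-value matrix
#'
#' The on-disk format is tab-separated text: a header row of sample IDs, then
#' one row per locus whose first column (`locus_id`) is the locus identifier.
#' Values must lie in `[0, 1]` or be `NA`. Round-tripping preserves values to
#' at least 12 significant digits.
#'
#' @param path file path.
#' @return `read_beta_matrix()` returns a numeric matrix with locus IDs as
#'   row names and sample IDs as column names.
#' @export
read_beta_matrix <- function(path) {
  check_no_ragged(path, sep = "\t")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA,
                          na.strings = "NA", stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stopf("'%s' has no columns", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stopf("duplicate locus ID '%s' in '%s'", ids[duplicated(ids)][1L], path)
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample ID '%s' in '%s'",
          sample_ids[duplicated(sample_ids)][1L], path)
  }
  if (nrow(df) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = length(sample_ids),
                  dimnames = list(character(0), sample_ids)))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("beta value out of [0,1] at locus '%s', sample '%s' in '%s'",
          ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]], path)
  }
  vals
}

#' @param mat numeric matrix of beta values (loci as rows).
#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) && nrow(mat) > 0L) {
    stopf("matrix must have locus IDs as row names")
  }
  df <- data.frame(locus_id = rownames(mat) %||% character(0),
                   check.names = FALSE)
  for (j in seq_len(ncol(mat))) {
    df[[colnames(mat)[j]]] <- format(mat[, j], digits = 15, trim = TRUE,
                                     scientific = FALSE)
  }
  df[df == "NA"] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

sheet_required_cols <- c("sample_id", "person_id", "tissue", "msi_status",
                         "location", "sex", "age", "stage")

validate_sample_sheet <- function(sheet) {
  miss <- setdiff(sheet_required_cols, names(sheet))
  if (length(miss) > 0L) {
    stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stopf("duplicate sample_id '%s'",
          sheet$sample_id[duplicated(sheet$sample_id)][1L])
  }
  chk_enum <- function(col, levels) {
    bad <- !is.na(sheet[[col]]) & !(sheet[[col]] %in% levels)
    if (any(bad)) {
      stopf("invalid %s value '%s'", col, sheet[[col]][bad][1L])
    }
  }
  chk_enum("tissue", c("tumor", "normal"))
  chk_enum("msi_status", c("MSI", "MSS"))
  chk_enum("location", c("left", "right"))
  chk_enum("sex", c("male", "female"))
  # person-level attributes must be constant within person
  for (col in c("msi_status", "location", "sex", "age")) {
    n_per <- tapply(sheet[[col]], sheet$person_id,
                    function(v) length(unique(v[!is.na(v)])))
    if (any(n_per > 1L, na.rm = TRUE)) {
      stopf("%s varies within person '%s'", col,
            names(n_per)[which(n_per > 1L)[1L]])
    }
  }
  invisible(sheet)
}

#' Read and write a sample sheet
#'
#' Comma-separated metadata with one row per sample and columns `sample_id`,
#' `person_id`, `tissue` (tumor/normal), `msi_status` (MSI/MSS), `location`
#' (left/right), `sex`, `age`, `stage`. Person-level attributes must be
#' constant within a person.
#'
#' @param path file path.
#' @return a data frame with the validated columns.
#' @export
read_sample_sheet <- function(path) {
  check_no_ragged(path, sep = ",")
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$person_id <- as.character(sheet$person_id)
  validate_sample_sheet(sheet)
}

#' @param sheet sample-sheet data frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a locus annotation table
#'
#' Tab-separated with columns `locus_id`, `gene_symbols` (semicolon-separated
#' list, possibly empty), `region` (Island, N_Shelf, N_Shore, S_Shelf,
#' S_Shore, OpenSea; "Deep Sea" is accepted as an alias of OpenSea) and
#' `promoter_associated` (TRUE/FALSE).
#'
#' @param path file path.
#' @return a data frame with one row per locus; `region` is a factor over the
#'   six canonical categories.
#' @export
read_annotation <- function(path) {
  check_no_ragged(path, sep = "\t")
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("locus_id", "gene_symbols", "region", "promoter_associated")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ann$locus_id)) {
    stopf("duplicate locus_id '%s' in annotation",
          ann$locus_id[duplicated(ann$locus_id)][1L])
  }
  ann$region <- normalize_region(ann$region)
  ann$promoter_associated <- as.logical(ann$promoter_associated)
  ann$gene_symbols <- ifelse(is.na(ann$gene_symbols), "", ann$gene_symbols)
  ann
}

#' @param ann annotation data frame.
#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# Split semicolon-separated gene symbols into a list of character vectors.
split_genes <- function(gene_symbols) {
  out <- strsplit(as.character(gene_symbols), ";", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Tumor/normal pairing from a sample sheet
#'
#' Maps each person to their tumor and normal sample. Persons with only one
#' half of the pair are excluded from the map and listed in the `incomplete`
#' attribute; a person with two samples of the same tissue is a data
#' integrity error.
#'
#' @param sheet sample-sheet data frame.
#' @return data frame with columns `person_id`, `tumor_sample`,
#'   `normal_sample` (complete pairs only), with attribute `incomplete`
#'   naming persons lacking a half.
#' @export
validate_pairing <- function(sheet) {
  validate_sample_sheet(sheet)
  persons <- unique(sheet$person_id)
  tum <- nor <- character(length(persons))
  incomplete <- character(0)
  for (i in seq_along(persons)) {
    rows <- sheet[sheet$person_id == persons[i], ]
    t_s <- rows$sample_id[rows$tissue == "tumor"]
    n_s <- rows$sample_id[rows$tissue == "normal"]
    if (length(t_s) > 1L || length(n_s) > 1L) {
      stopf("person '%s' has duplicated %s samples", persons[i],
            if (length(t_s) > 1L) "tumor" else "normal")
    }
    if (length(t_s) == 1L && length(n_s) == 1L) {
      tum[i] <- t_s
      nor[i] <- n_s
    } else {
      tum[i] <- NA_character_
      incomplete <- c(incomplete, persons[i])
    }
  }
  keep <- !is.na(tum)
  out <- data.frame(person_id = persons[keep], tumor_sample = tum[keep],
                    normal_sample = nor[keep], stringsAsFactors = FALSE)
  attr(out, "incomplete") <- incomplete
  out
}
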