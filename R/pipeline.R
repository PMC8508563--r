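# End-to-end pipeline surface: each stage reads/writes the plain-text
# interchange files, refuses to overwrite without `overwrite = TRUE`, and
# records a manifest with checksums and the thresholds used. The thin
# command-line wrapper in inst/scripts/msimeth dispatches onto these
# functions.

out_path <- function(dir, name, overwrite) {
  path <- file.path(dir, name)
  if (file.exists(path) && !overwrite) {
    stopf("output '%s' exists; pass overwrite = TRUE (or --force) to replace",
          path)
  }
  path
}

write_manifest <- function(dir, files, extra = list()) {
  manifest <- c(list(
    package = "msimeth",
    version = as.character(utils::packageVersion("msimeth")),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    })
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Default planted effect mix for the demo pipeline
#'
#' A locus panel dominated by null loci with all four non-null effect
#' classes represented, at tumor-minus-normal deltas around the 0.2
#' calling threshold (0.3 for single-stratum effects; 0.6 vs 0.3 for the
#' shared-but-different class).
#'
#' @param n_loci total number of loci.
#' @param prop named proportions per effect class (summing to 1).
#' @param seed integer seed for the baseline draw.
#' @return effect table as from [locus_effects()].
#' @export
default_locus_effects <- function(n_loci = 300,
                                  prop = c(null = 0.7, shared = 0.1,
                                           msi_only = 0.1, mss_only = 0.05,
                                           both_diff = 0.05),
                                  seed = NULL) {
  stopifnot(abs(sum(prop) - 1) < 1e-9)
  counts <- diff(round(cumsum(c(0, prop)) * n_loci))
  names(counts) <- names(prop)
  with_seed(sub_seed(seed, 5L), {
    base <- stats::runif(n_loci, 0.2, 0.4)
    parts <- list()
    off <- 0L
    for (cls in names(counts)) {
      k <- counts[[cls]]
      if (k == 0L) next
      idx <- off + seq_len(k)
      args <- switch(cls,
        null = list(delta_msi = 0, delta_mss = 0),
        shared = list(delta_msi = 0.3, delta_mss = 0.3),
        msi_only = list(delta_msi = 0.3, delta_mss = 0),
        mss_only = list(delta_msi = 0, delta_mss = 0.3),
        both_diff = list(delta_msi = 0.6, delta_mss = 0.3))
      parts[[cls]] <- locus_effects(k, effect_class = cls,
                                    delta_msi = args$delta_msi,
                                    delta_mss = args$delta_mss,
                                    baseline = base[idx],
                                    locus_id = sprintf("cg%06d", idx))
      off <- off + k
    }
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
}

#' Pipeline stage: simulate a study
#'
#' Writes a beta matrix (TSV), sample sheet (CSV), locus annotation (TSV),
#' ground-truth table (TSV), log2 expression matrix (TSV) and a
#' `manifest.json` with MD5 checksums into `outdir`. Deterministic for a
#' fixed `seed`.
#'
#' @param outdir output directory (created if missing).
#' @param config a [cohort_config()].
#' @param effects planted effect table; default [default_locus_effects()].
#' @param noise a [noise_spec()].
#' @param seed integer seed used for every stage.
#' @param overwrite replace existing outputs.
#' @return invisibly, the manifest list.
#' @export
pipeline_simulate <- function(outdir, config = cohort_config(),
                              effects = NULL, noise = noise_spec(),
                              seed = 1, overwrite = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- config$seed %||% seed
  effects <- effects %||% default_locus_effects(seed = seed)
  sheet <- simulate_cohort(config)
  sim <- simulate_beta_matrix(sheet, effects, noise, seed = seed)
  ann <- simulate_annotation(nrow(effects), locus_id = effects$locus_id,
                             seed = seed)
  gene_univ <- sort(unique(unlist(split_genes(ann$gene_symbols))))
  n_probes <- min(50L, max(1L, length(gene_univ)))
  gene_eff <- data.frame(
    probe_id = sprintf("ILMN_%04d", seq_len(n_probes)),
    gene = gene_univ[seq_len(n_probes)],
    baseline_log2 = 8, fold_msi = 1, fold_mss = 1,
    stringsAsFactors = FALSE
  )
  expr <- simulate_expression(sheet, gene_eff, seed = seed)
  files <- c(
    beta = out_path(outdir, "beta.tsv", overwrite),
    sheet = out_path(outdir, "samples.csv", overwrite),
    annotation = out_path(outdir, "annotation.tsv", overwrite),
    truth = out_path(outdir, "truth.tsv", overwrite),
    expression = out_path(outdir, "expression.tsv", overwrite)
  )
  write_beta_matrix(sim$beta, files[["beta"]])
  write_sample_sheet(sheet, files[["sheet"]])
  write_annotation(ann, files[["annotation"]])
  utils::write.table(sim$truth, files[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ex <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(ex, files[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(write_manifest(outdir, files, extra = list(
    seed = seed, n_persons = config$n_persons, n_msi = config$n_msi,
    sigma_person = noise$sigma_person, sigma_error = noise$sigma_error)))
}

#' Pipeline stage: genome-wide scans
#'
#' Reads the beta matrix and sample sheet from `indir`, runs the stratified
#' paired scans and the interaction scan, attaches q-values and writes
#' `scan_results.tsv`.
#'
#' @param indir directory holding `beta.tsv` and `samples.csv`.
#' @param outdir output directory (default `indir`).
#' @param interaction_model `"interaction"` or `"location"`.
#' @param overwrite replace existing outputs.
#' @return invisibly, the results data frame.
#' @export
pipeline_scan <- function(indir, outdir = indir,
                          interaction_model = "interaction",
                          overwrite = FALSE) {
  mat <- read_beta_matrix(file.path(indir, "beta.tsv"))
  sheet <- read_sample_sheet(file.path(indir, "samples.csv"))
  res <- dml_scan_results(mat, sheet, interaction_model = interaction_model)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- out_path(outdir, "scan_results.tsv", overwrite)
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(res)
}

#' Pipeline stage: DML catalog, region table and Venn counts
#'
#' Reads `scan_results.tsv` and the annotation, builds the DML catalog and
#' interaction categories, tabulates the interaction DML by CpG-island
#' relation, and writes `dml_catalog.tsv`, `region_table.tsv` and
#' `venn.json`.
#'
#' @param indir directory with `scan_results.tsv` and `annotation.tsv`.
#' @param outdir output directory (default `indir`).
#' @param thresholds a [dml_thresholds()].
#' @param chip_totals chip background counts per region; defaults to the
#'   simulated annotation's own region counts so the chip column matches
#'   the simulated universe.
#' @param overwrite replace existing outputs.
#' @return invisibly, a list with `catalog`, `region_table`, `venn`,
#'   `promoter_island`.
#' @export
pipeline_classify <- function(indir, outdir = indir,
                              thresholds = dml_thresholds(),
                              chip_totals = NULL, overwrite = FALSE) {
  res <- utils::read.delim(file.path(indir, "scan_results.tsv"),
                           stringsAsFactors = FALSE)
  ann <- read_annotation(file.path(indir, "annotation.tsv"))
  catalog <- build_dml_catalog(res, thresholds)
  chip_totals <- chip_totals %||% table(ann$region)
  int_ids <- catalog$locus_id[catalog$in_interaction]
  dirs <- ifelse(res$delta_all[match(int_ids, res$locus_id)] > 0, "hyper",
                 "hypo")
  region_tab <- tabulate_regions(int_ids, dirs, ann,
                                 chip_totals = chip_totals)
  venn <- venn_counts(catalog$locus_id[catalog$in_msi_dml],
                      catalog$locus_id[catalog$in_mss_dml])
  strong <- promoter_island_filter(res, ann, thresholds)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(catalog),
                     out_path(outdir, "dml_catalog.tsv", overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(region_tab,
                     out_path(outdir, "region_table.tsv", overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(venn),
                       out_path(outdir, "venn.json", overwrite),
                       auto_unbox = TRUE)
  utils::write.table(strong,
                     out_path(outdir, "promoter_island.tsv", overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(catalog = catalog, region_table = region_tab, venn = venn,
                 promoter_island = strong))
}

#' Pipeline stage: enrichment scores
#'
#' Maps the interaction DML to genes via the annotation and scores them
#' against a category map; writes `enrichment.tsv`.
#'
#' @param indir directory with `dml_catalog.tsv` and `annotation.tsv`.
#' @param category_map named list of gene sets, or path to a two-column TSV
#'   (see [read_category_map()]).
#' @param outdir output directory (default `indir`).
#' @param overwrite replace existing outputs.
#' @return invisibly, the enrichment data frame.
#' @export
pipeline_enrich <- function(indir, category_map, outdir = indir,
                            overwrite = FALSE) {
  catalog <- utils::read.delim(file.path(indir, "dml_catalog.tsv"),
                               stringsAsFactors = FALSE)
  ann <- read_annotation(file.path(indir, "annotation.tsv"))
  if (is.character(category_map) && length(category_map) == 1L) {
    category_map <- read_category_map(category_map)
  }
  sig_genes <- genes_for_loci(catalog$locus_id[catalog$in_interaction], ann)
  universe <- sort(unique(unlist(split_genes(ann$gene_symbols))))
  enr <- enrichment_score(sig_genes, category_map, universe)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(enr, out_path(outdir, "enrichment.tsv", overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(enr)
}

#' Pipeline stage: cohort characteristics
#'
#' @param indir directory with `samples.csv`.
#' @param outdir output directory (default `indir`).
#' @param overwrite replace existing outputs.
#' @return invisibly, the cohort table.
#' @export
pipeline_cohort <- function(indir, outdir = indir, overwrite = FALSE) {
  sheet <- read_sample_sheet(file.path(indir, "samples.csv"))
  tab <- cohort_table(sheet)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tab, out_path(outdir, "cohort_table.tsv", overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(tab)
}

#' Pipeline stage: expression interaction and fold changes
#'
#' Runs the tumor-by-MSI interaction scan on the expression matrix and the
#' per-probe fold changes in each group; writes
#' `expression_interaction.tsv` and `expression_folds.tsv`.
#'
#' @param indir directory with `expression.tsv` and `samples.csv`.
#' @param outdir output directory (default `indir`).
#' @param alpha interaction significance threshold.
#' @param overwrite replace existing outputs.
#' @return invisibly, list with `interaction` and `folds`.
#' @export
pipeline_expression <- function(indir, outdir = indir, alpha = 0.05,
                                overwrite = FALSE) {
  raw <- utils::read.delim(file.path(indir, "expression.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(expr) <- raw[[1L]]
  sheet <- read_sample_sheet(file.path(indir, "samples.csv"))
  scan <- expression_interaction_scan(expr, sheet, alpha = alpha)
  folds <- do.call(rbind, lapply(c("all", "MSI", "MSS"), function(g) {
    paired_fold_change(expr, sheet, group = g)
  }))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(scan),
                     out_path(outdir, "expression_interaction.tsv",
                              overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(folds,
                     out_path(outdir, "expression_folds.tsv", overwrite),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(list(interaction = scan, folds = folds))
}

#' Run the full demo workflow
#'
#' Simulates a study and runs every downstream stage in order:
#' simulate, scan, classify, enrich (against a category map built from the
#' simulated gene universe), cohort, expression.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param config a [cohort_config()].
#' @param overwrite replace existing outputs.
#' @return invisibly, a list with the classify and expression results.
#' @export
pipeline_demo <- function(outdir, seed = 1, config = cohort_config(),
                          overwrite = FALSE) {
  pipeline_simulate(outdir, config = config, seed = seed,
                    overwrite = overwrite)
  pipeline_scan(outdir, overwrite = overwrite)
  cls <- pipeline_classify(outdir, overwrite = overwrite)
  ann <- read_annotation(file.path(outdir, "annotation.tsv"))
  universe <- sort(unique(unlist(split_genes(ann$gene_symbols))))
  k <- max(1L, length(universe) %/% 5L)
  cmap <- with_seed(sub_seed(seed, 6L), {
    list(setA = sample(universe, k), setB = sample(universe, k))
  })
  pipeline_enrich(outdir, cmap, overwrite = overwrite)
  pipeline_cohort(outdir, overwrite = overwrite)
  expr_out <- pipeline_expression(outdir, overwrite = overwrite)
  invisible(list(classify = cls, expression = expr_out))
}
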