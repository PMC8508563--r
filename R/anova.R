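# Per-locus ANOVA engine. Three models on per-locus methylation (or
# expression) values y:
#   paired:      y ~ tumor + person          (person random; paired design)
#   interaction: y ~ tumor + msi + tumor:msi
#   location:    y ~ tumor + msi + location + tumor:msi + tumor:location
# Fixed factors use sum-to-zero coding and Type III sums of squares
# (each term tested against the model containing every other term).
# The fit is computed by QR projector algebra shared across loci, so a
# genome-wide scan reduces to a handful of matrix products.

model_term_labels <- function(model) {
  switch(model,
         paired = c("tumor", "person"),
         interaction = c("tumor", "msi", "tumor:msi"),
         location = c("tumor", "msi", "location", "tumor:msi",
                      "tumor:location"),
         stopf("unknown model '%s'", model))
}

build_factors <- function(sheet) {
  data.frame(
    tumor = factor(sheet$tissue, levels = c("normal", "tumor")),
    msi = factor(sheet$msi_status, levels = c("MSS", "MSI")),
    person = factor(sheet$person_id),
    location = factor(sheet$location, levels = c("left", "right")),
    row.names = sheet$sample_id, stringsAsFactors = FALSE
  )
}

# Drop terms referencing factors with fewer than 2 observed levels; returns
# the surviving labels plus the dropped ones (degenerate-design handling).
prune_terms <- function(labels, data) {
  n_lev <- vapply(data, function(f) length(unique(f[!is.na(f)])), 0L)
  ok <- vapply(labels, function(lab) {
    all(n_lev[strsplit(lab, ":", fixed = TRUE)[[1L]]] >= 2L)
  }, TRUE)
  list(kept = labels[ok], dropped = labels[!ok])
}

# Thin orthonormal basis of the column space of X.
ortho_basis <- function(x) {
  d <- qr(x)
  qr.Q(d)[, seq_len(d$rank), drop = FALSE]
}

# Projector set for a fixed design: full-model basis plus, for each term,
# the basis of the model with that term removed (Type III reduction).
projector_set <- function(data, labels) {
  vars <- unique(unlist(strsplit(labels, ":", fixed = TRUE)))
  contrasts <- lapply(data[vars], function(f) "contr.sum")
  contrasts <- contrasts[vapply(data[vars], is.factor, TRUE)]
  ff <- stats::reformulate(labels)
  x <- stats::model.matrix(ff, data = data, contrasts.arg = contrasts)
  assign <- attr(x, "assign")
  q_full <- ortho_basis(x)
  rank_full <- ncol(q_full)
  term_ids <- seq_along(labels)
  reductions <- lapply(term_ids, function(i) {
    keep <- assign %in% c(0L, setdiff(term_ids, i))
    q_red <- ortho_basis(x[, keep, drop = FALSE])
    list(q = q_red, df = rank_full - ncol(q_red))
  })
  names(reductions) <- labels
  list(x = x, q_full = q_full, rank_full = rank_full,
       df_residual = nrow(x) - rank_full, reductions = reductions,
       labels = labels)
}

# Type III ANOVA of every row of Y (loci x samples) against one projector
# set. Returns per-term SS/F/p matrices plus residual SS.
project_anova <- function(y_mat, ps) {
  tot <- rowSums(y_mat^2)
  fit_full <- rowSums((y_mat %*% ps$q_full)^2)
  rss <- pmax(tot - fit_full, 0)
  ss <- vapply(ps$reductions, function(r) {
    pmax(fit_full - rowSums((y_mat %*% r$q)^2), 0)
  }, numeric(nrow(y_mat)))
  if (nrow(y_mat) == 1L) ss <- matrix(ss, nrow = 1L,
                                      dimnames = list(NULL, ps$labels))
  # SS below the rounding floor of the projections are exact zeros
  tol <- 1e-11 * pmax(tot, 1)
  ss[ss < tol] <- 0
  rss[rss < tol] <- 0
  df <- vapply(ps$reductions, function(r) r$df, 0L)
  ms_err <- rss / ps$df_residual
  f <- sweep(ss, 2L, df, "/") / ms_err
  p <- matrix(stats::pf(f, rep(df, each = nrow(f)), ps$df_residual,
                        lower.tail = FALSE),
              nrow = nrow(f), dimnames = dimnames(f))
  # exactly interpolated rows: a zero term SS is no evidence (F 0, p 1),
  # a positive one against zero residual is overwhelming (F Inf, p 0)
  zr <- rss == 0
  if (any(zr)) {
    f[zr, ] <- ifelse(ss[zr, , drop = FALSE] == 0, 0, Inf)
    p[zr, ] <- ifelse(ss[zr, , drop = FALSE] == 0, 1, 0)
  }
  list(ss = ss, df = df, rss = rss, df_residual = ps$df_residual,
       ms_error = ms_err, f = f, p = p)
}

# ---- single-locus fits ------------------------------------------------------

new_locus_anova <- function(model, flags, n = 0L, n_pairs = NA_integer_) {
  structure(list(model = model, table = NULL, coefficients = NULL,
                 grand_mean = NA_real_, n = n, n_pairs = n_pairs,
                 deltas = c(all = NA_real_, msi = NA_real_, mss = NA_real_),
                 sigma2_person = NA_real_, sigma2_person_raw = NA_real_,
                 sigma2_error = NA_real_, flags = flags),
            class = "locus_anova")
}

# Delta betas (tumor minus normal mean) over complete pairs, overall and per
# MSI stratum; pairs with a missing half of y are dropped (pairwise deletion).
pair_deltas <- function(y, sheet) {
  pairing <- validate_pairing(sheet)
  yt <- y[pairing$tumor_sample]
  yn <- y[pairing$normal_sample]
  d <- yt - yn
  msi <- sheet$msi_status[match(pairing$person_id, sheet$person_id)]
  ok <- !is.na(d)
  c(all = if (any(ok)) mean(d[ok]) else NA_real_,
    msi = if (any(ok & msi == "MSI")) mean(d[ok & msi == "MSI"]) else NA_real_,
    mss = if (any(ok & msi == "MSS")) mean(d[ok & msi == "MSS"]) else NA_real_)
}

#' Per-locus ANOVA fit
#'
#' Fits one of the three per-locus models to a vector of sample values.
#' `"paired"` is the randomized-block model `y ~ tumor + person` with person
#' a random effect (its variance component is estimated by the method of
#' moments); `"interaction"` adds MSI status and the tumor-by-MSI
#' interaction (no person term); `"location"` further adds tumor location
#' and the tumor-by-location interaction. Fixed-effect tests use Type III
#' sums of squares with sum-to-zero contrasts; the F denominator is the
#' residual mean square throughout.
#'
#' @param y numeric vector of per-sample values, named by sample ID (or in
#'   sheet order). Missing values cause pairwise deletion.
#' @param sheet sample-sheet data frame.
#' @param model `"paired"`, `"interaction"` or `"location"`.
#' @param stratum optional MSI level (`"MSI"` or `"MSS"`); restricts the fit
#'   to persons with that status.
#' @return object of class `locus_anova` with components `table` (per-term
#'   df, SS, MS, F, p plus a residual row), `coefficients`, `deltas` (mean
#'   tumor-minus-normal difference overall / in MSI / in MSS),
#'   `sigma2_person` (method-of-moments person variance component, truncated
#'   at zero; the untruncated value is in `sigma2_person_raw`), `n`,
#'   `n_pairs` and `flags`. Degenerate designs are flagged, not thrown.
#' @seealso [genomewide_scan()] for the vectorised multi-locus version.
#' @export
locus_anova <- function(y, sheet,
                        model = c("paired", "interaction", "location"),
                        stratum = NULL) {
  model <- match.arg(model)
  validate_sample_sheet(sheet)
  if (is.null(names(y))) {
    if (length(y) != nrow(sheet)) {
      stopf("unnamed y must have one value per sheet row")
    }
    names(y) <- sheet$sample_id
  }
  if (!is.null(stratum)) {
    stopifnot(stratum %in% c("MSI", "MSS"))
    sheet <- sheet[sheet$msi_status == stratum, , drop = FALSE]
  }
  deltas <- tryCatch(pair_deltas(y, sheet), error = function(e) {
    c(all = NA_real_, msi = NA_real_, mss = NA_real_)
  })
  sheet <- sheet[!is.na(y[sheet$sample_id]), , drop = FALSE]
  if (model == "paired") {
    # pairwise deletion: a pair is used only if both halves are observed
    pairing <- validate_pairing(sheet)
    sheet <- sheet[sheet$person_id %in% pairing$person_id, , drop = FALSE]
    if (nrow(pairing) < 2L) {
      out <- new_locus_anova(model, flags = "insufficient_data",
                             n = nrow(sheet), n_pairs = nrow(pairing))
      out$deltas <- deltas
      return(out)
    }
  }
  data <- build_factors(sheet)
  yv <- y[rownames(data)]
  flags <- character(0)

  labels <- model_term_labels(model)
  pr <- prune_terms(labels, data)
  if (length(pr$dropped) > 0L) {
    flags <- c(flags, paste0("dropped:", pr$dropped))
  }
  labels <- pr$kept
  if (!("tumor" %in% labels)) {
    out <- new_locus_anova(model, flags = c(flags, "inestimable"),
                           n = nrow(sheet))
    out$deltas <- deltas
    return(out)
  }
  if (model %in% c("interaction", "location") && "tumor:msi" %in% labels) {
    cells <- table(data$tumor, data$msi)
    if (any(cells == 0L)) {
      out <- new_locus_anova(model, flags = c(flags, "inestimable_interaction"),
                             n = nrow(sheet))
      out$deltas <- deltas
      return(out)
    }
  }
  ps <- projector_set(data, labels)
  if (any(vapply(ps$reductions, function(r) r$df, 0L) == 0L)) {
    flags <- c(flags, "collinear_terms")
  }
  res <- project_anova(matrix(yv, nrow = 1L), ps)
  tab <- data.frame(
    term = c(labels, "error"),
    df = c(res$df, res$df_residual),
    ss = c(res$ss[1L, ], res$rss),
    ms = c(res$ss[1L, ] / res$df, res$rss / res$df_residual),
    f = c(res$f[1L, ], NA_real_),
    p = c(res$p[1L, ], NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  out <- new_locus_anova(model, flags = flags, n = nrow(sheet))
  out$table <- tab
  out$grand_mean <- mean(yv)
  out$coefficients <- qr.coef(qr(ps$x), yv)
  out$deltas <- deltas
  out$sigma2_error <- res$rss / res$df_residual
  if (model == "paired") {
    out$n_pairs <- nrow(sheet) / 2L
    ms_person <- tab$ms[tab$term == "person"]
    ms_error <- tab$ms[tab$term == "error"]
    out$sigma2_person_raw <- (ms_person - ms_error) / 2
    out$sigma2_person <- max(0, out$sigma2_person_raw)
  }
  if (length(out$flags) == 0L) out$flags <- character(0)
  out
}

#' @rdname locus_anova
#' @export
fit_paired_model <- function(y, sheet, stratum = NULL) {
  locus_anova(y, sheet, model = "paired", stratum = stratum)
}

#' @rdname locus_anova
#' @export
fit_interaction_model <- function(y, sheet) {
  locus_anova(y, sheet, model = "interaction")
}

#' @rdname locus_anova
#' @export
fit_location_model <- function(y, sheet) {
  locus_anova(y, sheet, model = "location")
}

#' @export
print.locus_anova <- function(x, ...) {
  cat(sprintf("Per-locus ANOVA (%s model), n = %d\n", x$model, x$n))
  if (length(x$flags) > 0L) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$table)) {
    print(transform(x$table, ss = signif(ss, 6), ms = signif(ms, 6),
                    f = signif(f, 6), p = signif(p, 6)), row.names = FALSE)
  }
  cat(sprintf("delta beta: all %.4g | MSI %.4g | MSS %.4g\n",
              x$deltas[["all"]], x$deltas[["msi"]], x$deltas[["mss"]]))
  if (!is.na(x$sigma2_person)) {
    cat(sprintf("person variance component (MoM): %.4g\n", x$sigma2_person))
  }
  invisible(x)
}

#' @export
summary.locus_anova <- function(object, ...) {
  out <- list(model = object$model, table = object$table,
              deltas = object$deltas, n = object$n,
              sigma2_person = object$sigma2_person,
              decomposition = if (!is.null(object$table))
                variance_decomposition(object) else NULL,
              flags = object$flags)
  class(out) <- "summary.locus_anova"
  out
}

#' @export
print.summary.locus_anova <- function(x, ...) {
  cat(sprintf("Per-locus ANOVA (%s model), n = %d\n", x$model, x$n))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (!is.null(x$decomposition)) {
    cat("\nVariance decomposition (share of total SS):\n")
    print(x$decomposition, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.locus_anova <- function(object, ...) object$coefficients

#' Paired t-test on a vector of within-pair differences
#'
#' @param deltas numeric vector of paired differences (NAs dropped).
#' @return list with `t`, `p` (two-sided), `n`, `mean`, `sd` and `flag`
#'   (`"degenerate"` when the differences have zero spread: p is 0 when the
#'   common value is nonzero and 1 when it is zero).
#' @export
paired_t_test <- function(deltas) {
  d <- deltas[!is.na(deltas)]
  n <- length(d)
  if (n < 2L) {
    return(list(t = NA_real_, p = NA_real_, n = n, mean = NA_real_,
                sd = NA_real_, flag = "insufficient_data"))
  }
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else Inf * sign(m),
                p = if (m == 0) 1 else 0, n = n, mean = m, sd = 0,
                flag = "degenerate"))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE), n = n,
       mean = m, sd = s, flag = "")
}

#' Variance decomposition of a per-locus fit
#'
#' Shares of the total (model + error) sum of squares per ANOVA factor,
#' with the F ratio (factor mean square over error mean square) alongside.
#' Shares include the residual ("error") row and sum to 1. A fit with zero
#' total SS is flagged degenerate and all shares are reported as 0.
#'
#' @param fit a `locus_anova` object.
#' @return data frame with columns `term`, `df`, `ss`, `share`, `f_ratio`
#'   and attribute `degenerate`.
#' @export
variance_decomposition <- function(fit) {
  stopifnot(inherits(fit, "locus_anova"))
  if (is.null(fit$table)) stopf("fit carries no ANOVA table (flags: %s)",
                                paste(fit$flags, collapse = ", "))
  tab <- fit$table
  total <- sum(tab$ss)
  degenerate <- total < 1e-12
  share <- if (degenerate) rep(0, nrow(tab)) else tab$ss / total
  out <- data.frame(term = tab$term, df = tab$df, ss = tab$ss, share = share,
                    f_ratio = tab$f, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}
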