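# Fixture builders and independent oracles used across the test files.

# Paired sample sheet: n_msi MSI persons then n_mss MSS persons, two rows
# (tumor, normal) each.
make_sheet <- function(n_msi = 2, n_mss = 3, location = NULL) {
  n <- n_msi + n_mss
  person <- sprintf("p%02d", seq_len(n))
  msi <- c(rep("MSI", n_msi), rep("MSS", n_mss))
  loc <- if (is.null(location)) rep(c("left", "right"), length.out = n) else
    rep_len(location, n)
  data.frame(
    sample_id = as.vector(rbind(paste0(person, "_T"), paste0(person, "_N"))),
    person_id = rep(person, each = 2),
    tissue = rep(c("tumor", "normal"), n),
    msi_status = rep(msi, each = 2),
    location = rep(loc, each = 2),
    sex = "male", age = 50, stage = 1L,
    stringsAsFactors = FALSE
  )
}

# Locus values for a sheet: `tumor` and `normal` hold one value per person;
# returns a named vector keyed by sample_id.
sheet_values <- function(sheet, tumor, normal) {
  idx <- match(sheet$person_id, unique(sheet$person_id))
  y <- ifelse(sheet$tissue == "tumor", rep_len(tumor, max(idx))[idx],
              rep_len(normal, max(idx))[idx])
  names(y) <- sheet$sample_id
  y
}

# Definitional Benjamini-Hochberg: q_i = min over j with p_(j) >= p_i of
# m * p_(j) / j, computed by brute force.
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    min(vapply(seq_len(m), function(j) {
      pj <- sort(p)[j]
      if (pj >= pi) m * pj / j else Inf
    }, 0), 1)
  }, 0)
}

# Brute-force Pearson chi-square statistic.
chisq_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table.
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
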