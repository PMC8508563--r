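#' Methylation beta value from probe intensities
#'
#' Computes the methylation score (beta value) from the methylated-probe
#' intensity `x_meth` and the unmethylated-probe intensity `y_unmeth` as
#' `x / (x + y + offset)`. With the default `offset = 0` this is the plain
#' intensity fraction: 0 when fully unmethylated, 1 when fully methylated,
#' 0.5 when both channels are equal.
#'
#' @param x_meth numeric vector of methylated-probe intensities (>= 0).
#' @param y_unmeth numeric vector of unmethylated-probe intensities (>= 0).
#' @param offset nonnegative constant added to the denominator. The Illumina
#'   convention adds 100 to stabilise low-intensity probes; the default here
#'   is 0 (no offset).
#' @return numeric vector of beta values in `[0, 1]`.
#' @examples
#' compute_beta(50, 50)   # 0.5
#' compute_beta(0, 200)   # 0
#' compute_beta(120, 0)   # 1
#' @export
compute_beta <- function(x_meth, y_unmeth, offset = 0) {
  if (!is.numeric(x_meth) || !is.numeric(y_unmeth)) {
    stopf("intensities must be numeric")
  }
  if (length(offset) != 1L || !is.numeric(offset) || offset < 0) {
    stopf("`offset` must be a single nonnegative number")
  }
  n <- max(length(x_meth), length(y_unmeth))
  x <- rep_len(x_meth, n)
  y <- rep_len(y_unmeth, n)
  bad <- !is.na(x) & !is.na(y) & (x < 0 | y < 0)
  if (any(bad)) stopf("negative intensity at position %d", which(bad)[1L])
  tot <- x + y + offset
  zero <- !is.na(tot) & tot == 0
  if (any(zero)) {
    stopf("undefined beta: total intensity is zero at position %d",
          which(zero)[1L])
  }
  x / tot
}

#' Illumina 450K chip composition by relation to CpG island
#'
#' Number of interrogated loci per CpG-island relation category on the
#' HumanMethylation450 array (485,577 loci total): 150,254 in islands,
#' 112,067 in shores (0--2 kb, split north/south), 47,114 in shelves
#' (2--4 kb, split north/south) and 176,112 in open sea (>4 kb).
#' Used as the default chip background for region tabulation and as the
#' default region mix of the annotation simulator.
#'
#' @format named integer vector with elements `Island`, `N_Shelf`,
#'   `N_Shore`, `S_Shelf`, `S_Shore`, `OpenSea`.
#' @export
chip450k_region_counts <- c(
  Island  = 150254L,
  N_Shelf = 24844L,
  N_Shore = 62870L,
  S_Shelf = 22300L,
  S_Shore = 49197L,
  OpenSea = 176112L
)

# Canonical region levels; "Deep Sea"/"DeepSea" are accepted input aliases
# for OpenSea.
region_levels <- function() {
  c("Island", "N_Shelf", "N_Shore", "S_Shelf", "S_Shore", "OpenSea")
}

normalize_region <- function(x) {
  x <- as.character(x)
  x[x %in% c("Deep Sea", "DeepSea", "Deep_Sea", "Open Sea", "Open_Sea")] <-
    "OpenSea"
  bad <- !is.na(x) & !(x %in% region_levels())
  if (any(bad)) stopf("unknown region category '%s'", x[bad][1L])
  factor(x, levels = region_levels())
}
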