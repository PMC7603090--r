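# Two-population Weir-Cockerham Fst from allele-frequency mean squares.
#
# With r = 2 populations, allele sample sizes m_i (2 x genotyped diploids)
# and allele frequencies p_i:
#   pbar = sum(m_i p_i) / sum(m_i)
#   MSP  = sum(m_i (p_i - pbar)^2) / (r - 1)          (among populations)
#   MSG  = sum(m_i p_i (1 - p_i)) / sum(m_i - 1)      (within populations)
#   n_c  = (sum(m_i) - sum(m_i^2) / sum(m_i)) / (r - 1)
#   Fst  = (MSP - MSG) / (MSP + (n_c - 1) MSG)
# Fst = 1 exactly at fixed differences (MSG = 0, MSP > 0); equal
# frequencies force MSP = 0 and Fst = -1/(n_c - 1). Negative values are
# reported as computed.

.fst_parts <- function(m1, p1, m2, p2) {
  mt <- m1 + m2
  pbar <- (m1 * p1 + m2 * p2) / mt
  msp <- m1 * (p1 - pbar)^2 + m2 * (p2 - pbar)^2  # r - 1 = 1
  msg <- (m1 * p1 * (1 - p1) + m2 * p2 * (1 - p2)) / (mt - 2)
  nc <- mt - (m1^2 + m2^2) / mt
  list(msp = msp, msg = msg, nc = nc)
}

#' Per-SNP two-population Fst from mean squares
#'
#' @param m1,m2 Allele sample sizes (2 x genotyped diploids), each >= 2.
#' @param p1,p2 Alternate-allele frequencies in the two populations.
#' @return List with `msp`, `msg`, `n_c` and `fst` (`NA` when the
#'   denominator is zero, i.e. both populations monomorphic for the same
#'   allele).
#' @export
fst_per_snp <- function(m1, p1, m2, p2) {
  stopifnot(m1 >= 2, m2 >= 2, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  parts <- .fst_parts(m1, p1, m2, p2)
  denom <- parts$msp + (parts$nc - 1) * parts$msg
  fst <- if (denom == 0) NA_real_ else (parts$msp - parts$msg) / denom
  list(msp = parts$msp, msg = parts$msg, n_c = parts$nc, fst = fst)
}

.pop_freqs <- function(geno, pops, label) {
  rows <- rownames(geno) %in% pops$sample_id[pops$population == label]
  if (!any(rows)) stop("unknown or empty population: ", label)
  g <- geno[rows, , drop = FALSE]
  n <- colSums(!is.na(g))
  m <- 2 * n
  p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / m, NA_real_)
  list(m = m, p = p)
}

#' Genome scan of per-SNP Fst between two populations
#'
#' Vectorized application of [fst_per_snp()] to every SNP column; SNPs with
#' fewer than one genotyped sample (two alleles) in either population, or a
#' zero denominator, are `NA`.
#'
#' @param geno Genotype dosage matrix (samples x SNPs, sample rownames).
#' @param pops Population map data.frame (`sample_id`, `population`).
#' @param object_pop,reference_pop Population labels to compare.
#' @return Numeric vector of Fst values aligned to the SNP columns.
#' @export
fst_scan <- function(geno, pops, object_pop, reference_pop) {
  f1 <- .pop_freqs(geno, pops, object_pop)
  f2 <- .pop_freqs(geno, pops, reference_pop)
  ok <- f1$m >= 2 & f2$m >= 2
  parts <- .fst_parts(f1$m, f1$p, f2$m, f2$p)
  denom <- parts$msp + (parts$nc - 1) * parts$msg
  fst <- ifelse(ok & denom != 0, (parts$msp - parts$msg) / denom, NA_real_)
  unname(fst)
}

#' Multi-locus pairwise Fst matrix
#'
#' Weir-Cockerham ratio-of-sums estimator per population pair:
#' `sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG)` over SNPs with at least one
#' genotyped sample in both populations. Negative entries are floored at 0
#' so the matrix can serve as a distance.
#'
#' @param geno Genotype dosage matrix (samples x SNPs).
#' @param pops Population map with at least two labels.
#' @return Symmetric matrix with zero diagonal, labelled by population.
#' @export
pairwise_fst_matrix <- function(geno, pops) {
  labels <- unique(pops$population)
  if (length(labels) < 2L) stop("need at least two populations")
  freqs <- lapply(labels, function(l) .pop_freqs(geno, pops, l))
  names(freqs) <- labels
  d <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(labels)[-1L]) for (j in seq_len(i - 1L)) {
    f1 <- freqs[[i]]; f2 <- freqs[[j]]
    ok <- f1$m >= 2 & f2$m >= 2
    parts <- .fst_parts(f1$m[ok], f1$p[ok], f2$m[ok], f2$p[ok])
    num <- sum(parts$msp - parts$msg)
    den <- sum(parts$msp + (parts$nc - 1) * parts$msg)
    d[i, j] <- d[j, i] <- max(0, num / den)
  }
  d
}
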