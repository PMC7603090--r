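# Independent oracles and fixture builders shared across the suite.

# Allele-level ANOVA oracle for the two-population Fst: lays the alleles
# out as 0/1 observations grouped by population and reads the mean squares
# off stats::anova(), independently of the closed-form implementation.
fst_anova_oracle <- function(m1, x1, m2, x2) {
  if ((x1 == 0 && x2 == 0) || (x1 == m1 && x2 == m2))
    return(NA_real_)  # constant response: lm mean squares are round-off
  y <- c(rep(1, x1), rep(0, m1 - x1), rep(1, x2), rep(0, m2 - x2))
  pop <- factor(rep(c("a", "b"), c(m1, m2)))
  tab <- suppressWarnings(anova(lm(y ~ pop)))  # perfect fits are fine here
  msp <- tab[["Mean Sq"]][1L]
  msg <- tab[["Mean Sq"]][2L]
  mt <- m1 + m2
  nc <- mt - (m1^2 + m2^2) / mt
  denom <- msp + (nc - 1) * msg
  if (denom == 0) NA_real_ else (msp - msg) / denom
}

# Exact HWE oracle: direct enumeration of all heterozygote counts of
# matching parity, probabilities from choose() products.
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(NA_real_)
  n1 <- min(2L * n_hom_ref + n_het, 2L * n_hom_alt + n_het)
  if (n1 == 0L) return(1)
  h <- seq.int(n1 %% 2L, n1, by = 2L)
  hom_min <- (n1 - h) %/% 2L
  hom_maj <- n - h - hom_min
  prob <- choose(n, hom_min) * choose(n - hom_min, h) * 2^h /
    choose(2L * n, n1)
  prob <- prob / sum(prob)
  p_obs <- prob[h == n_het]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Brute-force EHH oracle: for every marker x, partition haplotypes by the
# pasted allele string over [core..x]; pooled denominator fixed at the
# core. Haplotypes missing anywhere in the interval are dropped.
ehh_string_oracle <- function(H, core, x) {
  a <- H[, core]
  n_a <- sum(a == 0L, na.rm = TRUE)
  n_A <- sum(a == 1L, na.rm = TRUE)
  den <- choose(n_a, 2) + choose(n_A, 2)
  if (den == 0) return(NA_real_)
  idx <- if (x >= core) core:x else x:core
  sub <- H[, idx, drop = FALSE]
  ok <- !is.na(a) & !apply(sub, 1L, anyNA)
  key <- apply(sub[ok, , drop = FALSE], 1L, paste, collapse = "")
  sum(choose(table(key), 2)) / den
}

random_hap_matrix <- function(n_hap, n_markers, seed, miss = 0) {
  set.seed(seed)
  H <- matrix(rbinom(n_hap * n_markers, 1L, runif(n_markers, 0.2, 0.8)),
              nrow = n_hap, byrow = TRUE)
  if (miss > 0) H[runif(length(H)) < miss] <- NA_integer_
  H
}

toy_variants <- function(pos, chrom = "1") {
  data.frame(variant_id = sprintf("v%03d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos), ref = "A", alt = "G", autosome = TRUE,
             stringsAsFactors = FALSE)
}

# Random additive distance matrix: path lengths of a random unrooted tree
# with positive edge lengths.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 5)
  as.matrix(ape::cophenetic.phylo(tr))
}

# Small phased VCF written as text, for parser tests.
write_toy_vcf <- function(path, records, samples = c("s1", "s2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

# Six-SNP QC fixture: one SNP failing exactly one rule each (HWE, call
# rate, MAF, autosome) plus two clean SNPs, over 22 diploid samples.
qc_toy_panel <- function() {
  n <- 22L
  clean <- c(rep(0L, 6), rep(1L, 11), rep(2L, 5))       # HWE-balanced
  hwe_fail <- c(rep(0L, 11), rep(2L, 11))               # no hets: exact p 3.4e-7
  cr_fail <- c(rep(NA_integer_, 3), clean[4:22])        # call rate 19/22 = 0.86
  maf_fail <- rep(0L, n)                                # monomorphic: MAF 0, HWE p 1
  geno <- cbind(clean, hwe_fail, cr_fail, maf_fail, clean, clean)
  variants <- toy_variants(seq(1e5, 6e5, by = 1e5))
  variants$chrom[6L] <- "X"
  variants$autosome[6L] <- FALSE
  rownames(geno) <- sprintf("s%02d", seq_len(n))
  list(geno = geno, variants = variants)
}
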