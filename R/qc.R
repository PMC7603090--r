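# Chip-style SNP quality control: exact Hardy-Weinberg test, call rate,
# minor allele frequency and autosome filters. Pass rules are strict in the
# conventional direction: fail when HWE p < hwe_p_min, call rate <=
# call_rate_min, or MAF <= maf_min.

#' QC thresholds
#'
#' @param hwe_p_min Minimum exact HWE p-value (fail when p < this;
#'   default `1e-6`).
#' @param call_rate_min SNP call-rate bound (pass requires rate strictly
#'   greater; default `0.90`).
#' @param maf_min Minor-allele-frequency bound (pass requires MAF strictly
#'   greater; default `0.01`).
#' @param autosomes_only Drop variants flagged non-autosomal (default
#'   `TRUE`).
#' @param hwe_by_pop Test HWE within each population and fail on the
#'   smallest p (default `FALSE`: pooled test across all samples).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, call_rate_min = 0.90,
                          maf_min = 0.01, autosomes_only = TRUE,
                          hwe_by_pop = FALSE) {
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  structure(list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
                 maf_min = maf_min, autosomes_only = autosomes_only,
                 hwe_by_pop = hwe_by_pop), class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the sample size and minor-allele count,
#' the p-value is the sum of the conditional probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count (plain sum, no mid-p correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return p-value in (0, 1]; `NA` when the total count is zero.
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(NA_real_)
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n1 <- min(2L * n_hom_ref + n_het, 2L * n_hom_alt + n_het)  # minor alleles
  if (n1 == 0L) return(1)
  h <- seq.int(n1 %% 2L, n1, by = 2L)
  hom_min <- (n1 - h) %/% 2L
  hom_maj <- n - h - hom_min
  logp <- lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) -
    lgamma(hom_maj + 1) + h * log(2) +
    lgamma(n1 + 1) + lgamma(2 * n - n1 + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, h)]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

#' Per-SNP call rate
#'
#' @param column Genotype dosages (0/1/2/NA) for one SNP.
#' @return Fraction of non-missing genotypes.
#' @export
snp_call_rate <- function(column) {
  stopifnot(length(column) >= 1L)
  mean(!is.na(column))
}

#' Per-SNP minor allele frequency
#'
#' @param column Genotype dosages (0/1/2/NA) for one SNP.
#' @return `min(p, 1 - p)` over the non-missing alleles; `NA` if all
#'   genotypes are missing.
#' @export
snp_maf <- function(column) {
  ok <- !is.na(column)
  if (!any(ok)) return(NA_real_)
  p <- sum(column[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

.genotype_counts <- function(geno) {
  cbind(n0 = colSums(geno == 0L, na.rm = TRUE),
        n1 = colSums(geno == 1L, na.rm = TRUE),
        n2 = colSums(geno == 2L, na.rm = TRUE))
}

.hwe_vector <- function(geno) {
  cnt <- .genotype_counts(geno)
  vapply(seq_len(nrow(cnt)), function(i)
    hwe_exact_p(cnt[i, 1L], cnt[i, 2L], cnt[i, 3L]), numeric(1))
}

#' Apply SNP quality control
#'
#' A SNP passes iff HWE p >= `hwe_p_min` AND call rate > `call_rate_min`
#' AND MAF > `maf_min` AND (autosomal, when `autosomes_only`). HWE is
#' tested on the pooled sample unless `hwe_by_pop` is set in the
#' thresholds. Variant order is preserved; the filter is idempotent.
#'
#' @param geno Genotype dosage matrix (samples x SNPs).
#' @param variants Matching variant table (needs an `autosome` column when
#'   the autosome filter is active).
#' @param thresholds A [qc_thresholds()] object.
#' @param pops Optional population map (needed for `hwe_by_pop`).
#' @param haplotypes Optional haplotype matrix, filtered alongside.
#' @return List with `genotypes`, `variants`, optional `haplotypes`, and
#'   `report` (`n_input`, `n_pass`, `n_fail_by_rule`, `pass_mask`).
#' @export
apply_qc <- function(geno, variants, thresholds = qc_thresholds(),
                     pops = NULL, haplotypes = NULL) {
  stopifnot(ncol(geno) == nrow(variants))
  m <- ncol(geno)

  hwe <- if (isTRUE(thresholds$hwe_by_pop)) {
    if (is.null(pops)) stop("hwe_by_pop requires a population map")
    per_pop <- sapply(unique(pops$population), function(lab) {
      rows <- rownames(geno) %in% pops$sample_id[pops$population == lab]
      .hwe_vector(geno[rows, , drop = FALSE])
    })
    apply(as.matrix(per_pop), 1L, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  } else .hwe_vector(geno)
  call_rate <- colMeans(!is.na(geno))
  n_ok <- colSums(!is.na(geno))
  p <- ifelse(n_ok > 0, colSums(geno, na.rm = TRUE) / (2 * n_ok), NA_real_)
  maf <- pmin(p, 1 - p)

  # a zero bound disables its rule, so all-zero thresholds are the
  # identity filter even on degenerate (monomorphic / all-missing) columns
  ok_hwe <- if (thresholds$hwe_p_min <= 0) rep(TRUE, m)
            else !is.na(hwe) & hwe >= thresholds$hwe_p_min
  ok_cr <- if (thresholds$call_rate_min <= 0) rep(TRUE, m)
           else call_rate > thresholds$call_rate_min
  ok_maf <- if (thresholds$maf_min <= 0) rep(TRUE, m)
            else !is.na(maf) & maf > thresholds$maf_min
  ok_auto <- if (isTRUE(thresholds$autosomes_only)) {
    if (is.null(variants$autosome)) stop("variants lack an autosome flag")
    variants$autosome
  } else rep(TRUE, m)

  pass <- ok_hwe & ok_cr & ok_maf & ok_auto
  if (!any(pass)) warning("no SNP passed quality control")
  report <- list(
    n_input = m, n_pass = sum(pass),
    n_fail_by_rule = c(hwe = sum(!ok_hwe), call_rate = sum(!ok_cr),
                       maf = sum(!ok_maf), autosome = sum(!ok_auto)),
    pass_mask = pass
  )
  out <- list(
    genotypes = geno[, pass, drop = FALSE],
    variants = variants[pass, , drop = FALSE],
    report = report
  )
  rownames(out$variants) <- NULL
  if (!is.null(haplotypes)) {
    h <- haplotypes[, pass, drop = FALSE]
    attr(h, "sample_ids") <- attr(haplotypes, "sample_ids")
    attr(h, "phased") <- attr(haplotypes, "phased")
    out$haplotypes <- h
  }
  out
}
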