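# Candidate calling and gene-set assembly: empirical top-5% thresholds,
# +/-50 kb candidate regions, per-method gene sets, cross-method merge and
# cross-pair overlap.

#' Empirical upper-quantile threshold (nearest rank)
#'
#' Sorts the non-missing values in decreasing order and returns the value
#' at rank `ceiling((1 - quantile) * n)`, so the threshold is always
#' attained by at least one SNP and, for distinct values, exactly
#' `ceiling((1 - quantile) * n)` values are >= it (ties may add more).
#'
#' @param values Statistic vector (NAs ignored).
#' @param quantile Empirical quantile, default 0.95 (top 5%).
#' @return The threshold value.
#' @export
empirical_threshold <- function(values, quantile = 0.95) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no non-missing values")
  # round away float fuzz (0.05 * 100 = 5.000000000000004) before ceiling
  k <- max(1L, ceiling(round((1 - quantile) * length(v), 9)))
  sort(v, decreasing = TRUE)[k]
}

#' Scan result container
#'
#' Bundles per-SNP Fst and XP-EHH vectors for one population pair with the
#' empirical thresholds and candidate flags (value >= threshold).
#'
#' @param variants Variant table aligned to the statistic vectors.
#' @param fst Per-SNP Fst vector.
#' @param xpehh Per-SNP XP-EHH (integral-ratio) vector.
#' @param pair Population-pair label, e.g. `"MGR-HHG"`.
#' @param quantile Empirical quantile for candidate calling (default 0.95).
#' @return A `scan_result` object.
#' @export
scan_result <- function(variants, fst, xpehh, pair = "obj-ref",
                        quantile = 0.95) {
  stopifnot(nrow(variants) == length(fst), length(fst) == length(xpehh))
  thr <- c(fst = empirical_threshold(fst, quantile),
           xpehh = empirical_threshold(xpehh, quantile))
  structure(list(
    variants = variants, fst = fst, xpehh = xpehh,
    ln_xpehh = suppressWarnings(log(xpehh)),
    thresholds = thr, quantile = quantile, pair = pair,
    candidate_fst = !is.na(fst) & fst >= thr[["fst"]],
    candidate_xpehh = !is.na(xpehh) & xpehh >= thr[["xpehh"]]
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", x$pair, "-", nrow(x$variants), "SNPs\n")
  cat(sprintf("  thresholds (top %.0f%%): Fst >= %.6f, XP-EHH >= %.6f\n",
              100 * (1 - x$quantile), x$thresholds[["fst"]],
              x$thresholds[["xpehh"]]))
  cat("  candidates: Fst", sum(x$candidate_fst),
      "| XP-EHH", sum(x$candidate_xpehh), "\n")
  invisible(x)
}

#' Candidate SNP lists per statistic
#'
#' @param result A [scan_result()].
#' @return List with data.frames `fst` and `xpehh` (`chrom`, `pos`,
#'   `value`), each sorted by value decreasing.
#' @export
candidate_snps <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  pick <- function(flag, value) {
    df <- data.frame(chrom = result$variants$chrom[flag],
                     pos = result$variants$pos[flag],
                     value = value[flag], stringsAsFactors = FALSE)
    df[order(-df$value, df$chrom, df$pos), , drop = FALSE]
  }
  list(fst = pick(result$candidate_fst, result$fst),
       xpehh = pick(result$candidate_xpehh, result$xpehh))
}

#' Genes within a flanking window of candidate SNPs
#'
#' A gene is included iff its span intersects `[pos - flank, pos + flank]`
#' (clipped at 1) of at least one candidate SNP on the same chromosome.
#'
#' @param snps data.frame with `chrom` and `pos` of candidate SNPs.
#' @param genes Gene data.frame (see [read_gene_models()]).
#' @param flank Window half-width in bp (default 50000).
#' @return Sorted character vector of gene ids.
#' @export
genes_near <- function(snps, genes, flank = 50000) {
  out <- character(0)
  for (ch in intersect(unique(genes$chrom), unique(snps$chrom))) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    w <- IRanges::IRanges(pmax(s$pos - flank, 1), s$pos + flank)
    gi <- IRanges::IRanges(g$start, g$end)
    out <- c(out, g$gene_id[IRanges::overlapsAny(gi, w)])
  }
  sort(unique(out))
}

#' Nearest gene per candidate SNP
#'
#' One best gene per SNP: the gene within `flank` bp at minimal gap
#' distance (0 when the SNP falls inside the gene); ties go to the gene
#' with the smallest start.
#'
#' @inheritParams genes_near
#' @return data.frame (`chrom`, `pos`, `gene_id`), `gene_id` `""` when no
#'   gene lies within the window.
#' @export
nearest_gene_map <- function(snps, genes, flank = 50000) {
  gene_id <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chrom == snps$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    gap <- pmax(g$start - snps$pos[i], snps$pos[i] - g$end, 0)
    ok <- gap <= flank
    if (!any(ok)) next
    g <- g[ok, , drop = FALSE]; gap <- gap[ok]
    best <- order(gap, g$start)[1L]
    gene_id[i] <- g$gene_id[best]
  }
  data.frame(chrom = snps$chrom, pos = snps$pos, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Intersect the gene lists of the two scan statistics
#'
#' The merged set of a population pair: genes flagged by both the Fst and
#' the XP-EHH scan (the Venn overlap of the two approaches).
#'
#' @param fst_genes,xpehh_genes Character vectors of gene ids.
#' @return Sorted intersection.
#' @export
merge_methods <- function(fst_genes, xpehh_genes)
  sort(intersect(fst_genes, xpehh_genes))

#' Genes shared by every population pair
#'
#' @param merged_by_pair Named list of merged gene sets, one per pair.
#' @return Sorted intersection across all pairs.
#' @export
overlap_pairs <- function(merged_by_pair) {
  stopifnot(length(merged_by_pair) >= 2L)
  sort(Reduce(intersect, merged_by_pair))
}

#' Per-pair gene-set report
#'
#' Runs [candidate_snps()], [genes_near()] and [merge_methods()] for each
#' scan result and, with two or more pairs, [overlap_pairs()].
#'
#' @param scans List of [scan_result()] objects (named by pair).
#' @param genes Gene data.frame.
#' @param flank Window half-width in bp.
#' @return List with `sets` (per pair: `fst`, `xpehh`, `merged`) and
#'   `overlap` (across pairs, `NULL` for a single pair).
#' @export
gene_set_report <- function(scans, genes, flank = 50000) {
  sets <- lapply(scans, function(res) {
    cand <- candidate_snps(res)
    fst_g <- genes_near(cand$fst, genes, flank)
    xp_g <- genes_near(cand$xpehh, genes, flank)
    list(fst = fst_g, xpehh = xp_g, merged = merge_methods(fst_g, xp_g))
  })
  names(sets) <- vapply(scans, function(s) s$pair, character(1))
  overlap <- if (length(sets) >= 2L)
    overlap_pairs(lapply(sets, `[[`, "merged")) else NULL
  list(sets = sets, overlap = overlap)
}
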