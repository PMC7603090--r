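# Hypergeometric over-representation of a candidate gene set against a
# pathway-to-gene map, with Benjamini-Hochberg control and the q < 0.05
# significance rule.

#' Hypergeometric pathway over-representation
#'
#' For each pathway with `K` background genes, of which `k` are among the
#' `n` candidates drawn from a background of `N` genes, the p-value is the
#' upper hypergeometric tail `P(X >= k)`; q-values are Benjamini-Hochberg
#' over all tested pathways.
#'
#' @param candidates Character vector of candidate gene ids (intersected
#'   with the background).
#' @param pathways Either a named list of gene-id vectors or a data.frame
#'   with `pathway_id` and `gene_id` columns.
#' @param background Character vector of background gene ids (defaults to
#'   the union of all pathway genes and candidates).
#' @param q_cutoff Significance cutoff on q (default 0.05).
#' @return data.frame with one row per pathway: `pathway_id`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `significant`, sorted by `q` then `p` then id.
#'   Zero rows when the candidate set is empty.
#' @export
hypergeom_enrich <- function(candidates, pathways, background = NULL,
                             q_cutoff = 0.05) {
  if (is.data.frame(pathways))
    pathways <- split(pathways$gene_id, pathways$pathway_id)
  if (is.null(background))
    background <- unique(c(unlist(pathways), candidates))
  background <- unique(background)
  cand <- unique(intersect(candidates, background))
  N <- length(background)
  n <- length(cand)
  if (n == 0L)
    return(data.frame(pathway_id = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(names(pathways), function(id) {
    pw <- unique(intersect(pathways[[id]], background))
    K <- length(pw)
    k <- length(intersect(pw, cand))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_cutoff
  out <- out[order(out$q, out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
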