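# Population-structure summaries: neighbor-joining tree from the pairwise
# multi-locus Fst matrix, and genotype PCA with allele-frequency
# standardization.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero with the deficit transferred to the sibling edge, so
#' leaf-to-leaf path lengths through the parent are preserved. Additive
#' matrices are reconstructed exactly.
#'
#' @param d Symmetric distance matrix with labels as dimnames.
#' @return An [ape::read.tree()]-style `phylo` object (unrooted for
#'   n >= 3; a two-leaf tree splits the distance evenly).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least two labels")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               tip.label = labels, Nnode = 1L,
               edge.length = rep(d[1L, 2L] / 2, 2L))
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib))
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per SNP; each SNP is centred by
#' `2 p_hat` and scaled by `sqrt(2 p_hat (1 - p_hat))` (monomorphic SNPs
#' dropped). Coordinates are the leading left singular vectors scaled by
#' their singular values; each component's sign is fixed so its
#' largest-magnitude SNP loading is positive.
#'
#' @param geno Genotype dosage matrix (samples x SNPs).
#' @param n_components Number of components to return.
#' @return List with `coordinates` (samples x components),
#'   `explained_variance` (fraction per returned component) and `sdev`.
#' @export
genotype_pca <- function(geno, n_components = 2L) {
  stopifnot(nrow(geno) >= 2L, ncol(geno) >= 2L)
  pm <- colMeans(geno, na.rm = TRUE)
  phat <- pm / 2
  keep <- !is.na(phat) & phat > 0 & phat < 1
  if (!any(keep)) stop("all SNPs monomorphic")
  G <- geno[, keep, drop = FALSE]
  pm <- pm[keep]; phat <- phat[keep]
  na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na)) G[na] <- pm[na[, 2L]]
  X <- sweep(sweep(G, 2L, 2 * phat, "-"), 2L,
             sqrt(2 * phat * (1 - phat)), "/")
  s <- svd(X)
  k <- min(n_components, length(s$d))
  for (j in seq_len(k)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  coords <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  rownames(coords) <- rownames(geno)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       explained_variance = (s$d^2 / sum(s$d^2))[seq_len(k)],
       sdev = s$d / sqrt(nrow(X) - 1))
}
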