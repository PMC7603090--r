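# Extended haplotype homozygosity (EHH) and the cross-population XP-EHH
# statistic from phased haplotypes.
#
# Moving outward from a core SNP, haplotypes are partitioned by their full
# allele vector over the closed marker interval [core..x]; in the default
# pooled mode
#   EHH(x) = sum_i C(n_i, 2) / (C(n_a, 2) + C(n_A, 2))
# where n_i are the partition class sizes and n_a, n_A the counts of the
# two core alleles. Because the core allele is part of the interval, the
# partition never mixes core alleles and EHH(core) = 1. Classes only refine
# outward, so every curve is non-increasing in |offset|.
#
# XP-EHH integrates each population's EHH over a shared domain D, extended
# per direction until max(EHH_obj, EHH_ref) < epsilon (the first
# below-threshold marker closes the domain), and reports the plain ratio
# of the trapezoidal integrals plus its log.

.choose2 <- function(n) n * (n - 1) / 2

# Partition state over the active (non-missing-so-far) haplotypes.
# The denominator is fixed at the core; haplotypes with a missing allele
# are dropped from the numerator from that marker outward.
.ehh_init <- function(H, core, mode = "pooled", allele = 1L) {
  a <- H[, core]
  active <- which(!is.na(a))
  if (mode == "per_allele") active <- active[a[active] == allele]
  n_a <- sum(a == 0L, na.rm = TRUE)
  n_A <- sum(a == 1L, na.rm = TRUE)
  den <- if (mode == "pooled") .choose2(n_a) + .choose2(n_A)
         else .choose2(length(active))
  g <- match(a[active], unique(a[active]))
  tab <- tabulate(g)
  list(active = active, g = g, num = sum(.choose2(tab)), den = den,
       n_a = n_a, n_A = n_A)
}

.ehh_step <- function(state, col) {
  if (state$num == 0) return(state)  # fully refined, EHH stays 0
  a <- col[state$active]
  if (anyNA(a)) {
    keep <- !is.na(a)
    state$active <- state$active[keep]
    state$g <- state$g[keep]
    a <- a[keep]
  }
  key <- state$g * 2L + a
  g <- match(key, unique(key))
  tab <- tabulate(g)
  state$g <- g
  state$num <- sum(tab * (tab - 1L)) / 2
  state
}

#' EHH decay curve around a core SNP
#'
#' @param haps Haplotype matrix of one population (0/1/NA, 2 rows per
#'   sample).
#' @param variants Matching variant table (for bp positions).
#' @param core Core variant index (column of `haps`).
#' @param epsilon Stop extending a direction once EHH < `epsilon`
#'   (default 0.05); the terminal marker is retained.
#' @param mode `"pooled"` (default) uses the pooled denominator
#'   `C(n_a,2) + C(n_A,2)`; `"per_allele"` gives the classical single-core-
#'   allele EHH for the haplotypes carrying `allele`.
#' @param allele Core allele (0 or 1) tracked in `per_allele` mode.
#' @return data.frame (`index`, `pos`, `offset`, `ehh`) ordered left to
#'   right with the core included (EHH = 1), plus attributes `core_index`,
#'   `n_a`, `n_A`. Returns `NULL` when EHH is undefined (denominator 0).
#' @export
ehh_curve <- function(haps, variants, core, epsilon = 0.05,
                      mode = c("pooled", "per_allele"), allele = 1L) {
  mode <- match.arg(mode)
  stopifnot(nrow(haps) >= 2L, core >= 1L, core <= ncol(haps))
  st0 <- .ehh_init(haps, core, mode, allele)
  if (st0$den == 0) return(NULL)
  m <- ncol(haps)
  walk <- function(idx) {
    st <- st0
    out_i <- integer(0); out_e <- numeric(0)
    for (j in idx) {
      st <- .ehh_step(st, haps[, j])
      e <- st$num / st$den
      out_i <- c(out_i, j); out_e <- c(out_e, e)
      if (e < epsilon) break
    }
    list(i = out_i, e = out_e)
  }
  left <- walk(rev(seq_len(core - 1L)))
  right <- walk(seq_len(m)[-seq_len(core)])
  idx <- c(rev(left$i), core, right$i)
  ehh <- c(rev(left$e), 1, right$e)
  out <- data.frame(index = idx, pos = variants$pos[idx],
                    offset = variants$pos[idx] - variants$pos[core],
                    ehh = ehh)
  attr(out, "core_index") <- core
  attr(out, "n_a") <- st0$n_a
  attr(out, "n_A") <- st0$n_A
  class(out) <- c("ehh_curve", "data.frame")
  out
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Joint extension for one core: returns c(iehh_obj, iehh_ref, left, right)
# or NULL when either population's denominator is 0.
.xpehh_core <- function(Hobj, Href, pos, core, epsilon) {
  so <- .ehh_init(Hobj, core)
  sr <- .ehh_init(Href, core)
  if (so$den == 0 || sr$den == 0) return(NULL)
  m <- length(pos)
  walk <- function(idx) {
    o <- so; r <- sr
    px <- numeric(0); eo <- numeric(0); er <- numeric(0)
    for (j in idx) {
      o <- .ehh_step(o, Hobj[, j])
      r <- .ehh_step(r, Href[, j])
      vo <- o$num / o$den; vr <- r$num / r$den
      px <- c(px, pos[j]); eo <- c(eo, vo); er <- c(er, vr)
      if (max(vo, vr) < epsilon) break
    }
    list(px = px, eo = eo, er = er)
  }
  lf <- walk(rev(seq_len(core - 1L)))
  rt <- walk(seq_len(m)[-seq_len(core)])
  px <- c(rev(lf$px), pos[core], rt$px)
  eo <- c(rev(lf$eo), 1, rt$eo)
  er <- c(rev(lf$er), 1, rt$er)
  c(.trapz(px, eo), .trapz(px, er), px[1L], px[length(px)])
}

#' XP-EHH at one core SNP
#'
#' Integrates the EHH of the object and reference populations over the
#' shared domain D and reports the plain integral ratio
#' `iEHH_obj / iEHH_ref` together with its natural log.
#'
#' @param core Core variant index.
#' @param haps_obj,haps_ref Haplotype matrices of the object and reference
#'   populations over the same variants.
#' @param variants Matching variant table.
#' @param epsilon Domain cutoff: extension stops per direction once both
#'   populations' EHH are below `epsilon` (default 0.05).
#' @return List with `iehh_obj`, `iehh_ref`, `ratio`, `ln_ratio` and
#'   `domain` (bp bounds); values are `NA` when undefined (e.g. reference
#'   integral 0).
#' @export
xpehh_at <- function(core, haps_obj, haps_ref, variants, epsilon = 0.05) {
  stopifnot(ncol(haps_obj) == nrow(variants),
            ncol(haps_ref) == nrow(variants))
  v <- .xpehh_core(haps_obj, haps_ref, variants$pos, core, epsilon)
  if (is.null(v) || v[2L] == 0) {
    return(list(iehh_obj = if (is.null(v)) NA_real_ else v[1L],
                iehh_ref = if (is.null(v)) NA_real_ else v[2L],
                ratio = NA_real_, ln_ratio = NA_real_,
                domain = if (is.null(v)) c(NA_real_, NA_real_) else v[3:4]))
  }
  ratio <- v[1L] / v[2L]
  list(iehh_obj = v[1L], iehh_ref = v[2L], ratio = ratio,
       ln_ratio = log(ratio), domain = v[3:4])
}

#' Genome scan of XP-EHH
#'
#' Applies [xpehh_at()] to every variant as core. The `ln_z` column is the
#' genome-wide z-standardization of `ln_ratio`.
#'
#' @inheritParams xpehh_at
#' @param haps_obj,haps_ref Haplotype matrices of the two populations.
#' @return data.frame with `variant_id`, `ratio`, `ln_ratio`, `ln_z`,
#'   `iehh_obj`, `iehh_ref`, `left_bp`, `right_bp`; `NA` where undefined.
#' @export
xpehh_scan <- function(haps_obj, haps_ref, variants, epsilon = 0.05) {
  m <- nrow(variants)
  stopifnot(ncol(haps_obj) == m, ncol(haps_ref) == m)
  pos <- variants$pos
  io <- ir <- lb <- rb <- rep(NA_real_, m)
  Ho <- haps_obj; Hr <- haps_ref
  storage.mode(Ho) <- "integer"; storage.mode(Hr) <- "integer"
  for (core in seq_len(m)) {
    v <- .xpehh_core(Ho, Hr, pos, core, epsilon)
    if (!is.null(v)) {
      io[core] <- v[1L]; ir[core] <- v[2L]
      lb[core] <- v[3L]; rb[core] <- v[4L]
    }
  }
  ratio <- ifelse(!is.na(ir) & ir > 0, io / ir, NA_real_)
  ln_ratio <- log(ratio)
  sd_ln <- stats::sd(ln_ratio, na.rm = TRUE)
  ln_z <- if (is.na(sd_ln) || sd_ln == 0) rep(NA_real_, m)
          else (ln_ratio - mean(ln_ratio, na.rm = TRUE)) / sd_ln
  data.frame(variant_id = variants$variant_id, ratio = ratio,
             ln_ratio = ln_ratio, ln_z = ln_z, iehh_obj = io, iehh_ref = ir,
             left_bp = lb, right_bp = rb, stringsAsFactors = FALSE)
}

#' Haplotype rows of one population
#'
#' Convenience accessor: subsets a haplotype matrix (2 rows per sample) to
#' the samples of one population, preserving attributes.
#'
#' @param haps Haplotype matrix.
#' @param pops Population map data.frame.
#' @param label Population label.
#' @return Haplotype matrix of that population.
#' @export
pop_haplotypes <- function(haps, pops, label) {
  rows <- .pop_hap_rows(haps, pops, label)
  h <- haps[rows, , drop = FALSE]
  attr(h, "sample_ids") <-
    attr(haps, "sample_ids")[unique((rows + 1L) %/% 2L)]
  attr(h, "phased") <- attr(haps, "phased")
  h
}
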