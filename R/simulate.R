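# Balding-Nichols panel simulator with planted selective sweeps.
#
# Sites are independent given the population allele frequencies (no
# background LD); a planted sweep is the only haplotype structure, which
# makes the XP-EHH signal analytically clean. All randomness flows from the
# integer seed in the configuration.

#' Simulation configuration
#'
#' Describes a star-split multi-population SNP panel: an ancestral allele
#' frequency per site, Balding-Nichols drift to each population
#' (`p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `divergence_F` equals the
#' expected Fst), and optional selective sweeps.
#'
#' Defaults mirror a 50K-chip-style breed comparison: three populations of
#' 17, 20 and 16 diploid samples (labelled MGR, LNR, HHG).
#'
#' @param n_pops Number of populations.
#' @param samples_per_pop Integer vector of diploid sample counts (each
#'   >= 2); defaults to `c(17, 20, 16)` truncated/extended to `n_pops`.
#' @param pop_labels Population labels; defaults to
#'   `c("MGR", "LNR", "HHG", "POP4", ...)`.
#' @param n_snps Number of SNPs (>= 10).
#' @param chrom Chromosome name (single simulated chromosome).
#' @param chrom_length Chromosome length in bp.
#' @param divergence_F Balding-Nichols differentiation, in (0, 1).
#' @param ancestral_maf_range Range of the uniform ancestral frequency.
#' @param missing_rate Per-haplotype-entry missingness probability.
#' @param sweeps List of [sweep_spec()] objects applied after the neutral
#'   draw.
#' @param seed Integer seed; same seed gives byte-identical panels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 3L, samples_per_pop = NULL,
                       pop_labels = NULL, n_snps = 5000L, chrom = "1",
                       chrom_length = 5e7, divergence_F = 0.1,
                       ancestral_maf_range = c(0.05, 0.95),
                       missing_rate = 0, sweeps = list(), seed = 1L) {
  n_pops <- as.integer(n_pops)
  if (is.null(samples_per_pop))
    samples_per_pop <- rep_len(c(17L, 20L, 16L), max(n_pops, 3L))[seq_len(n_pops)]
  if (is.null(pop_labels)) {
    base <- c("MGR", "LNR", "HHG")
    pop_labels <- c(base, paste0("POP", seq_len(max(0L, n_pops - 3L)) + 3L))[seq_len(n_pops)]
  }
  stopifnot(length(samples_per_pop) == n_pops,
            all(samples_per_pop >= 2L),
            n_snps >= 10L,
            divergence_F > 0, divergence_F < 1,
            length(ancestral_maf_range) == 2L,
            ancestral_maf_range[1L] > 0, ancestral_maf_range[2L] < 1,
            missing_rate >= 0, missing_rate < 1,
            chrom_length >= n_snps)
  structure(list(
    n_pops = n_pops, samples_per_pop = as.integer(samples_per_pop),
    pop_labels = pop_labels, n_snps = as.integer(n_snps), chrom = chrom,
    chrom_length = chrom_length, divergence_F = divergence_F,
    ancestral_maf_range = ancestral_maf_range, missing_rate = missing_rate,
    sweeps = sweeps, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Sweep specification
#'
#' A sweep is modelled as distance-decaying copying from one donor
#' haplotype: each carrier haplotype takes the donor allele at a variant
#' with probability `exp(-|pos - core_pos| / decay_length)`. This directly
#' produces the extended-homozygosity signature XP-EHH targets without
#' forward-time simulation.
#'
#' @param target_pop Population label carrying the sweep.
#' @param core_pos Sweep core position, bp.
#' @param carrier_fraction Fraction of the target population's haplotypes
#'   that carry the swept haplotype, in (0, 1].
#' @param decay_length e-folding distance (bp) of haplotype identity.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(target_pop, core_pos, carrier_fraction = 0.8,
                       decay_length = 2e6) {
  stopifnot(carrier_fraction > 0, carrier_fraction <= 1, decay_length > 0,
            core_pos >= 1)
  structure(list(target_pop = target_pop, core_pos = core_pos,
                 carrier_fraction = carrier_fraction,
                 decay_length = decay_length), class = "sweep_spec")
}

#' Simulate a phased multi-population SNP panel
#'
#' Positions are drawn uniformly without replacement and sorted; ancestral
#' frequencies are uniform on `ancestral_maf_range`; population frequencies
#' follow the Balding-Nichols Beta; haplotype alleles are independent
#' Bernoulli draws per site. Sweeps in `config$sweeps` are planted
#' afterwards (replicate seeds derived from `config$seed`).
#'
#' @param config A [sim_config()].
#' @return List with `variants`, `haplotypes` (0/1/NA matrix, 2 rows per
#'   sample), and `pops` (sample-to-population data.frame).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  pos <- sort(sample.int(config$chrom_length, m))
  p0 <- runif(m, config$ancestral_maf_range[1L], config$ancestral_maf_range[2L])
  f <- config$divergence_F
  shape1 <- p0 * (1 - f) / f
  shape2 <- (1 - p0) * (1 - f) / f

  ref_alt <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2L)
  pick <- sample.int(4L, m, replace = TRUE)
  variants <- data.frame(
    variant_id = sprintf("snp_%06d", seq_len(m)),
    chrom = config$chrom, pos = as.integer(pos),
    ref = ref_alt[pick, 1L], alt = ref_alt[pick, 2L],
    autosome = !(config$chrom %in% c("X", "Y", "MT")),
    stringsAsFactors = FALSE
  )

  sample_ids <- unlist(lapply(seq_len(config$n_pops), function(k)
    sprintf("%s_%02d", config$pop_labels[k], seq_len(config$samples_per_pop[k]))))
  pops <- data.frame(
    sample_id = sample_ids,
    population = rep(config$pop_labels, config$samples_per_pop),
    stringsAsFactors = FALSE
  )

  blocks <- lapply(seq_len(config$n_pops), function(k) {
    pk <- rbeta(m, shape1, shape2)
    nh <- 2L * config$samples_per_pop[k]
    matrix(rbinom(nh * m, 1L, rep(pk, each = nh)), nrow = nh)
  })
  H <- do.call(rbind, blocks)
  if (config$missing_rate > 0)
    H[runif(length(H)) < config$missing_rate] <- NA_integer_
  rownames(H) <- paste0(rep(sample_ids, each = 2L), "_", rep(1:2, length(sample_ids)))
  attr(H, "sample_ids") <- sample_ids
  attr(H, "phased") <- TRUE

  for (i in seq_along(config$sweeps))
    H <- plant_sweep(H, variants, pops, config$sweeps[[i]],
                     seed = config$seed + 100000L + i)
  list(variants = variants, haplotypes = H, pops = pops)
}

.pop_hap_rows <- function(haps, pops, label) {
  samples <- attr(haps, "sample_ids")
  idx <- which(samples %in% pops$sample_id[pops$population == label])
  if (!length(idx)) stop("no samples in population ", label)
  sort(c(2L * idx - 1L, 2L * idx))
}

#' Plant a selective sweep into a haplotype matrix
#'
#' One donor haplotype is chosen uniformly in the target population; each
#' of a `carrier_fraction` of that population's haplotypes takes the donor
#' allele at each variant with probability
#' `exp(-|pos - core_pos| / decay_length)`. Haplotypes outside the target
#' population are never touched.
#'
#' @param haps Haplotype matrix (2 rows per sample).
#' @param variants Matching variant table.
#' @param pops Sample-to-population data.frame.
#' @param spec A [sweep_spec()].
#' @param seed Integer seed for donor/carrier choice and copying.
#' @return The modified haplotype matrix.
#' @export
plant_sweep <- function(haps, variants, pops, spec, seed) {
  stopifnot(inherits(spec, "sweep_spec"))
  set.seed(seed)
  rows <- .pop_hap_rows(haps, pops, spec$target_pop)
  donor <- rows[sample.int(length(rows), 1L)]
  n_car <- round(spec$carrier_fraction * length(rows))
  if (n_car < 2L)
    warning("fewer than 2 carrier haplotypes; EHH undefined on the sweep")
  carriers <- rows[sample.int(length(rows), n_car)]
  p_copy <- exp(-abs(variants$pos - spec$core_pos) / spec$decay_length)
  donor_row <- haps[donor, ]
  m <- ncol(haps)
  for (h in carriers) {
    take <- runif(m) < p_copy
    haps[h, take] <- donor_row[take]
  }
  haps
}

#' Generate a matching gene and pathway fixture
#'
#' Tiles `n_genes` non-overlapping genes (5-50 kb each) over the simulated
#' chromosome and assigns every gene to 1-3 synthetic pathways, giving
#' downstream annotation and enrichment something real to chew on.
#'
#' @param variants Variant table of the simulated panel.
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param chrom_length Chromosome length; defaults to slightly past the
#'   last variant.
#' @param cover_pos Optional bp positions (e.g. sweep cores) that must each
#'   be covered by a gene; the gene in the containing tile is shifted over
#'   the position, preserving non-overlap.
#' @return List with `genes` and `pathways` data.frames.
#' @export
make_gene_fixture <- function(variants, n_genes, seed, chrom_length = NULL,
                              cover_pos = NULL) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  if (is.null(chrom_length)) chrom_length <- max(variants$pos) + 10000
  slot <- floor(chrom_length / n_genes)
  if (slot < 5000)
    stop("chromosome too short for ", n_genes, " genes of >= 5 kb")
  len_max <- min(50000, slot)
  len <- floor(runif(n_genes, 5000, len_max + 1))
  offset <- floor(runif(n_genes, 0, slot - len + 1))
  start <- (seq_len(n_genes) - 1L) * slot + offset + 1
  end <- start + len - 1

  for (p in cover_pos) {
    i <- min(n_genes, max(1L, ceiling(p / slot)))
    slot_lo <- (i - 1L) * slot + 1
    slot_hi <- i * slot
    s <- max(slot_lo, min(p - floor(len[i] / 2), slot_hi - len[i] + 1))
    start[i] <- s
    end[i] <- s + len[i] - 1
    if (p < start[i] || p > end[i]) {  # position near a tile edge
      start[i] <- max(slot_lo, p - len[i] + 1)
      end[i] <- min(slot_hi, start[i] + len[i] - 1)
    }
  }

  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    name = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = variants$chrom[1L],
    start = as.integer(start), end = as.integer(end),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  n_path <- max(2L, ceiling(n_genes / 4))
  path_ids <- sprintf("pw%03d", seq_len(n_path))
  assignments <- lapply(seq_len(n_genes), function(i)
    sample(path_ids, sample.int(min(3L, n_path), 1L)))
  pathways <- data.frame(
    pathway_id = unlist(assignments),
    gene_id = rep(genes$gene_id, lengths(assignments)),
    stringsAsFactors = FALSE
  )
  pathways <- pathways[order(pathways$pathway_id, pathways$gene_id), ]
  rownames(pathways) <- NULL
  list(genes = genes, pathways = pathways)
}

#' Collapse phased haplotypes to genotype dosages
#'
#' Sums the two haplotypes of each sample to an alt-allele dosage 0/1/2;
#' the genotype is missing if either haplotype is missing.
#'
#' @param haps Haplotype matrix (2 rows per sample).
#' @return n_samples x n_variants integer matrix with sample rownames.
#' @export
haplotypes_to_genotypes <- function(haps) {
  n <- nrow(haps) / 2L
  G <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(G) <- attr(haps, "sample_ids")
  G
}
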