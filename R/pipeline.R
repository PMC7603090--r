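# End-to-end driver: simulate -> write inputs -> QC -> Fst + XP-EHH scans
# per object population -> candidate genes -> merge/overlap -> population
# structure -> enrichment. All outputs are plain text and byte-stable for
# a fixed seed.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] (including any sweeps).
#' @param object_pops Labels scanned against the reference (default: all
#'   simulated populations except `reference_pop`).
#' @param reference_pop Reference population label (default: last
#'   simulated population).
#' @param n_genes Number of fixture genes to tile over the chromosome.
#' @param qc A [qc_thresholds()].
#' @param flank Candidate-region half-width in bp (default 50000).
#' @param epsilon EHH extension cutoff (default 0.05).
#' @param quantile Empirical candidate quantile (default 0.95).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), object_pops = NULL,
                            reference_pop = NULL, n_genes = 100L,
                            qc = qc_thresholds(), flank = 50000,
                            epsilon = 0.05, quantile = 0.95) {
  if (is.null(reference_pop))
    reference_pop <- sim$pop_labels[sim$n_pops]
  if (is.null(object_pops))
    object_pops <- setdiff(sim$pop_labels, reference_pop)
  stopifnot(length(object_pops) >= 1L,
            !(reference_pop %in% object_pops))
  structure(list(sim = sim, object_pops = object_pops,
                 reference_pop = reference_pop, n_genes = as.integer(n_genes),
                 qc = qc, flank = flank, epsilon = epsilon,
                 quantile = quantile), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys mirror the [sim_config()] / [pipeline_config()] arguments;
#' `sweeps` is a list of blocks with `target_pop`, `core_pos`,
#' `carrier_fraction`, `decay_length`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  sweeps <- lapply(y$sweeps, function(s)
    sweep_spec(s$target_pop, s$core_pos,
               carrier_fraction = if (is.null(s$carrier_fraction)) 0.8
                                  else s$carrier_fraction,
               decay_length = if (is.null(s$decay_length)) 2e6
                              else s$decay_length))
  sim_args <- y[intersect(names(y), names(formals(sim_config)))]
  sim_args$sweeps <- sweeps
  sim <- do.call(sim_config, sim_args)
  qc_args <- y[intersect(names(y), names(formals(qc_thresholds)))]
  pc_args <- y[intersect(names(y),
                         setdiff(names(formals(pipeline_config)),
                                 c("sim", "qc")))]
  do.call(pipeline_config,
          c(list(sim = sim, qc = do.call(qc_thresholds, qc_args)), pc_args))
}

.write_tsv <- function(df, path, digits_cols = NULL) {
  for (col in digits_cols) df[[col]] <- .fmt6(df[[col]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Run the full selection-signature pipeline
#'
#' Simulates a panel (with any configured sweeps), writes the standard
#' input formats (phased VCF, population map, gene GFF3, pathway TSV),
#' applies QC, runs the per-SNP Fst and XP-EHH scans for every object
#' population against the reference, calls top-quantile candidates,
#' annotates flanking genes, merges the method gene lists, intersects the
#' pairs, summarizes population structure (pairwise-Fst matrix, NJ tree,
#' PCA) and runs pathway enrichment on each pair's merged set. Outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config A [pipeline_config()] (or [pipeline_config_from_yaml()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, paste0(...))

  panel <- simulate_panel(config$sim)
  cores <- vapply(config$sim$sweeps, `[[`, numeric(1), "core_pos")
  fixture <- make_gene_fixture(panel$variants, config$n_genes,
                               seed = config$sim$seed + 555L,
                               chrom_length = config$sim$chrom_length,
                               cover_pos = cores)
  write_phased_vcf(panel$variants, panel$haplotypes, path("panel.vcf"))
  write_population_map(panel$pops, path("populations.tsv"))
  write_gene_models(fixture$genes, path("genes.gff3"), format = "gff3")
  write_pathway_map(fixture$pathways, path("pathways.tsv"))

  G <- haplotypes_to_genotypes(panel$haplotypes)
  qc <- apply_qc(G, panel$variants, config$qc, pops = panel$pops,
                 haplotypes = panel$haplotypes)
  .write_tsv(data.frame(rule = c("input", "pass",
                                 names(qc$report$n_fail_by_rule)),
                        n = c(qc$report$n_input, qc$report$n_pass,
                              unname(qc$report$n_fail_by_rule))),
             path("qc_report.tsv"))
  write_phased_vcf(qc$variants, qc$haplotypes, path("panel_qc.vcf"))

  ref_h <- pop_haplotypes(qc$haplotypes, panel$pops, config$reference_pop)
  scans <- list()
  for (obj in config$object_pops) {
    pair <- paste0(obj, "-", config$reference_pop)
    fst <- fst_scan(qc$genotypes, panel$pops, obj, config$reference_pop)
    obj_h <- pop_haplotypes(qc$haplotypes, panel$pops, obj)
    xp <- xpehh_scan(obj_h, ref_h, qc$variants, config$epsilon)
    res <- scan_result(qc$variants, fst, xp$ratio, pair = pair,
                       quantile = config$quantile)
    gene_map <- nearest_gene_map(qc$variants, fixture$genes, config$flank)
    write_scan_results(res, path("scan_", pair, ".tsv"),
                       genes = gene_map$gene_id)
    scans[[pair]] <- res
  }

  report <- gene_set_report(scans, fixture$genes, config$flank)
  gene_rows <- do.call(rbind, lapply(names(report$sets), function(pair) {
    s <- report$sets[[pair]]
    data.frame(pair = pair,
               method = rep(c("fst", "xpehh", "merged"),
                            c(length(s$fst), length(s$xpehh),
                              length(s$merged))),
               gene_id = c(s$fst, s$xpehh, s$merged),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(report$overlap) && length(report$overlap))
    gene_rows <- rbind(gene_rows,
                       data.frame(pair = "all", method = "overlap",
                                  gene_id = report$overlap,
                                  stringsAsFactors = FALSE))
  .write_tsv(gene_rows, path("candidate_genes.tsv"))

  enrich <- lapply(names(report$sets), function(pair) {
    e <- hypergeom_enrich(report$sets[[pair]]$merged, fixture$pathways,
                          background = fixture$genes$gene_id)
    .write_tsv(e, path("enrichment_", pair, ".tsv"),
               digits_cols = c("p", "q"))
    e
  })
  names(enrich) <- names(report$sets)

  fst_mat <- pairwise_fst_matrix(qc$genotypes, panel$pops)
  .write_tsv(cbind(data.frame(population = rownames(fst_mat)),
                   as.data.frame(round(fst_mat, 6))),
             path("pairwise_fst.tsv"))
  tree <- NULL
  if (nrow(fst_mat) >= 3L) {
    tree <- nj_tree(fst_mat)
    ape::write.tree(tree, path("nj_tree.nwk"))
  }
  pca <- genotype_pca(qc$genotypes, n_components = 2L)
  .write_tsv(data.frame(sample_id = rownames(pca$coordinates),
                        population = panel$pops$population,
                        PC1 = pca$coordinates[, 1L],
                        PC2 = pca$coordinates[, 2L]),
             path("pca.tsv"), digits_cols = c("PC1", "PC2"))

  invisible(list(panel = panel, fixture = fixture, qc = qc, scans = scans,
                 genes = report, enrichment = enrich, fst_matrix = fst_mat,
                 tree = tree, pca = pca, out_dir = out_dir))
}
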