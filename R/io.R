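# External formats: phased VCF, population map TSV, gene BED/GFF3,
# pathway map TSV, scan-result TSV. Coordinates are 1-based inclusive
# internally; BED is converted on read.

#' Read a phased VCF into a variant table and haplotype matrix
#'
#' Parses a VCF 4.x file with per-sample GT fields. Only biallelic SNP
#' records are kept; multiallelic records and indels are dropped with a
#' message. Allele 0 maps to the reference allele, 1 to the alternate.
#' `./.` becomes missing on both haplotypes; half-calls keep the known
#' allele and are never treated as phase violations.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param require_phased If `TRUE` (default), a non-missing unphased
#'   genotype (`/` separator) is an error; if `FALSE` it is accepted with a
#'   warning and the written allele order is used as the phase.
#' @param non_autosomes Chromosome names flagged as non-autosomal
#'   (default `c("X", "Y", "MT")`); downstream QC can drop them.
#' @return A list with `variants` (data.frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `autosome`) and `haplotypes` (integer 0/1/NA matrix,
#'   2 rows per sample in header order, with attributes `sample_ids` and
#'   `phased`).
#' @export
read_phased_vcf <- function(path, require_phased = TRUE,
                            non_autosomes = c("X", "Y", "MT")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L)
    stop("VCF has no genotype columns")
  fmt <- vcf@gt[, "FORMAT"]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (!all(has_gt)) stop("every VCF record must carry a GT field")
  samples <- colnames(vcf@gt)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id in VCF header: ",
         samples[duplicated(samples)][1L])

  fix <- vcf@fix
  keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("read_phased_vcf: dropped ", n_drop,
            " non-biallelic-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  id <- fix[keep, "ID"]
  synth <- is.na(id) | id == "."
  id[synth] <- paste0(chrom[synth], "_", pos[synth])
  if (anyDuplicated(id)) {
    warning("non-unique variant ids; made unique")
    id <- make.unique(id, sep = "_")
  }

  # deterministic order: chromosomes in input order, positions increasing
  ord <- order(match(chrom, unique(chrom)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; id <- id[ord]
  ref <- fix[keep, "REF"][ord]; alt <- fix[keep, "ALT"][ord]
  gt <- gt[ord, , drop = FALSE]
  dup <- duplicated(paste(chrom, pos))
  if (any(dup))
    stop("duplicate variant position: ", chrom[dup][1L], ":", pos[dup][1L])

  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  no_sep <- !grepl("[/|]", gt) & !is.na(gt)
  if (any(no_sep & gt != "."))
    stop("haploid or malformed GT encountered: ", gt[no_sep & gt != "."][1L])
  a1[no_sep] <- "."; a2[no_sep] <- "."
  a1[is.na(gt)] <- "."; a2[is.na(gt)] <- "."
  half_missing <- a1 == "." | a2 == "."
  unphased <- grepl("/", gt, fixed = TRUE) & !half_missing & !is.na(gt)
  if (any(unphased)) {
    if (require_phased)
      stop("unphased genotype found (use require_phased = FALSE to accept)")
    warning("unphased genotypes accepted; written allele order used as phase")
  }
  to_int <- function(a) {
    a[a == "."] <- NA
    v <- suppressWarnings(as.integer(a))
    if (any(!is.na(v) & !(v %in% c(0L, 1L))))
      stop("allele index other than 0/1 in a biallelic record")
    v
  }
  a1 <- matrix(to_int(a1), nrow = nrow(gt))
  a2 <- matrix(to_int(a2), nrow = nrow(gt))

  n <- length(samples)
  H <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(gt))
  H[seq(1L, 2L * n, by = 2L), ] <- t(a1)
  H[seq(2L, 2L * n, by = 2L), ] <- t(a2)
  rownames(H) <- paste0(rep(samples, each = 2L), "_", rep(1:2, n))
  attr(H, "sample_ids") <- samples
  attr(H, "phased") <- !any(unphased)

  variants <- data.frame(
    variant_id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    autosome = !(chrom %in% non_autosomes),
    stringsAsFactors = FALSE
  )
  list(variants = variants, haplotypes = H, n_dropped = n_drop)
}

#' Write a variant table and phased haplotype matrix as VCF
#'
#' Emits a minimal plain-text VCF 4.2 with phased GT fields; missing
#' haplotypes are written as `./.`. `read_phased_vcf()` is its inverse.
#'
#' @param variants Variant data.frame as returned by [read_phased_vcf()].
#' @param haplotypes 0/1/NA haplotype matrix, 2 rows per sample, with a
#'   `sample_ids` attribute (or rownames `<sample>_1` / `<sample>_2`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(variants, haplotypes, path) {
  samples <- attr(haplotypes, "sample_ids")
  if (is.null(samples))
    samples <- unique(sub("_[12]$", "", rownames(haplotypes)))
  stopifnot(nrow(haplotypes) == 2L * length(samples),
            ncol(haplotypes) == nrow(variants))
  n <- length(samples)
  a1 <- haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                      ifelse(is.na(a2), ".", a2)), nrow = n)
  gt[is.na(a1) & is.na(a2)] <- "./."
  body <- cbind(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", ".", ".", "GT", t(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=selsig",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  con <- file(path, "wb")  # fixed newlines for byte-stable output
  on.exit(close(con))
  writeLines(c(header, apply(body, 1L, paste, collapse = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated file: `sample_id<TAB>population`. A header line
#' `sample_id<TAB>population` is tolerated.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `sample_id`, `population`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample_id", "population"),
                          colClasses = "character")
  if (nrow(df) && df$sample_id[1L] == "sample_id") df <- df[-1L, ]
  if (anyDuplicated(df$sample_id))
    stop("sample assigned to more than one population: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  rownames(df) <- NULL
  df
}

#' @rdname read_population_map
#' @param pops data.frame with `sample_id` and `population`.
#' @export
write_population_map <- function(pops, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(pops$sample_id, pops$population, sep = "\t"), con)
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Coordinates are normalized to 1-based inclusive (BED start `s` becomes
#' `s + 1`); GFF3 files are reduced to their `gene` features when typed
#' features are present.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame with `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-` or `*`).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(df) &&
      any(df$type == "gene")) df <- df[df$type == "gene", ]
  gene_id <- if (format == "bed") {
    if ("name" %in% names(df)) as.character(df$name) else
      paste0("gene_", seq_len(nrow(df)))
  } else {
    id <- rep(NA_character_, nrow(df))
    for (col in c("gene_id", "ID", "Name"))
      if (col %in% names(df)) id <- ifelse(is.na(id), as.character(df[[col]]), id)
    id[is.na(id)] <- paste0("gene_", which(is.na(id)))
    id
  }
  name <- if ("Name" %in% names(df)) as.character(df$Name) else gene_id
  name[is.na(name)] <- gene_id[is.na(name)]
  out <- data.frame(
    gene_id = gene_id, name = name,
    chrom = as.character(df$seqnames),
    start = as.integer(df$start), end = as.integer(df$end),
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
  if (any(out$end < out$start))
    stop("gene with end < start after normalization")
  rownames(out) <- NULL
  out
}

#' Write gene models as BED4+ or GFF3
#'
#' @param genes Gene data.frame (see [read_gene_models()]).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  lines <- if (format == "bed") {
    paste(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
          0L, strand, sep = "\t")
  } else {
    c("##gff-version 3",
      paste(genes$chrom, "selsig", "gene", genes$start, genes$end, ".",
            strand, ".",
            paste0("ID=", genes$gene_id, ";Name=", genes$name),
            sep = "\t"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read or write a pathway-to-gene map
#'
#' Two-column tab-separated file, one `pathway_id<TAB>gene_id` pair per
#' line; a header is tolerated on read.
#'
#' @param path Path to the TSV.
#' @return data.frame with `pathway_id`, `gene_id`.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("pathway_id", "gene_id"),
                          colClasses = "character")
  if (nrow(df) && df$pathway_id[1L] == "pathway_id") df <- df[-1L, ]
  rownames(df) <- NULL
  df
}

#' @rdname read_pathway_map
#' @param pathways data.frame with `pathway_id` and `gene_id`.
#' @export
write_pathway_map <- function(pathways, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(pathways$pathway_id, pathways$gene_id, sep = "\t"), con)
  invisible(path)
}

.fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Write scan results as TSV
#'
#' Columns mirror the per-SNP report of a two-statistic scan: `breed_pair`,
#' `chrom`, `pos`, `fst`, `xpehh`, `ln_xpehh`, `candidate_fst`,
#' `candidate_xpehh`, `genes`. Floats are written at 6 decimals, so
#' write-read-write is byte identical.
#'
#' @param result A [scan_result()] object, or a data.frame already in the
#'   output column layout (as returned by [read_scan_results()]).
#' @param path Output path.
#' @param genes Optional character vector (one entry per variant) with the
#'   nearest candidate gene per SNP; defaults to empty strings.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(result, path, genes = NULL) {
  df <- if (inherits(result, "scan_result")) {
    v <- result$variants
    data.frame(
      breed_pair = result$pair, chrom = v$chrom, pos = v$pos,
      fst = result$fst, xpehh = result$xpehh, ln_xpehh = result$ln_xpehh,
      candidate_fst = result$candidate_fst,
      candidate_xpehh = result$candidate_xpehh,
      genes = if (is.null(genes)) "" else genes,
      stringsAsFactors = FALSE
    )
  } else result
  out <- data.frame(
    breed_pair = df$breed_pair, chrom = df$chrom, pos = df$pos,
    fst = .fmt6(df$fst), xpehh = .fmt6(df$xpehh),
    ln_xpehh = .fmt6(df$ln_xpehh),
    candidate_fst = df$candidate_fst, candidate_xpehh = df$candidate_xpehh,
    genes = ifelse(is.na(df$genes), "", df$genes),
    stringsAsFactors = FALSE
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  df <- utils::read.table(
    path, sep = "\t", header = TRUE, na.strings = "NA", quote = "",
    colClasses = c(breed_pair = "character", chrom = "character",
                   pos = "integer", fst = "numeric", xpehh = "numeric",
                   ln_xpehh = "numeric", candidate_fst = "logical",
                   candidate_xpehh = "logical", genes = "character"),
    stringsAsFactors = FALSE
  )
  df$genes[is.na(df$genes)] <- ""
  df
}
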