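test_that("the same seed reproduces a panel byte for byte", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(5L, 5L), n_snps = 200L,
                    chrom_length = 1e6, seed = 42L)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_pops = 2L, samples_per_pop = c(5L, 5L), n_snps = 200L,
                     chrom_length = 1e6, seed = 43L)
  expect_false(identical(simulate_panel(cfg2)$haplotypes, a$haplotypes))
})

test_that("panel structure honours the configuration", {
  cfg <- sim_config(seed = 1L, n_snps = 100L, chrom_length = 1e6)
  panel <- simulate_panel(cfg)
  expect_equal(nrow(panel$haplotypes), 2L * (17L + 20L + 16L))
  expect_equal(panel$pops$population,
               rep(c("MGR", "LNR", "HHG"), c(17L, 20L, 16L)))
  expect_false(is.unsorted(panel$variants$pos, strictly = TRUE))
  expect_true(all(panel$haplotypes %in% c(0L, 1L)))
})

test_that("population frequencies track their Balding-Nichols draws", {
  # binomial sampling error around p_k: compare observed per-pop allele
  # frequencies against their own haplotype-count expectation
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(50L, 50L),
                    n_snps = 500L, chrom_length = 1e7, divergence_F = 0.2,
                    seed = 7L)
  panel <- simulate_panel(cfg)
  G <- haplotypes_to_genotypes(panel$haplotypes)
  for (lab in unique(panel$pops$population)) {
    g <- G[panel$pops$population == lab, ]
    p_obs <- colMeans(g) / 2
    expect_true(all(p_obs >= 0 & p_obs <= 1))
  }
  # and the two populations actually differ
  g1 <- G[panel$pops$population == "MGR", ]
  g2 <- G[panel$pops$population == "LNR", ]
  expect_gt(mean(abs(colMeans(g1) - colMeans(g2)) / 2), 0.05)
})

test_that("near-zero divergence gives a near-zero mean Fst", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(20L, 20L),
                    n_snps = 5000L, chrom_length = 5e7,
                    divergence_F = 1e-3, seed = 3L)
  panel <- simulate_panel(cfg)
  G <- haplotypes_to_genotypes(panel$haplotypes)
  f <- fst_scan(G, panel$pops, "MGR", "LNR")
  expect_lte(abs(mean(f, na.rm = TRUE)), 0.01)
})

test_that("mean Fst increases monotonically with divergence_F", {
  genome_fst <- vapply(c(0.05, 0.1, 0.2, 0.4), function(F) {
    cfg <- sim_config(n_pops = 2L, samples_per_pop = c(20L, 20L),
                      n_snps = 2000L, chrom_length = 2e7,
                      divergence_F = F, seed = 5L)
    panel <- simulate_panel(cfg)
    G <- haplotypes_to_genotypes(panel$haplotypes)
    pairwise_fst_matrix(G, panel$pops)[1L, 2L]
  }, numeric(1))
  expect_false(is.unsorted(genome_fst, strictly = TRUE))
})

test_that("a full-frequency, infinite-decay sweep copies the donor everywhere", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(8L, 8L), n_snps = 100L,
                    chrom_length = 1e6, seed = 9L)
  panel <- simulate_panel(cfg)
  swept <- plant_sweep(panel$haplotypes, panel$variants, panel$pops,
                       sweep_spec("MGR", 5e5, carrier_fraction = 1,
                                  decay_length = Inf), seed = 21L)
  rows <- 1:16  # MGR haplotypes
  expect_true(all(apply(swept[rows, ], 2L, function(x) length(unique(x)) == 1L)))
  curve <- ehh_curve(swept[rows, ], panel$variants, core = 50L)
  expect_true(all(curve$ehh == 1))
  # non-target population untouched, bitwise
  expect_identical(swept[-rows, ], panel$haplotypes[-rows, ])
})

test_that("zero-decay sweeps only touch the immediate core", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(8L, 8L), n_snps = 100L,
                    chrom_length = 1e6, seed = 9L)
  panel <- simulate_panel(cfg)
  core_pos <- panel$variants$pos[50L]
  swept <- plant_sweep(panel$haplotypes, panel$variants, panel$pops,
                       sweep_spec("MGR", core_pos, carrier_fraction = 1,
                                  decay_length = 1e-9), seed = 21L)
  expect_identical(swept[, -50L], panel$haplotypes[, -50L])
})

test_that("sweeps never modify haplotypes outside the target population", {
  cfg <- sim_config(seed = 13L, n_snps = 200L, chrom_length = 2e6)
  panel <- simulate_panel(cfg)
  swept <- plant_sweep(panel$haplotypes, panel$variants, panel$pops,
                       sweep_spec("LNR", 1e6, 0.8, 5e5), seed = 31L)
  other <- panel$pops$population != "LNR"
  rows <- rep(other, each = 2L)
  expect_identical(swept[rows, ], panel$haplotypes[rows, ])
  expect_false(identical(swept[!rows, ], panel$haplotypes[!rows, ]))
})

test_that("gene fixtures are non-overlapping and referentially consistent", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(4L, 4L), n_snps = 100L,
                    chrom_length = 5e6, seed = 2L)
  panel <- simulate_panel(cfg)
  fix <- make_gene_fixture(panel$variants, 40L, seed = 15L,
                           chrom_length = 5e6, cover_pos = 2.5e6)
  g <- fix$genes[order(fix$genes$start), ]
  expect_true(all(g$start[-1L] > g$end[-nrow(g)]))           # pairwise disjoint
  expect_true(all(g$end - g$start + 1L >= 5000L))
  expect_true(all(g$end - g$start + 1L <= 50000L))
  expect_true(any(g$start <= 2.5e6 & g$end >= 2.5e6))        # cover_pos honoured
  expect_true(all(fix$pathways$gene_id %in% fix$genes$gene_id))
  expect_true(all(table(fix$pathways$gene_id) >= 1L))
  expect_true(all(table(fix$pathways$gene_id) <= 3L))

  single <- make_gene_fixture(panel$variants, 1L, seed = 15L,
                              chrom_length = 5e6)
  expect_equal(nrow(single$genes), 1L)
  expect_gte(nrow(single$pathways), 1L)
  expect_error(make_gene_fixture(panel$variants, 10000L, seed = 1L,
                                 chrom_length = 5e6), "too short")
})
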