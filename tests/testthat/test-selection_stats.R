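test_that("per-SNP Fst matches the closed-form edge cases", {
  expect_equal(fst_per_snp(20, 1, 20, 0)$fst, 1)           # fixed difference
  r <- fst_per_snp(20, 0.5, 20, 0.5)
  expect_equal(r$msp, 0)
  expect_equal(r$fst, -1 / (r$n_c - 1))                    # = -1/19
  expect_equal(r$fst, -1 / 19, tolerance = 1e-12)
  r2 <- fst_per_snp(20, 0.8, 20, 0.2)
  expect_equal(r2$msp, 3.6, tolerance = 1e-12)
  expect_equal(r2$msg, 6.4 / 38, tolerance = 1e-12)
  expect_equal(r2$n_c, 20, tolerance = 1e-12)
  expect_equal(r2$fst, 0.50464, tolerance = 1e-4)
  expect_true(is.na(fst_per_snp(10, 0, 10, 0)$fst))        # 0/0
})

test_that("per-SNP Fst equals the allele-level ANOVA oracle", {
  set.seed(10)
  for (i in 1:200) {
    m1 <- 2L * sample(2:30, 1L); m2 <- 2L * sample(2:30, 1L)
    x1 <- sample(0:m1, 1L); x2 <- sample(0:m2, 1L)
    if (x1 == 0 && x2 == 0) next
    if (x1 == m1 && x2 == m2) next
    got <- fst_per_snp(m1, x1 / m1, m2, x2 / m2)$fst
    expect_lt(abs(got - fst_anova_oracle(m1, x1, m2, x2)), 1e-12)
    expect_lte(got, 1)
  }
})

test_that("fst_scan composes fst_per_snp column-wise and ignores sample order", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(10L, 12L),
                    n_snps = 80L, chrom_length = 1e6, divergence_F = 0.2,
                    missing_rate = 0.05, seed = 4L)
  panel <- simulate_panel(cfg)
  G <- haplotypes_to_genotypes(panel$haplotypes)
  f <- fst_scan(G, panel$pops, "MGR", "LNR")
  for (j in c(1L, 17L, 80L)) {
    g1 <- G[panel$pops$population == "MGR", j]
    g2 <- G[panel$pops$population == "LNR", j]
    m1 <- 2 * sum(!is.na(g1)); m2 <- 2 * sum(!is.na(g2))
    ref <- fst_per_snp(m1, sum(g1, na.rm = TRUE) / m1,
                       m2, sum(g2, na.rm = TRUE) / m2)$fst
    expect_equal(f[j], ref, tolerance = 1e-12)
  }
  perm <- sample(nrow(G))
  expect_equal(fst_scan(G[perm, ], panel$pops, "MGR", "LNR"), f)
  expect_error(fst_scan(G, panel$pops, "MGR", "NOPE"), "population")
})

test_that("a panel of fixed differences scans to Fst = 1 everywhere", {
  G <- rbind(matrix(0L, 6L, 10L), matrix(2L, 6L, 10L))
  rownames(G) <- sprintf("s%02d", 1:12)
  pops <- data.frame(sample_id = rownames(G),
                     population = rep(c("A", "B"), each = 6L))
  expect_equal(fst_scan(G, pops, "A", "B"), rep(1, 10L))
})

test_that("EHH hits the hand-computable configurations", {
  variants <- toy_variants(c(100L, 200L, 300L))
  # two identical pairs out to both ends: EHH = 1 everywhere
  H <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  curve <- ehh_curve(H, variants, core = 2L)
  expect_equal(curve$ehh, rep(1, 3L))
  expect_equal(curve$ehh[curve$offset == 0], 1)
  # all four haplotypes distinct over [core..x]: EHH = 0
  H2 <- rbind(c(0L, 0L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L), c(1L, 1L, 1L))
  curve2 <- ehh_curve(H2, variants, core = 2L, epsilon = 0)
  expect_equal(curve2$ehh[curve2$offset == 0], 1)
  expect_equal(curve2$ehh[curve2$offset > 0], 0)
})

test_that("EHH equals brute-force partition counting on random panels", {
  cases <- 0L
  for (seed in 1:40) {
    n_hap <- sample(4:12, 1L)
    n_mark <- sample(8:20, 1L)
    H <- random_hap_matrix(n_hap, n_mark, seed = seed,
                           miss = if (seed %% 4 == 0) 0.05 else 0)
    variants <- toy_variants(sort(sample.int(1e5, n_mark)))
    core <- sample(n_mark, 1L)
    curve <- ehh_curve(H, variants, core, epsilon = 0)
    if (is.null(curve)) next
    for (r in seq_len(nrow(curve))) {
      expect_equal(curve$ehh[r],
                   ehh_string_oracle(H, core, curve$index[r]),
                   tolerance = 1e-12,
                   info = sprintf("seed %d core %d x %d", seed, core,
                                  curve$index[r]))
    }
    # non-increasing outward in both directions
    left <- curve$ehh[curve$offset <= 0]
    right <- curve$ehh[curve$offset >= 0]
    expect_true(all(diff(left) >= -1e-12))
    expect_true(all(diff(right) <= 1e-12))
    cases <- cases + 1L
  }
  expect_gte(cases, 30L)
})

test_that("per-allele mode reproduces the classical single-allele EHH", {
  H <- random_hap_matrix(10L, 12L, seed = 99L)
  variants <- toy_variants(sort(sample.int(1e5, 12L)))
  core <- 6L
  curve <- ehh_curve(H, variants, core, epsilon = 0, mode = "per_allele",
                     allele = 1L)
  carriers <- H[, core] == 1L
  if (!is.null(curve) && sum(carriers) >= 2L) {
    for (r in seq_len(nrow(curve))) {
      idx <- sort(unique(c(core, curve$index[r])))
      key <- apply(H[carriers, idx[1L]:idx[length(idx)], drop = FALSE],
                   1L, paste, collapse = "")
      expect_equal(curve$ehh[r],
                   sum(choose(table(key), 2)) / choose(sum(carriers), 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("XP-EHH is 1 on identical panels and antisymmetric under swap", {
  H <- random_hap_matrix(12L, 40L, seed = 8L)
  variants <- toy_variants(sort(sample.int(1e6, 40L)))
  res <- xpehh_at(20L, H, H, variants)
  expect_equal(res$ratio, 1)
  expect_equal(res$ln_ratio, 0)

  H2 <- random_hap_matrix(12L, 40L, seed = 88L)
  fwd <- xpehh_scan(H, H2, variants)
  rev <- xpehh_scan(H2, H, variants)
  expect_equal(fwd$ln_ratio, -rev$ln_ratio, tolerance = 1e-12)
})

test_that("an all-identical object population forces XP-EHH > 1", {
  variants <- toy_variants(seq(1000L, 40000L, by = 1000L))
  H_obj <- matrix(0L, 10L, 40L)                    # one shared haplotype
  H_ref <- random_hap_matrix(10L, 40L, seed = 5L)  # EHH breaks down fast
  res <- xpehh_at(20L, H_obj, H_ref, variants)
  expect_gt(res$ratio, 1)
})

test_that("trapezoid and rectangle integration agree on dense curves", {
  # densely spaced markers with a planted mini-sweep: the two quadratures
  # must agree within 2%
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(12L, 12L),
                    n_snps = 1600L, chrom_length = 4e5, divergence_F = 0.1,
                    sweeps = list(sweep_spec("MGR", 2e5, 0.9, 5e4)),
                    seed = 6L)
  panel <- simulate_panel(cfg)
  core <- which.min(abs(panel$variants$pos - 2e5))
  ho <- pop_haplotypes(panel$haplotypes, panel$pops, "MGR")
  hr <- pop_haplotypes(panel$haplotypes, panel$pops, "LNR")
  res <- xpehh_at(core, ho, hr, panel$variants)

  rect_ratio <- local({
    dom <- res$domain
    idx <- which(panel$variants$pos >= dom[1L] & panel$variants$pos <= dom[2L])
    eo <- vapply(idx, function(x) ehh_string_oracle(ho, core, x), numeric(1))
    er <- vapply(idx, function(x) ehh_string_oracle(hr, core, x), numeric(1))
    px <- panel$variants$pos[idx]
    left_rect <- function(y) sum(diff(px) * y[-length(y)])
    left_rect(eo) / left_rect(er)
  })
  expect_equal(res$ratio, rect_ratio, tolerance = 0.02)
})

test_that("a no-sweep panel has median ln XP-EHH near zero", {
  cfg <- sim_config(n_pops = 2L, samples_per_pop = c(17L, 16L),
                    pop_labels = c("MGR", "HHG"), n_snps = 2000L,
                    chrom_length = 2e7, divergence_F = 0.1, seed = 12L)
  panel <- simulate_panel(cfg)
  ho <- pop_haplotypes(panel$haplotypes, panel$pops, "MGR")
  hr <- pop_haplotypes(panel$haplotypes, panel$pops, "HHG")
  xp <- xpehh_scan(ho, hr, panel$variants)
  expect_lte(abs(median(xp$ln_ratio, na.rm = TRUE)), 0.1)
})
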