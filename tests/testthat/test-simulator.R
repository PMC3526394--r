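test_that("the Haldane map function has the right limits and closed-form values", {
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(1e9), 0.5)
  expect_equal(haldane_theta(1), (1 - exp(-0.02)) / 2)
  expect_equal(haldane_theta(1), 0.00990, tolerance = 1e-3)
})

test_that("marker placement is seeded, spans scaffolds, and always includes the causal locus", {
  cfg <- tiny_sim_config(seed = 3)
  set.seed(cfg$seed); m1 <- place_markers(cfg)
  set.seed(cfg$seed); m2 <- place_markers(cfg)
  expect_identical(m1, m2)
  expect_equal(sum(m1$is_causal), 1)
  expect_true(all(m1$N_allele != m1$mapcross_allele))
  expect_true(all(m1$pos >= 1))
  # ~50 markers per 0.5 Mb scaffold at 10 kb spacing
  expect_gt(nrow(m1), 100)
  expect_lt(nrow(m1), 220)

  # spacing beyond the scaffold length: the causal marker survives
  sparse <- sim_config(scaffolds = c(z = 1000), snp_spacing_bp = 1e6,
                       causal = list(chrom = "z", pos = 500), seed = 1)
  set.seed(1)
  expect_true(any(place_markers(sparse)$is_causal))
})

test_that("gamete walks switch origin with Haldane probability", {
  set.seed(9)
  # zero distance: origins never switch
  g <- replicate(50, simulate_gamete(c(1000, 1000 + 0), 1.2))
  expect_true(all(g[1, ] == g[2, ]))
  # huge distance: switch fraction near 1/2
  sw <- replicate(4000, {x <- simulate_gamete(c(1, 1e9), 100); x[1] != x[2]})
  expect_equal(mean(sw), 0.5, tolerance = 0.05)
})

test_that("every mutant embryo is N-homozygous at the causal locus, WT bulk is not", {
  for (s in 1:3) {
    sim <- simulate_bsa(tiny_sim_config(seed = s))
    ci <- which(sim$truth$markers$is_causal)
    expect_true(all(sim$truth$mut_g1[ci, ] & sim$truth$mut_g2[ci, ]))
    expect_false(any(sim$truth$wt_g1[ci, ] & sim$truth$wt_g2[ci, ]))
    expect_equal(ncol(sim$truth$mut_g1), 20)
    expect_equal(ncol(sim$truth$wt_g1), 20)
  }
})

test_that("pool allele frequencies match the analytic truth-table expectations", {
  # aggregate over replicates; compare to exp_wt_n_freq / exp_mut_n_freq
  nrep <- 30
  wt_obs <- wt_exp <- mut_obs <- mut_exp <- 0
  n_wt_chrom <- n_mut_chrom <- 0
  for (s in 1:nrep) {
    sim <- simulate_bsa(tiny_sim_config(seed = 1000 + s))
    tr <- sim$truth
    ci <- which(tr$markers$is_causal)
    wt_obs <- wt_obs + sum(tr$wt_g1[ci, ]) + sum(tr$wt_g2[ci, ])
    wt_exp <- wt_exp + tr$expectations$exp_wt_n_freq[ci] * 2 * ncol(tr$wt_g1)
    n_wt_chrom <- n_wt_chrom + 2 * ncol(tr$wt_g1)
    # one unlinked marker per replicate (markers on a scaffold are linked,
    # so only across-replicate draws are independent)
    ui <- which(tr$markers$chrom == "a")[1]
    mut_obs <- mut_obs + sum(tr$mut_g1[ui, ]) + sum(tr$mut_g2[ui, ])
    mut_exp <- mut_exp + tr$expectations$exp_mut_n_freq[ui] * 2 * ncol(tr$mut_g1)
    n_mut_chrom <- n_mut_chrom + 2 * ncol(tr$mut_g1)
  }
  # WT bulk at the causal locus: 1/3 N alleles (2:1 het : mapcross-hom)
  p_wt <- wt_exp / n_wt_chrom
  expect_equal(p_wt, 1 / 3, tolerance = 1e-9)
  se_wt <- sqrt(p_wt * (1 - p_wt) / n_wt_chrom)
  expect_lt(abs(wt_obs / n_wt_chrom - p_wt), 3 * se_wt)
  # unlinked markers in the mutant bulk: 1/2
  p_mut <- mut_exp / n_mut_chrom
  expect_equal(p_mut, 0.5, tolerance = 1e-9)
  se_mut <- sqrt(0.25 / n_mut_chrom)
  expect_lt(abs(mut_obs / n_mut_chrom - p_mut), 3 * se_mut)
})

test_that("sequencing conserves counts, hits the Poisson depth, and degrades with error", {
  cfg <- tiny_sim_config(seed = 4, depth_mean = 30)
  sim <- simulate_bsa(cfg)
  for (pool in list(sim$wt, sim$mut)) {
    expect_true(all(pool$A + pool$C + pool$G + pool$T + pool$skipped == pool$depth))
  }
  both <- c(sim$wt$depth, sim$mut$depth)
  expect_equal(mean(both), 30, tolerance = 0.05 * 30)

  # error-free pool fixed for one allele shows only that allele
  cfg0 <- tiny_sim_config(seed = 5, error_rate = 0)
  sim0 <- simulate_bsa(cfg0)
  ci <- which(sim0$truth$markers$is_causal)
  n_base <- sim0$truth$markers$N_allele[ci]
  row <- sim0$mut[sim0$mut$chrom == sim0$truth$markers$chrom[ci] &
                    sim0$mut$pos == sim0$truth$markers$pos[ci], ]
  expect_equal(row[[n_base]], row$depth)

  # pathological error rate pushes major-allele fractions toward uniform
  cfg5 <- tiny_sim_config(seed = 6, error_rate = 0.5)
  sim5 <- simulate_bsa(cfg5)
  m5 <- as.matrix(sim5$mut[, c("A", "C", "G", "T")])
  maf5 <- apply(m5, 1, max) / rowSums(m5)
  m0 <- as.matrix(sim0$mut[, c("A", "C", "G", "T")])
  maf0 <- apply(m0, 1, max) / rowSums(m0)
  expect_lt(mean(maf5), mean(maf0) - 0.2)
})

test_that("runs are bit-reproducible from the seed and round-trip through pileup files", {
  cfg <- tiny_sim_config(seed = 12)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  run_simulation(cfg, d1)
  run_simulation(cfg, d2)
  for (f in c("wt.pileup", "mut.pileup", "truth_markers.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  sim <- simulate_bsa(cfg)
  wt_back <- read_pileup(file.path(d1, "wt.pileup"))
  expect_equal(wt_back, sim$wt[sim$wt$depth > 0, ],
               ignore_attr = "row.names")
  pooled <- join_pools(wt_back, read_pileup(file.path(d1, "mut.pileup")))
  expect_gt(nrow(pooled), 0)
  expect_lte(nrow(pooled), nrow(sim$truth$markers))
})

test_that("the relocation fixture re-addresses a block, preserving genotypes", {
  cfg <- tiny_sim_config(seed = 13,
                         relocate = list(chrom = "b", start = 1, end = 100000,
                                         to = "c", at = 300000))
  plain <- tiny_sim_config(seed = 13)
  sim_r <- simulate_bsa(cfg)
  sim_p <- simulate_bsa(plain)
  mk <- sim_r$truth$markers
  moved <- mk[mk$orig_chrom == "b" & mk$orig_pos <= 100000, ]
  expect_gt(nrow(moved), 0)
  expect_true(all(moved$chrom == "c"))
  expect_true(all(moved$pos >= 300000))
  # genotype columns of a moved marker equal the unrelocated run's
  key_r <- paste(mk$orig_chrom, mk$orig_pos)
  key_p <- paste(sim_p$truth$markers$chrom, sim_p$truth$markers$pos)
  i <- match(paste(moved$orig_chrom[1], moved$orig_pos[1]), key_r)
  j <- match(paste(moved$orig_chrom[1], moved$orig_pos[1]), key_p)
  expect_equal(sim_r$truth$mut_g1[i, ], sim_p$truth$mut_g1[j, ])
})
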