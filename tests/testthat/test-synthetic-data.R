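test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_chrom = 1, chrom_lengths = 1e6), ">= 2")
  expect_error(sim_config(beta = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(chrom_lengths = c(5e3, rep(5e6, 7))), "10 \\* s_min")
  cfg <- sim_config(sex = "Z0")
  expect_equal(cfg$z_chrom, "chr8")  # defaults to the last chromosome
})

test_that("genome-wide masked fraction tracks the configured base mean", {
  cfg <- quick_config(seed = 11)
  g <- simulate_genome(cfg)
  expect_equal(mean(unlist(g$density)), cfg$repeat_base_mean,
               tolerance = 0.02)
  # annotated bases agree with the density track (one interval per bin)
  frac <- sum(g$repeats$end - g$repeats$start) / sum(g$scaffolds$length)
  expect_equal(frac, cfg$repeat_base_mean, tolerance = 0.02)
})

test_that("junction neighborhoods carry the planted repeat density", {
  cfg <- quick_config(seed = 12)
  sp <- data.frame(chrom = "chr4", pos = 3e6, junction_mean = 0.999)
  g <- simulate_genome(cfg, sp)
  bins <- g$density[["chr4"]][(3e6 / 1000 - 99):(3e6 / 1000 + 100)]
  expect_gte(mean(bins), 0.99)       # >=99% masked around an extreme junction
  outside <- g$density[["chr4"]][1:2000]
  expect_lt(mean(outside), 0.75)
})

test_that("generator outputs are deterministic in the seed", {
  cfg <- quick_config(n_pairs = 5e3, seed = 33)
  sp <- data.frame(chrom = "chr6", pos = 4e6)
  g1 <- simulate_genome(cfg, sp); g2 <- simulate_genome(cfg, sp)
  expect_identical(g1$density, g2$density)
  expect_identical(g1$repeats, g2$repeats)
  d1 <- derive_assembly(g1, sp, "a"); d2 <- derive_assembly(g2, sp, "a")
  expect_identical(simulate_hic_pairs(g1, d1, cfg),
                   simulate_hic_pairs(g2, d2, cfg))
  expect_identical(simulate_depth(g1, d1, cfg), simulate_depth(g2, d2, cfg))
})

test_that("derived scaffold counts are K plus the number of splits", {
  cfg <- quick_config(seed = 2)
  plans <- study_split_plans(cfg)
  g <- simulate_genome(cfg, rbind(plans$a, plans$b))
  expect_equal(nrow(derive_assembly(g, plans$a, "a")$scaffolds), 9)   # K+1
  expect_equal(nrow(derive_assembly(g, plans$b, "b")$scaffolds), 11)  # K+3
  ident <- derive_assembly(g, NULL, "o")
  expect_equal(nrow(ident$scaffolds), 8)
  expect_equal(ident$liftover$start, rep(0, 8))
  expect_equal(ident$liftover$end, g$scaffolds$length)
})

test_that("invalid split plans are rejected", {
  cfg <- quick_config()
  expect_error(simulate_genome(cfg, data.frame(chrom = "chr1", pos = 500)),
               "s_min")
  g <- simulate_genome(cfg)
  expect_error(
    derive_assembly(g, data.frame(chrom = "chr3", pos = c(2e6, 2.1e6)), "a"),
    "closer")
})

test_that("liftover is exact and invertible", {
  cfg <- quick_config(seed = 9)
  plans <- study_split_plans(cfg)
  g <- simulate_genome(cfg, rbind(plans$a, plans$b))
  d <- derive_assembly(g, plans$b, "b")
  set.seed(99)
  chrom <- sample(g$scaffolds$name, 500, replace = TRUE)
  pos <- floor(runif(500) * scaffold_length(g$scaffolds, chrom))
  fwd <- lift_to_assembly(d, chrom, pos)
  back <- lift_to_truth(d, fwd$scaffold, fwd$pos)
  expect_equal(back$chrom, chrom)
  expect_equal(back$pos, pos)
  # liftover intervals tile each chromosome exactly
  per <- tapply(d$liftover$end - d$liftover$start, d$liftover$chrom, sum)
  expect_equal(as.numeric(per[g$scaffolds$name]), g$scaffolds$length)
})

test_that("beta = 0 forces all trans signal through planted splits", {
  cfg <- quick_config(n_pairs = 2e4, beta = 0, seed = 21)
  g0 <- simulate_genome(cfg)
  d0 <- derive_assembly(g0, NULL, "flat")
  p0 <- simulate_hic_pairs(g0, d0, cfg)
  expect_equal(sum(p0$scaffold1 != p0$scaffold2), 0)

  sp <- data.frame(chrom = "chr7", pos = 4e6)
  g1 <- simulate_genome(cfg, sp)
  d1 <- derive_assembly(g1, sp, "split")
  p1 <- simulate_hic_pairs(g1, d1, cfg)
  tr <- p1[p1$scaffold1 != p1$scaffold2, ]
  expect_gt(nrow(tr), 0)
  halves <- d1$liftover$scaffold[d1$liftover$chrom == "chr7"]
  expect_true(all(tr$scaffold1 %in% halves & tr$scaffold2 %in% halves))
})

test_that("emitted trans fraction matches beta within binomial error", {
  cfg <- quick_config(n_pairs = 5e4, seed = 14)
  g <- simulate_genome(cfg)
  d <- derive_assembly(g, NULL, "flat")
  p <- simulate_hic_pairs(g, d, cfg)
  f <- sum(p$scaffold1 != p$scaffold2) / nrow(p)
  tol <- 4 * sqrt(cfg$beta * (1 - cfg$beta) / cfg$n_pairs)
  expect_lt(abs(f - cfg$beta), tol)
  expect_lt(abs(attr(p, "n_trans_true") / nrow(p) - cfg$beta), tol)
})

test_that("log-log regression on cis separations recovers alpha", {
  cfg <- quick_config(n_pairs = 2e5, seed = 15)
  g <- simulate_genome(cfg)
  d <- derive_assembly(g, NULL, "flat")
  p <- simulate_hic_pairs(g, d, cfg)
  est <- estimate_contact_decay(p)
  expect_equal(est$alpha_hat, cfg$alpha, tolerance = 0.15)
})

test_that("depth model has the advertised means", {
  cfg <- quick_config(gamma = 0, seed = 16)
  g <- simulate_genome(cfg)
  d <- derive_assembly(g, NULL, "flat")
  dep <- simulate_depth(g, d, cfg)
  expect_equal(mean(dep$per_kb$depth), cfg$depth_lambda, tolerance = 0.01)

  cfgz <- quick_config(gamma = 0, sex = "Z0", seed = 17)
  gz <- simulate_genome(cfgz)
  dz <- derive_assembly(gz, NULL, "flat")
  depz <- simulate_depth(gz, dz, cfgz)
  on_z <- depz$per_kb$scaffold == dz$liftover$scaffold[
    dz$liftover$chrom == cfgz$z_chrom]
  expect_equal(mean(depz$per_kb$depth[on_z]), 0.5 * cfgz$depth_lambda,
               tolerance = 0.02)
  # 500 kb windows are the mean of their constituent 1 kb bins
  s1 <- depz$per_kb[depz$per_kb$scaffold == "flat_s01" &
                    depz$per_kb$start < 5e5, ]
  w1 <- depz$per_500kb[depz$per_500kb$scaffold == "flat_s01" &
                       depz$per_500kb$start == 0, ]
  expect_equal(w1$depth, mean(s1$depth))
})

test_that("qPCR generator is exact when noiseless and sign-stable with noise", {
  m <- simulate_qpcr("male", noise_sd = 0, seed = 1)
  expect_equal(mean(m$a_cq) - mean(m$s_cq), 1.0)
  f <- simulate_qpcr("female", noise_sd = 0, seed = 1)
  expect_equal(mean(f$a_cq) - mean(f$s_cq), -1.0)
  signs <- vapply(1:200, function(s) {
    q <- simulate_qpcr("male", noise_sd = 0.1, seed = s)
    sign(mean(q$a_cq) - mean(q$s_cq))
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.99)
})

test_that("a study bundle writes all artifacts with provenance", {
  cfg <- quick_config(n_pairs = 2e3, seed = 55)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  files <- list.files(dir)
  expect_true(all(c("asmA.pairs", "asmB.fai", "asmA_repeats.bed",
                    "asmB_depth_500kb.bed", "asmA_vs_asmB.paf",
                    "asmA_vs_outgroup.paf", "provenance.json") %in% files))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 55)
  p2 <- read_pairs(file.path(dir, "asmA.pairs"),
                   scaffolds = study$assemblies$A$derivation$scaffolds)
  expect_equal(nrow(p2), cfg$n_pairs)
  expect_equal(p2$pos1, study$assemblies$A$pairs$pos1)
})
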