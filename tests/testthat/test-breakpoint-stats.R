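make_paf_row <- function(q, qlen, qs, qe, t, tlen, ts, te, strand = "+") {
  data.frame(query = q, query_len = qlen, qstart = qs, qend = qe,
             strand = strand, target = t, target_len = tlen, tstart = ts,
             tend = te, matches = te - ts, block_len = te - ts, mapq = 60,
             stringsAsFactors = FALSE)
}

test_that("a two-partner scaffold yields one breakpoint at the span boundary", {
  set_a <- scaffold_set(c("P", "Q"), c(30e6, 40e6), assembly_id = "A")
  set_b <- scaffold_set("X", 70e6, assembly_id = "B")
  paf <- rbind(make_paf_row("P", 30e6, 0, 30e6, "X", 70e6, 0, 30e6),
               make_paf_row("Q", 40e6, 0, 40e6, "X", 70e6, 30e6, 70e6))
  bps <- detect_breakpoints(paf, set_a, set_b)
  expect_equal(nrow(bps), 1)
  expect_equal(bps$split_assembly, "A")
  expect_equal(bps$joined_scaffold, "X")
  expect_equal(bps$junction_position, 30e6)
  expect_equal(bps$left_scaffold, "P")
  expect_equal(bps$left_terminus, "end")
  expect_equal(bps$right_terminus, "start")
})

test_that("identical assemblies yield no breakpoints; 3-way splits are complex", {
  set_a <- scaffold_set(c("P", "Q"), c(3e6, 4e6), assembly_id = "A")
  set_b <- scaffold_set(c("U", "V"), c(3e6, 4e6), assembly_id = "B")
  paf <- rbind(make_paf_row("P", 3e6, 0, 3e6, "U", 3e6, 0, 3e6),
               make_paf_row("Q", 4e6, 0, 4e6, "V", 4e6, 0, 4e6))
  expect_equal(nrow(detect_breakpoints(paf, set_a, set_b)), 0)

  set_a3 <- scaffold_set(c("P", "Q", "R"), c(2e6, 2e6, 2e6),
                         assembly_id = "A")
  set_b3 <- scaffold_set("X", 6e6, assembly_id = "B")
  paf3 <- rbind(make_paf_row("P", 2e6, 0, 2e6, "X", 6e6, 0, 2e6),
                make_paf_row("Q", 2e6, 0, 2e6, "X", 6e6, 2e6, 4e6),
                make_paf_row("R", 2e6, 0, 2e6, "X", 6e6, 4e6, 6e6))
  suppressWarnings(bps3 <- detect_breakpoints(paf3, set_a3, set_b3))
  expect_equal(nrow(bps3), 0)
  expect_equal(attr(bps3, "complex"), "X")
})

test_that("the study-shaped simulation yields 4 breakpoints, 1 vs 3 by assembly", {
  cfg <- quick_config(seed = 3)
  plans <- study_split_plans(cfg)
  g <- simulate_genome(cfg, rbind(plans$a, plans$b))
  dA <- derive_assembly(g, plans$a, "asmA")
  dB <- derive_assembly(g, plans$b, "asmB")
  bps <- detect_breakpoints(paf_from_derivations(dA, dB),
                            dA$scaffolds, dB$scaffolds)
  expect_equal(nrow(bps), 4)
  expect_equal(sum(bps$split_assembly == "asmA"), 1)
  expect_equal(sum(bps$split_assembly == "asmB"), 3)
  # junctions land where the splits were planted (lifted to truth coords)
  b1 <- bps[bps$split_assembly == "asmA", ]
  expect_equal(b1$junction_position, plans$a$pos)
})

test_that("control selection is nearest-length among uninvolved scaffolds", {
  opp <- scaffold_set(c("c1", "c2", "c3", "c4"), c(70, 65, 80, 100) * 1e6,
                      assembly_id = "B")
  bp <- data.frame(id = "BP1", joined_scaffold = "c1",
                   stringsAsFactors = FALSE)
  ctrl <- select_control(bp, opp, involved = "c1")
  expect_equal(ctrl$scaffold_b, "c2")   # |65-70| = 5 is minimal
  # tie broken toward earlier assembly order
  opp2 <- scaffold_set(c("c1", "c2", "c3"), c(70, 60, 80) * 1e6,
                       assembly_id = "B")
  expect_equal(select_control(bp, opp2, "c1")$scaffold_b, "c2")
  expect_error(select_control(bp, opp2, c("c1", "c2", "c3")),
               "no uninvolved")
})

test_that("empirical p counts rates at or above the observation", {
  expect_equal(empirical_pvalue(3, c(1, 2, 3, 4), floor_n = 4), 0.5)
  expect_equal(empirical_pvalue(0, c(1, 2, 3, 4), floor_n = 4), 1.0)
  expect_error(empirical_pvalue(1, 1:10), "background")
  # monotone non-increasing in the observed rate
  set.seed(31)
  bg <- rexp(50)
  ps <- vapply(sort(runif(20, 0, 3)), empirical_pvalue, numeric(1),
               background = bg)
  expect_true(all(diff(ps) <= 0))
})

test_that("the maximum of a seeded null background has p = 1/n", {
  cfg <- quick_config(n_pairs = 2e4, seed = 44, n_chrom = 20,
                      chrom_lengths = round(seq(2e6, 6e6, length.out = 20)))
  g <- simulate_genome(cfg)
  d <- derive_assembly(g, NULL, "flat")
  ct <- count_contacts(simulate_hic_pairs(g, d, cfg), d$scaffolds)
  bg <- ct$pairs$rate
  expect_equal(length(bg), 190)
  r_max <- max(bg)
  expect_equal(empirical_pvalue(r_max, bg), 1 / length(bg))
})

test_that("the joint rank-sum test reproduces exact small-sample p-values", {
  jt <- joint_rank_test(c(5, 6, 7), c(1, 2, 3, 4))
  expect_equal(jt$U, 12)
  expect_equal(jt$p, 1 / 35)
  expect_equal(jt$method, "exact")
  # no shift: p must exceed 0.5
  expect_gt(joint_rank_test(c(1, 2, 3), c(1, 2, 3))$p, 0.5)
})

test_that("exact and normal-approximation paths agree at moderate n", {
  set.seed(77)
  x <- rnorm(30, 0.3); y <- rnorm(200)
  exact <- joint_rank_test(x, y)
  expect_equal(exact$method, "exact")   # 30*200 <= 1e4 and no ties
  approx <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE))
  expect_lt(abs(exact$p - approx$p.value), 1e-2)
})

test_that("intra-rate comparison reports fraction and median position", {
  r <- compare_intra(0.5, c(1, 2, 3))
  expect_equal(r$fraction_above, 1.0)
  expect_true(r$below_intra)
  r2 <- compare_intra(5, c(1, 2, 3))
  expect_equal(r2$fraction_above, 0.0)
  expect_false(r2$below_intra)
})

test_that("outgroup collinearity follows the dominant-partner rule", {
  paf <- rbind(make_paf_row("L", 3e6, 0, 3e6, "O1", 7e6, 0, 3e6),
               make_paf_row("R", 4e6, 0, 4e6, "O1", 7e6, 3e6, 7e6))
  bp <- data.frame(left_scaffold = "L", right_scaffold = "R",
                   stringsAsFactors = FALSE)
  expect_true(collinear_in_outgroup(bp, paf))
  paf2 <- rbind(make_paf_row("L", 3e6, 0, 3e6, "O1", 3e6, 0, 3e6),
                make_paf_row("R", 4e6, 0, 4e6, "O2", 4e6, 0, 4e6))
  expect_false(collinear_in_outgroup(bp, paf2))
  expect_true(is.na(collinear_in_outgroup(bp, paf2[1, ])))
})
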