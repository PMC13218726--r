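test_that("terminal window depth honors the MAPQ filter", {
  ss <- scaffold_set("S", 3e5)
  one_read <- function(mq) data.frame(
    query = "r1", target = "S", target_start = 0, mapq = mq,
    cigar = "1000M", is_supplementary = FALSE, is_duplicate = FALSE,
    stringsAsFactors = FALSE)
  d <- terminal_window_depth(one_read(60), ss, "S", "start")
  expect_equal(d$depth[1], 1.0)
  expect_equal(sum(d$depth), 1.0)           # all other bins zero
  d5 <- terminal_window_depth(one_read(5), ss, "S", "start")
  expect_equal(sum(d5$depth), 0)
  # duplicates contribute nothing
  dup <- one_read(60); dup$is_duplicate <- TRUE
  expect_equal(sum(terminal_window_depth(dup, ss, "S", "start")$depth), 0)
})

test_that("terminal window depth matches the per-base pileup oracle", {
  set.seed(19)
  for (rep in 1:4) {
    L <- sample(8e4:2e5, 1)
    ss <- scaffold_set("S", L)
    aln <- rand_alignments("S", L, 80)
    for (terminus in c("start", "end")) {
      d <- terminal_window_depth(aln, ss, "S", terminus, window = 5e4)
      orc <- oracle_pileup_depth(aln, L, "S", terminus, window = 5e4)
      expect_equal(d$depth, orc)
    }
  }
})

test_that("CIGAR reference span counts M/=/X/D only", {
  expect_equal(cigar_ref_length(c("100M", "50M10I50M", "50M10D50M",
                                  "20S100M30S", "40=10X", "*")),
               c(100, 100, 110, 100, 50, 0))
})

test_that("spanning reads need anchors on both junction termini", {
  ss <- scaffold_set(c("L", "R"), c(1e5, 1e5))
  bp <- data.frame(id = "BP1", left_scaffold = "L", right_scaffold = "R",
                   left_terminus = "end", right_terminus = "start",
                   stringsAsFactors = FALSE)
  aln <- data.frame(
    query = c("q1", "q1", "q2", "q2"),
    target = c("L", "R", "L", "L"),
    target_start = c(1e5 - 3000, 2000, 1e5 - 3000, 1e5 - 8000),
    mapq = 60, cigar = "1000M",
    is_supplementary = c(FALSE, TRUE, FALSE, TRUE),
    is_duplicate = FALSE, stringsAsFactors = FALSE)
  # q1 crosses the junction (counted once); q2 stays on L
  expect_equal(detect_spanning_reads(aln, bp, ss), 1)
  expect_equal(detect_spanning_reads(aln[3:4, ], bp, ss), 0)
})

test_that("coverage fold is the flank/core median ratio", {
  track <- data.frame(offset = seq(-2e5, 2e5, by = 1000))
  track$depth <- ifelse(abs(track$offset) <= 2.5e4, 5, 25)
  cf <- coverage_fold(track)
  expect_equal(cf$fold, 5.0)
  expect_true(cf$low_mappability)
  # uniform depth: fold 1, no flag
  flat <- data.frame(offset = track$offset, depth = 12)
  expect_equal(coverage_fold(flat)$fold, 1.0)
  expect_false(coverage_fold(flat)$low_mappability)
  # scale invariance
  sc <- track; sc$depth <- sc$depth * 7.3
  expect_equal(coverage_fold(sc)$fold, 5.0)
  # zero core flagged infinite
  zc <- track; zc$depth[abs(zc$offset) <= 2.5e4] <- 0
  expect_equal(coverage_fold(zc)$fold, Inf)
  expect_true(coverage_fold(zc)$low_mappability)
})

test_that("simulated extreme junctions reach the analytic coverage fold", {
  cfg <- quick_config(seed = 23)
  sp <- data.frame(chrom = "chr6", pos = 4e6, junction_mean = 0.999)
  g <- simulate_genome(cfg, sp)
  d <- derive_assembly(g, sp, "a")
  dep <- simulate_depth(g, d, cfg)
  bp <- data.frame(id = "BP1",
                   left_scaffold = d$scaffolds$name[6],
                   right_scaffold = d$scaffolds$name[7],
                   left_terminus = "end", right_terminus = "start",
                   stringsAsFactors = FALSE)
  track <- junction_depth_track(dep$per_kb, bp, d$scaffolds)
  f_analytic <- (1 - cfg$gamma * cfg$repeat_base_mean) /
                (1 - cfg$gamma * 0.999)
  cf <- coverage_fold(track)
  expect_equal(cf$fold, f_analytic, tolerance = 0.15)
  expect_true(cf$low_mappability)
})

test_that("window masked fractions merge within and across classes", {
  ann <- data.frame(scaffold = "S", start = c(0, 50), end = c(100, 150),
                    raw_class = c("LINE/L2", "LTR/Gypsy"),
                    class8 = c("LINE", "LTR"), stringsAsFactors = FALSE)
  p <- window_masked_fraction(ann, "S", 0, 200)
  expect_equal(unname(p$class_fraction["LINE"]), 0.5)
  expect_equal(unname(p$class_fraction["LTR"]), 0.5)
  expect_equal(p$f_tot, 0.75)
  # overlapping intervals of one class merge rather than double count
  ann2 <- data.frame(scaffold = "S", start = c(0, 50), end = c(100, 150),
                     raw_class = "LINE/L2", class8 = "LINE",
                     stringsAsFactors = FALSE)
  p2 <- window_masked_fraction(ann2, "S", 0, 200)
  expect_equal(unname(p2$class_fraction["LINE"]), 0.75)
  expect_equal(p2$f_tot, 0.75)
})

test_that("window masked fractions match the per-base oracle", {
  set.seed(27)
  for (rep in 1:4) {
    L <- 5e4
    ann <- rand_annotation("S", L, 50)
    w0 <- sample(0:(L / 2), 1); w1 <- w0 + sample(1e3:2e4, 1)
    p <- window_masked_fraction(ann, "S", w0, w1)
    orc <- oracle_masked_fraction(ann, "S", w0, w1)
    expect_equal(p$f_tot, orc$f_tot)
    expect_equal(p$class_fraction, orc$class_fraction)
    # bounds: max class fraction <= total <= capped sum
    expect_lte(max(p$class_fraction), p$f_tot + 1e-12)
    expect_lte(p$f_tot, min(1, sum(p$class_fraction)) + 1e-12)
  }
})

test_that("junction/control repeat comparison reports means and enrichment", {
  prof <- function(f_tot, f_unk = f_tot / 2) list(
    class_fraction = c(SINE = 0, LINE = 0, DNA = 0, LTR = 0, simple = 0,
                       low_complexity = 0, unknown = f_unk, other = 0),
    f_tot = f_tot, scaffold = "S", start = 0, end = 1)
  cmp <- compare_junction_repeats(list(prof(0.72), prof(0.71)),
                                  list(prof(0.68), prof(0.67)))
  expect_equal(cmp$mean_f_tot_junction, 0.715)
  expect_equal(cmp$mean_f_tot_control, 0.675)
  expect_true(cmp$repeat_enriched)
  same <- compare_junction_repeats(list(prof(0.7)), list(prof(0.7)))
  expect_equal(same$diff_f_tot, 0)
  expect_false(same$repeat_enriched)
})
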