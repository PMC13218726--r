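test_that("read_pairs filters pair types and honors headers", {
  f <- withr::local_tempfile()
  writeLines(c("## pairs format v1.0",
               "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2 pair_type",
               "r1\tA\t100\tB\t200\t+\t-\tUU",
               "r2\tA\t150\tA\t900\t+\t+\tMM",
               "r3\tB\t10\tB\t5000\t-\t-\tUU"), f)
  p <- read_pairs(f)
  expect_equal(nrow(p), 2)
  expect_setequal(p$readID, c("r1", "r3"))

  g <- withr::local_tempfile()
  writeLines(c("## pairs format v1.0", "#columns: ..."), g)
  expect_equal(nrow(read_pairs(g)), 0)
})

test_that("read_pairs validates against a scaffold set", {
  ss <- scaffold_set(c("A", "B"), c(1000, 2000))
  f <- withr::local_tempfile()
  writeLines("r1\tA\t1000\tB\t5\t+\t-\tUU", f)  # pos1 == L_A, out of range
  expect_error(read_pairs(f, scaffolds = ss), "out of range")
  g <- withr::local_tempfile()
  writeLines("r1\tA\t10\tC\t5\t+\t-\tUU", g)
  expect_error(read_pairs(g, scaffolds = ss), "absent")
  h <- withr::local_tempfile()
  writeLines(c("r1\tA\t10\tB\t5\t+\t-\tUU", "r2\tA\t3"), h)
  expect_error(read_pairs(h), "line 2")
})

test_that("pairs round-trip through the text dialect record-for-record", {
  set.seed(41)
  ss <- rand_scaffolds(5)
  for (rep in 1:3) {
    p <- canonicalize_pairs(rand_pairs(ss, 200), ss)
    f <- withr::local_tempfile()
    write_pairs(p, f)
    p2 <- read_pairs(f, scaffolds = ss)
    rownames(p) <- rownames(p2) <- NULL
    expect_equal(p2, p)
  }
})

test_that("canonical ordering is the upper-triangle convention", {
  ss <- scaffold_set(c("A", "B"), c(1e4, 1e4))
  p <- data.frame(readID = c("r1", "r2"), scaffold1 = c("B", "A"),
                  pos1 = c(5, 800), scaffold2 = c("A", "A"),
                  pos2 = c(10, 20), strand1 = c("+", "-"),
                  strand2 = c("-", "+"), pair_type = "UU",
                  stringsAsFactors = FALSE)
  cp <- canonicalize_pairs(p, ss)
  expect_equal(cp$scaffold1, c("A", "A"))
  expect_equal(cp$pos1, c(10, 20))
  expect_equal(cp$strand1, c("-", "+"))  # strands travel with their ends
  # idempotent
  expect_equal(canonicalize_pairs(cp, ss), cp)
})

test_that("read_paf parses, filters short blocks, rejects bad rows", {
  f <- withr::local_tempfile()
  writeLines(c(
    "q1\t50000\t0\t30000\t+\tt1\t80000\t1000\t31000\t29000\t30000\t60",
    "q2\t50000\t0\t5000\t+\tt1\t80000\t0\t5000\t4800\t5000\t60"), f)
  paf <- read_paf(f)
  expect_equal(nrow(paf), 1)          # 5 kb block dropped at default 10 kb
  expect_equal(paf$query, "q1")
  expect_gt(paf$qend - paf$qstart, 0)
  expect_equal(nrow(read_paf(f, min_block = 1000)), 2)

  g <- withr::local_tempfile()
  writeLines("q1\t50000\t0\t30000\t+\tt1\t80000\t1000", g)
  expect_error(read_paf(g), "8 column")
  h <- withr::local_tempfile()
  writeLines("q1\t50000\t0\txyz\t+\tt1\t80000\t1000\t31000\t29000\t30000\t60", h)
  expect_error(read_paf(h), "non-integer")
})

test_that("PAF round-trips through the writer", {
  set.seed(5)
  ss <- rand_scaffolds(3)
  cfg <- quick_config(n_pairs = 10)
  g <- simulate_genome(cfg, data.frame(chrom = "chr2", pos = 2e6))
  dA <- derive_assembly(g, data.frame(chrom = "chr2", pos = 2e6), "a")
  dB <- derive_assembly(g, NULL, "b")
  paf <- paf_from_derivations(dA, dB)
  f <- withr::local_tempfile()
  write_paf(paf, f)
  expect_equal(read_paf(f, min_block = 0), paf)
})

test_that("repeat class collapse follows the eight-class rules", {
  expect_equal(collapse_repeat_class(
    c("LINE/L2", "SINE/tRNA", "DNA/hAT-Charlie", "LTR/Gypsy",
      "Simple_repeat", "Low_complexity", "Unknown", "Satellite",
      "rRNA", "RC/Helitron", "DNA?")),
    c("LINE", "SINE", "DNA", "LTR", "simple", "low_complexity",
      "unknown", "other", "other", "other", "DNA"))
})

test_that("RepeatMasker .out coordinates are normalized to 0-based half-open", {
  f <- withr::local_tempfile()
  writeLines(c(
    "   SW  perc perc perc  query     position in query",
    "score  div. del. ins.  sequence  begin end (left) repeat class/family",
    "",
    " 1000  10.0  0.1  0.2  chrA  101  200  (500)  +  L2  LINE/L2  1 100 (0)  1",
    "  900  12.0  0.1  0.2  chrA  301  350  (400)  C  rep  Unknown  1 50 (0)  2"),
    f)
  ann <- read_repeat_annotation(f, "rmout")
  expect_equal(ann$start, c(100, 300))
  expect_equal(ann$end, c(200, 350))
  expect_equal(ann$class8, c("LINE", "unknown"))
  # total annotated bases match the 1-based inclusive arithmetic
  expect_equal(sum(ann$end - ann$start), (200 - 101 + 1) + (350 - 301 + 1))
})

test_that("BED repeat dialect reads and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("#scaffold\tstart\tend\traw_class",
               "chrA\t0\t500\tLTR/Copia", "chrA\t1000\t1200\tUnknown"), f)
  ann <- read_repeat_annotation(f, "bed")
  expect_equal(ann$class8, c("LTR", "unknown"))
  g <- withr::local_tempfile()
  write_repeat_bed(ann, g)
  expect_equal(read_repeat_annotation(g, "bed"), ann)
  h <- withr::local_tempfile()
  writeLines("chrA\t500\t500\tLTR", h)
  expect_error(read_repeat_annotation(h, "bed"), "start >= end")
})

test_that("SAM text alignments decode flags and coordinates", {
  f <- withr::local_tempfile()
  writeLines(c("@SQ\tSN:chrA\tLN:10000",
               "r1\t0\tchrA\t101\t60\t500M\t*\t0\t0\t*\t*",
               "r1\t2048\tchrA\t900\t60\t100M400S\t*\t0\t0\t*\t*",
               "r2\t1024\tchrA\t1\t60\t300M\t*\t0\t0\t*\t*"), f)
  aln <- read_alignments(f, "sam")
  expect_equal(nrow(aln), 2)          # duplicate dropped
  expect_equal(aln$target_start[1], 100)
  expect_equal(aln$is_supplementary, c(FALSE, TRUE))
  aln_all <- read_alignments(f, "sam", drop_duplicates = FALSE)
  expect_equal(sum(aln_all$is_duplicate), 1)
})

test_that("scaffold length and depth tables round-trip", {
  ss <- scaffold_set(c("A", "B"), c(1234567, 89), assembly_id = "x")
  f <- withr::local_tempfile()
  write_fai(ss, f)
  ss2 <- read_fai(f, assembly_id = "x")
  expect_equal(as.data.frame(ss2), as.data.frame(ss))

  win <- data.frame(scaffold = c("A", "A"), start = c(0, 500000),
                    end = c(500000, 1000000), depth = c(30.25, 28))
  g <- withr::local_tempfile()
  write_depth_bed(win, g)
  win2 <- read_depth_bed(g)
  expect_equal(win2$depth, win$depth)
  expect_equal(attr(win2, "window_size"), 500000)
})

test_that("duplicate scaffold names and bad lengths are rejected", {
  expect_error(scaffold_set(c("A", "A"), c(10, 20)), "unique")
  expect_error(scaffold_set("A", 0), ">= 1")
})
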