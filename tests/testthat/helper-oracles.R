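# Independent brute-force oracles and random fixture builders. These stay
# deliberately naive (per-record loops, per-base marking, full enumeration)
# so they share no code path with the implementation they check.

oracle_count_contacts <- function(pairs, scaffolds, min_sep = 1000) {
  n <- nrow(scaffolds)
  Tm <- matrix(0, n, n, dimnames = list(scaffolds$name, scaffolds$name))
  I <- stats::setNames(numeric(n), scaffolds$name)
  short <- 0
  for (k in seq_len(nrow(pairs))) {
    s1 <- pairs$scaffold1[k]; s2 <- pairs$scaffold2[k]
    if (s1 == s2) {
      if (abs(pairs$pos2[k] - pairs$pos1[k]) > min_sep)
        I[s1] <- I[s1] + 1
      else short <- short + 1
    } else {
      i <- match(s1, scaffolds$name); j <- match(s2, scaffolds$name)
      Tm[min(i, j), max(i, j)] <- Tm[min(i, j), max(i, j)] + 1
    }
  }
  list(T = Tm, I = I, short = short)
}

oracle_trans_density <- function(pairs, scaffolds, bin = 5e5) {
  res <- list()
  for (k in seq_len(nrow(scaffolds))) {
    nb <- ceiling(scaffolds$length[k] / bin)
    res[[scaffolds$name[k]]] <- numeric(nb)
  }
  for (k in seq_len(nrow(pairs))) {
    if (pairs$scaffold1[k] == pairs$scaffold2[k]) next
    for (side in 1:2) {
      sc <- pairs[[paste0("scaffold", side)]][k]
      b <- floor(pairs[[paste0("pos", side)]][k] / bin) + 1
      res[[sc]][b] <- res[[sc]][b] + 1
    }
  }
  res
}

# per-base pileup; own trivial CIGAR parser (M/=/X/D consume reference)
oracle_ref_len <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  total <- 0
  for (t in toks) {
    op <- substr(t, nchar(t), nchar(t))
    if (op %in% c("M", "=", "X", "D"))
      total <- total + as.numeric(substr(t, 1, nchar(t) - 1))
  }
  total
}

oracle_pileup_depth <- function(aln, L, scaffold, terminus, window = 2e5,
                                bin = 1000, mq_min = 10) {
  w <- min(window, L)
  w0 <- if (terminus == "start") 0 else L - w
  cover <- numeric(w)
  for (k in seq_len(nrow(aln))) {
    if (aln$is_duplicate[k] || aln$target[k] != scaffold ||
        aln$mapq[k] < mq_min) next
    a0 <- aln$target_start[k]
    a1 <- a0 + oracle_ref_len(aln$cigar[k])
    lo <- max(a0, w0); hi <- min(a1, w0 + w)
    if (hi > lo)
      for (b in (lo + 1):hi) cover[b - w0] <- cover[b - w0] + 1
  }
  vapply(seq_len(ceiling(w / bin)), function(i) {
    mean(cover[((i - 1) * bin + 1):min(i * bin, w)])
  }, numeric(1))
}

oracle_masked_fraction <- function(ann, scaffold, start, end) {
  w <- end - start
  any_mask <- logical(w)
  per_class <- sapply(c("SINE", "LINE", "DNA", "LTR", "simple",
                        "low_complexity", "unknown", "other"),
                      function(x) logical(w))
  for (k in seq_len(nrow(ann))) {
    if (ann$scaffold[k] != scaffold) next
    lo <- max(ann$start[k], start); hi <- min(ann$end[k], end)
    if (hi <= lo) next
    idx <- (lo - start + 1):(hi - start)
    any_mask[idx] <- TRUE
    per_class[idx, ann$class8[k]] <- TRUE
  }
  list(f_tot = mean(any_mask), class_fraction = colMeans(per_class))
}

# exact one-tailed rank-sum p by full enumeration (assumes no ties)
oracle_rank_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  U_of <- function(xx, yy) sum(outer(xx, yy, ">"))
  pooled <- c(x, y)
  combs <- utils::combn(length(pooled), length(x))
  Us <- apply(combs, 2, function(idx) U_of(pooled[idx], pooled[-idx]))
  U_obs <- U_of(x, y)
  if (alternative == "greater") mean(Us >= U_obs) else mean(Us <= U_obs)
}

## ---- random fixture builders ------------------------------------------

rand_scaffolds <- function(n = 4, min_len = 4e5, max_len = 2e6,
                           id = "fix") {
  scaffold_set(paste0("s", seq_len(n)),
               round(stats::runif(n, min_len, max_len)), assembly_id = id)
}

rand_pairs <- function(scaffolds, n = 500) {
  i1 <- sample.int(nrow(scaffolds), n, replace = TRUE)
  i2 <- sample.int(nrow(scaffolds), n, replace = TRUE)
  data.frame(readID = paste0("r", seq_len(n)),
             scaffold1 = scaffolds$name[i1],
             pos1 = floor(stats::runif(n) * scaffolds$length[i1]),
             scaffold2 = scaffolds$name[i2],
             pos2 = floor(stats::runif(n) * scaffolds$length[i2]),
             strand1 = sample(c("+", "-"), n, TRUE),
             strand2 = sample(c("+", "-"), n, TRUE),
             pair_type = "UU", stringsAsFactors = FALSE)
}

rand_cigar <- function(n) {
  vapply(seq_len(n), function(i) {
    parts <- sample(c("M", "D", "I", "S"), sample(1:3, 1), replace = TRUE)
    if (!any(parts == "M")) parts <- c(parts, "M")
    paste0(sample(100:2000, length(parts), TRUE), parts, collapse = "")
  }, character(1))
}

rand_alignments <- function(scaffold, L, n = 100) {
  data.frame(query = paste0("q", sample.int(max(2, n %/% 2), n, TRUE)),
             target = scaffold,
             target_start = floor(stats::runif(n) * max(1, L - 3000)),
             mapq = sample(0:60, n, TRUE), cigar = rand_cigar(n),
             is_supplementary = stats::runif(n) < 0.2,
             is_duplicate = stats::runif(n) < 0.1,
             stringsAsFactors = FALSE)
}

rand_annotation <- function(scaffold, L, n = 60) {
  start <- floor(stats::runif(n) * (L - 1))
  width <- pmax(1, round(stats::rexp(n, 1 / 2000)))
  cls <- sample(c("SINE", "LINE", "DNA", "LTR", "simple", "low_complexity",
                  "unknown", "other"), n, TRUE)
  data.frame(scaffold = scaffold, start = start,
             end = pmin(start + width, L), raw_class = cls, class8 = cls,
             stringsAsFactors = FALSE)
}

# a fast desk-scale config for unit tests (fewer pairs than the study
# defaults; statistical acceptance tests use the real defaults)
quick_config <- function(n_pairs = 5e4, seed = 1L, ...) {
  sim_config(n_pairs = n_pairs, seed = seed, ...)
}
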