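#' Normalize a depth window table to a reference chromosome
#'
#' Divides every window's depth by the median depth of the reference
#' chromosome's windows (by convention the first chromosome of the
#' assembly), removing library-size and coverage differences so that an
#' autosome sits near 1 and a single-copy Z in a Z0 female near 0.5.
#'
#' @param windows depth window `data.frame` (scaffold/start/end/depth).
#' @param reference_chrom reference chromosome name; defaults to the first
#'   scaffold appearing in the table.
#' @return The table with `depth` replaced by normalized depth; attribute
#'   `reference_median` records the divisor.
#' @export
normalize_depth <- function(windows, reference_chrom = NULL) {
  if (is.null(reference_chrom)) reference_chrom <- windows$scaffold[1]
  ref <- windows$depth[windows$scaffold == reference_chrom]
  if (length(ref) == 0) stop("no windows on reference chromosome ",
                             reference_chrom)
  m <- stats::median(ref)
  if (m == 0) stop("reference chromosome median depth is zero")
  windows$depth <- windows$depth / m
  attr(windows, "reference_median") <- m
  attr(windows, "reference_chrom") <- reference_chrom
  windows
}

#' Call putative sex chromosomes from normalized depth windows
#'
#' Each chromosome's normalized depth windows are tested against the
#' windows of all remaining chromosomes with a one-sided Wilcoxon rank-sum
#' test (alternative "less"); p-values are Benjamini-Hochberg adjusted
#' across chromosomes, and a chromosome is called only when its adjusted
#' p falls below `alpha` *and* its median normalized depth shows at least
#' `min_decrease` relative decrease — the 10% floor guards against
#' statistically significant but biologically meaningless dips.
#'
#' @param normalized a [normalize_depth()] result.
#' @param alpha FDR threshold (default 0.05).
#' @param min_decrease minimum relative decrease in median normalized
#'   depth (default 0.10).
#' @param min_windows chromosomes with fewer windows are excluded with a
#'   warning (default 5).
#' @return A `data.frame` with one row per tested chromosome: `chrom`,
#'   `n_windows`, `median_norm_depth`, `decrease`, `p`, `q`, `called`.
#' @export
call_sex_chromosomes <- function(normalized, alpha = 0.05,
                                 min_decrease = 0.10, min_windows = 5) {
  chroms <- unique(normalized$scaffold)
  if (length(chroms) < 2) stop("need at least two chromosomes")
  counts <- table(normalized$scaffold)[chroms]
  small <- names(counts)[counts < min_windows]
  if (length(small)) {
    warning("excluding chromosome(s) below the window floor: ",
            paste(small, collapse = ", "))
    chroms <- setdiff(chroms, small)
  }
  rows <- lapply(chroms, function(ch) {
    x <- normalized$depth[normalized$scaffold == ch]
    y <- normalized$depth[normalized$scaffold != ch &
                          normalized$scaffold %in% chroms]
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "less",
                         exact = length(x) * length(y) <= 1e4, correct = TRUE))
    m <- stats::median(x)
    data.frame(chrom = ch, n_windows = length(x), median_norm_depth = m,
               decrease = 1 - m, p = wt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$called <- res$q < alpha & res$decrease >= min_decrease
  rownames(res) <- NULL
  res
}

#' Classify individual sex from qPCR Cq replicates
#'
#' Computes `delta Cq = mean(A_Cq) - mean(S_Cq)` between the autosomal and
#' sex-locus assays and calls the individual by sign: positive values are
#' diagnostic of males (ZZ), negative of females (Z0). An optional dead
#' zone `epsilon` returns `indeterminate` for |delta Cq| <= epsilon; the
#' default 0 is the strict published sign rule. The delta Cq value is
#' always returned so borderline calls can be audited.
#'
#' @param a_reps,s_reps numeric Cq replicates for the autosomal and
#'   sex-chromosomal assays (>= 1 each, all finite).
#' @param epsilon dead-zone half-width in cycles (default 0).
#' @return List with `delta_cq`, `call` (`"male"`, `"female"`, or
#'   `"indeterminate"`), `a_mean`, `s_mean`.
#' @export
classify_sex_qpcr <- function(a_reps, s_reps, epsilon = 0) {
  if (length(a_reps) < 1 || length(s_reps) < 1)
    stop("need at least one replicate per assay")
  if (any(!is.finite(a_reps)) || any(!is.finite(s_reps)))
    stop("non-finite Cq value")
  if (epsilon < 0) stop("epsilon must be >= 0")
  a <- mean(a_reps); s <- mean(s_reps)
  d <- a - s
  call <- if (d > epsilon) "male" else if (d < -epsilon) "female" else
    "indeterminate"
  list(delta_cq = d, call = call, a_mean = a, s_mean = s)
}
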