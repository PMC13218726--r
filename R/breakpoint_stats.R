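#' Detect candidate breakpoints from a whole-genome alignment
#'
#' A breakpoint is a scaffold in one assembly (the *joined* scaffold) whose
#' aligned bases distribute over exactly two scaffolds of the other
#' assembly (the *split* side). For every scaffold of each assembly the
#' aligned bases per partner scaffold are aggregated; partners contributing
#' at least `per_partner_floor` of the scaffold's aligned bases are
#' retained, and a breakpoint is emitted when exactly two partners remain
#' and jointly cover at least `min_cov_frac` of aligned bases. Scaffolds
#' with three or more substantial partners are reported as complex and
#' excluded from testing; clean 1-to-1 matches emit nothing. The junction
#' is placed at the boundary between the two partners' aligned spans on
#' the joined scaffold.
#'
#' @param paf alignment blocks from [read_paf()] (queries from `set_a`,
#'   targets from `set_b`).
#' @param set_a,set_b the two [scaffold_set()]s.
#' @param min_cov_frac the two partners must jointly cover this fraction
#'   of the joined scaffold's aligned bases (default 0.5).
#' @param per_partner_floor minimum fraction each partner must contribute
#'   (default 0.2).
#' @return A `data.frame` of class `breakpoint_set`: one row per
#'   breakpoint with `id`, `split_assembly`, `left_scaffold`,
#'   `right_scaffold`, `left_terminus`, `right_terminus`,
#'   `joined_assembly`, `joined_scaffold`, `junction_position`. Complex
#'   scaffolds are listed in attribute `complex`.
#' @export
detect_breakpoints <- function(paf, set_a, set_b, min_cov_frac = 0.5,
                               per_partner_floor = 0.2) {
  scan_side <- function(paf, joined_col, partner_col, joined_set,
                        partner_set, jstart, jend) {
    res <- list(); complex <- character()
    for (x in joined_set$name) {
      blk <- paf[paf[[joined_col]] == x, , drop = FALSE]
      if (nrow(blk) == 0) {
        warning("scaffold ", x, " has no alignment blocks above min_block; ",
                "skipped")
        next
      }
      span <- blk[[jend]] - blk[[jstart]]
      per <- tapply(span, blk[[partner_col]], sum)
      total <- sum(per)
      big <- names(per)[per / total >= per_partner_floor]
      if (length(big) >= 3) { complex <- c(complex, x); next }
      if (length(big) != 2) next
      if (sum(per[big]) / total < min_cov_frac) next
      mids <- vapply(big, function(q) {
        b <- blk[blk[[partner_col]] == q, , drop = FALSE]
        stats::weighted.mean((b[[jstart]] + b[[jend]]) / 2,
                             b[[jend]] - b[[jstart]])
      }, numeric(1))
      ord <- big[order(mids)]
      left_blk <- blk[blk[[partner_col]] == ord[1], , drop = FALSE]
      right_blk <- blk[blk[[partner_col]] == ord[2], , drop = FALSE]
      junction <- round((max(left_blk[[jend]]) +
                         min(right_blk[[jstart]])) / 2)
      l_strand <- left_blk$strand[which.max(left_blk[[jend]])]
      r_strand <- right_blk$strand[which.min(right_blk[[jstart]])]
      res[[length(res) + 1]] <- data.frame(
        split_assembly = assembly_id(partner_set),
        left_scaffold = ord[1], right_scaffold = ord[2],
        left_terminus = if (l_strand == "+") "end" else "start",
        right_terminus = if (r_strand == "+") "start" else "end",
        joined_assembly = assembly_id(joined_set),
        joined_scaffold = x, junction_position = junction,
        stringsAsFactors = FALSE)
    }
    list(bp = res, complex = complex)
  }
  # joined in B, split in A (queries), and the transpose
  s1 <- scan_side(paf, "target", "query", set_b, set_a, "tstart", "tend")
  s2 <- scan_side(paf, "query", "target", set_a, set_b, "qstart", "qend")
  bp <- do.call(rbind, c(s1$bp, s2$bp))
  if (is.null(bp))
    bp <- data.frame(split_assembly = character(),
                     left_scaffold = character(),
                     right_scaffold = character(),
                     left_terminus = character(),
                     right_terminus = character(),
                     joined_assembly = character(),
                     joined_scaffold = character(),
                     junction_position = numeric(),
                     stringsAsFactors = FALSE)
  bp <- cbind(id = sprintf("BP%d", seq_len(nrow(bp))), bp,
              stringsAsFactors = FALSE)
  rownames(bp) <- NULL
  attr(bp, "complex") <- unique(c(s1$complex, s2$complex))
  class(bp) <- c("breakpoint_set", "data.frame")
  bp
}

#' Choose a length-matched control scaffold pair
#'
#' The joined scaffold is paired with the uninvolved scaffold of the same
#' assembly whose length is nearest to its own; ties break toward the
#' earlier scaffold in assembly order. "Uninvolved" means not participating
#' in any breakpoint, on either side.
#'
#' @param bp one row of a [detect_breakpoints()] result.
#' @param opposing the [scaffold_set()] containing the joined scaffold.
#' @param involved character vector of scaffold names involved in any
#'   breakpoint (in the opposing assembly).
#' @return List with `scaffold_a` (the joined scaffold), `scaffold_b`
#'   (the control partner) and `partner_length`.
#' @export
select_control <- function(bp, opposing, involved) {
  L_joined <- scaffold_length(opposing, bp$joined_scaffold)
  cand <- opposing[!(opposing$name %in% involved) &
                   opposing$name != bp$joined_scaffold, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no uninvolved scaffold available as control for ", bp$id)
  d <- abs(cand$length - L_joined)
  best <- cand[order(d, cand$order_index), ][1, ]
  list(scaffold_a = bp$joined_scaffold, scaffold_b = best$name,
       partner_length = best$length)
}

#' Empirical p-value of a contact rate against the genome-wide background
#'
#' The fraction of background rates equal to or exceeding the observed
#' rate. When the observed pair is itself part of the background (the
#' default convention), p is bounded below by `1/length(background)` and
#' can never be zero.
#'
#' @param r_obs observed rate (pairs per Mb^2).
#' @param background numeric vector of genome-wide scaffold-pair rates.
#' @param floor_n minimum background size (default 20); smaller
#'   backgrounds are refused because the p-value resolution becomes
#'   meaningless.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(r_obs, background, floor_n = 20) {
  n <- length(background)
  if (n < floor_n)
    stop("background has only ", n, " rates (< ", floor_n,
         "); use an assembly with more scaffolds")
  sum(background >= r_obs) / n
}

#' One-tailed rank-sum test of breakpoint rates against the background
#'
#' Wilcoxon rank-sum with alternative "greater" (breakpoint rates shifted
#' above background). The exact null distribution is used when
#' `n * m <= 1e4` and there are no ties; otherwise midranks with tie
#' correction and a continuity-corrected normal approximation. U is
#' reported for the breakpoint sample.
#'
#' @param breakpoint_rates numeric vector (the x sample).
#' @param background numeric vector (the y sample).
#' @return List with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
joint_rank_test <- function(breakpoint_rates, background) {
  x <- breakpoint_rates; y <- background
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  want_exact <- length(x) * length(y) <= 1e4 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = want_exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (want_exact) "exact" else "normal")
}

#' Compare an observed rate with the within-scaffold contact rates
#'
#' Cross-junction contacts of a genuinely contiguous chromosome are still
#' expected to sit below typical within-scaffold rates (contacts decay
#' with distance, and a junction only sees the tail), so this comparison
#' is a sanity check, not a verdict criterion.
#'
#' @param r_obs observed breakpoint rate (pairs per Mb^2).
#' @param intra_rates within-scaffold rates `I_i / (L_i/1e6)^2`.
#' @return List with `fraction_above` (fraction of intra rates exceeding
#'   `r_obs`) and `below_intra` (is `r_obs` below the median intra rate?).
#' @export
compare_intra <- function(r_obs, intra_rates) {
  list(fraction_above = mean(intra_rates > r_obs),
       below_intra = r_obs < stats::median(intra_rates))
}

#' Outgroup collinearity of a breakpoint
#'
#' Applies the partner-coverage rule to an alignment of the split assembly
#' against an outgroup: the breakpoint is collinear when both split
#' scaffolds have the same dominant outgroup partner (i.e. the outgroup
#' carries them on one chromosome).
#'
#' @param bp one row of a [detect_breakpoints()] result.
#' @param paf_split_vs_outgroup PAF blocks, split-assembly queries against
#'   outgroup targets.
#' @return `TRUE`, `FALSE`, or `NA` when either scaffold has no alignment.
#' @export
collinear_in_outgroup <- function(bp, paf_split_vs_outgroup) {
  dominant <- function(scaf) {
    blk <- paf_split_vs_outgroup[paf_split_vs_outgroup$query == scaf, ,
                                 drop = FALSE]
    if (nrow(blk) == 0) return(NA_character_)
    per <- tapply(blk$tend - blk$tstart, blk$target, sum)
    names(per)[which.max(per)]
  }
  d1 <- dominant(bp$left_scaffold)
  d2 <- dominant(bp$right_scaffold)
  if (is.na(d1) || is.na(d2)) return(NA)
  identical(d1, d2)
}
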