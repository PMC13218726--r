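#' Mean read depth in a terminal scaffold window
#'
#' Computes per-1 kb mean depth over the terminal `window` bp at one
#' scaffold end from alignment records, counting only alignments with
#' `mapq >= mq_min`. Coverage uses the reference span of each alignment
#' (CIGAR M/=/X/D operations; see [cigar_ref_length()]); duplicates are
#' excluded.
#'
#' @param alignments alignment `data.frame` (see [read_alignments()]).
#' @param scaffolds the [scaffold_set()] (for scaffold lengths).
#' @param scaffold scaffold name.
#' @param terminus `"start"` or `"end"`.
#' @param window window size in bp (default 200 kb; truncated to the
#'   scaffold with a warning when the scaffold is shorter).
#' @param bin bin size in bp (default 1 kb).
#' @param mq_min mapping-quality threshold (default 10).
#' @return `data.frame` with columns `scaffold`, `start`, `end`, `depth`
#'   (mean per-base depth in each bin), attribute `terminus`.
#' @export
terminal_window_depth <- function(alignments, scaffolds, scaffold,
                                  terminus = c("start", "end"),
                                  window = 2e5, bin = 1000, mq_min = 10) {
  terminus <- match.arg(terminus)
  L <- scaffold_length(scaffolds, scaffold)
  if (L < bin)
    warning("scaffold ", scaffold, " shorter than one bin; single partial bin")
  w <- min(window, L)
  w0 <- if (terminus == "start") 0 else L - w
  w1 <- w0 + w

  aln <- alignments[!alignments$is_duplicate &
                    alignments$target == scaffold &
                    alignments$mapq >= mq_min, , drop = FALSE]
  cover <- numeric(w)  # per-base depth inside the window
  if (nrow(aln) > 0) {
    a0 <- aln$target_start
    a1 <- a0 + cigar_ref_length(aln$cigar)
    s <- pmax(a0, w0) - w0
    e <- pmin(a1, w1) - w0
    keep <- e > s
    if (any(keep)) {
      # difference-array accumulation of interval coverage
      d <- numeric(w + 1)
      for (i in which(keep)) {
        d[s[i] + 1] <- d[s[i] + 1] + 1
        d[e[i] + 1] <- d[e[i] + 1] - 1
      }
      cover <- cumsum(d[seq_len(w)])
    }
  }
  bin_start <- seq(0, w - 1, by = bin)
  bin_end <- pmin(bin_start + bin, w)
  depth <- vapply(seq_along(bin_start), function(i)
    mean(cover[(bin_start[i] + 1):bin_end[i]]), numeric(1))
  out <- data.frame(scaffold = scaffold, start = w0 + bin_start,
                    end = w0 + bin_end, depth = depth,
                    stringsAsFactors = FALSE)
  attr(out, "terminus") <- terminus
  attr(out, "window_size") <- bin
  out
}

#' Count reads spanning a scaffold junction
#'
#' A spanning read has alignments (primary or supplementary, sharing a
#' query name) on both sides of a breakpoint: one within `flank` of the
#' left scaffold's junction terminus and one within `flank` of the right
#' scaffold's junction terminus. Each qualifying query name counts once.
#' At a junction that was never assembled no read can be anchored across
#' it, so zero is the expected value for a true assembly gap.
#'
#' @param alignments alignment `data.frame`.
#' @param bp one row of a [detect_breakpoints()] result.
#' @param scaffolds [scaffold_set()] of the split assembly.
#' @param flank distance from the junction terminus within which an
#'   alignment must fall (default 10 kb).
#' @return Integer count of distinct spanning query names.
#' @export
detect_spanning_reads <- function(alignments, bp, scaffolds, flank = 1e4) {
  aln <- alignments[!alignments$is_duplicate, , drop = FALSE]
  in_terminal <- function(scaf, terminus) {
    L <- scaffold_length(scaffolds, scaf)
    reg0 <- if (terminus == "start") 0 else L - flank
    reg1 <- if (terminus == "start") flank else L
    sel <- aln$target == scaf
    a0 <- aln$target_start[sel]
    a1 <- a0 + cigar_ref_length(aln$cigar[sel])
    unique(aln$query[sel][a1 > reg0 & a0 < reg1])
  }
  left <- in_terminal(bp$left_scaffold, bp$left_terminus)
  right <- in_terminal(bp$right_scaffold, bp$right_terminus)
  length(intersect(left, right))
}

#' Coverage fold-change around a junction
#'
#' Ratio of median flank depth to median core depth on a junction-centered
#' 1 kb track. The core is the innermost `core` bp (straddling the
#' junction); the flank is the distal portion of the track, beyond
#' `flank_gap` from the junction and out to `flank`, so that the
#' repeat-enriched neighborhood immediately around a junction does not
#' contaminate the reference level. A fold of `fold_threshold` or more
#' (or an undefined ratio over a zero-depth core) flags the junction as
#' low-mappability.
#'
#' @param track `data.frame` with columns `offset` (signed bp of the bin
#'   center relative to the junction) and `depth`; see
#'   [junction_depth_track()].
#' @param core total width of the core region in bp (default 50 kb).
#' @param flank maximum |offset| used (default 200 kb).
#' @param flank_gap minimum |offset| of flank bins (default 100 kb).
#' @param fold_threshold flag threshold (default 2).
#' @return List with `fold`, `low_mappability`, `median_core`,
#'   `median_flank`.
#' @export
coverage_fold <- function(track, core = 5e4, flank = 2e5, flank_gap = 1e5,
                          fold_threshold = 2) {
  off <- abs(track$offset)
  core_d <- track$depth[off <= core / 2]
  flank_d <- track$depth[off > flank_gap & off <= flank]
  if (length(core_d) == 0 || length(flank_d) == 0)
    stop("core or flank region empty; check track offsets")
  m_core <- stats::median(core_d)
  m_flank <- stats::median(flank_d)
  if (m_core == 0) {
    return(list(fold = Inf, low_mappability = TRUE, median_core = 0,
                median_flank = m_flank))
  }
  fold <- m_flank / m_core
  list(fold = fold, low_mappability = fold >= fold_threshold,
       median_core = m_core, median_flank = m_flank)
}

#' Junction-centered depth track for a breakpoint
#'
#' Assembles the 1 kb depth bins of the terminal `window` bp on each side
#' of a breakpoint junction into one track with signed offsets from the
#' junction (negative on the left scaffold's side).
#'
#' @param depth_kb per-1 kb depth `data.frame` (assembly coordinates).
#' @param bp one row of a [detect_breakpoints()] result.
#' @param scaffolds [scaffold_set()] of the split assembly.
#' @param window bp taken from each side (default 200 kb).
#' @return `data.frame` with columns `offset`, `depth`.
#' @export
junction_depth_track <- function(depth_kb, bp, scaffolds, window = 2e5) {
  side <- function(scaf, terminus, sign) {
    L <- scaffold_length(scaffolds, scaf)
    d <- depth_kb[depth_kb$scaffold == scaf, , drop = FALSE]
    if (terminus == "end") {
      sel <- d$start >= L - window
      dist <- L - (d$start[sel] + d$end[sel]) / 2   # bp back from junction
    } else {
      sel <- d$start < window
      dist <- (d$start[sel] + d$end[sel]) / 2
    }
    data.frame(offset = sign * dist, depth = d$depth[sel])
  }
  rbind(side(bp$left_scaffold, bp$left_terminus, -1),
        side(bp$right_scaffold, bp$right_terminus, 1))
}

#' Masked fraction of a window, per repeat class
#'
#' Clips the annotation to the window, merges overlapping intervals within
#' each of the eight classes (no double counting), and reports the masked
#' fraction per class plus the total masked fraction from the union across
#' classes.
#'
#' @param annotation repeat annotation `data.frame` (with `class8`).
#' @param scaffold,start,end the window (0-based half-open).
#' @return List with `class_fraction` (named numeric over the eight
#'   classes), `f_tot`, and the window coordinates.
#' @export
window_masked_fraction <- function(annotation, scaffold, start, end) {
  if (end <= start) stop("window must have positive length")
  w <- end - start
  a <- annotation[annotation$scaffold == scaffold &
                  annotation$end > start & annotation$start < end, ,
                  drop = FALSE]
  s <- pmax(a$start, start)
  e <- pmin(a$end, end)
  merged_width <- function(sel) {
    if (!any(sel)) return(0)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = s[sel] + 1, end = e[sel]))))
  }
  cls <- vapply(repeat_class8, function(cc) merged_width(a$class8 == cc),
                numeric(1))
  f_tot <- merged_width(rep(TRUE, nrow(a))) / w
  list(class_fraction = cls / w, f_tot = f_tot,
       scaffold = scaffold, start = start, end = end)
}

#' Compare repeat content of junction and control windows
#'
#' Summarizes masked fractions (total and unclassified) across junction
#' windows versus control windows, the comparison used to argue that
#' repeat-rich boundaries drove an assembly split.
#'
#' @param junction_profiles,control_profiles lists of
#'   [window_masked_fraction()] results.
#' @return List with `mean_f_tot_junction`, `mean_f_tot_control`,
#'   `mean_f_unknown_junction`, `mean_f_unknown_control`, their
#'   differences, per-window `table`, and `repeat_enriched`.
#' @export
compare_junction_repeats <- function(junction_profiles, control_profiles) {
  if (length(junction_profiles) == 0 || length(control_profiles) == 0)
    stop("need at least one profile per side")
  row1 <- function(p, side) data.frame(
    side = side, scaffold = p$scaffold, start = p$start, end = p$end,
    f_tot = p$f_tot, f_unknown = unname(p$class_fraction["unknown"]),
    stringsAsFactors = FALSE)
  tab <- rbind(
    do.call(rbind, lapply(junction_profiles, row1, side = "junction")),
    do.call(rbind, lapply(control_profiles, row1, side = "control")))
  mj <- mean(tab$f_tot[tab$side == "junction"])
  mc <- mean(tab$f_tot[tab$side == "control"])
  uj <- mean(tab$f_unknown[tab$side == "junction"])
  uc <- mean(tab$f_unknown[tab$side == "control"])
  list(mean_f_tot_junction = mj, mean_f_tot_control = mc,
       mean_f_unknown_junction = uj, mean_f_unknown_control = uc,
       diff_f_tot = mj - mc, diff_f_unknown = uj - uc,
       table = tab, repeat_enriched = mj > mc)
}
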