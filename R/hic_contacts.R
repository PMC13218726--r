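#' Count trans and intra-scaffold Hi-C contacts
#'
#' Single pass over filtered, deduplicated pair records. Every trans pair
#' increments the count T_ij of exactly one unordered scaffold pair
#' (i < j by scaffold-set order); intra pairs with separation strictly
#' greater than `min_intra_sep` increment the scaffold's intra count I_i;
#' shorter intra pairs are tallied separately (they are dominated by
#' self-ligation artifacts and excluded from the intra rate). Rates are
#' length-normalized to pairs per Mb^2:
#' `r_ij = T_ij / ((L_i/1e6) * (L_j/1e6))`, and all scaffold pairs —
#' including zero-count ones — carry a rate, because the genome-wide
#' background distribution is defined over all pairs.
#'
#' @param pairs a pairs `data.frame` (see [read_pairs()]).
#' @param scaffolds the [scaffold_set()] the pairs are mapped to.
#' @param min_intra_sep intra pairs must exceed this separation (bp) to
#'   count (strict inequality; default 1 kb).
#' @return A list of class `contact_rate_table`: `pairs` (`data.frame`
#'   scaffold_i, scaffold_j, L_i, L_j, T, rate for all i < j),
#'   `intra` (`data.frame` scaffold, L, I, rate_intra), `n_short_intra`,
#'   `n_total`, `scaffolds`.
#' @export
count_contacts <- function(pairs, scaffolds, min_intra_sep = 1000) {
  r1 <- scaffold_rank(scaffolds, pairs$scaffold1)
  r2 <- scaffold_rank(scaffolds, pairs$scaffold2)
  lo <- pmin(r1, r2)
  hi <- pmax(r1, r2)
  n <- nrow(scaffolds)

  grid <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key_all <- (grid[, "row"] - 1) * n + (grid[, "col"] - 1)
  is_trans <- lo != hi
  key_obs <- lo[is_trans] * n + hi[is_trans]
  T_ij <- as.vector(table(factor(key_obs, levels = key_all)))

  L <- scaffolds$length
  Li <- L[grid[, "row"]]
  Lj <- L[grid[, "col"]]
  pair_tab <- data.frame(
    scaffold_i = scaffolds$name[grid[, "row"]],
    scaffold_j = scaffolds$name[grid[, "col"]],
    L_i = Li, L_j = Lj, T = T_ij,
    rate = T_ij / ((Li / 1e6) * (Lj / 1e6)),
    stringsAsFactors = FALSE)
  pair_tab <- pair_tab[order(grid[, "row"], grid[, "col"]), ]
  rownames(pair_tab) <- NULL

  sep <- abs(pairs$pos2 - pairs$pos1)
  qual_intra <- !is_trans & sep > min_intra_sep
  I_i <- as.vector(table(factor(lo[qual_intra], levels = 0:(n - 1))))
  intra_tab <- data.frame(scaffold = scaffolds$name, L = L, I = I_i,
                          rate_intra = I_i / (L / 1e6)^2,
                          stringsAsFactors = FALSE)

  structure(list(pairs = pair_tab, intra = intra_tab,
                 n_short_intra = sum(!is_trans & sep <= min_intra_sep),
                 n_total = nrow(pairs), scaffolds = scaffolds),
            class = "contact_rate_table")
}

#' @export
print.contact_rate_table <- function(x, ...) {
  cat(sprintf(paste0("<contact_rate_table> %s: %d pairs counted ",
                     "(%d trans across %d scaffold pairs, %d intra >sep, ",
                     "%d short intra)\n"),
              assembly_id(x$scaffolds), x$n_total, sum(x$pairs$T),
              nrow(x$pairs), sum(x$intra$I), x$n_short_intra))
  invisible(x)
}

#' Look up the trans contact rate of one scaffold pair
#'
#' @param ct a [count_contacts()] result.
#' @param scaffold_a,scaffold_b scaffold names (order-free).
#' @return List with `T` (count) and `rate` (pairs per Mb^2).
#' @export
contact_rate <- function(ct, scaffold_a, scaffold_b) {
  i <- which((ct$pairs$scaffold_i == scaffold_a &
              ct$pairs$scaffold_j == scaffold_b) |
             (ct$pairs$scaffold_i == scaffold_b &
              ct$pairs$scaffold_j == scaffold_a))
  if (length(i) != 1) stop("no such scaffold pair: ",
                           scaffold_a, " / ", scaffold_b)
  list(T = ct$pairs$T[i], rate = ct$pairs$rate[i])
}

#' Bin trans pair ends into a contact density track
#'
#' Each trans pair contributes one count to the bin of each of its two
#' ends, so the track's total mass is twice the trans pair count. Bins are
#' half-open `[start, start + bin)`; the final partial bin is retained.
#' Zero bins are included, which makes the track directly plottable.
#'
#' @param pairs a pairs `data.frame`.
#' @param scaffolds the [scaffold_set()].
#' @param bin bin width in bp (default 500 kb).
#' @return `data.frame` with columns `scaffold`, `start`, `end`, `count`.
#' @export
bin_trans_density <- function(pairs, scaffolds, bin = 5e5) {
  r1 <- scaffold_rank(scaffolds, pairs$scaffold1)
  r2 <- scaffold_rank(scaffolds, pairs$scaffold2)
  tr <- r1 != r2
  ends <- data.frame(
    scaffold = c(pairs$scaffold1[tr], pairs$scaffold2[tr]),
    pos = c(pairs$pos1[tr], pairs$pos2[tr]), stringsAsFactors = FALSE)

  out <- lapply(seq_len(nrow(scaffolds)), function(k) {
    L <- scaffolds$length[k]
    nb <- ceiling(L / bin)
    start <- (seq_len(nb) - 1) * bin
    pos <- ends$pos[ends$scaffold == scaffolds$name[k]]
    cnt <- tabulate(floor(pos / bin) + 1, nbins = nb)
    data.frame(scaffold = scaffolds$name[k], start = start,
               end = pmin(start + bin, L), count = cnt,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin") <- bin
  res
}
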