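#' Read Hi-C pair records
#'
#' Parses a tab-separated pairs file in the 4DN dialect: `#`-prefixed header
#' lines followed by records with at least 7 columns (readID, chrom1, pos1,
#' chrom2, pos2, strand1, strand2) and an optional 8th pair-type column.
#' Positions are 0-based. Records are filtered to the requested pair types
#' (by default `UU`, both ends uniquely mapped) and re-ordered into the
#' canonical upper-triangle convention: end 1 not after end 2 under the
#' scaffold-set order, then position.
#'
#' @param path file path.
#' @param keep_pair_types character vector of pair-type codes to retain.
#'   Records whose file has no pair-type column are treated as `UU`.
#' @param scaffolds optional [scaffold_set()]; when supplied, records naming
#'   unknown scaffolds or with positions outside `[0, L)` are an error, and
#'   canonical ordering follows its `order_index` (file order otherwise).
#' @return A `data.frame` with columns `readID`, `scaffold1`, `pos1`,
#'   `scaffold2`, `pos2`, `strand1`, `strand2`, `pair_type`.
#' @export
read_pairs <- function(path, keep_pair_types = "UU", scaffolds = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (length(body_idx) == 0) return(empty_pairs())
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7)) {
    bad <- body_idx[which(nf < 7)[1]]
    stop(sprintf("malformed pairs line %d: %d column(s), expected >= 7",
                 bad, nf[which(nf < 7)[1]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:8)), ncol = 8, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 3]))
  pos2 <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(pos1) || anyNA(pos2)) {
    bad <- body_idx[which(is.na(pos1) | is.na(pos2))[1]]
    stop(sprintf("malformed pairs line %d: non-numeric position", bad))
  }
  pt <- m[, 8]
  pt[is.na(pt) | !nzchar(pt)] <- "UU"
  pairs <- data.frame(readID = m[, 1], scaffold1 = m[, 2], pos1 = pos1,
                      scaffold2 = m[, 4], pos2 = pos2,
                      strand1 = m[, 6], strand2 = m[, 7], pair_type = pt,
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pair_type %in% keep_pair_types, , drop = FALSE]
  rownames(pairs) <- NULL
  if (!is.null(scaffolds)) validate_pairs(pairs, scaffolds)
  canonicalize_pairs(pairs, scaffolds)
}

empty_pairs <- function() {
  data.frame(readID = character(), scaffold1 = character(), pos1 = numeric(),
             scaffold2 = character(), pos2 = numeric(), strand1 = character(),
             strand2 = character(), pair_type = character(),
             stringsAsFactors = FALSE)
}

validate_pairs <- function(pairs, scaffolds) {
  for (side in 1:2) {
    sc <- pairs[[paste0("scaffold", side)]]
    po <- pairs[[paste0("pos", side)]]
    i <- match(sc, scaffolds$name)
    if (anyNA(i))
      stop("pair references scaffold absent from the scaffold set: ",
           sc[is.na(i)][1])
    L <- scaffolds$length[i]
    bad <- which(po < 0 | po >= L)
    if (length(bad))
      stop(sprintf("pair position out of range on %s: %d (length %d)",
                   sc[bad[1]], as.integer(po[bad[1]]), as.integer(L[bad[1]])))
  }
  invisible(TRUE)
}

#' Canonically order pair records
#'
#' Enforces the upper-triangle convention: the end on the earlier scaffold
#' (by scaffold-set order, or file-given order of first appearance when no
#' set is supplied) comes first; within a scaffold, the smaller position.
#' Strands travel with their ends. The row order of the input is preserved.
#'
#' @param pairs a pairs `data.frame` as returned by [read_pairs()].
#' @param scaffolds optional [scaffold_set()] defining scaffold order.
#' @return The reordered pairs `data.frame`.
#' @export
canonicalize_pairs <- function(pairs, scaffolds = NULL) {
  if (nrow(pairs) == 0) return(pairs)
  if (is.null(scaffolds)) {
    lev <- unique(c(pairs$scaffold1, pairs$scaffold2))
  } else {
    lev <- scaffolds$name
  }
  r1 <- match(pairs$scaffold1, lev)
  r2 <- match(pairs$scaffold2, lev)
  swap <- r1 > r2 | (r1 == r2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, ]
    pairs$scaffold1[swap] <- tmp$scaffold2
    pairs$pos1[swap] <- tmp$pos2
    pairs$strand1[swap] <- tmp$strand2
    pairs$scaffold2[swap] <- tmp$scaffold1
    pairs$pos2[swap] <- tmp$pos1
    pairs$strand2[swap] <- tmp$strand1
  }
  pairs
}

#' Write Hi-C pair records
#'
#' Writes the tab-separated pairs dialect read by [read_pairs()], with a
#' single `#`-prefixed header line.
#'
#' @param pairs a pairs `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2 pair_type",
             path)
  out <- pairs[, c("readID", "scaffold1", "pos1", "scaffold2", "pos2",
                   "strand1", "strand2", "pair_type")]
  out$pos1 <- format(out$pos1, scientific = FALSE, trim = TRUE)
  out$pos2 <- format(out$pos2, scientific = FALSE, trim = TRUE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
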