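#' Read whole-genome alignment blocks (PAF)
#'
#' Parses the standard 12+-column PAF produced by minimap2/Winnowmap-class
#' aligners. Coordinates stay 0-based half-open. Blocks shorter than
#' `min_block` (alignment block length, column 11) are dropped: short
#' spurious blocks otherwise litter the partner-coverage statistics used
#' for breakpoint detection.
#'
#' @param path file path.
#' @param min_block minimum alignment block length in bp (default 10 kb).
#' @return A `data.frame` with columns `query`, `query_len`, `qstart`,
#'   `qend`, `strand`, `target`, `target_len`, `tstart`, `tend`, `matches`,
#'   `block_len`, `mapq`.
#' @export
read_paf <- function(path, min_block = 10000) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop(sprintf("truncated PAF row %d: %d column(s), expected >= 12",
                 which(nf < 12)[1], min(nf)))
  m <- matrix(unlist(lapply(fields, `[`, 1:12)), ncol = 12, byrow = TRUE)
  num_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  nums <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums))
    stop(sprintf("non-integer coordinate field in PAF row %d",
                 which(apply(is.na(nums), 1, any))[1]))
  paf <- data.frame(query = m[, 1], query_len = nums[, 1],
                    qstart = nums[, 2], qend = nums[, 3], strand = m[, 5],
                    target = m[, 6], target_len = nums[, 4],
                    tstart = nums[, 5], tend = nums[, 6],
                    matches = nums[, 7], block_len = nums[, 8],
                    mapq = nums[, 9], stringsAsFactors = FALSE)
  paf[paf$block_len >= min_block, , drop = FALSE]
}

empty_paf <- function() {
  data.frame(query = character(), query_len = numeric(), qstart = numeric(),
             qend = numeric(), strand = character(), target = character(),
             target_len = numeric(), tstart = numeric(), tend = numeric(),
             matches = numeric(), block_len = numeric(), mapq = numeric(),
             stringsAsFactors = FALSE)
}

#' Write alignment blocks as PAF
#'
#' @param paf a `data.frame` in the layout returned by [read_paf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  cols <- c("query", "query_len", "qstart", "qend", "strand", "target",
            "target_len", "tstart", "tend", "matches", "block_len", "mapq")
  out <- paf[, cols]
  for (cc in setdiff(cols, c("query", "strand", "target")))
    out[[cc]] <- format(out[[cc]], scientific = FALSE, trim = TRUE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
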