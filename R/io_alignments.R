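#' Read alignment records (SAM text or tabular)
#'
#' Normalizes read alignments into the minimal record the junction-evidence
#' stage needs: query name, target scaffold, 0-based target start, mapping
#' quality, CIGAR and the supplementary/duplicate flags. Two dialects are
#' accepted: plain SAM text (`@`-prefixed headers skipped, flags decoded
#' from column 2) and a 7-column tab-separated table
#' (`query target target_start mapq cigar is_supplementary is_duplicate`,
#' optional `#` header). Binary BAM is deliberately out of scope; convert
#' with `samtools view` first.
#'
#' @param path file path.
#' @param format `"sam"` or `"tsv"`.
#' @param drop_duplicates drop records flagged duplicate (default TRUE; all
#'   counting assumes deduplicated input).
#' @return A `data.frame` with columns `query`, `target`, `target_start`,
#'   `mapq`, `cigar`, `is_supplementary`, `is_duplicate`.
#' @export
read_alignments <- function(path, format = c("sam", "tsv"),
                            drop_duplicates = TRUE) {
  format <- match.arg(format)
  if (format == "sam") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
    if (length(lines) == 0) return(empty_alignments())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 6))
      stop("malformed SAM row: fewer than 6 fields")
    flag <- as.integer(vapply(fields, `[`, "", 2))
    aln <- data.frame(
      query = vapply(fields, `[`, "", 1),
      target = vapply(fields, `[`, "", 3),
      target_start = as.numeric(vapply(fields, `[`, "", 4)) - 1, # SAM 1-based
      mapq = as.integer(vapply(fields, `[`, "", 5)),
      cigar = vapply(fields, `[`, "", 6),
      is_supplementary = bitwAnd(flag, 2048L) > 0L,
      is_duplicate = bitwAnd(flag, 1024L) > 0L,
      stringsAsFactors = FALSE)
    aln <- aln[aln$target != "*", , drop = FALSE]
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                            fill = TRUE)
    dt <- dt[!startsWith(as.character(dt[[1]]), "#")]
    if (ncol(dt) < 7) stop("tabular alignments need 7 columns")
    aln <- data.frame(query = as.character(dt[[1]]),
                      target = as.character(dt[[2]]),
                      target_start = as.numeric(dt[[3]]),
                      mapq = as.integer(dt[[4]]),
                      cigar = as.character(dt[[5]]),
                      is_supplementary = as.logical(dt[[6]]),
                      is_duplicate = as.logical(dt[[7]]),
                      stringsAsFactors = FALSE)
  }
  if (any(aln$mapq < 0 | aln$mapq > 255))
    stop("mapq outside [0, 255]")
  if (drop_duplicates) aln <- aln[!aln$is_duplicate, , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

empty_alignments <- function() {
  data.frame(query = character(), target = character(),
             target_start = numeric(), mapq = integer(), cigar = character(),
             is_supplementary = logical(), is_duplicate = logical(),
             stringsAsFactors = FALSE)
}

#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed by the alignment: the sum of M, =, X
#' and D operation lengths. Insertions, clips and padding consume nothing
#' on the reference. `N` (intron skip) is not expected in genomic DNA
#' alignments and is ignored for coverage.
#'
#' @param cigar character vector of CIGAR strings.
#' @return numeric vector of reference-consumed lengths in bp.
#' @export
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*" || !nzchar(cg)) return(0)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (length(toks) == 0) return(0)
    len <- as.numeric(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(len[op %in% c("M", "=", "X", "D")])
  }, numeric(1), USE.NAMES = FALSE)
}
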