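#' Collapse a raw repeat class into the eight working classes
#'
#' RepeatMasker emits a fine-grained `class/family` taxonomy; all analyses
#' here use eight collapsed bins: `SINE`, `LINE`, `DNA` (DNA transposons),
#' `LTR` (LTR retroelements), `simple` (simple repeats), `low_complexity`,
#' `unknown` (unclassified repeats) and `other` (everything else, e.g.
#' satellites, rRNA, rolling-circle elements).
#'
#' @param raw_class character vector of raw class strings, e.g. `"LINE/L2"`.
#' @return character vector of collapsed class labels.
#' @export
collapse_repeat_class <- function(raw_class) {
  raw_class <- as.character(raw_class)
  out <- rep("other", length(raw_class))
  top <- toupper(sub("/.*$", "", sub("\\?$", "", raw_class)))
  out[top == "SINE"] <- "SINE"
  out[top == "LINE"] <- "LINE"
  out[top == "DNA"] <- "DNA"
  out[top == "LTR"] <- "LTR"
  out[top == "SIMPLE_REPEAT"] <- "simple"
  out[top == "LOW_COMPLEXITY"] <- "low_complexity"
  out[top %in% c("UNKNOWN", "UNSPECIFIED", "") | is.na(raw_class)] <- "unknown"
  out
}

repeat_class8 <- c("SINE", "LINE", "DNA", "LTR", "simple", "low_complexity",
                   "unknown", "other")

#' Read a repeat annotation
#'
#' Supports two dialects: RepeatMasker `.out` (three header lines,
#' whitespace-separated, 1-based inclusive coordinates; the query, begin,
#' end and class/family columns are used) and BED3/BED4 (0-based half-open;
#' the optional 4th column is the raw class, `unknown` when absent). All
#' coordinates are normalized to 0-based half-open and every interval gets
#' a collapsed class via [collapse_repeat_class()].
#'
#' @param path file path.
#' @param dialect `"rmout"` or `"bed"`.
#' @return A `data.frame` with columns `scaffold`, `start`, `end`,
#'   `raw_class`, `class8`.
#' @export
read_repeat_annotation <- function(path, dialect = c("rmout", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "rmout") {
    lines <- readLines(path)
    if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character()
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      ann <- data.frame(scaffold = character(), start = numeric(),
                        end = numeric(), raw_class = character(),
                        stringsAsFactors = FALSE)
    } else {
      fields <- strsplit(lines, "[ \t]+")
      if (any(lengths(fields) < 11))
        stop("malformed RepeatMasker .out row: fewer than 11 fields")
      ann <- data.frame(
        scaffold = vapply(fields, `[`, "", 5),
        start = as.numeric(vapply(fields, `[`, "", 6)) - 1, # 1-based -> 0-based
        end = as.numeric(vapply(fields, `[`, "", 7)),       # inclusive -> exclusive
        raw_class = vapply(fields, `[`, "", 11),
        stringsAsFactors = FALSE)
    }
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
    dt <- dt[!startsWith(as.character(dt[[1]]), "#")]
    raw <- if (ncol(dt) >= 4) as.character(dt[[4]]) else
      rep("Unknown", nrow(dt))
    ann <- data.frame(scaffold = as.character(dt[[1]]),
                      start = as.numeric(dt[[2]]), end = as.numeric(dt[[3]]),
                      raw_class = raw, stringsAsFactors = FALSE)
  }
  if (any(ann$start >= ann$end))
    stop("repeat interval with start >= end after normalization at row ",
         which(ann$start >= ann$end)[1])
  ann$class8 <- collapse_repeat_class(ann$raw_class)
  ann
}

#' Write a repeat annotation as BED4
#'
#' 0-based half-open coordinates; the raw class goes in column 4. A single
#' `#`-prefixed header line is included.
#'
#' @param ann repeat annotation `data.frame` (see [read_repeat_annotation()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(ann, path) {
  writeLines("#scaffold\tstart\tend\traw_class", path)
  out <- data.frame(ann$scaffold,
                    format(ann$start, scientific = FALSE, trim = TRUE),
                    format(ann$end, scientific = FALSE, trim = TRUE),
                    ann$raw_class)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
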