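#' Read a windowed depth table (mosdepth-style regions BED)
#'
#' Four tab-separated columns: scaffold, start, end, mean depth; 0-based
#' half-open windows; optional `#`-prefixed header line.
#'
#' @param path file path.
#' @param window_size nominal window size in bp, recorded as an attribute
#'   (inferred from the first full window when `NULL`).
#' @return A `data.frame` with columns `scaffold`, `start`, `end`, `depth`
#'   and attribute `window_size`.
#' @export
read_depth_bed <- function(path, window_size = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                          fill = TRUE)
  dt <- dt[!startsWith(as.character(dt[[1]]), "#")]
  win <- data.frame(scaffold = as.character(dt[[1]]),
                    start = as.numeric(dt[[2]]), end = as.numeric(dt[[3]]),
                    depth = as.numeric(dt[[4]]), stringsAsFactors = FALSE)
  if (any(win$depth < 0)) stop("negative depth value")
  if (is.null(window_size))
    window_size <- max(win$end - win$start)
  attr(win, "window_size") <- window_size
  win
}

#' Write a windowed depth table
#'
#' @param win depth window `data.frame` (see [read_depth_bed()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(win, path) {
  writeLines("#scaffold\tstart\tend\tdepth", path)
  out <- data.frame(win$scaffold,
                    format(win$start, scientific = FALSE, trim = TRUE),
                    format(win$end, scientific = FALSE, trim = TRUE),
                    win$depth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
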