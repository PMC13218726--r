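#' Construct a scaffold set
#'
#' A scaffold set is the ordered table of sequences making up one assembly
#' (or the true chromosome complement of a simulated genome): one row per
#' scaffold with its name, length in bp and a dense 0-based order index.
#' All coordinate bookkeeping downstream is relative to a scaffold set, and
#' the canonical ordering of Hi-C pair records follows its `order_index`.
#'
#' @param name character vector of scaffold names (unique within assembly).
#' @param length integer-ish vector of scaffold lengths in bp, all >= 1.
#' @param assembly_id single string labelling the assembly.
#' @return A `data.frame` of class `scaffold_set` with columns `name`,
#'   `length`, `order_index` and attribute `assembly_id`.
#' @export
scaffold_set <- function(name, length, assembly_id = "assembly") {
  name <- as.character(name)
  length <- as.numeric(length)
  if (length(name) != length(length))
    stop("name and length must have equal length")
  if (anyDuplicated(name))
    stop("scaffold names must be unique within an assembly: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (any(!is.finite(length)) || any(length < 1))
    stop("all scaffold lengths must be finite and >= 1")
  ss <- data.frame(name = name, length = length,
                   order_index = seq_along(name) - 1L,
                   stringsAsFactors = FALSE)
  attr(ss, "assembly_id") <- as.character(assembly_id)[1]
  class(ss) <- c("scaffold_set", "data.frame")
  ss
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("<scaffold_set> assembly '%s': %d scaffolds, %.2f Mb total\n",
              attr(x, "assembly_id"), nrow(x), sum(x$length) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Assembly label of a scaffold set
#' @param ss a [scaffold_set()].
#' @return The assembly id string.
#' @export
assembly_id <- function(ss) attr(ss, "assembly_id")

scaffold_length <- function(ss, name) {
  i <- match(name, ss$name)
  if (anyNA(i)) stop("unknown scaffold(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  ss$length[i]
}

scaffold_rank <- function(ss, name) {
  i <- match(name, ss$name)
  if (anyNA(i)) stop("unknown scaffold(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  ss$order_index[i]
}

#' Read a scaffold length table (.fai-style)
#'
#' Reads the first two columns (name, length) of a samtools faidx-style
#' index, or any tab-separated name/length table with an optional
#' `#`-prefixed header line.
#'
#' @param path file path.
#' @param assembly_id assembly label to attach; defaults to the file name.
#' @return A [scaffold_set()].
#' @export
read_fai <- function(path, assembly_id = basename(path)) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          skip = "#", fill = TRUE)
  if (nrow(dt) == 0) stop("empty length table: ", path)
  # fread's skip="#" only skips up to a match; strip residual comment rows
  dt <- dt[!startsWith(as.character(dt[[1]]), "#")]
  scaffold_set(dt[[1]], as.numeric(dt[[2]]), assembly_id = assembly_id)
}

#' Write a scaffold length table
#'
#' Emits a two-column tab-separated table with a single `#`-prefixed header
#' line, readable by [read_fai()].
#'
#' @param ss a [scaffold_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fai <- function(ss, path) {
  writeLines("#name\tlength", path)
  data.table::fwrite(data.frame(ss$name, format(ss$length, scientific = FALSE,
                                                trim = TRUE)),
                     path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
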