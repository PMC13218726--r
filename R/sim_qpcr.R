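#' Simulate qPCR Cq replicates for sex genotyping
#'
#' Emulates the two-assay copy-number design: an autosomal locus (A) and a
#' sex-chromosomal locus (S), four technical replicates each. The
#' noiseless expectation of `delta Cq = mean(A_Cq) - mean(S_Cq)` is +1
#' cycle for a male and -1 cycle for a female (one copy-number doubling);
#' replicates add independent Gaussian noise. Note the sign convention is
#' the published diagnostic rule (positive = male ZZ), which runs opposite
#' to the naive copy-number expectation for a two-Z male; the simulator
#' follows the diagnostic rule so classifier and generator agree.
#'
#' @param sex `"male"` or `"female"`.
#' @param noise_sd replicate noise standard deviation in cycles (>= 0).
#' @param n_replicates technical replicates per assay.
#' @param base_cq autosomal assay mean Cq.
#' @param seed RNG seed.
#' @return List with numeric vectors `a_cq`, `s_cq` and the true `sex`.
#' @export
simulate_qpcr <- function(sex = c("male", "female"), noise_sd = 0.1,
                          n_replicates = 4, base_cq = 20, seed = 1L) {
  sex <- match.arg(sex)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  delta <- if (sex == "male") 1 else -1
  a <- base_cq + stats::rnorm(n_replicates, 0, noise_sd)
  s <- base_cq - delta + stats::rnorm(n_replicates, 0, noise_sd)
  list(a_cq = a, s_cq = s, sex = sex)
}

#' Write / read qPCR replicate tables
#'
#' Tab-separated with columns `assay` (`A` autosomal, `S` sex locus),
#' `replicate`, `cq`, and a `#`-prefixed header line.
#'
#' @param qpcr a [simulate_qpcr()]-style list.
#' @param path file path.
#' @return `write_qpcr`: `path` invisibly; `read_qpcr`: a list with
#'   `a_cq` and `s_cq`.
#' @export
write_qpcr <- function(qpcr, path) {
  writeLines("#assay\treplicate\tcq", path)
  out <- data.frame(
    assay = rep(c("A", "S"), c(length(qpcr$a_cq), length(qpcr$s_cq))),
    replicate = c(seq_along(qpcr$a_cq), seq_along(qpcr$s_cq)),
    cq = c(qpcr$a_cq, qpcr$s_cq))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#")
  dt <- dt[!startsWith(as.character(dt[[1]]), "#")]
  list(a_cq = as.numeric(dt[[3]][dt[[1]] == "A"]),
       s_cq = as.numeric(dt[[3]][dt[[1]] == "S"]))
}
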