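#' Simulate read-depth tracks for a derived assembly
#'
#' Per-1 kb bin depth is Poisson with mean
#' `depth_lambda * (1 - gamma * density) * c`, where `density` is the
#' bin's masked fraction and `c = 0.5` on the Z chromosome of a Z0
#' (single-Z female) genome, 1 otherwise. Repeat-rich bins therefore show
#' the depressed apparent coverage that low mappability produces in real
#' alignments. Returns both the 1 kb track and the 500 kb window table
#' (mean of constituent 1 kb bins, final partial window retained), in
#' assembly coordinates.
#'
#' @param genome a [simulate_genome()] result.
#' @param derivation an [derive_assembly()] result.
#' @param config the [sim_config()] (defaults to the genome's).
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return List with depth `data.frame`s `per_kb` (window 1000) and
#'   `per_500kb` (window 500000), each with columns `scaffold`, `start`,
#'   `end`, `depth`.
#' @export
simulate_depth <- function(genome, derivation, config = genome$config,
                           seed = config$seed + 2L) {
  stopifnot(inherits(genome, "sim_genome"),
            inherits(derivation, "assembly_derivation"))
  set.seed(seed)
  z <- if (identical(config$sex, "Z0")) config$z_chrom else NULL
  depth_truth <- lapply(names(genome$density), function(ch) {
    d <- genome$density[[ch]]
    cc <- if (!is.null(z) && ch == z) 0.5 else 1
    stats::rpois(length(d), config$depth_lambda * (1 - config$gamma * d) * cc)
  })
  names(depth_truth) <- names(genome$density)

  lo <- derivation$liftover
  per <- vector("list", nrow(lo))
  for (k in seq_len(nrow(lo))) {
    bins <- depth_truth[[lo$chrom[k]]][
      (lo$start[k] / 1000 + 1):ceiling(lo$end[k] / 1000)]
    L <- lo$end[k] - lo$start[k]
    start <- (seq_along(bins) - 1) * 1000
    per[[k]] <- data.frame(scaffold = lo$scaffold[k], start = start,
                           end = pmin(start + 1000, L), depth = bins,
                           stringsAsFactors = FALSE)
  }
  per_kb <- do.call(rbind, per)
  rownames(per_kb) <- NULL
  attr(per_kb, "window_size") <- 1000

  dt <- data.table::as.data.table(per_kb)
  wid <- floor(dt$start / 5e5)
  agg <- dt[, list(start = min(start), end = max(end),
                   depth = mean(depth)),
            by = list(scaffold = dt$scaffold, .wid = wid)]
  agg[, ".wid" := NULL]
  per_500kb <- as.data.frame(agg)
  attr(per_500kb, "window_size") <- 5e5
  list(per_kb = per_kb, per_500kb = per_500kb)
}
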