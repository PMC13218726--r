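#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator. The defaults
#' define desk-scale study conditions: a K = 8 genome with 3-10 Mb
#' chromosomes, a power-law cis contact decay with exponent `alpha` = 1
#' (the canonical contact-probability scaling), a uniform trans background
#' making up `beta` = 10% of pairs, strong repeat-driven mappability loss
#' (`gamma` = 0.8, so a fully masked bin loses 80% of its read ends), a
#' baseline masked fraction of 0.67 rising to 0.72 in +/-100 kb junction
#' neighborhoods (mirroring the 67.6% vs 71.5% contrast the method is
#' built to detect), and 60x mean depth per 1 kb bin, in the range of a
#' high-coverage HiFi dataset. See [full_scale_config()] for a K = 46
#' preset.
#'
#' @param n_chrom haploid chromosome count K (>= 2).
#' @param chrom_lengths chromosome lengths in bp; each >= `10 * s_min`.
#' @param alpha cis contact-decay exponent: P(s) proportional to s^-alpha.
#' @param beta trans background fraction in `[0, 1]`.
#' @param s_min minimum cis separation in bp.
#' @param n_pairs number of emitted Hi-C pairs per assembly.
#' @param depth_lambda mean read depth per 1 kb bin at full mappability.
#' @param gamma mappability-loss coefficient in `[0, 1]`: a read end in a
#'   bin with masked density d is lost with probability `gamma * d`.
#' @param repeat_base_mean baseline masked fraction per 1 kb bin.
#' @param repeat_junction_mean masked fraction in junction neighborhoods.
#' @param repeat_concentration Beta-distribution concentration for per-bin
#'   masked-fraction draws (larger = less bin-to-bin variation).
#' @param sex `"ZZ"` (male, two Z copies) or `"Z0"` (female, one Z).
#' @param z_chrom name of the Z chromosome; defaults to the last chromosome
#'   when `sex = "Z0"`.
#' @param seed integer seed; every generator output is deterministic in it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 8,
                       chrom_lengths = seq(3e6, 10e6, length.out = n_chrom),
                       alpha = 1.0, beta = 0.1, s_min = 1000,
                       n_pairs = 5e5, depth_lambda = 60, gamma = 0.8,
                       repeat_base_mean = 0.67, repeat_junction_mean = 0.72,
                       repeat_concentration = 50,
                       sex = c("ZZ", "Z0"), z_chrom = NULL, seed = 1L) {
  sex <- match.arg(sex)
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_lengths = round(chrom_lengths),
              alpha = alpha, beta = beta, s_min = s_min,
              n_pairs = as.integer(n_pairs), depth_lambda = depth_lambda,
              gamma = gamma, repeat_base_mean = repeat_base_mean,
              repeat_junction_mean = repeat_junction_mean,
              repeat_concentration = repeat_concentration,
              sex = sex, z_chrom = z_chrom, seed = as.integer(seed))
  if (cfg$n_chrom < 2) stop("n_chrom must be >= 2")
  if (length(cfg$chrom_lengths) != cfg$n_chrom)
    stop("chrom_lengths must have n_chrom entries")
  if (any(cfg$chrom_lengths < 10 * cfg$s_min))
    stop("all chromosome lengths must be >= 10 * s_min")
  for (p in c("beta", "gamma", "repeat_base_mean", "repeat_junction_mean")) {
    v <- cfg[[p]]
    if (!is.finite(v) || v < 0 || v > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$n_pairs < 1) stop("n_pairs must be >= 1")
  if (cfg$depth_lambda <= 0) stop("depth_lambda must be > 0")
  if (cfg$sex == "Z0" && is.null(cfg$z_chrom))
    cfg$z_chrom <- paste0("chr", cfg$n_chrom)
  class(cfg) <- "sim_config"
  cfg
}

#' Full-scale simulation preset
#'
#' A K = 46 genome totalling ~5.7 Gb, matching the scale of a large
#' cuttlefish-class assembly. Used only for end-to-end smoke runs; the
#' desk-scale [sim_config()] defaults drive all statistical validation.
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
full_scale_config <- function(...) {
  lens <- round(seq(190e6, 58e6, length.out = 46) / 1e6) * 1e6
  sim_config(n_chrom = 46, chrom_lengths = lens, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> K=%d (%.0f Mb total), alpha=%.2f, ",
                     "beta=%.2f, n_pairs=%s, lambda=%.0f, gamma=%.2f,\n",
                     "  repeat base/junction=%.2f/%.2f, sex=%s%s, seed=%d\n"),
              x$n_chrom, sum(x$chrom_lengths) / 1e6, x$alpha, x$beta,
              format(x$n_pairs, big.mark = ","), x$depth_lambda, x$gamma,
              x$repeat_base_mean, x$repeat_junction_mean, x$sex,
              if (is.null(x$z_chrom)) "" else paste0(" (Z=", x$z_chrom, ")"),
              x$seed))
  invisible(x)
}
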