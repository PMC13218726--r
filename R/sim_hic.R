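#' Simulate Hi-C pairs for a derived assembly
#'
#' Draws read pairs from a two-component contact model. With probability
#' `1 - beta` a pair is cis: a chromosome is chosen proportional to length,
#' the first end is uniform, and the separation s is sampled from
#' P(s) proportional to s^-alpha truncated to `[s_min, L]`; draws whose
#' second end falls off the chromosome are resampled. With probability
#' `beta` a pair is trans: both ends uniform on the genome, conditioned on
#' landing on distinct chromosomes. Each end is then independently lost
#' with probability `gamma * density(bin)` (mappability loss in masked
#' sequence); losing either end discards the pair, mimicking unmapped-mate
#' filtering. Emitted pairs are lifted to the derived assembly, canonically
#' sorted and typed `UU`; exactly `n_pairs` pairs are returned.
#'
#' @param genome a [simulate_genome()] result.
#' @param derivation an [derive_assembly()] result for the same genome.
#' @param config the [sim_config()] (defaults to the genome's).
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A pairs `data.frame` (see [read_pairs()]) in assembly
#'   coordinates, with attributes `n_trans_true` (pairs that are trans in
#'   true-genome coordinates) and `n_candidates` (raw draws consumed).
#' @export
simulate_hic_pairs <- function(genome, derivation, config = genome$config,
                               seed = config$seed + 1L) {
  stopifnot(inherits(genome, "sim_genome"),
            inherits(derivation, "assembly_derivation"))
  set.seed(seed)
  lens <- genome$scaffolds$length
  K <- length(lens)
  chroms <- genome$scaffolds$name
  dens_all <- unlist(genome$density, use.names = FALSE)
  nb <- vapply(genome$density, length, integer(1))
  bin_offset <- c(0, cumsum(nb))[seq_len(K)]

  surv <- (1 - config$gamma * mean(dens_all))^2
  if (surv < 1e-4)
    stop("mappability loss leaves essentially no pairs (all-zero mappability?)")

  got <- list()
  n_got <- 0L
  n_cand <- 0L
  iter <- 0L
  while (n_got < config$n_pairs) {
    iter <- iter + 1L
    if (iter > 100L)
      stop("resample cap reached while emitting pairs; ",
           "check gamma and the repeat density track")
    need <- config$n_pairs - n_got
    n <- ceiling(need / max(surv, 0.05) * 1.1) + 100L
    is_trans <- stats::runif(n) < config$beta
    c1 <- integer(n); p1 <- numeric(n); c2 <- integer(n); p2 <- numeric(n)

    nc <- sum(!is_trans)
    if (nc > 0) {
      ci <- sample.int(K, nc, replace = TRUE, prob = lens)
      pos1 <- pos2 <- numeric(nc)
      todo <- seq_len(nc)
      for (r in 1:100) {
        if (length(todo) == 0) break
        L <- lens[ci[todo]]
        u1 <- stats::runif(length(todo))
        s <- sample_decay_separation(stats::runif(length(todo)),
                                     config$s_min, L, config$alpha)
        a <- floor(u1 * L)
        b <- a + sample(c(-1, 1), length(todo), replace = TRUE) * round(s)
        ok <- b >= 0 & b < L
        pos1[todo[ok]] <- a[ok]
        pos2[todo[ok]] <- b[ok]
        todo <- todo[!ok]
      }
      if (length(todo))
        stop("cis resample cap (100) exceeded")
      c1[!is_trans] <- ci; p1[!is_trans] <- pos1
      c2[!is_trans] <- ci; p2[!is_trans] <- pos2
    }

    nt <- sum(is_trans)
    if (nt > 0) {
      ta <- sample.int(K, nt, replace = TRUE, prob = lens)
      tb <- sample.int(K, nt, replace = TRUE, prob = lens)
      for (r in 1:100) {
        clash <- which(ta == tb)
        if (length(clash) == 0) break
        tb[clash] <- sample.int(K, length(clash), replace = TRUE, prob = lens)
      }
      if (any(ta == tb)) stop("trans resample cap (100) exceeded")
      c1[is_trans] <- ta
      p1[is_trans] <- floor(stats::runif(nt) * lens[ta])
      c2[is_trans] <- tb
      p2[is_trans] <- floor(stats::runif(nt) * lens[tb])
    }

    d1 <- dens_all[bin_offset[c1] + floor(p1 / 1000) + 1]
    d2 <- dens_all[bin_offset[c2] + floor(p2 / 1000) + 1]
    # both ends must survive; the joint survival probability factorizes
    keep <- stats::runif(n) < (1 - config$gamma * d1) * (1 - config$gamma * d2)
    n_cand <- n_cand + n
    if (any(keep)) {
      got[[length(got) + 1]] <- data.frame(
        c1 = c1[keep], p1 = p1[keep], c2 = c2[keep], p2 = p2[keep],
        tr = is_trans[keep])
      n_got <- n_got + sum(keep)
    }
  }
  raw <- do.call(rbind, got)[seq_len(config$n_pairs), ]

  e1 <- lift_to_assembly(derivation, chroms[raw$c1], raw$p1)
  e2 <- lift_to_assembly(derivation, chroms[raw$c2], raw$p2)
  pairs <- data.frame(
    readID = paste0("P", seq_len(nrow(raw))),
    scaffold1 = e1$scaffold, pos1 = e1$pos,
    scaffold2 = e2$scaffold, pos2 = e2$pos,
    strand1 = sample(c("+", "-"), nrow(raw), replace = TRUE),
    strand2 = sample(c("+", "-"), nrow(raw), replace = TRUE),
    pair_type = "UU", stringsAsFactors = FALSE)
  pairs <- canonicalize_pairs(pairs, derivation$scaffolds)
  attr(pairs, "n_trans_true") <- sum(raw$tr)
  attr(pairs, "n_candidates") <- n_cand
  pairs
}

# Inverse-CDF sampling of P(s) ~ s^-alpha truncated to [s_min, L];
# u uniform(0,1), L may be a vector.
sample_decay_separation <- function(u, s_min, L, alpha) {
  if (abs(alpha - 1) < 1e-9) {
    s_min * (L / s_min)^u
  } else {
    a1 <- 1 - alpha
    (s_min^a1 + u * (L^a1 - s_min^a1))^(1 / a1)
  }
}

#' Estimate the cis contact-decay exponent from pairs
#'
#' Bins cis separations into log-spaced bins, converts counts to a density
#' per bp, and fits log(density) against log(separation) by least squares.
#' Under the power-law contact model the slope recovers `-alpha`. The fit
#' range defaults to separations well inside the truncation limits so the
#' power law is unbiased by chromosome ends.
#'
#' @param pairs a pairs `data.frame`.
#' @param s_range separation range (bp) used for the fit.
#' @param n_bins number of log-spaced bins.
#' @return List with `alpha_hat` and the per-bin `data.frame` `bins`.
#' @export
estimate_contact_decay <- function(pairs, s_range = c(2e3, 3e5),
                                   n_bins = 25) {
  cis <- pairs[pairs$scaffold1 == pairs$scaffold2, , drop = FALSE]
  s <- abs(cis$pos2 - cis$pos1)
  s <- s[s >= s_range[1] & s <= s_range[2]]
  if (length(s) < 100) stop("too few cis pairs in the fit range")
  breaks <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n_bins + 1))
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  dens <- h$counts / diff(breaks)
  keep <- h$counts > 0
  fit <- stats::lm(log(dens[keep]) ~ log(h$mids[keep]))
  list(alpha_hat = -unname(stats::coef(fit)[2]),
       bins = data.frame(mid = h$mids, count = h$counts, density = dens))
}
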