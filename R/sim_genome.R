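# Class composition of masked bases, desk-scale caricature of a
# decapod-like repeat landscape: dominated by unclassified repeats, almost
# no SINEs. Junction neighborhoods are shifted further toward unclassified
# repeats, the signature the junction-repeat comparison is meant to pick up.
.repeat_comp_base <- c(unknown = 0.45, LINE = 0.15, LTR = 0.12, DNA = 0.09,
                       simple = 0.08, low_complexity = 0.06, other = 0.04,
                       SINE = 0.01)
.repeat_comp_junction <- c(unknown = 0.70, LINE = 0.08, LTR = 0.06,
                           DNA = 0.04, simple = 0.04, low_complexity = 0.03,
                           other = 0.04, SINE = 0.01)
.repeat_raw_rep <- c(SINE = "SINE/tRNA", LINE = "LINE/L2", DNA = "DNA/TcMar",
                     LTR = "LTR/Gypsy", simple = "Simple_repeat",
                     low_complexity = "Low_complexity", unknown = "Unknown",
                     other = "Satellite")

# Half-width of the repeat-enriched neighborhood planted around each
# prospective split position.
.junction_halfwidth <- 1e5

#' Simulate a true genome with a repeat landscape
#'
#' Draws a per-1 kb masked-fraction (repeat density) track for each of K
#' chromosomes from a Beta distribution around `repeat_base_mean`, raises
#' the mean to each split's junction mean inside a +/-100 kb neighborhood
#' of every planned split position, and materializes the track as a repeat
#' annotation (one interval per bin, class sampled from an
#' unclassified-dominated composition that is further skewed toward
#' unclassified repeats at junctions). Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param splits optional `data.frame` with columns `chrom`, `pos` and
#'   optionally `junction_mean` (defaulting to `config$repeat_junction_mean`):
#'   every position where any derived assembly will later be split.
#'   Positions are snapped to the 1 kb grid.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A list of class `sim_genome`: `scaffolds` (truth
#'   [scaffold_set()], chromosomes `chr1..chrK`), `density` (named list of
#'   per-1 kb masked fractions), `repeats` (annotation `data.frame`),
#'   `splits`, `config`.
#' @export
simulate_genome <- function(config, splits = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  K <- config$n_chrom
  chroms <- paste0("chr", seq_len(K))
  lens <- config$chrom_lengths
  truth <- scaffold_set(chroms, lens, assembly_id = "truth")
  splits <- normalize_splits(splits, truth, config)

  nu <- config$repeat_concentration
  rdens <- function(n, m) {
    m <- min(max(m, 1e-6), 1 - 1e-6)
    stats::rbeta(n, m * nu, (1 - m) * nu)
  }
  density <- vector("list", K)
  names(density) <- chroms
  junction_bins <- vector("list", K)
  for (k in seq_len(K)) {
    nb <- ceiling(lens[k] / 1000)
    d <- rdens(nb, config$repeat_base_mean)
    jb <- integer()
    sp <- splits[splits$chrom == chroms[k], , drop = FALSE]
    for (j in seq_len(nrow(sp))) {
      b0 <- max(0, floor((sp$pos[j] - .junction_halfwidth) / 1000))
      b1 <- min(nb, ceiling((sp$pos[j] + .junction_halfwidth) / 1000))
      idx <- seq.int(b0 + 1, b1)
      d[idx] <- rdens(length(idx), sp$junction_mean[j])
      jb <- c(jb, idx)
    }
    density[[k]] <- d
    junction_bins[[k]] <- unique(jb)
  }

  reps <- vector("list", K)
  for (k in seq_len(K)) {
    d <- density[[k]]
    nb <- length(d)
    bin_start <- (seq_len(nb) - 1) * 1000
    bin_width <- pmin(1000, lens[k] - bin_start)
    masked <- pmin(round(d * 1000), bin_width)
    cls <- sample(names(.repeat_comp_base), nb, replace = TRUE,
                  prob = .repeat_comp_base)
    jb <- junction_bins[[k]]
    if (length(jb))
      cls[jb] <- sample(names(.repeat_comp_junction), length(jb),
                        replace = TRUE, prob = .repeat_comp_junction)
    keep <- masked > 0
    reps[[k]] <- data.frame(scaffold = chroms[k], start = bin_start[keep],
                            end = bin_start[keep] + masked[keep],
                            raw_class = unname(.repeat_raw_rep[cls[keep]]),
                            class8 = cls[keep], stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, reps)
  rownames(repeats) <- NULL

  structure(list(scaffolds = truth, density = density, repeats = repeats,
                 splits = splits, config = config),
            class = "sim_genome")
}

normalize_splits <- function(splits, truth, config) {
  if (is.null(splits) || nrow(splits) == 0)
    return(data.frame(chrom = character(), pos = numeric(),
                      junction_mean = numeric(), stringsAsFactors = FALSE))
  splits <- as.data.frame(splits)
  if (is.null(splits$junction_mean))
    splits$junction_mean <- config$repeat_junction_mean
  splits$junction_mean[is.na(splits$junction_mean)] <-
    config$repeat_junction_mean
  splits$chrom <- as.character(splits$chrom)
  bad <- setdiff(splits$chrom, truth$name)
  if (length(bad)) stop("split on unknown chromosome: ", bad[1])
  splits$pos <- round(splits$pos / 1000) * 1000  # snap to the 1 kb bin grid
  L <- scaffold_length(truth, splits$chrom)
  if (any(splits$pos <= config$s_min | splits$pos >= L - config$s_min))
    stop("split position within s_min of a chromosome end")
  splits[, c("chrom", "pos", "junction_mean")]
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> K=%d, %.1f Mb, %d planted junction(s)\n",
              nrow(x$scaffolds), sum(x$scaffolds$length) / 1e6,
              nrow(x$splits)))
  invisible(x)
}

#' Derive an assembly from a simulated genome
#'
#' Cuts chromosomes at the given split positions and emits the resulting
#' scaffold set together with an exact, invertible liftover (each derived
#' scaffold maps to one `(chromosome, start, end)` interval on the plus
#' strand; the intervals tile every chromosome).
#'
#' @param genome a [simulate_genome()] result.
#' @param split_plan `data.frame` with columns `chrom`, `pos` (bp), or
#'   `NULL` for an identity derivation. Positions are snapped to the 1 kb
#'   grid; two splits on one chromosome must be at least 200 kb apart so
#'   their junction neighborhoods do not overlap.
#' @param assembly_id label for the derived assembly.
#' @return A list of class `assembly_derivation`: `scaffolds`
#'   ([scaffold_set()]), `liftover` (`data.frame` scaffold/chrom/start/end/
#'   strand), `split_plan`, `assembly_id`.
#' @export
derive_assembly <- function(genome, split_plan = NULL,
                            assembly_id = "assembly") {
  stopifnot(inherits(genome, "sim_genome"))
  truth <- genome$scaffolds
  split_plan <- normalize_splits(split_plan, truth, genome$config)
  rows <- list()
  for (k in seq_len(nrow(truth))) {
    chrom <- truth$name[k]
    L <- truth$length[k]
    cuts <- sort(split_plan$pos[split_plan$chrom == chrom])
    if (length(cuts) >= 2 && any(diff(cuts) < 2 * .junction_halfwidth))
      stop("two splits on ", chrom, " closer than ",
           2 * .junction_halfwidth, " bp: junction windows would overlap")
    bounds <- c(0, cuts, L)
    for (j in seq_len(length(bounds) - 1))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = bounds[j], end = bounds[j + 1],
        stringsAsFactors = FALSE)
  }
  lo <- do.call(rbind, rows)
  lo$scaffold <- sprintf("%s_s%02d", assembly_id, seq_len(nrow(lo)))
  lo$strand <- "+"
  lo <- lo[, c("scaffold", "chrom", "start", "end", "strand")]
  ss <- scaffold_set(lo$scaffold, lo$end - lo$start,
                     assembly_id = assembly_id)
  stopifnot(nrow(ss) == nrow(truth) + nrow(split_plan))
  structure(list(scaffolds = ss, liftover = lo, split_plan = split_plan,
                 assembly_id = assembly_id),
            class = "assembly_derivation")
}

#' Map true-genome coordinates into a derived assembly
#'
#' @param derivation an [derive_assembly()] result.
#' @param chrom,pos parallel vectors of truth coordinates (0-based).
#' @return `data.frame` with columns `scaffold`, `pos`.
#' @export
lift_to_assembly <- function(derivation, chrom, pos) {
  lo <- derivation$liftover
  out_scaf <- character(length(chrom))
  out_pos <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    seg <- lo[lo$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0) stop("unknown chromosome: ", ch)
    sel <- which(chrom == ch)
    j <- findInterval(pos[sel], seg$start)
    if (any(j < 1) || any(pos[sel] >= seg$end[j]))
      stop("position outside chromosome ", ch)
    out_scaf[sel] <- seg$scaffold[j]
    out_pos[sel] <- pos[sel] - seg$start[j]
  }
  data.frame(scaffold = out_scaf, pos = out_pos, stringsAsFactors = FALSE)
}

#' Map derived-assembly coordinates back to the true genome
#'
#' Exact inverse of [lift_to_assembly()].
#'
#' @param derivation an [derive_assembly()] result.
#' @param scaffold,pos parallel vectors of assembly coordinates (0-based).
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
lift_to_truth <- function(derivation, scaffold, pos) {
  lo <- derivation$liftover
  i <- match(scaffold, lo$scaffold)
  if (anyNA(i)) stop("unknown scaffold: ", scaffold[is.na(i)][1])
  if (any(pos < 0 | pos >= lo$end[i] - lo$start[i]))
    stop("position outside scaffold")
  data.frame(chrom = lo$chrom[i], pos = lo$start[i] + pos,
             stringsAsFactors = FALSE)
}

#' Lift a repeat annotation into derived-assembly coordinates
#'
#' Intervals crossing a split position are clipped at the boundary.
#'
#' @param ann truth-coordinate repeat annotation.
#' @param derivation an [derive_assembly()] result.
#' @return Annotation `data.frame` in assembly coordinates.
#' @export
lift_annotation <- function(ann, derivation) {
  lo <- derivation$liftover
  by_chrom <- split(seq_len(nrow(ann)), ann$scaffold)
  out <- vector("list", nrow(lo))
  for (k in seq_len(nrow(lo))) {
    idx <- by_chrom[[lo$chrom[k]]]
    if (is.null(idx)) next
    a_start <- ann$start[idx]; a_end <- ann$end[idx]
    sel <- which(a_end > lo$start[k] & a_start < lo$end[k])
    if (length(sel) == 0) next
    ii <- idx[sel]
    out[[k]] <- data.frame(
      scaffold = lo$scaffold[k],
      start = pmax(ann$start[ii], lo$start[k]) - lo$start[k],
      end = pmin(ann$end[ii], lo$end[k]) - lo$start[k],
      raw_class = ann$raw_class[ii], class8 = ann$class8[ii],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

lift_density <- function(density, derivation) {
  # density bins are 1 kb and splits sit on the 1 kb grid, so assembly
  # tracks are concatenations of truth bin ranges
  lo <- derivation$liftover
  out <- vector("list", nrow(lo))
  names(out) <- lo$scaffold
  for (k in seq_len(nrow(lo))) {
    d <- density[[lo$chrom[k]]]
    out[[k]] <- d[(lo$start[k] / 1000 + 1):ceiling(lo$end[k] / 1000)]
  }
  out
}

#' Exact whole-genome alignment between two derived assemblies
#'
#' Because both assemblies tile the same true genome, their alignment is
#' known exactly: each elementary interval between consecutive cut points
#' yields one plus-strand PAF block. This stands in for a
#' Winnowmap/minimap2 whole-genome alignment of the two assemblies.
#'
#' @param deriv_query,deriv_target [derive_assembly()] results sharing a
#'   genome.
#' @return PAF-block `data.frame` in the layout of [read_paf()].
#' @export
paf_from_derivations <- function(deriv_query, deriv_target) {
  loq <- deriv_query$liftover
  lot <- deriv_target$liftover
  rows <- list()
  for (ch in unique(loq$chrom)) {
    q <- loq[loq$chrom == ch, , drop = FALSE]
    t <- lot[lot$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(q$start, q$end, t$start, t$end)))
    for (j in seq_len(length(bounds) - 1)) {
      u <- bounds[j]; v <- bounds[j + 1]
      qi <- which(q$start <= u & q$end >= v)
      ti <- which(t$start <= u & t$end >= v)
      rows[[length(rows) + 1]] <- data.frame(
        query = q$scaffold[qi], query_len = q$end[qi] - q$start[qi],
        qstart = u - q$start[qi], qend = v - q$start[qi], strand = "+",
        target = t$scaffold[ti], target_len = t$end[ti] - t$start[ti],
        tstart = u - t$start[ti], tend = v - t$start[ti],
        matches = v - u, block_len = v - u, mapq = 60,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
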