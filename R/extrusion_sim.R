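## Two-population stochastic loop-extrusion simulator. Cohesin-like
## extruders diffuse on a 1D lattice polymer; orientation-dependent CTCF
## barriers pin legs in place; the Monte Carlo temperature follows a linear
## simulated-annealing schedule. Sampled extruder positions aggregate into a
## contact map and can be exported as a BEDPE-compatible loop set for the
## stripe caller.

#' Configuration for the loop-extrusion simulator
#'
#' Defaults reproduce the reference study conditions: a 1000-monomer
#' polymer, 8e4 Monte Carlo sweeps sampled every 400 after a 4e4 burn-in
#' (100 samples), simulated annealing from temperature 4 to 1, and two
#' extruder populations (100 slow + 5 fast, the fast class making 10
#' proposals per sweep).
#'
#' @param n_monomers lattice size.
#' @param n_steps number of Monte Carlo sweeps.
#' @param sample_every sampling period in sweeps (after burn-in).
#' @param burn_in sweeps discarded before sampling (< n_steps).
#' @param t_init,t_final initial and final Monte Carlo temperatures.
#' @param n_slow,n_fast extruder counts per speed class.
#' @param fast_multiplier proposals per sweep for the fast class (>= 1).
#' @param c_fold folding coefficient (reward for loop growth).
#' @param c_cross crossing coefficient (penalty per crossing loop pair).
#' @param c_bind CTCF binding coefficient scaling barrier strengths
#'   (reference sweep: 0.25, 0.5, 1).
#' @param unbind_prob per-sweep probability that an extruder unbinds and
#'   rebinds at a random loading site (Metropolis-accepted).
#' @param bin_size bp per monomer (contact-map/loop export scale).
#' @param seed RNG seed; every run is bit-reproducible from it.
#' @return list of class "sim_config".
#' @export
sim_config <- function(n_monomers = 1000, n_steps = 80000,
                       sample_every = 400, burn_in = 40000,
                       t_init = 4, t_final = 1,
                       n_slow = 100, n_fast = 5, fast_multiplier = 10,
                       c_fold = 1, c_cross = 10, c_bind = 1,
                       unbind_prob = 0.002, bin_size = 5000, seed = 1) {
  cfg <- list(n_monomers = as.integer(n_monomers),
              n_steps = as.integer(n_steps),
              sample_every = as.integer(sample_every),
              burn_in = as.integer(burn_in),
              t_init = t_init, t_final = t_final,
              n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
              fast_multiplier = as.integer(fast_multiplier),
              c_fold = c_fold, c_cross = c_cross, c_bind = c_bind,
              unbind_prob = unbind_prob, bin_size = as.integer(bin_size),
              seed = as.integer(seed))
  stopifnot(cfg$n_monomers >= 2, cfg$n_steps >= 1, cfg$sample_every >= 1,
            cfg$burn_in >= 0, cfg$burn_in < cfg$n_steps,
            cfg$fast_multiplier >= 1, cfg$n_slow >= 0, cfg$n_fast >= 0,
            cfg$unbind_prob >= 0, cfg$unbind_prob <= 1, cfg$bin_size >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Build orientation-dependent barrier strengths from CTCF anchors
#'
#' Each anchor interval is mapped onto monomers via \code{bin_size} and
#' \code{origin}; at those monomers the left-moving-leg block strength is
#' \code{clamp(c_bind * p_right, 0, 1)} and the right-moving-leg strength
#' \code{clamp(c_bind * p_left, 0, 1)} (right-pointing motifs stall
#' left-moving legs and vice versa, anchoring convergent loops). Overlapping
#' anchors take the maximum. Anchors outside the region are skipped with a
#' warning.
#'
#' @param anchors data.frame with columns start, end (bp) and p_right.
#' @param config \code{\link{sim_config}}.
#' @param origin bp coordinate of monomer 0.
#' @return list with numeric vectors \code{left} and \code{right} of length
#'   n_monomers.
#' @export
build_barrier_map <- function(anchors, config, origin = 0) {
  n <- config$n_monomers
  left <- numeric(n); right <- numeric(n)
  skipped <- 0L
  for (i in seq_len(NROW(anchors))) {
    m0 <- (anchors$start[i] - origin) %/% config$bin_size
    m1 <- (anchors$end[i] - 1 - origin) %/% config$bin_size
    if (m1 < 0 || m0 > n - 1) { skipped <- skipped + 1L; next }
    m <- max(m0, 0):min(m1, n - 1) + 1
    pr <- anchors$p_right[i]
    left[m] <- pmax(left[m], pmin(pmax(config$c_bind * pr, 0), 1))
    right[m] <- pmax(right[m], pmin(pmax(config$c_bind * (1 - pr), 0), 1))
  }
  if (skipped > 0)
    warning("build_barrier_map: skipped ", skipped,
            " anchor(s) outside the simulated region")
  list(left = left, right = right)
}

zero_barriers <- function(config) {
  list(left = numeric(config$n_monomers), right = numeric(config$n_monomers))
}

#' Energy of an extruder configuration
#'
#' \code{E = -c_fold * sum(ln(span)) + c_cross * (number of crossing loop
#' pairs)}, where loops (l_i, r_i) and (l_j, r_j) cross when
#' \code{l_i < l_j < r_i < r_j}. Reference implementation used to verify the
#' simulator's incremental bookkeeping.
#'
#' @param left,right integer vectors of bound extruder leg positions.
#' @param c_fold,c_cross energy coefficients.
#' @return scalar energy.
#' @export
sim_energy <- function(left, right, c_fold = 1, c_cross = 10) {
  stopifnot(length(left) == length(right), all(left < right))
  e <- -c_fold * sum(log(right - left))
  n <- length(left)
  if (n > 1 && c_cross != 0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if ((left[i] < left[j] && left[j] < right[i] && right[i] < right[j]) ||
          (left[j] < left[i] && left[i] < right[j] && right[j] < right[i]))
        e <- e + c_cross
    }
  e
}

#' Annealed Monte Carlo temperature at a given sweep
#'
#' Linear interpolation from \code{t_init} at sweep 0 to \code{t_final} at
#' sweep \code{n_steps}.
#'
#' @param step sweep index in [0, n_steps].
#' @param config \code{\link{sim_config}}.
#' @return temperature.
#' @export
anneal_temperature <- function(step, config) {
  stopifnot(all(step >= 0), all(step <= config$n_steps))
  config$t_init + (config$t_final - config$t_init) * step / config$n_steps
}

#' Run the loop-extrusion simulation
#'
#' Executes \code{n_steps} Monte Carlo sweeps with the annealed temperature
#' schedule and records every bound extruder's legs each
#' \code{sample_every} sweeps after the burn-in. Fully reproducible from
#' \code{config$seed}.
#'
#' @param config \code{\link{sim_config}}.
#' @param barriers barrier map from \code{\link{build_barrier_map}}, or
#'   NULL for a barrier-free polymer.
#' @return list with \code{samples} (data.frame: sample, step, extruder,
#'   class, left, right), \code{n_samples}, \code{final} (left/right legs),
#'   \code{final_energy} and the \code{config}.
#' @export
run_extrusion <- function(config, barriers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(barriers)) barriers <- zero_barriers(config)
  stopifnot(length(barriers$left) == config$n_monomers,
            length(barriers$right) == config$n_monomers,
            all(barriers$left >= 0 & barriers$left <= 1),
            all(barriers$right >= 0 & barriers$right <= 1))
  set.seed(config$seed)
  res <- cpp_run_extrusion(config$n_monomers, config$n_steps,
                           config$sample_every, config$burn_in,
                           config$t_init, config$t_final,
                           config$n_slow, config$n_fast,
                           config$fast_multiplier,
                           config$c_fold, config$c_cross, config$unbind_prob,
                           barriers$left, barriers$right)
  m <- res$samples
  samples <- data.frame(sample = m[, 1], step = m[, 2], extruder = m[, 3],
                        class = ifelse(m[, 3] <= config$n_slow,
                                       "slow", "fast"),
                        left = m[, 4], right = m[, 5],
                        stringsAsFactors = FALSE)
  list(samples = samples, n_samples = res$n_samples,
       final = list(left = res$final_left, right = res$final_right),
       final_energy = res$final_energy, config = config)
}

#' Aggregate sampled extruder positions into a contact map
#'
#' Each sampled bound extruder adds weight 1 at (left, right) and its
#' transpose. Optionally a 1/distance polymer background is added, scaled so
#' its total equals \code{background_fraction} of the loop weight.
#'
#' @param run result of \code{\link{run_extrusion}}.
#' @param background_fraction background total as a fraction of loop weight
#'   (0 disables).
#' @return symmetric non-negative n_monomers x n_monomers matrix.
#' @export
contact_map <- function(run, background_fraction = 0) {
  if (run$n_samples < 1) stop("contact_map needs at least one sample")
  n <- run$config$n_monomers
  map <- matrix(0, n, n)
  s <- run$samples
  for (k in seq_len(nrow(s))) {
    i <- s$left[k] + 1; j <- s$right[k] + 1
    map[i, j] <- map[i, j] + 1
    map[j, i] <- map[j, i] + 1
  }
  if (background_fraction > 0) {
    idx <- abs(outer(seq_len(n), seq_len(n), "-"))
    bg <- ifelse(idx == 0, 0, 1 / idx)
    bg <- bg * (background_fraction * sum(map) / sum(bg))
    map <- map + bg
  }
  map
}

#' Export recurrent extruder positions as a loop set
#'
#' Monomer pairs (left, right) observed in at least \code{min_frequency}
#' distinct samples become loops with anchors of width \code{bin_size} at
#' \code{left * bin_size} and \code{right * bin_size}; the count is the
#' number of supporting samples.
#'
#' @param run result of \code{\link{run_extrusion}}.
#' @param min_frequency minimum number of supporting samples (>= 1).
#' @param chrom chromosome name for the exported records.
#' @return canonical loop data.frame, readable by the stripe caller.
#' @export
export_loops <- function(run, min_frequency = 1, chrom = "chr_sim") {
  stopifnot(min_frequency >= 1)
  s <- run$samples
  if (nrow(s) == 0) return(empty_loops())
  key <- unique(paste(s$sample, s$left, s$right))  # one vote per sample
  pair <- sub("^[0-9]+ ", "", key)
  freq <- table(pair)
  freq <- freq[freq >= min_frequency]
  if (length(freq) == 0) return(empty_loops())
  lr <- do.call(rbind, strsplit(names(freq), " ", fixed = TRUE))
  l <- as.numeric(lr[, 1]); r <- as.numeric(lr[, 2])
  bs <- run$config$bin_size
  as_loops(data.frame(chrom = chrom,
                      start1 = l * bs, end1 = (l + 1) * bs,
                      start2 = r * bs, end2 = (r + 1) * bs,
                      count = as.numeric(freq), stringsAsFactors = FALSE))
}

#' Loop-strength correlation between two contact maps
#'
#' Pearson correlation of the two maps restricted to the given loop pixels
#' (the positions where loops were detected).
#'
#' @param map_a,map_b contact matrices of equal shape.
#' @param loop_pixels data.frame or matrix with columns i, j (1-based).
#' @return Pearson r in [-1, 1]; NA with a warning when either restricted
#'   vector is constant.
#' @export
loop_strength_correlation <- function(map_a, map_b, loop_pixels) {
  stopifnot(all(dim(map_a) == dim(map_b)))
  loop_pixels <- as.matrix(loop_pixels)[, 1:2, drop = FALSE]
  if (nrow(loop_pixels) < 3) stop("need at least 3 loop pixels")
  a <- map_a[loop_pixels]; b <- map_b[loop_pixels]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant values over loop pixels; correlation undefined")
    return(NA_real_)
  }
  cor(a, b, method = "pearson")
}

# Separable truncated-Gaussian blur (kernel radius 3*sigma), with edge
# renormalisation so border rows keep unit kernel mass.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n <- nrow(m)
  r <- ceiling(3 * sigma)
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- ifelse(idx <= r, exp(-(idx^2) / (2 * sigma^2)), 0)
  K <- K / rowSums(K)
  K %*% m %*% t(K)
}

#' Smoothed Spearman correlation of two heatmaps
#'
#' Both maps are Gaussian-smoothed with the given sigma (in bins; 0
#' disables smoothing), then the Spearman rank correlation is computed over
#' the strict upper triangle.
#'
#' @param map_a,map_b square matrices of equal shape.
#' @param smoothing_sigma Gaussian sigma in bins.
#' @return Spearman rho.
#' @export
heatmap_correlation <- function(map_a, map_b, smoothing_sigma = 0) {
  if (!all(dim(map_a) == dim(map_b))) stop("heatmap shapes differ")
  a <- gaussian_blur(map_a, smoothing_sigma)
  b <- gaussian_blur(map_b, smoothing_sigma)
  ut <- upper.tri(a)
  cor(a[ut], b[ut], method = "spearman")
}
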