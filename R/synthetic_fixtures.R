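## Deterministic synthetic loop sets with planted stripes and background
## noise, plus a frozen hand-computed worked example. Fixtures emulate what
## a loop caller emits for a stripe-rich region: bin-aligned anchors of one
## resolution unit, a shared anchor with a chain of leaves at geometric-ish
## gaps, and background loops whose spans are resampled from the planted
## spans so that detection cannot key on span alone. The fixture chromosome
## is named "chr_sim" to prevent accidental mixing with real data.

#' Specification for a synthetic stripe fixture
#'
#' @param n_stripes number of planted stripes.
#' @param leaves_min,leaves_max per-stripe leaf-count range.
#' @param mean_gap mean gap between consecutive leaves in bp; gaps are
#'   \code{resolution * (1 + geometric)} with this mean, so always at least
#'   one resolution unit.
#' @param n_noise_loops number of background loops; NULL means twice the
#'   planted loop count.
#' @param genome_extent simulated chromosome length in bp (default 250 Mb,
#'   the scale of the largest human chromosome).
#' @param resolution anchor width and alignment grid in bp.
#' @param seed RNG seed (mandatory; generators are pure in spec + seed).
#' @return list of class "fixture_spec".
#' @export
fixture_spec <- function(n_stripes = 20, leaves_min = 4, leaves_max = 6,
                         mean_gap = 10000, n_noise_loops = NULL,
                         genome_extent = 250e6, resolution = 5000,
                         seed = 1) {
  stopifnot(n_stripes >= 0, leaves_min >= 1, leaves_max >= leaves_min,
            mean_gap >= resolution, resolution > 0, genome_extent > 0,
            length(seed) == 1, is.finite(seed))
  spec <- list(n_stripes = n_stripes, leaves_min = leaves_min,
               leaves_max = leaves_max, mean_gap = mean_gap,
               n_noise_loops = n_noise_loops,
               genome_extent = genome_extent, resolution = resolution,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate a loop set with planted stripes and noise
#'
#' For each planted stripe, one loop per leaf connects a common bin-aligned
#' anchor to the leaf at its offset (downstream for horizontal stripes,
#' upstream for vertical). Noise loops draw anchor positions uniformly and
#' spans by resampling the planted leaf offsets. Deterministic given the
#' spec's seed.
#'
#' @param spec \code{\link{fixture_spec}}.
#' @return list with \code{loops} (canonical loop data.frame) and
#'   \code{truth} (data.frame: planted_id, chrom, direction, anchor_start,
#'   anchor_end, n_leaves, max_offset).
#' @export
make_stripe_loopset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  res <- spec$resolution
  set.seed(spec$seed)
  max_extent_needed <- res * (1 + spec$leaves_max * 64)
  if (spec$genome_extent < 4 * max_extent_needed)
    stop("genome extent too small for the requested stripe offsets")
  n_bins <- spec$genome_extent %/% res

  loops <- list(); truth <- list()
  all_offsets <- c()
  for (s in seq_len(spec$n_stripes)) {
    k <- if (spec$leaves_max > spec$leaves_min)
      sample(spec$leaves_min:spec$leaves_max, 1) else spec$leaves_min
    direction <- sample(c("horizontal", "vertical"), 1)
    gaps <- res * (1 + rgeom(k, prob = res / spec$mean_gap))
    offsets <- cumsum(gaps)
    margin_bins <- offsets[k] %/% res + 2
    a_bin <- sample(margin_bins:(n_bins - margin_bins - 1), 1)
    a <- a_bin * res
    sgn <- if (direction == "horizontal") 1 else -1
    # anchors one bin wide, grid aligned
    lo <- pmin(a, a + sgn * offsets)
    hi <- pmax(a, a + sgn * offsets)
    loops[[length(loops) + 1]] <- data.frame(
      chrom = "chr_sim", start1 = lo, end1 = lo + res,
      start2 = hi, end2 = hi + res, count = 1, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      planted_id = s, chrom = "chr_sim", direction = direction,
      anchor_start = a, anchor_end = a + res, n_leaves = k,
      max_offset = offsets[k], stringsAsFactors = FALSE)
    all_offsets <- c(all_offsets, offsets)
  }
  planted <- if (length(loops)) do.call(rbind, loops) else empty_loops()

  n_noise <- if (is.null(spec$n_noise_loops)) 2L * nrow(planted)
             else spec$n_noise_loops
  if (n_noise > 0) {
    span_pool <- if (length(all_offsets)) all_offsets
                 else res * (1 + rgeom(200, prob = res / spec$mean_gap))
    spans <- sample(span_pool, n_noise, replace = TRUE)
    a_bins <- sample.int(n_bins - max(spans) %/% res - 2, n_noise,
                         replace = TRUE)
    a <- a_bins * res
    noise <- data.frame(chrom = "chr_sim", start1 = a, end1 = a + res,
                        start2 = a + spans, end2 = a + spans + res,
                        count = 1, stringsAsFactors = FALSE)
  } else noise <- empty_loops()

  loops <- as_loops(rbind(planted, noise))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(planted_id = integer(), chrom = character(),
               direction = character(), anchor_start = numeric(),
               anchor_end = numeric(), n_leaves = integer(),
               max_offset = numeric(), stringsAsFactors = FALSE)
  list(loops = loops, truth = truth)
}

#' Randomly jitter loop anchors
#'
#' Shifts each anchor (start and end together) by an independent uniform
#' integer in [-max_shift, +max_shift], clipped at 0; deterministic given
#' the seed.
#'
#' @param loops canonical loop data.frame.
#' @param max_shift maximum absolute shift in bp (>= 0).
#' @param seed RNG seed.
#' @return jittered canonical loop data.frame.
#' @export
jitter_loops <- function(loops, max_shift, seed = 1) {
  stopifnot(max_shift >= 0)
  loops <- as_loops(loops)
  set.seed(seed)
  n <- nrow(loops)
  s1 <- sample(-max_shift:max_shift, n, replace = TRUE)
  s2 <- sample(-max_shift:max_shift, n, replace = TRUE)
  s1 <- pmax(s1, -loops$start1); s2 <- pmax(s2, -loops$start2)
  loops$start1 <- loops$start1 + s1; loops$end1 <- loops$end1 + s1
  loops$start2 <- loops$start2 + s2; loops$end2 <- loops$end2 + s2
  as_loops(loops)
}

#' Score called stripes against a planted truth table
#'
#' A planted stripe is recovered when some called stripe of the same
#' direction has an anchor region within \code{tolerance} of the planted
#' anchor interval; a called stripe is a true positive when it matches some
#' planted stripe the same way.
#'
#' @param called stripe data.frame from \code{\link{call_stripes}}.
#' @param truth truth table from \code{\link{make_stripe_loopset}}.
#' @param tolerance matching tolerance in bp.
#' @return list with \code{recall}, \code{precision}, \code{n_called},
#'   \code{n_planted} (empty sides yield NA rates).
#' @export
score_stripe_calls <- function(called, truth, tolerance = 5000) {
  match_one <- function(ts, te, tdir) {
    any(called$direction == tdir &
          called$anchor_start - tolerance < te &
          ts < called$anchor_end + tolerance)
  }
  rec <- if (nrow(truth) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(truth)), function(i)
      match_one(truth$anchor_start[i], truth$anchor_end[i],
                truth$direction[i]), logical(1)))
  prec <- if (nrow(called) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(called)), function(i) {
      any(truth$direction == called$direction[i] &
            truth$anchor_start - tolerance < called$anchor_end[i] &
            called$anchor_start[i] < truth$anchor_end + tolerance)
    }, logical(1)))
  list(recall = rec, precision = prec,
       n_called = nrow(called), n_planted = nrow(truth))
}

#' Frozen three-loop worked example
#'
#' A fixed instance small enough to verify by hand: three loops over three
#' anchor clusters, yielding an interaction graph with 3 vertices and 3
#' unit-weight edges. The expected vertex table and edge list are frozen
#' here; per-leaf metrics for it are checked in the test suite against an
#' independent brute-force evaluation.
#'
#' @return list with \code{loops}, \code{expected_vertices},
#'   \code{expected_edges} and \code{resolution}.
#' @export
toy_worked_example <- function() {
  loops <- as_loops(data.frame(
    chrom = "chr_sim",
    start1 = c(10000, 12000, 40000), end1 = c(15000, 17000, 45000),
    start2 = c(40000, 100000, 100000), end2 = c(45000, 105000, 105000),
    count = 1, stringsAsFactors = FALSE))
  expected_vertices <- data.frame(
    id = 1:3, chrom = "chr_sim",
    span_start = c(10000, 40000, 100000),
    span_end = c(20000, 45000, 105000),
    position = c(15000, 42500, 102500),
    n_members = c(2L, 2L, 2L), stringsAsFactors = FALSE)
  expected_edges <- data.frame(u = c(1L, 1L, 2L), v = c(2L, 3L, 3L),
                               weight = c(1L, 1L, 1L))
  list(loops = loops, expected_vertices = expected_vertices,
       expected_edges = expected_edges, resolution = 5000)
}
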