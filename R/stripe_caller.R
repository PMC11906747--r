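## The graph-based stripe caller. A vertex with downstream (upstream)
## neighbours anchors a candidate horizontal (vertical) stripe whose leaves
## are all neighbours on that side, ordered by ascending distance. Per-leaf
## metrics: stripe length d_i, relative gap g_i = -ln((d_i - d_{i-1})/d_i),
## its dataset-wide quantile q_gap_i, the running quadratic mean
## stripe_score_i, and the cross score (ratio to the orthogonal-direction
## score at the same leaf). Stripes are trimmed where the gap collapses,
## merged when same-direction domains overlap with similar lengths, then
## filtered on leaf count, length, stripe score and mean cross score.

#' Configuration for the stripe caller
#'
#' @param resolution anchor binning resolution in bp.
#' @param gap_threshold a stripe ends at leaf i when g_{i+1} drops below
#'   this value (relative gaps use the natural logarithm).
#' @param min_leaves minimum number of leaves in a reported stripe.
#' @param min_length minimum stripe length in bp.
#' @param min_stripe_score lower threshold on the terminal stripe score.
#' @param min_mean_cross_score lower threshold on the mean cross score over
#'   the trimmed leaves.
#' @param merge_max_length_diff same-direction overlapping stripes whose
#'   lengths differ by no more than this are merged.
#' @param merge_max_anchor_gap stripes are "adjacent" (hence mergeable)
#'   only when their anchor regions are at most this far apart, matching
#'   the stripe-overlap convention.
#' @param min_length_clamp lengths and length differences are clamped below
#'   at this value so the gap logarithm is always defined.
#' @return list of class "stripe_call_config".
#' @export
stripe_call_config <- function(resolution = 5000,
                               gap_threshold = 0.05,
                               min_leaves = 2,
                               min_length = 20000,
                               min_stripe_score = 0.45,
                               min_mean_cross_score = 0.9,
                               merge_max_length_diff = 200000,
                               merge_max_anchor_gap = 10000,
                               min_length_clamp = 1000) {
  cfg <- list(resolution = resolution, gap_threshold = gap_threshold,
              min_leaves = min_leaves, min_length = min_length,
              min_stripe_score = min_stripe_score,
              min_mean_cross_score = min_mean_cross_score,
              merge_max_length_diff = merge_max_length_diff,
              merge_max_anchor_gap = merge_max_anchor_gap,
              min_length_clamp = min_length_clamp)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1))))
    stop("all stripe_call_config values must be non-negative scalars")
  class(cfg) <- "stripe_call_config"
  cfg
}

## ---- per-leaf metric primitives ---------------------------------------

# Clamp distances and force strict ascent: equidistant leaves (possible
# only through clamping) are pushed up by one clamp unit.
clamp_ascending <- function(d, clamp) {
  d <- pmax(d, clamp)
  if (length(d) > 1)
    for (i in 2:length(d)) if (d[i] <= d[i - 1]) d[i] <- d[i - 1] + clamp
  d
}

#' Relative gaps of an ascending stripe-length sequence
#'
#' \code{g_i = -ln((d_i - d_{i-1}) / d_i)} with \code{d_0 = 0}; both the
#' lengths and the differences are clamped below at \code{clamp} so the
#' logarithm never diverges. \code{g_1} is identically 0.
#'
#' @param d ascending numeric vector of stripe lengths (bp).
#' @param clamp minimum length / length difference in bp.
#' @return non-negative numeric vector of gaps, same length as \code{d}.
#' @export
relative_gaps <- function(d, clamp = 1000) {
  if (length(d) == 0) return(numeric())
  if (is.unsorted(d, strictly = TRUE)) stop("d must be strictly ascending")
  d <- pmax(d, clamp)
  diffs <- pmax(d - c(0, d[-length(d)]), clamp)
  -log(diffs / d)
}

#' Inclusive empirical-CDF quantiles of relative gaps
#'
#' \code{q_gap = (# pooled gaps <= g) / pool size}; the pool spans every
#' candidate stripe of the dataset, both directions, all chromosomes, so the
#' values lie in (0, 1] (each gap is in its own pool).
#'
#' @param g numeric vector of gap values to rank.
#' @param pool numeric vector of all gap values in the dataset.
#' @return numeric vector of quantiles in (0, 1].
#' @export
gap_quantiles <- function(g, pool) {
  if (length(pool) == 0) stop("empty gap pool")
  findInterval(g, sort(pool)) / length(pool)
}

#' Running quadratic-mean stripe scores
#'
#' \code{stripe_score_i = sqrt(mean(q_gap_j^2, j = 1..i))}: the average
#' quality of the stripe up to leaf i.
#'
#' @param q numeric vector of gap quantiles in (0, 1].
#' @return numeric vector of scores in [0, 1].
#' @export
stripe_scores <- function(q) {
  if (length(q) == 0) return(numeric())
  sqrt(cumsum(q^2) / seq_along(q))
}

#' Index of the leaf terminating a stripe
#'
#' The stripe ends at leaf i if \code{g_{i+1}} drops below the threshold, or
#' with the last leaf otherwise.
#'
#' @param g numeric vector of relative gaps.
#' @param threshold termination threshold on the gap.
#' @return integer index of the terminating leaf.
#' @export
trim_index <- function(g, threshold = 0.05) {
  k <- length(g)
  if (k == 0) return(0L)
  below <- which(g[-1] < threshold)
  if (length(below)) below[1] else k
}

## ---- candidate enumeration --------------------------------------------

#' Enumerate candidate stripes from an interaction graph
#'
#' One horizontal candidate per vertex with at least one downstream
#' neighbour and one vertical candidate per vertex with at least one
#' upstream neighbour; leaves are all neighbours on that side, ordered by
#' ascending distance, with distances clamped per the configuration.
#'
#' @param graph interaction graph.
#' @param config \code{\link{stripe_call_config}}.
#' @return list of candidates; each has direction, anchor_id, chrom,
#'   anchor_span, anchor_pos, leaf_ids, d (clamped ascending lengths).
#' @export
enumerate_candidates <- function(graph, config = stripe_call_config()) {
  v <- graph$vertices
  out <- list()
  for (i in seq_len(nrow(v))) {
    for (dir in c("horizontal", "vertical")) {
      side <- if (dir == "horizontal") "downstream" else "upstream"
      nb <- graph_neighbours(graph, v$id[i], side)
      if (nrow(nb) == 0) next
      d <- clamp_ascending(abs(nb$position - v$position[i]),
                           config$min_length_clamp)
      out[[length(out) + 1]] <- list(
        direction = dir, anchor_id = v$id[i], chrom = v$chrom[i],
        anchor_span = c(v$span_start[i], v$span_end[i]),
        anchor_pos = v$position[i], leaf_ids = nb$id, d = d)
    }
  }
  out
}

## ---- assembly helpers -------------------------------------------------

vertex_row <- function(graph, id) graph$vertices[match(id, graph$vertices$id), ]

stripe_domain <- function(graph, direction, anchor_span, leaf_ids) {
  lv <- graph$vertices[match(leaf_ids, graph$vertices$id), , drop = FALSE]
  if (direction == "horizontal")
    c(anchor_span[1], max(lv$span_end))
  else
    c(min(lv$span_start), anchor_span[2])
}

# Recompute d/g/q/score/cross/trim for a stripe given its leaf set and the
# per-leaf cross-score denominators; returns the internal stripe record.
assemble_stripe <- function(graph, direction, anchor_id, leaf_ids, den_map,
                            sorted_pool, pool_n, config) {
  av <- vertex_row(graph, anchor_id)
  lv <- graph$vertices[match(leaf_ids, graph$vertices$id), , drop = FALSE]
  o <- order(abs(lv$position - av$position), lv$span_start, lv$id)
  leaf_ids <- leaf_ids[o]
  d <- clamp_ascending(abs(lv$position[o] - av$position),
                       config$min_length_clamp)
  g <- relative_gaps(d, config$min_length_clamp)
  q <- findInterval(g, sorted_pool) / pool_n
  score <- stripe_scores(q)
  den <- pmax(den_map[as.character(leaf_ids)], 1e-9)
  cross <- score / den
  k <- trim_index(g, config$gap_threshold)
  keep <- seq_len(k)
  list(direction = direction, chrom = av$chrom, anchor_id = anchor_id,
       anchor_span = c(av$span_start, av$span_end), anchor_pos = av$position,
       leaf_ids = leaf_ids[keep], d = d[keep], g = g[keep], q = q[keep],
       score = score[keep], cross = cross[keep],
       den_map = den_map[as.character(leaf_ids[keep])],
       length = d[k],
       domain = stripe_domain(graph, direction,
                              c(av$span_start, av$span_end), leaf_ids[keep]))
}

## ---- merging ----------------------------------------------------------

#' Merge adjacent same-direction stripes
#'
#' Two adjacent stripes with the same direction are merged when their
#' domains overlap by at least 1 bp, their anchor regions are no more than
#' \code{merge_max_anchor_gap} apart, and their lengths differ by no more
#' than \code{merge_max_length_diff}: the surviving anchor is the one
#' nearer the diagonal extreme (smaller coordinate for horizontal stripes,
#' larger for vertical), leaves are pooled, and the length metrics are
#' recomputed from the surviving anchor; merging repeats to a fixed point.
#'
#' @param stripes list of internal stripe records.
#' @param graph interaction graph the stripes were called on.
#' @param pool dataset-wide gap pool.
#' @param config \code{\link{stripe_call_config}}.
#' @return list of internal stripe records after merging.
#' @export
merge_stripes <- function(stripes, graph, pool, config = stripe_call_config()) {
  sorted_pool <- sort(pool); pool_n <- length(pool)
  repeat {
    merged <- FALSE
    n <- length(stripes)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- stripes[[i]]; b <- stripes[[j]]
        if (a$direction != b$direction || a$chrom != b$chrom) next
        if (a$domain[1] >= b$domain[2] || b$domain[1] >= a$domain[2]) next
        anchor_gap <- max(0, max(a$anchor_span[1], b$anchor_span[1]) -
                               min(a$anchor_span[2], b$anchor_span[2]))
        if (anchor_gap > config$merge_max_anchor_gap) next
        if (abs(a$length - b$length) > config$merge_max_length_diff) next
        keep_a <- if (a$direction == "horizontal")
          a$anchor_pos <= b$anchor_pos else a$anchor_pos >= b$anchor_pos
        surv <- if (keep_a) a else b
        absorbed <- if (keep_a) b else a
        leaf_ids <- union(surv$leaf_ids, absorbed$leaf_ids)
        leaf_ids <- setdiff(leaf_ids, surv$anchor_id)
        den_map <- c(surv$den_map,
                     absorbed$den_map[setdiff(names(absorbed$den_map),
                                              names(surv$den_map))])
        stripes[[i]] <- assemble_stripe(graph, surv$direction, surv$anchor_id,
                                        leaf_ids, den_map, sorted_pool,
                                        pool_n, config)
        stripes[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  stripes
}

## ---- the full pipeline ------------------------------------------------

#' Call architectural stripes from a chromatin loop set
#'
#' Runs the full pipeline: bin anchors, merge them into graph vertices, add
#' collapsed weighted edges, enumerate candidate stripes on both sides of
#' every vertex, compute per-leaf metrics against the dataset-wide gap pool,
#' trim each candidate where its relative gap collapses below the
#' termination threshold, merge adjacent same-direction stripes, and filter
#' on leaf count, length, terminal stripe score and mean cross score.
#'
#' @param loops canonical loop data.frame (see \code{\link{read_bedpe}}).
#' @param config \code{\link{stripe_call_config}}.
#' @param details also return per-leaf candidate metrics, the graph and the
#'   gap pool.
#' @param verbose log candidate counts at each pipeline stage.
#' @return stripe data.frame (see \code{\link{write_stripes}} for columns);
#'   with \code{details = TRUE}, a list with elements stripes, candidates
#'   (per-leaf metric table), graph and pool.
#' @export
call_stripes <- function(loops, config = stripe_call_config(),
                         details = FALSE, verbose = FALSE) {
  loops <- as_loops(loops)
  if (nrow(loops) == 0) {
    warning("empty loop set: no stripes called")
    out <- empty_stripes()
    return(if (details) list(stripes = out, candidates = NULL,
                             graph = NULL, pool = numeric()) else out)
  }
  graph <- build_interaction_graph(loops, config$resolution)
  cands <- enumerate_candidates(graph, config)
  say <- function(...) if (verbose) message(...)
  say("call_stripes: ", nrow(graph$vertices), " vertices, ",
      nrow(graph$edges), " edges, ", length(cands), " candidates")
  if (length(cands) == 0) {
    out <- empty_stripes()
    return(if (details) list(stripes = out, candidates = NULL,
                             graph = graph, pool = numeric()) else out)
  }

  for (i in seq_along(cands))
    cands[[i]]$g <- relative_gaps(cands[[i]]$d, config$min_length_clamp)
  pool <- unlist(lapply(cands, `[[`, "g"), use.names = FALSE)
  sorted_pool <- sort(pool); pool_n <- length(pool)
  for (i in seq_along(cands)) {
    cands[[i]]$q <- findInterval(cands[[i]]$g, sorted_pool) / pool_n
    cands[[i]]$score <- stripe_scores(cands[[i]]$q)
  }

  # Cross scores: the denominator for leaf v_i of the candidate anchored at
  # v_0 is the stripe score, in the orthogonal-direction candidate anchored
  # at v_i, at the slot occupied by v_0 (which exists: the edge does).
  index <- setNames(seq_along(cands),
                    vapply(cands, function(cc)
                      paste(cc$direction, cc$anchor_id), ""))
  for (i in seq_along(cands)) {
    cc <- cands[[i]]
    orth_dir <- if (cc$direction == "horizontal") "vertical" else "horizontal"
    den <- vapply(cc$leaf_ids, function(leaf) {
      oi <- index[[paste(orth_dir, leaf)]]
      if (is.null(oi)) stop("internal error: missing orthogonal candidate")
      slot <- match(cc$anchor_id, cands[[oi]]$leaf_ids)
      if (is.na(slot)) stop("internal error: anchor absent from orthogonal candidate")
      cands[[oi]]$score[slot]
    }, numeric(1))
    cands[[i]]$den_map <- setNames(den, as.character(cc$leaf_ids))
    cands[[i]]$cross <- cc$score / pmax(den, 1e-9)
  }

  # Trim each candidate, then materialise internal stripe records.
  stripes <- lapply(cands, function(cc) {
    k <- trim_index(cc$g, config$gap_threshold)
    keep <- seq_len(k)
    list(direction = cc$direction, chrom = cc$chrom,
         anchor_id = cc$anchor_id, anchor_span = cc$anchor_span,
         anchor_pos = cc$anchor_pos, leaf_ids = cc$leaf_ids[keep],
         d = cc$d[keep], g = cc$g[keep], q = cc$q[keep],
         score = cc$score[keep], cross = cc$cross[keep],
         den_map = cc$den_map[keep], length = cc$d[k],
         domain = stripe_domain(graph, cc$direction, cc$anchor_span,
                                cc$leaf_ids[keep]))
  })
  say("call_stripes: ", length(stripes), " trimmed candidates")

  stripes <- merge_stripes(stripes, graph, pool, config)
  say("call_stripes: ", length(stripes), " after merging")

  keep <- vapply(stripes, function(s) {
    k <- length(s$leaf_ids)
    k >= config$min_leaves && s$length >= config$min_length &&
      s$score[k] >= config$min_stripe_score &&
      mean(s$cross) >= config$min_mean_cross_score
  }, logical(1))
  stripes <- stripes[keep]
  say("call_stripes: ", length(stripes), " final stripes")

  records <- if (length(stripes) == 0) empty_stripes() else do.call(rbind,
    lapply(stripes, function(s) {
      k <- length(s$leaf_ids)
      data.frame(chrom = s$chrom, anchor_start = s$anchor_span[1],
                 anchor_end = s$anchor_span[2], domain_start = s$domain[1],
                 domain_end = s$domain[2], direction = s$direction,
                 n_leaves = k, length_bp = s$length,
                 stripe_score = s$score[k],
                 mean_cross_score = mean(s$cross),
                 stringsAsFactors = FALSE)
    }))
  records <- sort_stripes(records)

  if (!details) return(records)
  cand_tab <- do.call(rbind, lapply(seq_along(cands), function(i) {
    cc <- cands[[i]]
    data.frame(candidate = i, direction = cc$direction,
               anchor_id = cc$anchor_id, slot = seq_along(cc$leaf_ids),
               leaf_id = cc$leaf_ids, d = cc$d, g = cc$g, q = cc$q,
               stripe_score = cc$score, cross_score = cc$cross,
               trimmed_k = trim_index(cc$g, config$gap_threshold),
               stringsAsFactors = FALSE)
  }))
  list(stripes = records, candidates = cand_tab, graph = graph, pool = pool)
}
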