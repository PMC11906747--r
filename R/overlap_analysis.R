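## Overlap, colocalization and annotation statistics on loops, stripes,
## striping domains and peaks. Loop-vs-loop matching allows a configurable
## tolerance: the query loop's anchors are extended on both sides before
## requiring a >= 1 bp overlap at both anchors.

#' Do two loops overlap (with tolerance)?
#'
#' Both anchors of the first (query) loop are extended by \code{tolerance}
#' upstream and downstream (clipped at 0); the loops overlap when the
#' extended anchor1 shares >= 1 bp with the other loop's anchor1 AND
#' likewise for anchor2 (anchors in canonical order). Vectorised over rows.
#'
#' @param a query loop data.frame (extended).
#' @param b subject loop data.frame.
#' @param tolerance extension in bp (>= 0); the stripe-analysis convention
#'   is 15 kb.
#' @return logical vector.
#' @export
loops_overlap <- function(a, b, tolerance = 0) {
  stopifnot(tolerance >= 0)
  a <- as_loops(a); b <- as_loops(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  a <- a[ai, , drop = FALSE]; b <- b[bi, , drop = FALSE]
  a$chrom == b$chrom &
    pmax(0, a$start1 - tolerance) < b$end1 & b$start1 < a$end1 + tolerance &
    pmax(0, a$start2 - tolerance) < b$end2 & b$start2 < a$end2 + tolerance
}

# Row indices of `query` loops with at least one tolerance-overlap in
# `subject`, via per-chromosome interval matching on both anchors.
matched_query_rows <- function(query, subject, tolerance) {
  hits <- logical(nrow(query))
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch); si <- which(subject$chrom == ch)
    q1 <- IRanges::IRanges(pmax(0, query$start1[qi] - tolerance) + 1,
                           query$end1[qi] + tolerance)
    q2 <- IRanges::IRanges(pmax(0, query$start2[qi] - tolerance) + 1,
                           query$end2[qi] + tolerance)
    s1 <- IRanges::IRanges(subject$start1[si] + 1, subject$end1[si])
    s2 <- IRanges::IRanges(subject$start2[si] + 1, subject$end2[si])
    h1 <- IRanges::findOverlaps(q1, s1, minoverlap = 1L)
    h2 <- IRanges::findOverlaps(q2, s2, minoverlap = 1L)
    k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    both <- unique(as.integer(sub(" .*", "", intersect(k1, k2))))
    hits[qi[both]] <- TRUE
  }
  which(hits)
}

#' Pairwise loop-set overlap matrix
#'
#' Entry (i, j) is the percentage of loops in row set i with at least one
#' tolerance-overlap in column set j; each element is counted once
#' regardless of match multiplicity, so the matrix is generally asymmetric.
#' Empty row sets yield NA.
#'
#' @param sets named list of loop data.frames.
#' @param tolerance anchor extension in bp.
#' @return list with matrices \code{percentages} and \code{counts}, and
#'   vector \code{sizes}.
#' @export
overlap_matrix <- function(sets, tolerance = 0) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  sets <- lapply(sets, as_loops)
  nm <- names(sets)
  counts <- matrix(0L, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    counts[i, j] <- length(matched_query_rows(sets[[i]], sets[[j]], tolerance))
  sizes <- vapply(sets, nrow, integer(1))
  pct <- 100 * counts / ifelse(sizes == 0, NA_real_, sizes)
  list(percentages = pct, counts = counts, sizes = sizes)
}

#' Do two stripes overlap?
#'
#' Stripes overlap when they share the chromosome and orientation and their
#' anchor regions (where the stripe meets the diagonal) are no more than
#' \code{max_anchor_gap} apart, measured edge to edge (0 when overlapping).
#'
#' @param s1,s2 stripe data.frames (vectorised over rows).
#' @param max_anchor_gap maximum anchor gap in bp (default 10 kb).
#' @return logical vector.
#' @export
stripes_overlap <- function(s1, s2, max_anchor_gap = 10000) {
  n <- max(nrow(s1), nrow(s2))
  i1 <- rep_len(seq_len(nrow(s1)), n); i2 <- rep_len(seq_len(nrow(s2)), n)
  s1 <- s1[i1, , drop = FALSE]; s2 <- s2[i2, , drop = FALSE]
  same <- s1$chrom == s2$chrom & s1$direction == s2$direction
  gap <- pmax(0, pmax(s1$anchor_start, s2$anchor_start) -
                   pmin(s1$anchor_end, s2$anchor_end))
  same & gap <= max_anchor_gap
}

#' Do two striping domains overlap?
#'
#' Domains overlap when, after expanding both by \code{pad} on each side
#' (clipped at 0), they share at least 1 bp.
#'
#' @param d1,d2 interval data.frames (chrom, start, end), vectorised.
#' @param pad expansion in bp on each side.
#' @return logical vector.
#' @export
domains_overlap <- function(d1, d2, pad = 10000) {
  stopifnot(pad >= 0)
  n <- max(nrow(d1), nrow(d2))
  i1 <- rep_len(seq_len(nrow(d1)), n); i2 <- rep_len(seq_len(nrow(d2)), n)
  d1 <- d1[i1, , drop = FALSE]; d2 <- d2[i2, , drop = FALSE]
  d1$chrom == d2$chrom &
    pmax(0, d1$start - pad) < d2$end + pad &
    pmax(0, d2$start - pad) < d1$end + pad
}

#' Fraction of stripes colocalized within a larger stripe's domain
#'
#' The proportion of stripes whose domain is fully contained in the domain
#' of a different stripe (any direction) with strictly greater domain
#' length.
#'
#' @param stripes stripe data.frame.
#' @return fraction in [0, 1]; NA for an empty input.
#' @export
colocalization_fraction <- function(stripes) {
  n <- nrow(stripes)
  if (n == 0) return(NA_real_)
  len <- stripes$domain_end - stripes$domain_start
  inside <- vapply(seq_len(n), function(i) {
    any(stripes$chrom == stripes$chrom[i] &
          stripes$domain_start <= stripes$domain_start[i] &
          stripes$domain_end >= stripes$domain_end[i] &
          len > len[i])
  }, logical(1))
  mean(inside)
}

#' Fraction of peaks inside loop anchors (3D peaks)
#'
#' @param peaks interval data.frame of peaks.
#' @param loops canonical loop data.frame.
#' @return fraction of peaks overlapping (>= 1 bp) any loop anchor; NA for
#'   an empty peak set.
#' @export
peaks_in_anchors <- function(peaks, loops) {
  if (nrow(peaks) == 0) return(NA_real_)
  loops <- as_loops(loops)
  if (nrow(loops) == 0) return(0)
  anchors <- rbind(anchor1(loops), anchor2(loops))
  hit <- logical(nrow(peaks))
  for (ch in intersect(unique(peaks$chrom), unique(anchors$chrom))) {
    pi <- which(peaks$chrom == ch); ai <- which(anchors$chrom == ch)
    p <- IRanges::IRanges(peaks$start[pi] + 1, peaks$end[pi])
    a <- IRanges::IRanges(anchors$start[ai] + 1, anchors$end[ai])
    hit[pi] <- IRanges::countOverlaps(p, a, minoverlap = 1L) > 0
  }
  mean(hit)
}

# >= 1 bp overlap of each interval row against any interval in `features`.
has_feature <- function(intervals, features) {
  hit <- logical(nrow(intervals))
  if (nrow(features) == 0) return(hit)
  for (ch in intersect(unique(intervals$chrom), unique(features$chrom))) {
    ii <- which(intervals$chrom == ch); fi <- which(features$chrom == ch)
    q <- IRanges::IRanges(intervals$start[ii] + 1, intervals$end[ii])
    s <- IRanges::IRanges(features$start[fi] + 1, features$end[fi])
    hit[ii] <- IRanges::countOverlaps(q, s, minoverlap = 1L) > 0
  }
  hit
}

#' Classify loops as enhancer-promoter or promoter-promoter
#'
#' Each anchor is labelled by >= 1 bp intersection with the enhancer and
#' promoter sets. A loop is "PP" when both anchors carry a promoter, else
#' "EP" when one anchor carries an enhancer and the other a promoter, else
#' "other" (PP takes precedence when anchors carry both labels).
#'
#' @param loops canonical loop data.frame.
#' @param enhancers,promoters interval data.frames.
#' @return character vector in \{"PP", "EP", "other"\}, one per loop.
#' @export
classify_loop_ep_pp <- function(loops, enhancers, promoters) {
  loops <- as_loops(loops)
  if (nrow(loops) == 0) return(character())
  a1 <- anchor1(loops); a2 <- anchor2(loops)
  e1 <- has_feature(a1, enhancers); e2 <- has_feature(a2, enhancers)
  p1 <- has_feature(a1, promoters); p2 <- has_feature(a2, promoters)
  ifelse(p1 & p2, "PP",
         ifelse((e1 & p2) | (e2 & p1), "EP", "other"))
}
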