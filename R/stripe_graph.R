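## Graph representation of a chromatin loop set: binned anchors are merged
## into vertices wherever they overlap (>= 1 shared bp, half-open, so
## touching bins stay distinct), and loops become weighted edges between
## vertex pairs. All structure is per-chromosome; loops are intra-chromosomal
## by construction.

#' Cluster binned loop anchors into graph vertices
#'
#' Anchors from both loop ends are snapped to the resolution grid and merged
#' transitively wherever the binned intervals share at least 1 bp. Each
#' cluster becomes one vertex whose position is the (floor) centre of the
#' cluster span.
#'
#' @param loops canonical loop data.frame.
#' @param resolution binning resolution in bp (default 5000).
#' @return data.frame with columns id, chrom, span_start, span_end,
#'   position, n_members, ordered by (chrom, span_start).
#' @export
cluster_anchors <- function(loops, resolution = 5000) {
  loops <- as_loops(loops)
  anchors <- rbind(bin_interval(anchor1(loops), resolution),
                   bin_interval(anchor2(loops), resolution))
  if (nrow(anchors) == 0)
    return(data.frame(id = integer(), chrom = character(),
                      span_start = numeric(), span_end = numeric(),
                      position = numeric(), n_members = integer(),
                      stringsAsFactors = FALSE))
  chroms <- sort(unique(anchors$chrom), method = "radix")
  pieces <- lapply(chroms, function(ch) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = a$start + 1, end = a$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # merge only true overlaps
    nm <- IRanges::countOverlaps(red, ir, minoverlap = 1L)
    data.frame(chrom = ch, span_start = IRanges::start(red) - 1,
               span_end = IRanges::end(red), n_members = as.integer(nm),
               stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, pieces)
  v$position <- (v$span_start + v$span_end) %/% 2
  v <- v[order(v$chrom, v$span_start, method = "radix"), , drop = FALSE]
  v$id <- seq_len(nrow(v))
  rownames(v) <- NULL
  v[, c("id", "chrom", "span_start", "span_end", "position", "n_members")]
}

# Map binned anchor intervals onto vertex ids (each binned anchor lies
# inside exactly one cluster span on its chromosome).
map_anchors_to_vertices <- function(anchors, vertices) {
  ids <- integer(nrow(anchors))
  for (ch in unique(anchors$chrom)) {
    qi <- which(anchors$chrom == ch)
    sv <- vertices[vertices$chrom == ch, , drop = FALSE]
    if (nrow(sv) == 0) stop("internal error: anchor on unclustered chromosome")
    q <- IRanges::IRanges(anchors$start[qi] + 1, anchors$end[qi])
    s <- IRanges::IRanges(sv$span_start + 1, sv$span_end)
    hit <- IRanges::findOverlaps(q, s, minoverlap = 1L, select = "first")
    if (anyNA(hit)) stop("internal error: anchor with no vertex assignment")
    ids[qi] <- sv$id[hit]
  }
  ids
}

#' Build the chromatin interaction graph
#'
#' Vertices are merged anchor clusters (\code{\link{cluster_anchors}});
#' loops whose two anchors map to different vertices become edges, with
#' parallel loops collapsed into a single edge whose weight is the number of
#' collapsed loop records (the result is not a multigraph). Loops with both
#' anchors inside one cluster are dropped and counted.
#'
#' @param loops canonical loop data.frame.
#' @param resolution binning resolution in bp (default 5000).
#' @return list with elements \code{vertices}, \code{edges} (data.frame u,
#'   v, weight with position(u) < position(v)), \code{n_self_dropped}, and
#'   \code{resolution}.
#' @export
build_interaction_graph <- function(loops, resolution = 5000) {
  loops <- as_loops(loops)
  vertices <- cluster_anchors(loops, resolution)
  if (nrow(loops) == 0)
    return(list(vertices = vertices,
                edges = data.frame(u = integer(), v = integer(),
                                   weight = integer()),
                n_self_dropped = 0L, resolution = resolution))
  u <- map_anchors_to_vertices(bin_interval(anchor1(loops), resolution), vertices)
  v <- map_anchors_to_vertices(bin_interval(anchor2(loops), resolution), vertices)
  self <- u == v
  uu <- pmin(u[!self], v[!self]); vv <- pmax(u[!self], v[!self])
  if (length(uu)) {
    key <- paste(uu, vv)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    edges <- data.frame(u = as.integer(parts[, 1]), v = as.integer(parts[, 2]),
                        weight = as.integer(tab))
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = integer(), v = integer(), weight = integer())
  }
  list(vertices = vertices, edges = edges,
       n_self_dropped = sum(self), resolution = resolution)
}

#' Positional neighbours of a vertex
#'
#' Adjacent vertices strictly downstream (greater position) or upstream
#' (smaller position) of the given vertex, ordered by ascending positional
#' distance; ties broken by span start, then id.
#'
#' @param graph interaction graph from \code{\link{build_interaction_graph}}.
#' @param vertex_id vertex id.
#' @param side "downstream" or "upstream".
#' @return data.frame of neighbour vertex rows (possibly empty).
#' @export
graph_neighbours <- function(graph, vertex_id,
                             side = c("downstream", "upstream")) {
  side <- match.arg(side)
  v <- graph$vertices
  if (!vertex_id %in% v$id) stop("unknown vertex id")
  e <- graph$edges
  adj <- c(e$v[e$u == vertex_id], e$u[e$v == vertex_id])
  nb <- v[match(adj, v$id), , drop = FALSE]
  p0 <- v$position[v$id == vertex_id]
  nb <- if (side == "downstream") nb[nb$position > p0, , drop = FALSE]
        else nb[nb$position < p0, , drop = FALSE]
  o <- order(abs(nb$position - p0), nb$span_start, nb$id)
  nb <- nb[o, , drop = FALSE]
  rownames(nb) <- NULL
  nb
}
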