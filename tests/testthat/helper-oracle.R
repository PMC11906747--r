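# Independent brute-force oracles, deliberately sharing no code with the
# package internals: plain floor/ceiling binning, union-find anchor
# clustering, all-pairs overlap scans, and direct evaluation of the per-leaf
# stripe metrics from their defining formulas.

# O(n^2) union-find clustering of binned anchors + direct metric formulas.
# Returns a per-leaf table keyed by (direction, anchor position, leaf
# position) comparable with call_stripes(details = TRUE)$candidates.
oracle_stripe_metrics <- function(loops, resolution = 5000, clamp = 1000) {
  bin_lo <- function(x) floor(x / resolution) * resolution
  bin_hi <- function(x) ceiling(x / resolution) * resolution
  anc <- rbind(
    data.frame(chrom = loops$chrom, s = bin_lo(loops$start1),
               e = bin_hi(loops$end1)),
    data.frame(chrom = loops$chrom, s = bin_lo(loops$start2),
               e = bin_hi(loops$end2)))
  n <- nrow(anc)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (anc$chrom[i] == anc$chrom[j] &&
        anc$s[i] < anc$e[j] && anc$s[j] < anc$e[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- unique(root)
  span_s <- vapply(clusters, function(r) min(anc$s[root == r]), numeric(1))
  span_e <- vapply(clusters, function(r) max(anc$e[root == r]), numeric(1))
  chrom <- vapply(clusters, function(r) anc$chrom[root == r][1], "")
  pos <- (span_s + span_e) %/% 2

  nl <- nrow(loops)
  v1 <- match(root[seq_len(nl)], clusters)
  v2 <- match(root[nl + seq_len(nl)], clusters)
  edges <- unique(data.frame(a = pmin(v1, v2), b = pmax(v1, v2)))
  edges <- edges[edges$a != edges$b, , drop = FALSE]

  # candidates: every vertex with neighbours on a side
  cands <- list()
  for (vi in seq_along(clusters)) {
    nb <- unique(c(edges$b[edges$a == vi], edges$a[edges$b == vi]))
    for (dir in c("horizontal", "vertical")) {
      leaves <- if (dir == "horizontal") nb[pos[nb] > pos[vi]]
                else nb[pos[nb] < pos[vi]]
      if (length(leaves) == 0) next
      leaves <- leaves[order(abs(pos[leaves] - pos[vi]))]
      d <- pmax(abs(pos[leaves] - pos[vi]), clamp)
      if (length(d) > 1)
        for (k in 2:length(d)) if (d[k] <= d[k - 1]) d[k] <- d[k - 1] + clamp
      g <- sapply(seq_along(d), function(k)
        -log(max(d[k] - if (k == 1) 0 else d[k - 1], clamp) / d[k]))
      cands[[length(cands) + 1]] <- list(dir = dir, anchor = vi,
                                         leaves = leaves, d = d, g = g)
    }
  }
  pool <- unlist(lapply(cands, `[[`, "g"))
  for (ci in seq_along(cands)) {
    g <- cands[[ci]]$g
    q <- sapply(g, function(x) sum(pool <= x) / length(pool))
    cands[[ci]]$q <- q
    cands[[ci]]$score <- sapply(seq_along(q), function(k)
      sqrt(mean(q[1:k]^2)))
  }
  # cross scores via the orthogonal candidate anchored at the leaf
  rows <- list()
  for (ci in seq_along(cands)) {
    cc <- cands[[ci]]
    odir <- if (cc$dir == "horizontal") "vertical" else "horizontal"
    for (k in seq_along(cc$leaves)) {
      leaf <- cc$leaves[k]
      oi <- Find(function(x) x$dir == odir && x$anchor == leaf, cands)
      slot <- match(cc$anchor, oi$leaves)
      den <- max(oi$score[slot], 1e-9)
      rows[[length(rows) + 1]] <- data.frame(
        direction = cc$dir, anchor_pos = pos[cc$anchor],
        leaf_pos = pos[leaf], d = cc$d[k], g = cc$g[k], q = cc$q[k],
        stripe_score = cc$score[k], cross_score = cc$score[k] / den)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$direction, out$anchor_pos, out$d), ]
}

# Reshape call_stripes(details = TRUE) output into the oracle's key space.
pipeline_metric_table <- function(res) {
  v <- res$graph$vertices
  cm <- res$candidates
  out <- data.frame(direction = cm$direction,
                    anchor_pos = v$position[match(cm$anchor_id, v$id)],
                    leaf_pos = v$position[match(cm$leaf_id, v$id)],
                    d = cm$d, g = cm$g, q = cm$q,
                    stripe_score = cm$stripe_score,
                    cross_score = cm$cross_score)
  out[order(out$direction, out$anchor_pos, out$d), ]
}

# Plain-arithmetic tolerance overlap of one query loop against a loop table.
oracle_loop_matches <- function(q, subject, tolerance) {
  s1 <- max(0, q$start1 - tolerance); e1 <- q$end1 + tolerance
  s2 <- max(0, q$start2 - tolerance); e2 <- q$end2 + tolerance
  which(subject$chrom == q$chrom &
          s1 < subject$end1 & subject$start1 < e1 &
          s2 < subject$end2 & subject$start2 < e2)
}

# Random small loop set (bin-aligned and not) for property tests.
random_loops <- function(n, extent = 2e6, resolution = 5000, seed = 1,
                         aligned = FALSE) {
  set.seed(seed)
  a <- sample.int(extent - 20 * resolution, n)
  span <- sample(seq(resolution, 10 * resolution, by = 1000), n, replace = TRUE)
  w <- sample(seq(2000, 8000, by = 500), n, replace = TRUE)
  if (aligned) {
    a <- (a %/% resolution) * resolution
    span <- (span %/% resolution) * resolution + resolution
    w <- resolution
  }
  as_loops(data.frame(chrom = "chr_sim", start1 = a, end1 = a + w,
                      start2 = a + span, end2 = a + span + w, count = 1,
                      stringsAsFactors = FALSE))
}
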