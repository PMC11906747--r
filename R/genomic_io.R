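#' @useDynLib stripekit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rgeom runif setNames
#' @importFrom utils read.table write.table
NULL

# Coordinates throughout the package are 0-based, half-open [start, end),
# the BED/BEDPE convention of every input format touched.

## ---- interval helpers -------------------------------------------------

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns \code{chrom}, \code{start},
#' \code{end}; coordinates are 0-based, half-open. Empty intervals
#' (\code{start >= end}) and negative starts are rejected.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 0-based half-open coordinates.
#' @return data.frame with columns chrom, start, end.
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("empty or inverted interval (start >= end)")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Snap intervals outward to a resolution grid
#'
#' Returns, for each interval, the union of resolution-sized grid bins it
#' intersects: \code{[floor(start/res)*res, ceiling(end/res)*res)}. The
#' operation is idempotent and never shrinks an interval.
#'
#' @param x interval data.frame (chrom, start, end).
#' @param resolution bin size in bp (> 0); loop callers typically emit 5 kb.
#' @return interval data.frame with grid-aligned coordinates.
#' @export
bin_interval <- function(x, resolution) {
  stopifnot(resolution > 0)
  x$start <- (x$start %/% resolution) * resolution
  x$end <- ((x$end + resolution - 1) %/% resolution) * resolution
  x
}

#' Gap between two co-chromosomal intervals
#'
#' 0 if the intervals overlap or touch, otherwise the distance between their
#' nearest edges. Vectorised over rows; chromosomes must match pairwise.
#'
#' @param a,b interval data.frames of equal (or length-1) row count.
#' @return non-negative numeric vector of distances in bp.
#' @export
interval_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  if (any(a$chrom[ai] != b$chrom[bi]))
    stop("interval_distance is undefined across chromosomes")
  pmax(0, pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi]))
}

# 1 bp-or-more overlap of co-chromosomal half-open intervals (vectorised).
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

## ---- BEDPE loops ------------------------------------------------------

empty_loops <- function() {
  data.frame(chrom = character(), start1 = numeric(), end1 = numeric(),
             start2 = numeric(), end2 = numeric(), count = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate and canonicalise a loop table
#'
#' Loops are data frames with columns \code{chrom}, \code{start1},
#' \code{end1}, \code{start2}, \code{end2}, \code{count}: two same-chromosome
#' anchors plus an interaction count. Anchors are stored in canonical order
#' (\code{start1 <= start2}).
#'
#' @param loops loop data.frame.
#' @return the canonicalised loop data.frame.
#' @export
as_loops <- function(loops) {
  need <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(loops))) stop("missing loop columns")
  if (is.null(loops$count)) loops$count <- 1
  if (nrow(loops) == 0) return(loops)
  if (any(loops$start1 >= loops$end1 | loops$start2 >= loops$end2))
    stop("empty anchor interval (start >= end)")
  if (any(loops$start1 < 0 | loops$start2 < 0)) stop("negative coordinate")
  flip <- loops$start1 > loops$start2
  if (any(flip)) {
    s1 <- loops$start1[flip]; e1 <- loops$end1[flip]
    loops$start1[flip] <- loops$start2[flip]
    loops$end1[flip] <- loops$end2[flip]
    loops$start2[flip] <- s1; loops$end2[flip] <- e1
  }
  rownames(loops) <- NULL
  loops
}

anchor1 <- function(loops) genomic_intervals(loops$chrom, loops$start1, loops$end1)
anchor2 <- function(loops) genomic_intervals(loops$chrom, loops$start2, loops$end2)

#' Read chromatin loops from a BEDPE file
#'
#' Expects >= 6 tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2, ...). Column 8 is read as the interaction count when it is
#' integer-valued, otherwise count defaults to 1. Inter-chromosomal and
#' malformed records are skipped; their counts are attached as the
#' \code{"skipped"} attribute and reported via \code{message()}. The file
#' fails as a whole only when it contains data lines but no valid record.
#'
#' @param path path to a BEDPE file; lines starting with "#", "track" or
#'   "chrom" are treated as headers.
#' @return canonical loop data.frame (see \code{\link{as_loops}}).
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser|chrom1?\\b)", lines)]
  if (length(lines) == 0) {
    out <- empty_loops()
    attr(out, "skipped") <- c(interchrom = 0L, malformed = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_inter <- 0L; n_bad <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6) { n_bad <- n_bad + 1L; next }
    co <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (anyNA(co) || any(co != floor(co)) || any(co[c(1, 3)] < 0) ||
        co[1] >= co[2] || co[3] >= co[4]) { n_bad <- n_bad + 1L; next }
    if (f[1] != f[4]) { n_inter <- n_inter + 1L; next }
    cnt <- 1
    if (length(f) >= 8) {
      v <- suppressWarnings(as.numeric(f[8]))
      if (!is.na(v) && v == floor(v) && v > 0) cnt <- v
    }
    rows[[i]] <- c(co, cnt)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no valid loop records in ", path)
  m <- do.call(rbind, rows[keep])
  out <- as_loops(data.frame(
    chrom = vapply(fields[keep], `[`, "", 1), start1 = m[, 1], end1 = m[, 2],
    start2 = m[, 3], end2 = m[, 4], count = m[, 5],
    stringsAsFactors = FALSE))
  if (n_inter + n_bad > 0)
    message("read_bedpe: skipped ", n_inter, " inter-chromosomal and ",
            n_bad, " malformed record(s)")
  attr(out, "skipped") <- c(interchrom = n_inter, malformed = n_bad)
  out
}

#' Write loops to a BEDPE file
#'
#' Emits 8 columns (chrom1, start1, end1, chrom2, start2, end2, name, count)
#' so that \code{read_bedpe()} round-trips the loop set exactly.
#'
#' @param loops canonical loop data.frame.
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  loops <- as_loops(loops)
  out <- data.frame(loops$chrom, format_bp(loops$start1), format_bp(loops$end1),
                    loops$chrom, format_bp(loops$start2), format_bp(loops$end2),
                    ".", format_bp(loops$count))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

## ---- BED / motif tables ----------------------------------------------

#' Read intervals from a BED3+ file
#'
#' @param path path to a BED file (tab-separated, >= 3 columns).
#' @return interval data.frame (chrom, start, end), plus \code{name},
#'   \code{score} and \code{strand} columns when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = paste0("V", 1:6), fill = TRUE)[, 1:6]
  out <- genomic_intervals(tab$V1, tab$V2, tab$V3)
  if (!all(is.na(tab$V4))) out$name <- tab$V4
  if (!all(is.na(tab$V5))) out$score <- suppressWarnings(as.numeric(tab$V5))
  if (!all(is.na(tab$V6))) out$strand <- tab$V6
  out
}

#' Read CTCF motif hits
#'
#' BED6-compatible table: chrom, start, end, name, log2 score, strand. The
#' strand symbol maps to a pointing direction: by default "+" is
#' right-pointing (downstream) and "-" left-pointing; set \code{invert} to
#' flip the convention.
#'
#' @param path path to the motif table.
#' @param invert flip the strand-to-orientation mapping.
#' @return data.frame with columns chrom, start, end, orientation
#'   ("right"/"left") and score (log2 scale).
#' @export
read_motif_hits <- function(path, invert = FALSE) {
  tab <- read_bed(path)
  if (is.null(tab$strand) || !all(tab$strand %in% c("+", "-")))
    stop("motif table needs a +/- strand in column 6")
  if (is.null(tab$score) || anyNA(tab$score) || any(!is.finite(tab$score)))
    stop("motif table needs a finite log2 score in column 5")
  right <- if (invert) "-" else "+"
  data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
             orientation = ifelse(tab$strand == right, "right", "left"),
             score = tab$score, stringsAsFactors = FALSE)
}

## ---- stripe tables ----------------------------------------------------

stripe_columns <- c("chrom", "anchor_start", "anchor_end", "domain_start",
                    "domain_end", "direction", "n_leaves", "length_bp",
                    "stripe_score", "mean_cross_score")

empty_stripes <- function() {
  out <- data.frame(chrom = character(), anchor_start = numeric(),
                    anchor_end = numeric(), domain_start = numeric(),
                    domain_end = numeric(), direction = character(),
                    n_leaves = integer(), length_bp = numeric(),
                    stripe_score = numeric(), mean_cross_score = numeric(),
                    stringsAsFactors = FALSE)
  out
}

sort_stripes <- function(stripes) {
  o <- order(stripes$chrom, stripes$anchor_start, stripes$direction,
             method = "radix")
  rownames(stripes) <- NULL
  stripes[o, , drop = FALSE]
}

#' Write called stripes to a tab-delimited table
#'
#' One row per stripe: chrom, anchor region, striping domain, direction
#' (horizontal/vertical), number of leaves, stripe length, terminal stripe
#' score and mean cross score, ordered deterministically by
#' (chrom, anchor_start, direction).
#'
#' @param stripes stripe data.frame as returned by \code{\link{call_stripes}}.
#' @param path output path.
#' @export
write_stripes <- function(stripes, path) {
  stopifnot(all(stripe_columns %in% names(stripes)))
  stripes <- sort_stripes(stripes[, stripe_columns, drop = FALSE])
  for (col in c("anchor_start", "anchor_end", "domain_start", "domain_end",
                "length_bp"))
    stripes[[col]] <- format_bp(stripes[[col]])
  write.table(stripes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stripe table written by \code{write_stripes}
#' @param path path to the table.
#' @return stripe data.frame.
#' @export
read_stripes <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(stripe_columns %in% names(tab)))
  tab[, stripe_columns, drop = FALSE]
}
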