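## Probabilistic CTCF motif orientation at loop anchors. Motif hits carry
## log2-scale scores; the probability of the anchor's motif content pointing
## right (downstream) is the 2^score-weighted mass of right-pointing hits.

#' Probabilistic orientation of an anchor's CTCF motif content
#'
#' \code{P_right = sum over right-pointing hits of 2^score / sum over all
#' hits of 2^score}, with scores on the log2 scale;
#' \code{P_left = 1 - P_right}. Scores are shifted by their maximum before
#' exponentiation, which leaves the ratio unchanged and keeps it finite.
#'
#' @param hits data.frame with columns \code{orientation}
#'   ("right"/"left") and \code{score} (log2 scale), e.g. from
#'   \code{\link{read_motif_hits}}; at least one hit is required.
#' @return list with \code{p_right}, \code{p_left}, \code{n_hits}.
#' @export
anchor_orientation <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0)
    stop("anchor orientation is undefined without motif hits")
  if (!all(hits$orientation %in% c("right", "left")))
    stop("orientation must be 'right' or 'left'")
  w <- 2^(hits$score - max(hits$score))
  p <- sum(w[hits$orientation == "right"]) / sum(w)
  list(p_right = p, p_left = 1 - p, n_hits = nrow(hits))
}

#' Does an anchor carry a motif above the presence threshold?
#'
#' @param hits motif-hit data.frame (possibly empty).
#' @param presence_threshold minimum log2 score counting as presence
#'   (default 7.0).
#' @return TRUE iff any hit scores at or above the threshold.
#' @export
anchor_has_motif <- function(hits, presence_threshold = 7.0) {
  !is.null(hits) && nrow(hits) > 0 && any(hits$score >= presence_threshold)
}

#' Classify the joint CTCF orientation of a loop's anchor pair
#'
#' Each anchor is discretised to its majority orientation
#' (\code{p_right >= 0.5} maps to right). The pair is convergent when the
#' left anchor points right and the right anchor points left; divergent in
#' the reverse case; tandem otherwise. Missing orientation on either side
#' yields "unclassified".
#'
#' @param left_anchor,right_anchor orientation lists from
#'   \code{\link{anchor_orientation}} (or NULL when no hits).
#' @return one of "convergent", "divergent", "tandem_right", "tandem_left",
#'   "unclassified".
#' @export
classify_pair_orientation <- function(left_anchor, right_anchor) {
  ok <- function(x) is.list(x) && !is.null(x$p_right) && isTRUE(x$n_hits >= 1)
  if (!ok(left_anchor) || !ok(right_anchor)) return("unclassified")
  l_right <- left_anchor$p_right >= 0.5
  r_right <- right_anchor$p_right >= 0.5
  if (l_right && !r_right) "convergent"
  else if (!l_right && r_right) "divergent"
  else if (l_right) "tandem_right"
  else "tandem_left"
}
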