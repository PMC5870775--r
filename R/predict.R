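#' Predict downstream regulation under a signed regulator hypothesis
#'
#' Breadth-first search from the hypothesis node's signed copy in the CCG,
#' to a maximum depth of \code{delta} edges (inclusive; the start copy
#' counts as reached at distance 0, so a regulator's own transcript is part
#' of its prediction). An entity whose positive copy alone is reachable is
#' predicted up (\code{+1}), negative copy alone down (\code{-1}); if both
#' copies are reachable within \code{delta} the regulator can push the
#' entity either way inside the horizon and the prediction is ambiguous
#' (\code{0}). Entities with neither copy reachable are absent from the
#' result. Ambiguity is defined by reachability of both copies within
#' \code{delta}, not by tied shortest distances, which makes predictions
#' monotone in \code{delta}: growing the horizon can add entities or turn a
#' signed prediction ambiguous, but never flips it to the opposite sign.
#'
#' @param ccg A [create_ccg()] object.
#' @param node Entity identifier of the hypothesized regulator.
#' @param sign Hypothesized direction, \code{+1} or \code{-1}.
#' @param delta Maximum path length in edges (positive integer).
#' @return Named integer vector of predictions in \code{-1, 0, 1} over the
#'   reachable entities.
#' @examples
#' edges <- data.frame(source = c("A", "B"), sign = c(1L, -1L),
#'                     target = c("B", "C"))
#' ccg <- create_ccg(edges)
#' predict_regulation(ccg, "A", 1L, delta = 2)
#' @export
predict_regulation <- function(ccg, node, sign = 1L, delta = 1L) {
  stopifnot(inherits(ccg, "ccg"))
  sign <- check_sign(sign)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 1) {
    stop("delta must be a positive integer", call. = FALSE)
  }
  i <- ccg_entity_index(ccg, node)
  d <- igraph::distances(ccg$graph, v = ccg_vertex(ccg, i, sign),
                         mode = "out")[1L, ]
  predictions_from_distances(d, ccg$entities, delta)
}

# Turn one row of the CCG distance matrix (from some signed start copy)
# into a prediction vector over entities.
predictions_from_distances <- function(d, entities, delta) {
  n <- length(entities)
  rp <- is.finite(d[seq_len(n)]) & d[seq_len(n)] <= delta
  rm_ <- is.finite(d[n + seq_len(n)]) & d[n + seq_len(n)] <= delta
  hit <- rp | rm_
  pred <- integer(sum(hit))
  pred[] <- ifelse(rp[hit] & rm_[hit], 0L, ifelse(rp[hit], 1L, -1L))
  names(pred) <- entities[hit]
  pred
}

#' Score a prediction map against a mapped signature
#'
#' Over genes present in both the prediction and the mapped signature:
#' a gene is \emph{correct} when the predicted and observed signs agree
#' (product \code{+1}), \emph{incorrect} when they disagree (product
#' \code{-1}), and \emph{ambiguous} when the prediction is 0 but the gene
#' was observed changed. Zero-observed genes and genes outside the
#' prediction contribute to no counter. The score is
#' \code{correct - incorrect}.
#'
#' @param pred Named prediction vector from [predict_regulation()].
#' @param msig A [map_signature()] object (or bare named signature vector).
#' @return List with \code{score}, \code{correct}, \code{incorrect},
#'   \code{ambiguous}.
#' @export
score_hypothesis <- function(pred, msig) {
  obs <- as_mapped_values(msig)
  common <- intersect(names(pred), names(obs))
  pv <- pred[common]
  ov <- obs[common]
  prods <- pv * ov
  list(score = sum(prods == 1L) - sum(prods == -1L),
       correct = sum(prods == 1L),
       incorrect = sum(prods == -1L),
       ambiguous = sum(pv == 0L & ov != 0L))
}

# Prediction values aligned to every mapped signature gene: +1 / -1 where a
# signed prediction exists, 0 where the prediction is ambiguous or absent.
# This collapsed coding is exactly what both the score and the permutation
# null depend on.
aligned_prediction <- function(pred, msig) {
  obs <- as_mapped_values(msig)
  pv <- integer(length(obs))
  hit <- match(names(obs), names(pred))
  ok <- !is.na(hit)
  pv[ok] <- pred[hit[ok]]
  names(pv) <- names(obs)
  pv
}
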