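#' Simulate a random signed causal network
#'
#' Draws a seeded random directed graph with exactly \code{n_edges} distinct
#' ordered node pairs (no self-loops, no duplicate pairs), each edge being
#' an activation with probability \code{p_activation} and an inhibition
#' otherwise. Entities are named \code{G01}, \code{G02}, ... The uniform
#' ordered-pair model keeps analytic expectations simple; it does not try to
#' mimic the degree distribution or motif content of curated interactomes.
#'
#' @param n_nodes Number of entities.
#' @param n_edges Number of edges; at most \code{n_nodes * (n_nodes - 1)}.
#' @param p_activation Probability that an edge is an activation.
#' @param seed Seed making the draw reproducible; \code{NULL} uses the
#'   current RNG stream.
#' @return Signed edge data frame as returned by [read_sif()].
#' @examples
#' simulate_network(5, 6, seed = 1)
#' @export
simulate_network <- function(n_nodes, n_edges, p_activation = 0.7,
                             seed = NULL) {
  if (n_edges > n_nodes * (n_nodes - 1)) {
    stop("n_edges exceeds the number of distinct ordered pairs",
         call. = FALSE)
  }
  if (p_activation < 0 || p_activation > 1) {
    stop("p_activation must be in [0, 1]", call. = FALSE)
  }
  ents <- sprintf("G%0*d", max(2L, nchar(n_nodes)), seq_len(n_nodes))
  with_seed(seed, {
    pair_id <- if (n_edges > 0) {
      sort(sample.int(n_nodes * (n_nodes - 1L), n_edges))
    } else {
      integer(0)
    }
    # decode ordered pair: source s, then target among the n-1 others
    s <- (pair_id - 1L) %/% (n_nodes - 1L) + 1L
    t_off <- (pair_id - 1L) %% (n_nodes - 1L) + 1L
    t <- ifelse(t_off >= s, t_off + 1L, t_off)
    sgn <- ifelse(stats::runif(n_edges) < p_activation, 1L, -1L)
    data.frame(source = ents[s], sign = as.integer(sgn), target = ents[t],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a signature from a planted regulator hypothesis
#'
#' Propagates a chosen hypothesis through the CCG with
#' [predict_regulation()] at path length \code{delta}, keeps a seeded random
#' \code{coverage} fraction of the predicted entities, assigns each its
#' predicted sign (ambiguous predictions become 0), and corrupts each value
#' independently with probability \code{noise} — half of corruptions flip
#' the sign, half zero the value, exercising both the mismatch and the
#' dropout path of downstream scoring. At \code{noise = 0},
#' \code{coverage = 1} the planted hypothesis attains the maximum possible
#' score at \code{delta}, which is the basis of the planted-regulator
#' recovery checks.
#'
#' @param ccg A [create_ccg()] object.
#' @param node,sign The planted signed hypothesis.
#' @param delta Generation path length.
#' @param coverage Fraction of predicted entities included in the signature.
#' @param noise Per-gene corruption probability.
#' @param seed Seed; \code{NULL} uses the current RNG stream.
#' @return Named integer signature vector (values in \code{-1, 0, 1}).
#' @export
simulate_signature <- function(ccg, node, sign = 1L, delta = 2L,
                               coverage = 1, noise = 0, seed = NULL) {
  stopifnot(inherits(ccg, "ccg"))
  if (coverage < 0 || coverage > 1 || noise < 0 || noise > 1) {
    stop("coverage and noise must be in [0, 1]", call. = FALSE)
  }
  pred <- predict_regulation(ccg, node, sign, delta)
  with_seed(seed, {
    k <- round(coverage * length(pred))
    keep <- if (k > 0) sort(sample.int(length(pred), k)) else integer(0)
    sig <- pred[keep]
    if (length(sig) > 0 && noise > 0) {
      corrupt <- stats::runif(length(sig)) < noise
      flip <- stats::runif(length(sig)) < 0.5
      sig[corrupt & flip] <- -sig[corrupt & flip]
      sig[corrupt & !flip] <- 0L
    }
    sig
  })
}

#' Exhaustive walk-enumeration prediction oracle
#'
#' Deliberately slow, independent reference for [predict_regulation()]:
#' enumerates every walk of at most \code{delta} edges from the hypothesis
#' node over the raw signed edge list (never touching the CCG construction)
#' and classifies each reached entity by the set of achievable edge-sign
#' products times the hypothesis sign. Guarded to small instances because
#' walk counts grow exponentially.
#'
#' @param edges Signed edge data frame (see [read_sif()]).
#' @param node,sign The signed hypothesis.
#' @param delta Maximum walk length in edges.
#' @param max_nodes,max_delta Size guards; larger instances are an error.
#' @return Named integer prediction vector with the same contract as
#'   [predict_regulation()].
#' @export
oracle_predict <- function(edges, node, sign = 1L, delta = 1L,
                           max_nodes = 14L, max_delta = 5L) {
  sign <- check_sign(sign)
  ents <- unique(c(edges$source, edges$target))
  if (length(ents) > max_nodes || delta > max_delta) {
    stop("oracle_predict is restricted to <= ", max_nodes, " nodes and ",
         "delta <= ", max_delta, call. = FALSE)
  }
  if (!node %in% ents) {
    stop("node '", node, "' is not in the causal network", call. = FALSE)
  }
  # reached[[entity]] is the set of walk sign products seen so far
  reached <- new.env(parent = emptyenv())
  note <- function(ent, prod) {
    assign(ent, union(get0(ent, envir = reached, ifnotfound = integer(0)),
                      prod),
           envir = reached)
  }
  walk <- function(current, prod, depth) {
    note(current, prod)
    if (depth == 0L) return(invisible())
    out <- which(edges$source == current)
    for (j in out) {
      walk(edges$target[[j]], prod * edges$sign[[j]], depth - 1L)
    }
  }
  walk(node, 1L, as.integer(delta))
  hit <- ls(reached)
  pred <- vapply(hit, function(e) {
    prods <- get(e, envir = reached) * sign
    if (length(prods) == 2L) 0L else prods
  }, integer(1))
  pred[order(match(names(pred), ents))]
}
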