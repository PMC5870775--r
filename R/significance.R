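#' Permutation-null significance of a sign-match score
#'
#' The null model keeps the predictions fixed and assigns the multiset of
#' observed values uniformly at random across the mapped signature genes;
#' the p-value is the probability of a score at least as large as the one
#' observed. Because the score depends only on the 3x3 contingency table of
#' prediction class (\code{+1}, \code{-1}, ambiguous-or-absent) against
#' observation class (\code{+1}, \code{-1}, \code{0}), the exact method
#' sums multivariate-hypergeometric probabilities over all tables with the
#' given margins whose score reaches the observed one. The Monte Carlo
#' method estimates the same tail with seeded shuffles and the add-one
#' estimator \code{(k + 1) / (n_perm + 1)}. With \code{method = "auto"} the
#' exact sum is used unless the number of candidate tables exceeds
#' \code{max_tables}, in which case the Monte Carlo estimate is returned.
#'
#' @param pred Named prediction vector from [predict_regulation()].
#' @param msig A [map_signature()] object (or bare named signature vector).
#' @param method \code{"auto"}, \code{"exact"} or \code{"montecarlo"}.
#' @param n_perm Number of Monte Carlo shuffles.
#' @param seed Seed for the Monte Carlo path; \code{NULL} uses the current
#'   RNG stream.
#' @param max_tables Table-count budget above which \code{"auto"} falls back
#'   to Monte Carlo.
#' @return The p-value. An empty signature returns 1 by convention.
#' @export
score_significance <- function(pred, msig,
                               method = c("auto", "exact", "montecarlo"),
                               n_perm = 1000L, seed = NULL,
                               max_tables = 1e7) {
  method <- match.arg(method)
  obs <- as_mapped_values(msig)
  if (length(obs) == 0L) return(1)
  pv <- aligned_prediction(pred, msig)
  s_obs <- sum(pv * obs)
  n <- c(sum(pv == 1L), sum(pv == -1L), sum(pv == 0L))
  q <- c(sum(obs == 1L), sum(obs == -1L), sum(obs == 0L))
  if (method == "auto") {
    n_tab <- prod(pmin(n[1], q[1]) + 1, pmin(n[1], q[2]) + 1,
                  pmin(n[2], q[1]) + 1, pmin(n[2], q[2]) + 1)
    method <- if (n_tab <= max_tables) "exact" else "montecarlo"
  }
  if (method == "exact") {
    exact_score_pvalue(n, q, s_obs)
  } else {
    with_seed(seed, {
      k <- 0L
      for (r in seq_len(n_perm)) {
        if (sum(pv * sample(obs)) >= s_obs) k <- k + 1L
      }
      (k + 1) / (n_perm + 1)
    })
  }
}

# Exact tail probability P(score >= s_obs) by summation over 3x3 tables
# with row margins n = (n+, n-, n0) (prediction classes) and column margins
# q = (q+, q-, q0) (observation classes). A table's probability under the
# uniform assignment null is prod_r multinom(n_r; x_r.) / multinom(N; q).
# Only the four sign-by-sign cells are free; the loops run over the first
# two and the remaining two are vectorized.
exact_score_pvalue <- function(n, q, s_obs) {
  N <- sum(n)
  stopifnot(N == sum(q))
  if (N == 0L) return(1)
  lden <- lgamma(N + 1) - sum(lgamma(q + 1))
  total <- 0
  for (a in 0:min(n[1], q[1])) {          # x(+ pred, + obs)
    for (b in 0:min(n[1] - a, q[2])) {    # x(+ pred, - obs)
      x_p0 <- n[1] - a - b
      if (x_p0 > q[3]) next
      cc <- 0:min(n[2], q[1] - a)         # x(- pred, + obs)
      dd <- 0:min(n[2], q[2] - b)         # x(- pred, - obs)
      if (length(cc) == 0L || length(dd) == 0L) next
      grid_c <- rep(cc, times = length(dd))
      grid_d <- rep(dd, each = length(cc))
      x_m0 <- n[2] - grid_c - grid_d
      x_0p <- q[1] - a - grid_c
      x_0m <- q[2] - b - grid_d
      x_00 <- n[3] - x_0p - x_0m
      ok <- x_m0 >= 0 & x_00 >= 0 & x_m0 <= q[3] &
        (a + grid_d - b - grid_c) >= s_obs
      if (!any(ok)) next
      gc_ <- grid_c[ok]; gd <- grid_d[ok]
      lp <- (lgamma(n[1] + 1) - lgamma(a + 1) - lgamma(b + 1) -
               lgamma(x_p0 + 1)) +
        (lgamma(n[2] + 1) - lgamma(gc_ + 1) - lgamma(gd + 1) -
           lgamma(x_m0[ok] + 1)) +
        (lgamma(n[3] + 1) - lgamma(x_0p[ok] + 1) - lgamma(x_0m[ok] + 1) -
           lgamma(x_00[ok] + 1)) - lden
      total <- total + sum(exp(lp))
    }
  }
  min(max(total, 0), 1)
}

#' Hypergeometric enrichment of predicted genes among changed genes
#'
#' A sign-blind companion to the permutation p-value: the one-sided
#' hypergeometric tail probability of seeing at least the observed count of
#' signature genes that are both covered by the prediction (signed or
#' ambiguous) and observed changed, given the margins. Degenerate margins
#' (nothing predicted, or nothing observed changed) return 1.
#'
#' @param pred Named prediction vector from [predict_regulation()].
#' @param msig A [map_signature()] object (or bare named signature vector).
#' @param universe Universe size; defaults to the number of mapped
#'   signature genes. Must be at least that number.
#' @return The enrichment p-value.
#' @export
enrichment_significance <- function(pred, msig, universe = NULL) {
  obs <- as_mapped_values(msig)
  universe <- universe %||% length(obs)
  if (universe < length(obs)) {
    stop("universe must be at least the number of signature genes",
         call. = FALSE)
  }
  predicted <- names(obs) %in% names(pred)
  changed <- obs != 0L
  n_pred <- sum(predicted)
  n_chg <- sum(changed)
  if (n_pred == 0L || n_chg == 0L) return(1)
  overlap <- sum(predicted & changed)
  stats::phyper(overlap - 1, n_pred, universe - n_pred, n_chg,
                lower.tail = FALSE)
}
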