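#' Multi-path-length consensus filtering of regulator hypotheses (SCAN)
#'
#' Hypotheses that explain the data at a single path length only are prone
#' to be false positives; hypotheses predicted to control the observed genes
#' across several path lengths are more plausibly true regulators. This
#' sequential analysis re-runs [rank_hypotheses()] at each of an increasing
#' sequence of path lengths, takes the top of each ranking, and retains only
#' the signed hypotheses common to every top list.
#'
#' The per-path-length top list is cut by score, not by row count: every
#' hypothesis whose score ties the score at rank \code{top_n} is included,
#' so the consensus does not depend on how ties happen to be ordered. The
#' atomic unit is the signed hypothesis (node plus direction): the up and
#' down hypotheses of one node are distinct candidates. Consensus membership
#' depends only on scores, so p-values are not computed during the scan.
#'
#' @param ccg A [create_ccg()] object.
#' @param msig A [map_signature()] object (or bare named signature vector).
#' @param deltas Strictly increasing sequence of positive path lengths.
#' @param top_n Number of top score ranks retained at each path length
#'   (ties at the boundary included).
#' @return An object of class \code{scan_result}: a list with \code{deltas},
#'   \code{top_n}, \code{rankings} (one ranking table per path length),
#'   \code{top} (one character vector of \code{"node|+"} / \code{"node|-"}
#'   keys per path length) and \code{consensus} (data frame of consensus
#'   hypotheses with per-path-length scores and ranks, ordered by rank at
#'   the largest path length).
#' @examples
#' ccg <- create_ccg(data.frame(source = c("A", "B"), sign = c(1L, 1L),
#'                              target = c("B", "C")))
#' msig <- map_signature(c(B = 1L, C = 1L), ccg)
#' scan_hypotheses(ccg, msig, deltas = c(1, 2), top_n = 2)
#' @export
scan_hypotheses <- function(ccg, msig, deltas = c(1L, 2L, 3L), top_n = 100L) {
  stopifnot(inherits(ccg, "ccg"))
  if (length(deltas) == 0L) stop("deltas must be non-empty", call. = FALSE)
  if (any(deltas < 1) || any(diff(deltas) <= 0)) {
    stop("deltas must be a strictly increasing sequence of positive integers",
         call. = FALSE)
  }
  if (top_n < 1) stop("top_n must be at least 1", call. = FALSE)
  if (!inherits(msig, "mapped_signature")) msig <- map_signature(msig, ccg)
  rankings <- lapply(deltas, function(d) {
    rank_hypotheses(ccg, msig, delta = d, p_method = "none")
  })
  top <- lapply(rankings, function(tbl) {
    cut_score <- tbl$Score[[min(top_n, nrow(tbl))]]
    keep <- tbl$Score >= cut_score
    paste0(tbl$NodeName[keep], "|", sign_label(tbl$Regulation[keep]))
  })
  consensus_keys <- Reduce(intersect, top)
  last <- rankings[[length(rankings)]]
  last_key <- paste0(last$NodeName, "|", sign_label(last$Regulation))
  consensus_keys <- last_key[last_key %in% consensus_keys]  # rank order at max delta
  consensus <- data.frame(
    NodeName = sub("\\|[+-]$", "", consensus_keys),
    Regulation = ifelse(endsWith(consensus_keys, "+"), 1L, -1L),
    stringsAsFactors = FALSE)
  for (j in seq_along(deltas)) {
    tbl <- rankings[[j]]
    key <- paste0(tbl$NodeName, "|", sign_label(tbl$Regulation))
    m <- match(consensus_keys, key)
    consensus[[paste0("Score_delta", deltas[[j]])]] <- tbl$Score[m]
    consensus[[paste0("Rank_delta", deltas[[j]])]] <- tbl$Rank[m]
  }
  structure(list(deltas = deltas, top_n = top_n, rankings = rankings,
                 top = top, consensus = consensus),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Path-length consensus scan\n")
  cat("  deltas:   ", paste(x$deltas, collapse = ", "), "\n", sep = "")
  cat("  top_n:    ", x$top_n, " (score ties at the cut included)\n", sep = "")
  cat("  top list sizes: ", paste(lengths(x$top), collapse = ", "), "\n",
      sep = "")
  cat("  consensus hypotheses: ", nrow(x$consensus), "\n", sep = "")
  if (nrow(x$consensus) > 0) {
    print(utils::head(x$consensus, 10))
  }
  invisible(x)
}

#' Write a scan consensus table as TSV
#'
#' @param scan A [scan_hypotheses()] result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  utils::write.table(scan$consensus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
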