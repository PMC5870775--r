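#' Read a signed causal network from a SIF file
#'
#' Parses a simple interaction format (SIF) file describing a signed,
#' directed interaction network. Each non-blank, non-comment line must have
#' exactly three whitespace/tab-separated fields:
#' \code{source relation target}, where the relation token is
#' \code{Activates} or \code{Inhibits} (matched case-insensitively).
#' Lines starting with \code{#} are comments. Exact duplicate edges are
#' collapsed to one, keeping the order of first appearance. Contradictory
#' edges (same ordered pair, both signs) are both retained: downstream they
#' render the target ambiguous for that regulator, which is the intended
#' semantics for curation conflicts.
#'
#' @param path Path to a SIF file.
#' @param strict If \code{TRUE}, an unknown relation token is an error; if
#'   \code{FALSE} (default) such lines are skipped with a warning. A line
#'   with a field count other than three is always an error.
#' @return A data frame of signed edges with columns \code{source}
#'   (character), \code{sign} (integer, \code{+1} activation, \code{-1}
#'   inhibition) and \code{target} (character).
#' @seealso [write_sif()], [create_ccg()]
#' @examples
#' sif <- tempfile(fileext = ".sif")
#' writeLines(c("ProteinA\tActivates\tProteinB",
#'              "ProteinC\tInhibits\tProteinD"), sif)
#' read_sif(sif)
#' @export
read_sif <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("SIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  src <- character(0)
  sgn <- integer(0)
  tgt <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (length(fields) != 3L) {
      stop("malformed SIF line ", i, " in ", path, ": expected 3 fields, got ",
           length(fields), call. = FALSE)
    }
    rel <- tolower(fields[[2]])
    if (rel == "activates") {
      s <- 1L
    } else if (rel == "inhibits") {
      s <- -1L
    } else if (strict) {
      stop("unknown relation token '", fields[[2]], "' on line ", i, " of ",
           path, call. = FALSE)
    } else {
      warning("skipping line ", i, " of ", path,
              ": unsigned relation token '", fields[[2]], "'", call. = FALSE)
      next
    }
    src <- c(src, fields[[1]])
    sgn <- c(sgn, s)
    tgt <- c(tgt, fields[[3]])
  }
  edges <- data.frame(source = src, sign = sgn, target = tgt,
                      stringsAsFactors = FALSE)
  edges[!duplicated(edges), , drop = FALSE]
}

#' Write a signed edge list to a SIF file
#'
#' Serializes edges in the same dialect [read_sif()] consumes, so a written
#' file round-trips exactly (modulo duplicate collapse).
#'
#' @param edges Data frame with columns \code{source}, \code{sign},
#'   \code{target} as returned by [read_sif()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sif <- function(edges, path) {
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  lines <- paste(edges$source, sign_to_relation(edges$sign), edges$target,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Build a computational causal graph (CCG) from signed edges
#'
#' Every entity of the input network is split into a positive and a negative
#' copy, and each signed edge \eqn{(a, s, b)} becomes the two arcs
#' \eqn{(a,+) \to (b, s)} and \eqn{(a,-) \to (b, -s)}. A path from a signed
#' copy of a regulator then ends at the copy of a target whose sign equals
#' the product of the traversed edge signs, so bounded-depth reachability in
#' the CCG encodes the predicted regulation direction.
#'
#' @param edges Data frame of signed edges (see [read_sif()]); may be empty.
#'   Self-loops and contradictory duplicate pairs are retained.
#' @return An object of class \code{ccg}: a list with \code{entities}
#'   (character vector, order of first appearance), \code{edges} (the
#'   distinct input edges) and \code{graph} (a directed \pkg{igraph} graph
#'   with \code{2 * length(entities)} vertices; vertex \code{i} is the
#'   positive copy of entity \code{i}, vertex \code{N + i} its negative
#'   copy).
#' @examples
#' edges <- data.frame(source = "A", sign = 1L, target = "B")
#' ccg <- create_ccg(edges)
#' ccg
#' @export
create_ccg <- function(edges) {
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  if (nrow(edges) > 0 && !all(edges$sign %in% c(1L, -1L))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  edges <- edges[!duplicated(edges[c("source", "sign", "target")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  entities <- unique(c(edges$source, edges$target))
  n <- length(entities)
  si <- match(edges$source, entities)
  ti <- match(edges$target, entities)
  # + copy of entity i is vertex i, - copy is vertex n + i
  to_plus_arm <- ifelse(edges$sign > 0L, ti, n + ti)   # from (a,+)
  to_minus_arm <- ifelse(edges$sign > 0L, n + ti, ti)  # from (a,-)
  from <- c(si, n + si)
  to <- c(to_plus_arm, to_minus_arm)
  g <- igraph::make_empty_graph(n = 2L * n, directed = TRUE)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  structure(list(entities = entities, edges = edges, graph = g),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat("Computational causal graph\n")
  cat("  entities: ", length(x$entities), " (", 2L * length(x$entities),
      " signed node copies)\n", sep = "")
  cat("  edges:    ", nrow(x$edges), " signed interactions, ",
      igraph::ecount(x$graph), " arcs\n", sep = "")
  invisible(x)
}

# Vertex id of the (entity index, sign) copy inside ccg$graph.
ccg_vertex <- function(ccg, entity_index, sign) {
  entity_index + (sign < 0L) * length(ccg$entities)
}

# Resolve an entity name to its index, with a helpful error.
ccg_entity_index <- function(ccg, node) {
  i <- match(node, ccg$entities)
  if (is.na(i)) {
    stop("node '", node, "' is not in the causal network", call. = FALSE)
  }
  i
}
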