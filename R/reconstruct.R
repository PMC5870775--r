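#' Genes explained by a regulator hypothesis
#'
#' The explained nodes of a hypothesis are the measured genes whose
#' predicted regulation is signed (not ambiguous) and equal to the observed
#' sign within path length \code{delta}.
#'
#' @param ccg A [create_ccg()] object.
#' @param msig A [map_signature()] object (or bare named signature vector).
#' @param node,sign The signed regulator hypothesis.
#' @param delta Maximum path length in edges.
#' @return Character vector of explained entity names.
#' @export
explained_nodes <- function(ccg, msig, node, sign = 1L, delta = 1L) {
  pred <- predict_regulation(ccg, node, sign, delta)
  obs <- as_mapped_values(msig)
  common <- intersect(names(pred), names(obs))
  common[pred[common] != 0L & pred[common] == obs[common]]
}

#' Reconstruct the explained regulatory subnetwork of a hypothesis
#'
#' For each explained node, every shortest sign-consistent path from the
#' hypothesis' signed copy to the node's matching copy in the CCG is
#' retained, and the traversed arcs are projected back to signed input
#' edges. Retaining all shortest paths (rather than one arbitrary path, or
#' every path up to \code{delta}) keeps the output deterministic and
#' size-bounded while still showing parallel branches of the cascade.
#' Path nodes that are neither the hypothesis nor explained are the
#' \emph{intermediate} ("grey") nodes: unmeasured or unchanged members of
#' the signalling cascade. Every output node carries its observed
#' regulation as an annotation, defaulting to 0 for genes absent from the
#' signature.
#'
#' @inheritParams explained_nodes
#' @return An object of class \code{explained_network}: a list with
#'   \code{node}, \code{sign}, \code{delta}, \code{explained},
#'   \code{intermediates}, \code{edges} (signed edge data frame),
#'   \code{paths} (the retained paths, each a character vector of entities
#'   from the hypothesis to one explained node) and \code{annotations}
#'   (named integer vector over all output nodes). With
#'   no explained nodes the network contains the hypothesis node alone and
#'   zero edges (a notice is emitted, not an error).
#' @examples
#' ccg <- create_ccg(data.frame(source = c("A", "B"), sign = c(1L, -1L),
#'                              target = c("B", "C")))
#' msig <- map_signature(c(B = 1L, C = -1L), ccg)
#' reconstruct_network(ccg, msig, "A", 1L, delta = 2)
#' @export
reconstruct_network <- function(ccg, msig, node, sign = 1L, delta = 1L) {
  stopifnot(inherits(ccg, "ccg"))
  sign <- check_sign(sign)
  if (!inherits(msig, "mapped_signature")) msig <- map_signature(msig, ccg)
  obs <- as_mapped_values(msig)
  expl <- explained_nodes(ccg, msig, node, sign, delta)
  i <- ccg_entity_index(ccg, node)
  start <- ccg_vertex(ccg, i, sign)
  n <- length(ccg$entities)
  edges <- ccg$edges[0, , drop = FALSE]
  nodes_out <- node
  paths <- list()
  if (length(expl) == 0L) {
    message("no explained nodes for hypothesis ", node, sign_label(sign),
            " at delta ", delta, "; writing the hypothesis node only")
  } else {
    targets <- ccg_vertex(ccg, match(expl, ccg$entities), obs[expl])
    asp <- suppressWarnings(
      igraph::all_shortest_paths(ccg$graph, from = start, to = targets,
                                 mode = "out"))
    vpaths <- asp$vpaths %||% asp$res
    from_v <- integer(0)
    to_v <- integer(0)
    for (p in vpaths) {
      v <- as.integer(p)
      if (length(v) >= 2L) {
        from_v <- c(from_v, v[-length(v)])
        to_v <- c(to_v, v[-1L])
      }
      ents_on_path <- ccg$entities[(v - 1L) %% n + 1L]
      paths[[length(paths) + 1L]] <- ents_on_path
      nodes_out <- c(nodes_out, ents_on_path)
    }
    if (length(from_v) > 0) {
      copy_sign <- function(v) ifelse(v <= n, 1L, -1L)
      edges <- unique(data.frame(
        source = ccg$entities[(from_v - 1L) %% n + 1L],
        sign = copy_sign(from_v) * copy_sign(to_v),
        target = ccg$entities[(to_v - 1L) %% n + 1L],
        stringsAsFactors = FALSE))
    }
    nodes_out <- unique(nodes_out)
  }
  ann <- integer(length(nodes_out))
  names(ann) <- nodes_out
  have <- intersect(nodes_out, names(obs))
  ann[have] <- obs[have]
  structure(list(node = node, sign = sign, delta = delta,
                 explained = expl,
                 intermediates = setdiff(nodes_out, c(node, expl)),
                 edges = edges[order(edges$source, edges$target, -edges$sign), ,
                               drop = FALSE],
                 paths = paths,
                 annotations = ann),
            class = "explained_network")
}

#' @export
print.explained_network <- function(x, ...) {
  cat("Explained regulatory network for hypothesis ", x$node,
      sign_label(x$sign), " (delta ", x$delta, ")\n", sep = "")
  cat("  explained nodes:    ", length(x$explained), "\n", sep = "")
  cat("  intermediate nodes: ", length(x$intermediates), "\n", sep = "")
  cat("  edges:              ", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Write an explained network as Cytoscape-ready SIF plus annotations
#'
#' The SIF file uses the same dialect [read_sif()] consumes (guaranteed
#' round-trip); the annotation file is a two-column TSV with header
#' \code{NodeName<TAB>Regulation} covering every node of the SIF, loadable
#' in Cytoscape as a node attribute table so that up/down/unchanged nodes
#' can be coloured. Lines are deduplicated and sorted lexicographically so
#' repeated runs are byte-identical.
#'
#' @param net An [reconstruct_network()] object.
#' @param sif_path,annot_path Output file paths.
#' @return Named character vector of the two written paths, invisibly.
#' @export
write_explained_sif <- function(net, sif_path, annot_path) {
  stopifnot(inherits(net, "explained_network"))
  lines <- paste(net$edges$source, sign_to_relation(net$edges$sign),
                 net$edges$target, sep = "\t")
  writeLines(sort(unique(lines)), sif_path)
  nodes <- sort(names(net$annotations))
  writeLines(c("NodeName\tRegulation",
               paste(nodes, net$annotations[nodes], sep = "\t")),
             annot_path)
  invisible(c(sif = sif_path, annotations = annot_path))
}

#' Write explained networks for every scan consensus hypothesis
#'
#' Runs [reconstruct_network()] and [write_explained_sif()] for each signed
#' hypothesis in the consensus of a [scan_hypotheses()] result. File names
#' encode the node name (non \code{[A-Za-z0-9._-]} characters replaced by
#' \code{_}) and the hypothesis direction (\code{+} / \code{-}); name
#' collisions after escaping get a deterministic numeric suffix.
#'
#' @param ccg A [create_ccg()] object.
#' @param msig A [map_signature()] object (or bare named signature vector).
#' @param scan A [scan_hypotheses()] result.
#' @param delta Path length used for reconstruction; defaults to the
#'   largest scanned path length.
#' @param out_dir Output directory (created if needed).
#' @return Data frame with one row per consensus hypothesis: \code{NodeName},
#'   \code{Regulation}, \code{sif}, \code{annotations}.
#' @export
write_scan_networks <- function(ccg, msig, scan, delta = max(scan$deltas),
                                out_dir = ".") {
  stopifnot(inherits(scan, "scan_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cons <- scan$consensus
  if (nrow(cons) == 0L) {
    message("empty scan consensus; no networks written")
    return(data.frame(NodeName = character(0), Regulation = integer(0),
                      sif = character(0), annotations = character(0),
                      stringsAsFactors = FALSE))
  }
  base <- paste0(gsub("[^A-Za-z0-9._-]", "_", cons$NodeName),
                 sign_label(cons$Regulation))
  # deterministic numeric suffixes on collisions after escaping
  for (b in unique(base[duplicated(base)])) {
    hits <- which(base == b)
    base[hits[-1L]] <- paste0(b, "_", seq_along(hits[-1L]) + 1L)
  }
  sif_paths <- file.path(out_dir, paste0(base, ".sif"))
  ann_paths <- file.path(out_dir, paste0(base, "_annotations.txt"))
  for (r in seq_len(nrow(cons))) {
    net <- reconstruct_network(ccg, msig, cons$NodeName[[r]],
                               cons$Regulation[[r]], delta)
    write_explained_sif(net, sif_paths[[r]], ann_paths[[r]])
  }
  data.frame(NodeName = cons$NodeName, Regulation = cons$Regulation,
             sif = sif_paths, annotations = ann_paths,
             stringsAsFactors = FALSE)
}
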