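# Shared fixtures and independent oracles for the test suite.

edge_df <- function(source, sign, target) {
  data.frame(source = source, sign = as.integer(sign), target = target,
             stringsAsFactors = FALSE)
}

# A -> B (activation) -> C (inhibition)
chain_edges <- function() {
  edge_df(c("A", "B"), c(1L, -1L), c("B", "C"))
}

# A activates B and C; both activate D (two parallel length-2 branches)
diamond_edges <- function() {
  edge_df(c("A", "A", "B", "C"), c(1L, 1L, 1L, 1L), c("B", "C", "D", "D"))
}

write_sif_lines <- function(lines) {
  path <- tempfile(fileext = ".sif")
  writeLines(lines, path)
  path
}

write_sig_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# Enumerate the signed arcs of a CCG as (from entity, from sign, to entity,
# to sign) rows, for invariant checks by direct arc inspection.
ccg_arc_table <- function(ccg) {
  el <- igraph::as_edgelist(ccg$graph, names = FALSE)
  n <- length(ccg$entities)
  copy_sign <- function(v) ifelse(v <= n, 1L, -1L)
  data.frame(from = ccg$entities[(el[, 1] - 1L) %% n + 1L],
             from_sign = copy_sign(el[, 1]),
             to = ccg$entities[(el[, 2] - 1L) %% n + 1L],
             to_sign = copy_sign(el[, 2]),
             stringsAsFactors = FALSE)
}

# Achievable sign products along an entity path, multiplying input edge
# signs step by step (contradictory duplicate pairs contribute both signs).
path_sign_products <- function(edges, path) {
  prods <- 1L
  for (k in seq_len(length(path) - 1L)) {
    s <- unique(edges$sign[edges$source == path[[k]] &
                             edges$target == path[[k + 1L]]])
    stopifnot(length(s) > 0)
    prods <- unique(as.vector(outer(prods, s)))
  }
  prods
}

# Exhaustive-permutation p-value oracle: enumerates every distinct
# assignment of the observed value multiset to the genes (all equally
# likely) and takes the fraction achieving at least the observed score.
# Independent of the contingency-table summation it checks.
perm_pvalue_oracle <- function(pv, ov) {
  stopifnot(length(pv) == length(ov))
  if (length(ov) == 0L) return(1)
  s_obs <- sum(pv * ov)
  hits <- 0
  total <- 0
  rec <- function(remaining, assigned) {
    if (length(assigned) == length(pv)) {
      total <<- total + 1
      if (sum(pv * assigned) >= s_obs) hits <<- hits + 1
      return(invisible())
    }
    for (v in unique(remaining)) {
      rec(remaining[-match(v, remaining)], c(assigned, v))
    }
  }
  rec(ov, integer(0))
  hits / total
}

# Seeded random instance: network, CCG and a hypothesis node that has at
# least one outgoing edge (falling back to any entity).
random_instance <- function(seed, n_nodes = NULL, n_edges = NULL) {
  set.seed(seed)
  n_nodes <- n_nodes %||% sample(4:12, 1)
  n_edges <- n_edges %||% sample(n_nodes:(2L * n_nodes), 1)
  edges <- simulate_network(n_nodes, min(n_edges, n_nodes * (n_nodes - 1L)),
                            p_activation = 0.7, seed = seed + 1000L)
  ccg <- create_ccg(edges)
  outdeg <- table(factor(edges$source, levels = ccg$entities))
  list(edges = edges, ccg = ccg,
       hyp_node = names(outdeg)[[which.max(outdeg)]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
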