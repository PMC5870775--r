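test_that("sign propagation over small hand-built graphs", {
  ccg <- create_ccg(chain_edges())
  # activation then inhibition: C is predicted down at depth 2
  expect_equal(predict_regulation(ccg, "A", 1L, 2),
               c(A = 1L, B = 1L, C = -1L))
  # depth 1 stops before C
  expect_equal(predict_regulation(ccg, "A", 1L, 1), c(A = 1L, B = 1L))
  # a down hypothesis negates everything
  expect_equal(predict_regulation(ccg, "A", -1L, 2),
               c(A = -1L, B = -1L, C = 1L))
  # contradictory curation makes the target ambiguous
  both <- create_ccg(edge_df(c("A", "A"), c(1L, -1L), c("B", "B")))
  expect_equal(predict_regulation(both, "A", 1L, 1), c(A = 1L, B = 0L))
  expect_error(predict_regulation(ccg, "NOPE", 1L, 1), "NOPE")
})

test_that("cycles do not create spurious ambiguity", {
  ccg <- create_ccg(edge_df(c("A", "B"), c(1L, 1L), c("B", "A")))
  expect_equal(predict_regulation(ccg, "A", 1L, 3), c(A = 1L, B = 1L))
  expect_equal(oracle_predict(edge_df(c("A", "B"), c(1L, 1L), c("B", "A")),
                              "A", 1L, 3),
               c(A = 1L, B = 1L))
  # negative feedback does: A inhibits B, B activates A; at depth 3 the
  # walk A -> B -> A -> B reaches both copies of each node
  neg_edges <- edge_df(c("A", "B"), c(-1L, 1L), c("B", "A"))
  neg <- create_ccg(neg_edges)
  expect_equal(predict_regulation(neg, "A", 1L, 1), c(A = 1L, B = -1L))
  expect_equal(predict_regulation(neg, "A", 1L, 3), c(A = 0L, B = 0L))
  expect_equal(oracle_predict(neg_edges, "A", 1L, 3), c(A = 0L, B = 0L))
})

test_that("BFS prediction equals the walk-enumeration oracle on random graphs", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    delta <- sample(1:4, 1)
    for (s in c(1L, -1L)) {
      expect_identical(
        predict_regulation(inst$ccg, inst$hyp_node, s, delta),
        oracle_predict(inst$edges, inst$hyp_node, s, delta),
        info = sprintf("seed %d sign %d delta %d", seed, s, delta))
    }
  }
})

test_that("predictions are monotone in the path-length horizon", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    prev <- predict_regulation(inst$ccg, inst$hyp_node, 1L, 1)
    for (delta in 2:5) {
      cur <- predict_regulation(inst$ccg, inst$hyp_node, 1L, delta)
      expect_true(all(names(prev) %in% names(cur)))
      # a signed prediction may stay or become ambiguous, never flip
      signed <- names(prev)[prev != 0L]
      expect_true(all(cur[signed] == prev[signed] | cur[signed] == 0L))
      prev <- cur
    }
  }
})

test_that("match/mismatch scoring follows the counting contract", {
  msig <- structure(list(mapped = c(B = 1L, C = -1L)),
                    class = "mapped_signature")
  expect_equal(score_hypothesis(c(B = 1L, C = -1L), msig),
               list(score = 2L, correct = 2L, incorrect = 0L, ambiguous = 0L))
  expect_equal(score_hypothesis(c(B = 1L),
                                structure(list(mapped = c(B = -1L)),
                                          class = "mapped_signature"))$score,
               -1L)
  amb <- score_hypothesis(c(B = 0L),
                          structure(list(mapped = c(B = 1L)),
                                    class = "mapped_signature"))
  expect_equal(amb$score, 0L)
  expect_equal(amb$ambiguous, 1L)
  # zero-observed and unpredicted genes touch no counter
  none <- score_hypothesis(c(B = 1L), structure(list(mapped = c(B = 0L, Z = 1L)),
                                                class = "mapped_signature"))
  expect_equal(none, list(score = 0L, correct = 0L, incorrect = 0L,
                          ambiguous = 0L))
})

test_that("flipping the hypothesis sign negates the score and swaps counts", {
  for (seed in 1:15) {
    inst <- random_instance(seed)
    sig <- simulate_signature(inst$ccg, inst$hyp_node, 1L, delta = 2,
                              noise = 0.4, seed = seed)
    msig <- map_signature(sig, inst$ccg)
    for (node in inst$ccg$entities) {
      up <- score_hypothesis(predict_regulation(inst$ccg, node, 1L, 2), msig)
      dn <- score_hypothesis(predict_regulation(inst$ccg, node, -1L, 2), msig)
      expect_equal(dn$score, -up$score)
      expect_equal(dn$correct, up$incorrect)
      expect_equal(dn$incorrect, up$correct)
      expect_equal(dn$ambiguous, up$ambiguous)
    }
  }
})

test_that("degenerate permutation nulls give p = 1", {
  one <- structure(list(mapped = c(B = 1L)), class = "mapped_signature")
  expect_equal(score_significance(c(B = 1L), one, method = "exact"), 1)
  # empty signature
  empty <- structure(list(mapped = integer(0)), class = "mapped_signature")
  expect_equal(score_significance(c(B = 1L), empty), 1)
  # no gene predicted: score is always 0
  msig <- structure(list(mapped = c(B = 1L, C = -1L)),
                    class = "mapped_signature")
  expect_equal(score_significance(integer(0), msig, method = "exact"), 1)
})

test_that("the two-gene perfect match has exact p = 1/2", {
  msig <- structure(list(mapped = c(B = 1L, C = -1L)),
                    class = "mapped_signature")
  expect_equal(score_significance(c(B = 1L, C = -1L), msig,
                                  method = "exact"), 0.5)
})

test_that("exact p-values equal exhaustive-permutation p-values", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(2:8, 1)
    pv <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    ov <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    names(pv) <- names(ov) <- paste0("g", seq_len(n))
    msig <- structure(list(mapped = ov), class = "mapped_signature")
    p_exact <- score_significance(pv[pv != 0L], msig, method = "exact")
    expect_equal(p_exact, perm_pvalue_oracle(pv, ov), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("Monte Carlo p-values converge to the exact tail", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    pv <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    ov <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    names(pv) <- names(ov) <- paste0("g", seq_len(n))
    msig <- structure(list(mapped = ov), class = "mapped_signature")
    p_exact <- score_significance(pv, msig, method = "exact")
    p_mc <- score_significance(pv, msig, method = "montecarlo",
                               n_perm = 10000L, seed = seed)
    expect_lt(abs(p_mc - p_exact),
              3 * sqrt(p_exact * (1 - p_exact) / 10000) + 2e-4)
  }
})

test_that("auto method falls back to Monte Carlo over the table budget", {
  set.seed(7)
  n <- 10
  pv <- sample(c(-1L, 1L), n, replace = TRUE)
  ov <- sample(c(-1L, 1L), n, replace = TRUE)
  names(pv) <- names(ov) <- paste0("g", seq_len(n))
  msig <- structure(list(mapped = ov), class = "mapped_signature")
  p1 <- score_significance(pv, msig, method = "auto", max_tables = 1,
                           n_perm = 500L, seed = 11)
  p2 <- score_significance(pv, msig, method = "montecarlo",
                           n_perm = 500L, seed = 11)
  expect_equal(p1, p2)
})

test_that("hypergeometric enrichment matches the combinatorial tail", {
  # universe 4, 2 predicted, 2 changed, overlap 2 -> C(2,2)/C(4,2) = 1/6
  msig <- structure(list(mapped = c(a = 1L, b = -1L, c = 0L, d = 0L)),
                    class = "mapped_signature")
  expect_equal(enrichment_significance(c(a = 1L, b = 1L), msig), 1 / 6)
  # degenerate margins
  expect_equal(enrichment_significance(integer(0), msig), 1)
  all0 <- structure(list(mapped = c(a = 0L, b = 0L)),
                    class = "mapped_signature")
  expect_equal(enrichment_significance(c(a = 1L), all0), 1)
  # saturated margins force the overlap
  sat <- structure(list(mapped = c(a = 1L, b = -1L)),
                   class = "mapped_signature")
  expect_equal(enrichment_significance(c(a = 1L, b = 1L), sat), 1)
  expect_error(enrichment_significance(c(a = 1L), msig, universe = 2),
               "universe")
})

test_that("ranking a 2-node chain puts the true regulator on top", {
  ccg <- create_ccg(edge_df("A", 1L, "B"))
  msig <- map_signature(c(B = 1L), ccg)
  tbl <- rank_hypotheses(ccg, msig, delta = 1)
  expect_equal(nrow(tbl), 4L)  # 2 entities x 2 signs
  expect_equal(tbl$NodeName[[1]], "A")
  expect_equal(tbl$Regulation[[1]], 1L)
  expect_equal(tbl$Score[[1]], 1L)
  expect_equal(tbl$Rank, 1:4)
})

test_that("ranking table is antisymmetric in the hypothesis sign", {
  inst <- random_instance(3)
  sig <- simulate_signature(inst$ccg, inst$hyp_node, 1L, delta = 2,
                            noise = 0.2, seed = 3)
  tbl <- rank_hypotheses(inst$ccg, map_signature(sig, inst$ccg), delta = 2)
  up <- tbl[tbl$Regulation == 1L, ]
  dn <- tbl[tbl$Regulation == -1L, ]
  m <- match(up$NodeName, dn$NodeName)
  expect_equal(dn$Score[m], -up$Score)
  expect_equal(dn$Ambiguous[m], up$Ambiguous)
})

test_that("empty signatures rank all hypotheses at score 0, p 1, by name", {
  ccg <- create_ccg(chain_edges())
  msig <- suppressWarnings(map_signature(c(Q = 1L), ccg))
  tbl <- rank_hypotheses(ccg, msig, delta = 2)
  expect_true(all(tbl$Score == 0L))
  expect_true(all(tbl$PValue == 1))
  expect_equal(tbl$NodeName, rep(c("A", "B", "C"), each = 2))
})

test_that("ranking is deterministic and supports a node filter", {
  inst <- random_instance(9)
  sig <- simulate_signature(inst$ccg, inst$hyp_node, 1L, delta = 2, seed = 9)
  msig <- map_signature(sig, inst$ccg)
  t1 <- rank_hypotheses(inst$ccg, msig, delta = 2, p_method = "montecarlo",
                        n_perm = 200L, seed = 42)
  t2 <- rank_hypotheses(inst$ccg, msig, delta = 2, p_method = "montecarlo",
                        n_perm = 200L, seed = 42)
  expect_identical(t1, t2)
  sub <- rank_hypotheses(inst$ccg, msig, delta = 2,
                         nodes = inst$ccg$entities[1:2])
  expect_equal(nrow(sub), 4L)
  expect_error(rank_hypotheses(inst$ccg, msig, delta = 2, nodes = "NOPE"),
               "NOPE")
})

test_that("a noise-free planted signature ranks its regulator first", {
  for (seed in c(2, 12, 22)) {
    inst <- random_instance(seed, n_nodes = 15, n_edges = 30)
    sig <- simulate_signature(inst$ccg, inst$hyp_node, 1L, delta = 2,
                              coverage = 1, noise = 0, seed = seed)
    tbl <- rank_hypotheses(inst$ccg, map_signature(sig, inst$ccg), delta = 2,
                           p_method = "none")
    top_score <- tbl$Score[[1]]
    planted_row <- tbl[tbl$NodeName == inst$hyp_node & tbl$Regulation == 1L, ]
    expect_equal(planted_row$Score, top_score)
    expect_equal(planted_row$Incorrect, 0L)
  }
})
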