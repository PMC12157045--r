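test_that("move proposal enumerates exactly the legal neighborhood", {
  # empty 2-node graph: the only legal moves are the two additions
  d <- dag(c("A", "B"))
  set.seed(1)
  seen <- character(0)
  for (i in 1:50) {
    nd <- propose_move(d)
    mv <- attr(nd, "move")
    expect_equal(mv$type, "add")
    seen <- c(seen, paste(mv$from, mv$to))
    expect_true(is_acyclic(nd))
  }
  expect_setequal(seen, c("A B", "B A"))
  # cycle-creating reversal is excluded: chain A->B->C plus C->A is cyclic,
  # so on A->B, B->C the reversal of A->B stays legal but adding C->A is not
  ch <- dag(c("A", "B", "C"), arcs = rbind(c("A", "B"), c("B", "C")))
  set.seed(2)
  for (i in 1:200) {
    nd <- propose_move(ch)
    expect_true(is_acyclic(nd))
    mv <- attr(nd, "move")
    expect_false(mv$type == "add" && mv$from == "C" && mv$to == "A")
  }
  # single node: no legal move
  expect_null(propose_move(dag("A")))
})

test_that("move proposal is uniform over the legal set", {
  d <- dag(c("A", "B", "C"))  # 6 legal additions, nothing else
  set.seed(3)
  draws <- replicate(6000, {
    mv <- attr(propose_move(d), "move")
    paste(mv$from, mv$to)
  })
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  # each cell ~ Bin(6000, 1/6): 3 sigma is ~87
  expect_true(all(abs(tab - 1000) < 3 * sqrt(6000 * (1 / 6) * (5 / 6))))
})

test_that("annealing bookkeeping returns the best-ever structure", {
  sim <- make_piz_like_dataset(seed = 5, n_genes = 5, n_per_condition = 20)
  dd <- sim$states
  start <- dag(variables(dd))
  res <- anneal(dd, start, budget = 500, seed = 7)
  expect_true(is_acyclic(res$dag))
  expect_gte(res$log_score, bde_network_score(start, dd)$log_score)
  expect_equal(res$log_score, bde_network_score(res$dag, dd)$log_score,
               tolerance = 1e-9)
  # determinism
  res2 <- anneal(dd, start, budget = 500, seed = 7)
  expect_identical(res$dag$amat, res2$dag$amat)
  expect_equal(res$log_score, res2$log_score)
})

test_that("near-zero temperature degenerates to hill climbing", {
  sim <- make_piz_like_dataset(seed = 6, n_genes = 4, n_per_condition = 25)
  dd <- sim$states
  res <- anneal(dd, dag(variables(dd)), budget = 1500, init_temp = 1e-12,
                cooling = 0.999, seed = 9)
  # with T ~ 0 only improvements are accepted, so the best equals the final
  # current state and must be a local optimum under single moves
  base <- res$log_score
  for (mv in bdenet:::legal_moves_raw(res$dag$amat[variables(dd), variables(dd)])) {
    nd <- res$dag
    nd$amat <- bdenet:::apply_move(nd$amat, mv)
    expect_lte(bde_network_score(nd, dd)$log_score, base + 1e-9)
  }
})

test_that("a round picks the champion by normalized score with derived seeds", {
  sim <- make_piz_like_dataset(seed = 11, n_genes = 4, n_per_condition = 15)
  dd <- sim$states
  res <- run_round(dd, budget = 300, searches = 3, seed = 13, round = 1)
  expect_equal(nrow(res$records), 3L)
  expect_false(anyDuplicated(res$records$seed) > 0)
  expect_equal(res$normalized_score, max(res$records$normalized_score))
  expect_equal(res$champion, which.max(res$records$normalized_score))
  # n = 1 reduces to a single anneal
  one <- run_round(dd, budget = 300, searches = 1, seed = 13, round = 1)
  direct <- anneal(dd, dag(variables(dd)), budget = 300,
                   seed = bdenet:::derive_seed(13, 1, 1))
  expect_identical(one$dag$amat, direct$dag$amat)
})

test_that("the stopping rule and budget schedule follow the doubling protocol", {
  # 10% improvement concludes the search; 20% continues
  expect_true(protocol_stop_decision(-10, -9)$stop)
  expect_equal(protocol_stop_decision(-10, -9)$improvement, 0.10)
  expect_false(protocol_stop_decision(-10, -8)$stop)
  expect_equal(protocol_stop_decision(-10, -8)$improvement, 0.20)
  expect_equal(protocol_budgets(2, 3), c(2L, 4L, 8L))
  # a real run logs budgets B, 2B, 4B, ... and monotone champion scores
  sim <- make_piz_like_dataset(seed = 15, n_genes = 5, n_per_condition = 10)
  fit <- run_protocol(sim$states, budget = 150, searches = 2, max_rounds = 4,
                      seed = 17)
  rounds <- fit$trace$rounds
  budgets <- vapply(rounds, `[[`, integer(1), "budget")
  expect_equal(budgets, protocol_budgets(150, length(rounds)))
  scores <- vapply(rounds, `[[`, numeric(1), "normalized_score")
  expect_true(all(diff(scores) >= -1e-12))
  expect_true(rounds[[length(rounds)]]$stopped)
  # determinism of the whole protocol
  fit2 <- run_protocol(sim$states, budget = 150, searches = 2, max_rounds = 4,
                       seed = 17)
  expect_identical(fit$dag$amat, fit2$dag$amat)
  expect_identical(fit$trace$rounds, fit2$trace$rounds)
})

test_that("exhaustive enumeration counts DAGs correctly and returns the maximum", {
  dd3 <- random_test_data(30, c(A = 2L, B = 3L, C = 2L), seed = 19)
  ex3 <- exhaustive_search(dd3)
  expect_equal(ex3$n_dags, 25L)
  expect_equal(ex3$log_score, max(ex3$scores), tolerance = 1e-12)
  expect_equal(bde_network_score(ex3$dag, dd3)$log_score, ex3$log_score,
               tolerance = 1e-9)
  dd4 <- random_test_data(25, c(A = 2L, B = 2L, C = 3L, D = 2L), seed = 20)
  expect_equal(exhaustive_search(dd4)$n_dags, 543L)
  toolarge <- random_test_data(5, stats::setNames(rep(2L, 6), LETTERS[1:6]))
  expect_error(exhaustive_search(toolarge), "refused")
})

test_that("independent variables leave the empty graph near the optimum", {
  set.seed(23)
  dd <- discrete_data(cbind(A = sample(0:1, 500, TRUE), B = sample(0:1, 500, TRUE)),
                      arity = c(A = 2L, B = 2L))
  ex <- exhaustive_search(dd)
  expect_equal(ex$n_dags, 3L)
  empty_score <- bde_network_score(dag(c("A", "B")), dd)$log_score
  expect_lt(ex$log_score - empty_score, 1)
})

test_that("refinement keeps the target's extended blanket plus interest genes", {
  sim <- make_piz_like_dataset(seed = 25, n_genes = 12, n_per_condition = 10)
  dd <- sim$states
  first <- run_protocol(dd, budget = 400, searches = 2, seed = 27)
  interest <- c("G001", "G002")
  ref <- refine_and_research(dd, first, target = "PiZ",
                             genes_of_interest = interest,
                             budget = 200, searches = 2, seed = 29)
  expected <- union(union(second_degree_mb(first$dag, "PiZ"), interest), "PiZ")
  expect_setequal(variables(ref$data), expected)
  expect_setequal(ref$model$dag$nodes, expected)
  # true-blanket containment: reducing on the true structure keeps its MB2
  truth_model <- fit_cpts(sim$truth$dag, dd)
  ref2 <- refine_and_research(dd, truth_model, target = "PiZ",
                              budget = 200, searches = 2, seed = 31)
  expect_true(all(second_degree_mb(sim$truth$dag, "PiZ") %in%
                    variables(ref2$data)))
  # degenerate case: no blanket, no interest -> just the target
  lone <- fit_cpts(dag(variables(dd)), dd)
  ref3 <- refine_and_research(dd, lone, target = "PiZ", budget = 100,
                              searches = 1, seed = 33)
  expect_equal(variables(ref3$data), "PiZ")
  expect_equal(n_arcs(ref3$model$dag), 0L)
  expect_error(refine_and_research(dd, first, target = "nope"), "unknown target")
})
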