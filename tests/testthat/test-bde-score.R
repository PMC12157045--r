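test_that("validate_dag reports cycles instead of throwing", {
  d <- dag(c("A", "B", "C"), arcs = rbind(c("A", "B"), c("B", "C")))
  expect_true(validate_dag(d)$ok)
  expect_true(validate_dag(dag("A"))$ok)
  bad <- dag(c("A", "B"))
  bad$amat["A", "B"] <- 1L
  bad$amat["B", "A"] <- 1L
  rep <- validate_dag(bad)
  expect_false(rep$ok)
  expect_setequal(rep$cycle, c("A", "B"))
})

test_that("family counts tabulate exactly and conserve the sample total", {
  dd <- discrete_data(cbind(P = c(0L, 0L, 1L, 1L), X = c(0L, 1L, 2L, 2L)),
                      arity = c(P = 2L, X = 3L))
  fc <- family_counts(dd, "P")
  expect_equal(fc$N, matrix(c(2L, 2L), 1, 2))
  fcx <- family_counts(dd, "X", "P")
  expect_equal(fcx$q, 2L)
  # rows are parent configs (P = 0, 1), columns states 0..2
  expect_equal(fcx$N, matrix(c(1L, 0L, 1L, 0L, 0L, 2L), 2, 3))
  expect_equal(sum(fcx$N), 4L)
  expect_error(family_counts(dd, "Z"), "unknown")
  # conservation on random data
  rd <- random_test_data(37, c(A = 3L, B = 2L, C = 3L), seed = 5)
  expect_equal(sum(family_counts(rd, "B", c("A", "C"))$N), 37L)
})

test_that("BDe family score equals the Dirichlet-multinomial closed form", {
  dd <- discrete_data(matrix(c(0L, 0L, 1L), 3, 1, dimnames = list(NULL, "P")),
                      arity = c(P = 2L))
  got <- bde_family_score(family_counts(dd, "P"), ess = 1)
  # sequential-predictive oracle: (0.5/1)(1.5/2)(0.5/3) = 1/16
  expect_equal(got, log(oracle_dirichlet_multinomial(c(0L, 0L, 1L), 2, 0.5)),
               tolerance = 1e-12)
  expect_equal(exp(got), 0.0625, tolerance = 1e-12)
  # zero observations score 0 (empty product)
  empty <- discrete_data(matrix(integer(0), 0, 1, dimnames = list(NULL, "P")),
                         arity = c(P = 2L))
  expect_equal(bde_family_score(family_counts(empty, "P")), 0)
  # oracle holds across random single-family cases and ess values
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(0:2, 12, TRUE)
    ess <- sample(c(0.5, 1, 4), 1)
    ddx <- discrete_data(matrix(x, ncol = 1, dimnames = list(NULL, "X")),
                         arity = c(X = 3L))
    expect_equal(bde_family_score(family_counts(ddx, "X"), ess),
                 log(oracle_dirichlet_multinomial(x, 3, ess / 3)),
                 tolerance = 1e-10)
  }
})

test_that("a constant never-varying parent changes the score only via the prior split", {
  set.seed(21)
  x <- sample(0:2, 30, TRUE)
  dd <- discrete_data(cbind(X = x, C = rep(0L, 30)), arity = c(X = 3L, C = 3L))
  with_parent <- bde_family_score(family_counts(dd, "X", "C"), ess = 1)
  # oracle: only the j = 1 configuration holds data; its pseudo-counts are
  # ess/(q*r) with q = 3, plus two empty configurations contributing 0
  expect_equal(with_parent,
               log(oracle_dirichlet_multinomial(x, 3, 1 / 9)),
               tolerance = 1e-10)
})

test_that("network score is decomposable and the empty graph sums marginals", {
  dd <- random_test_data(50, c(A = 3L, B = 3L), seed = 8)
  d_arc <- dag(c("A", "B"), arcs = cbind("A", "B"))
  sc <- bde_network_score(d_arc, dd)
  expect_equal(sc$log_score,
               bde_family_score(family_counts(dd, "A")) +
                 bde_family_score(family_counts(dd, "B", "A")),
               tolerance = 1e-12)
  expect_equal(sc$normalized_score, sc$log_score / (50 * 2), tolerance = 1e-12)
  d0 <- dag(c("A", "B"))
  expect_equal(bde_network_score(d0, dd)$log_score,
               log(oracle_dirichlet_multinomial(dd$states[, "A"], 3, 1 / 3)) +
                 log(oracle_dirichlet_multinomial(dd$states[, "B"], 3, 1 / 3)),
               tolerance = 1e-10)
})

test_that("scores are exchangeable over sample order", {
  dd <- random_test_data(40, c(A = 3L, B = 2L, C = 3L), seed = 12)
  perm <- sample(40)
  dd2 <- discrete_data(dd$states[perm, ], dd$arity)
  d <- dag(c("A", "B", "C"), arcs = rbind(c("A", "B"), c("C", "B")))
  expect_equal(bde_network_score(d, dd)$log_score,
               bde_network_score(d, dd2)$log_score, tolerance = 1e-12)
})

test_that("posterior-mean CPTs have the prior mean, consistency, and ML limits", {
  # no data -> uniform rows
  empty <- discrete_data(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("A", "B"))),
                         arity = c(A = 3L, B = 3L))
  fit0 <- fit_cpts(dag(c("A", "B"), arcs = cbind("A", "B")), empty)
  expect_equal(fit0$cpts$A, matrix(1 / 3, 1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit0$cpts$B, matrix(1 / 3, 3, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # rows sum to 1 and, on well-observed parent configurations, approach the
  # generating CPTs at large n (rarely-visited rows stay near the prior)
  d <- sample_ground_truth_dag(4, max_parents = 2, edge_prob = 0.5, seed = 2)
  cpts <- sample_cpts(d, concentration = 2, seed = 3)
  truth <- synthetic_truth(d, cpts, stats::setNames(rep(100, 4), sprintf("G%03d", 1:4)))
  st <- sample_discrete_states(truth, 4000, seed = 4)
  fit <- fit_cpts(truth$dag, st)
  for (v in d$nodes) {
    expect_lt(max(abs(rowSums(fit$cpts[[v]]) - 1)), 1e-12)
    if (v == "PiZ") next  # fixed by the two-arm design, not drawn from its CPT
    n_ij <- rowSums(family_counts(st, v, parents(d, v))$N)
    seen <- n_ij >= 200
    if (any(seen)) {
      tv <- max(rowSums(abs(fit$cpts[[v]] - cpts[[v]]))[seen] / 2)
      expect_lt(tv, 0.05)
    }
  }
  # ess -> 0: frequencies on observed configurations
  dd <- discrete_data(cbind(A = c(0L, 0L, 1L, 2L)), arity = c(A = 3L))
  tiny <- fit_cpts(dag("A"), dd, ess = 1e-10)
  expect_equal(unname(tiny$cpts$A[1, ]), c(0.5, 0.25, 0.25), tolerance = 1e-8)
})

test_that("edge annotation assigns sign by ordinal association and small strength to noise", {
  set.seed(6)
  x <- sample(0:2, 200, TRUE)
  flip <- ifelse(x == 1L, 2L, ifelse(x == 2L, 1L, 0L))  # low <-> high
  dd <- discrete_data(cbind(A = x, B = x, C = flip, D = sample(0:2, 200, TRUE)))
  d <- dag(c("A", "B", "C", "D"),
           arcs = rbind(c("A", "B"), c("A", "C"), c("A", "D")))
  model <- annotate_edges(fit_cpts(d, dd), dd)
  ed <- model$edges
  expect_equal(ed$sign[ed$child == "B"], "+")  # child copies parent
  expect_equal(ed$sign[ed$child == "C"], "-")  # state-reversed parent
  # independent child: the arc is not score-improving (its "strength" is the
  # negative Ockham penalty the marginal likelihood charges a useless parent)
  expect_lt(ed$strength[ed$child == "D"], 0)
  expect_gt(ed$strength[ed$child == "D"], -20)
  # strongly coupled child: deleting the arc costs real likelihood
  expect_gt(ed$strength[ed$child == "B"], 0)
  # strengths are recomputable score drops
  full <- bde_network_score(d, dd)$log_score
  without <- bde_network_score(remove_arc(d, "A", "B"), dd)$log_score
  expect_equal(ed$strength[ed$child == "B"], full - without, tolerance = 1e-10)
})
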