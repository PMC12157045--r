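hand_chain_model <- function() {
  # A -> B with P(A=1) = 0.6, P(B=1|A=1) = 0.9, P(B=1|A=0) = 0.2
  d <- dag(c("A", "B"), arcs = cbind("A", "B"))
  cpA <- matrix(c(0.4, 0.6), 1, 2)
  attr(cpA, "parents") <- character(0)
  cpB <- matrix(c(0.8, 0.1, 0.2, 0.9), 2, 2)
  attr(cpB, "parents") <- "A"
  as_bdenet(d, list(A = cpA, B = cpB), c(A = 2L, B = 2L))
}

test_that("joint probabilities multiply CPT entries and normalize", {
  one <- as_bdenet(dag("A"), list(A = structure(matrix(c(0.6, 0.4), 1, 2),
                                               parents = character(0))),
                   c(A = 2L))
  expect_equal(joint_probability(one, c(A = 0)), 0.6)
  m <- hand_chain_model()
  expect_equal(joint_probability(m, c(A = 1, B = 1)), 0.6 * 0.9, tolerance = 1e-12)
  # sums to one over all assignments
  model <- random_test_model(6, seed = 41)
  jt <- oracle_joint(model)
  total <- sum(vapply(seq_len(nrow(jt$grid)), function(i)
    joint_probability(model, jt$grid[i, ]), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)
  expect_error(joint_probability(m, c(A = 1)), "cover every variable")
})

test_that("conditional queries match Bayes' rule and clamped point masses", {
  m <- hand_chain_model()
  expect_equal(bn_query(m, "A", c(B = 1))[["1"]], 27 / 31, tolerance = 1e-12)
  # no evidence: ancestral marginal
  expect_equal(unname(bn_query(m, "B")), c(0.8 * 0.4 + 0.1 * 0.6,
                                           0.2 * 0.4 + 0.9 * 0.6),
               tolerance = 1e-12)
  # querying a clamped variable returns a point mass
  expect_equal(unname(bn_query(m, "B", c(B = 0))), c(1, 0))
})

test_that("variable elimination agrees with brute-force joint summation", {
  for (i in 1:50) {
    n <- sample(3:10, 1)
    model <- random_test_model(n, seed = 200 + i,
                               p = stats::runif(1, 0.15, 0.45))
    vars <- model$dag$nodes
    # single-target marginal, no evidence
    v <- sample(vars, 1)
    expect_equal(unname(bn_query(model, v)),
                 oracle_query(model, v), tolerance = 1e-9)
    # single target given 1-2 evidence variables
    ev_vars <- sample(setdiff(vars, v), sample(1:2, 1))
    ev <- vapply(ev_vars, function(w)
      sample.int(model$arity[[w]], 1) - 1L, integer(1))
    p_ev <- prob_of_evidence(model, ev)
    if (p_ev > 1e-12) {
      expect_equal(unname(bn_query(model, v, ev)),
                   oracle_query(model, v, ev), tolerance = 1e-9)
    }
    # two-target joint given evidence (when enough variables remain)
    pool <- setdiff(vars, ev_vars)
    if (length(pool) < 2L) next
    t2 <- sample(pool, 2)
    if (p_ev > 1e-12) {
      got <- bn_query(model, t2, ev)
      expect_equal(as.vector(got), oracle_query(model, t2, ev),
                   tolerance = 1e-9)
      expect_equal(sum(got), 1, tolerance = 1e-9)
    }
  }
})

test_that("impossible evidence raises the dedicated error", {
  d <- dag(c("A", "B"), arcs = cbind("A", "B"))
  cpA <- matrix(c(1, 0), 1, 2)   # A is always 0
  attr(cpA, "parents") <- character(0)
  cpB <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  attr(cpB, "parents") <- "A"
  m <- as_bdenet(d, list(A = cpA, B = cpB), c(A = 2L, B = 2L))
  expect_error(bn_query(m, "B", c(A = 1)), class = "bdenet_impossible_evidence")
  expect_error(simulate_scenario(m, c(A = 1)),
               class = "bdenet_impossible_evidence")
})

test_that("scenario simulation reports exact marginals and honors d-separation", {
  # PiZ disconnected from G: clamping PiZ leaves G's marginal untouched
  d <- dag(c("G", "H", "PiZ"), arcs = cbind("G", "H"))
  set.seed(51)
  cpG <- matrix(c(0.5, 0.2, 0.3), 1, 3)
  attr(cpG, "parents") <- character(0)
  cpH <- matrix(stats::rgamma(9, 1), 3, 3)
  cpH <- cpH / rowSums(cpH)
  attr(cpH, "parents") <- "G"
  cpP <- matrix(c(0.5, 0.5), 1, 2)
  attr(cpP, "parents") <- character(0)
  m <- as_bdenet(d, list(G = cpG, H = cpH, PiZ = cpP))
  base <- predict(m, targets = c("G", "H"))
  clamped <- simulate_scenario(m, c(PiZ = 1), targets = c("G", "H"))
  expect_equal(clamped$p0, base$p0, tolerance = 1e-9)
  expect_equal(clamped$p2, base$p2, tolerance = 1e-9)
  # rows are distributions
  model <- random_test_model(6, seed = 61)
  ev_var <- model$dag$nodes[1]
  tab <- simulate_scenario(model, stats::setNames(0L, ev_var))
  sums <- rowSums(cbind(tab$p0, tab$p1, ifelse(is.na(tab$p2), 0, tab$p2)))
  expect_equal(sums, rep(1, nrow(tab)), tolerance = 1e-9)
  # oracle check on a clamped 3-node chain
  ch <- simulate_scenario(m, c(G = 2), targets = "H")
  expect_equal(unlist(ch[, c("p0", "p1", "p2")], use.names = FALSE),
               oracle_query(m, "H", c(G = 2)), tolerance = 1e-12)
  # side-by-side contrast keeps both scenarios aligned
  con <- scenario_contrast(m, c(PiZ = 1), c(PiZ = 0), targets = c("G", "H"))
  expect_equal(con$p0_a, con$p0_b, tolerance = 1e-9)  # PiZ is disconnected
})

test_that("state combinations enumerate, normalize, and rank deterministically", {
  # two independent uniform ternary genes: all 9 pairs tie at 1/9,
  # ranking falls back to lexicographic order
  u <- matrix(1 / 3, 1, 3)
  attr(u, "parents") <- character(0)
  d <- dag(c("A", "B"))
  m <- as_bdenet(d, list(A = u, B = u), c(A = 3L, B = 3L))
  res <- top_state_combinations(m, c("A", "B"), k = 2)
  expect_equal(nrow(res), 9L)
  expect_equal(res$p_given_evidence, rep(1 / 9, 9), tolerance = 1e-12)
  expect_equal(res$states[1:3], c("0,0", "0,1", "0,2"))  # lexicographic ties
  # partition: probabilities of the 3^k assignments of one pair sum to 1
  model <- random_test_model(5, seed = 71)
  genes <- model$dag$nodes[model$arity == 3L][1:2]
  ev_var <- model$dag$nodes[model$arity == 2L][1]
  res2 <- top_state_combinations(model, genes, k = 2,
                                 evidence = stats::setNames(0L, ev_var))
  expect_equal(sum(res2$p_given_evidence), 1, tolerance = 1e-9)
  # forced state: a gene deterministically high under evidence tops every pair
  df <- dag(c("PiZ", "F", "X"), arcs = rbind(c("PiZ", "F")))
  cpF <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3)  # PiZ=0 -> state 0; PiZ=1 -> state 2
  attr(cpF, "parents") <- "PiZ"
  cpP <- matrix(c(0.5, 0.5), 1, 2)
  attr(cpP, "parents") <- character(0)
  cpX <- matrix(c(0.6, 0.3, 0.1), 1, 3)
  attr(cpX, "parents") <- character(0)
  mf <- as_bdenet(df, list(PiZ = cpP, F = cpF, X = cpX))
  resf <- top_state_combinations(mf, c("F", "X"), k = 2, evidence = c(PiZ = 1))
  top <- resf[resf$p_given_evidence >= max(resf$p_given_evidence) - 1e-12, ]
  expect_true(all(vapply(strsplit(top$states, ","),
                         function(s) s[1] == "2", logical(1))))
  # reverse conditional is a genuine probability
  expect_true(all(resf$p_evidence_given_states >= -1e-12 &
                    resf$p_evidence_given_states <= 1 + 1e-12))
  expect_error(top_state_combinations(mf, "F", k = 2), "exceeds")
})

test_that("covering all candidates with empty evidence reproduces the joint mode", {
  model <- random_test_model(4, seed = 81)
  vars <- model$dag$nodes
  res <- top_state_combinations(model, vars, k = length(vars))
  jt <- oracle_joint(model)
  expect_equal(res$p_given_evidence[1], max(jt$p), tolerance = 1e-9)
  mode_states <- jt$grid[which.max(jt$p), vars]
  expect_equal(res$states[1], paste(mode_states, collapse = ","))
})

test_that("the minimal gene set is the smallest k crossing the threshold", {
  df <- dag(c("PiZ", "F", "X"), arcs = rbind(c("PiZ", "F")))
  cpF <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3)
  attr(cpF, "parents") <- "PiZ"
  cpP <- matrix(c(0.5, 0.5), 1, 2)
  attr(cpP, "parents") <- character(0)
  cpX <- matrix(c(0.6, 0.3, 0.1), 1, 3)
  attr(cpX, "parents") <- character(0)
  mf <- as_bdenet(df, list(PiZ = cpP, F = cpF, X = cpX))
  ms <- minimal_gene_set(mf, c("F", "X"), evidence = c(PiZ = 1), threshold = 0.5)
  expect_equal(ms$k, 1L)  # F alone is deterministic given PiZ = 1
  expect_equal(ms$top$variables, "F")
})
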