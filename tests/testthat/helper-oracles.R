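# Independent oracles and fixture builders. Everything here avoids the
# package's own inference/scoring code paths wherever it is used to check
# them: the joint is built by grid multiplication, blankets by direct set
# algebra on the adjacency matrix, and marginal likelihoods by the
# sequential predictive (chain-rule) product.

# full joint table by direct grid multiplication (no variable elimination)
oracle_joint <- function(model) {
  vars <- model$dag$nodes
  arity <- model$arity
  grid <- as.matrix(expand.grid(lapply(arity[vars], function(r) 0:(r - 1L))))
  colnames(grid) <- vars
  p <- rep(1, nrow(grid))
  for (v in vars) {
    cpt <- model$cpts[[v]]
    pa <- attr(cpt, "parents")
    j <- if (length(pa)) {
      strides <- cumprod(c(1L, unname(arity[pa])))[seq_along(pa)]
      1L + as.vector(grid[, pa, drop = FALSE] %*% strides)
    } else rep(1L, nrow(grid))
    p <- p * cpt[cbind(j, grid[, v] + 1L)]
  }
  list(grid = grid, p = p)
}

# P(targets | evidence) by filtering and summing the full joint table
oracle_query <- function(model, targets, evidence = NULL) {
  jt <- oracle_joint(model)
  keep <- rep(TRUE, nrow(jt$grid))
  for (v in names(evidence)) keep <- keep & jt$grid[, v] == evidence[[v]]
  if (sum(jt$p[keep]) <= 0) stop("oracle: impossible evidence")
  grid <- jt$grid[keep, , drop = FALSE]
  p <- jt$p[keep]
  key <- apply(grid[, targets, drop = FALSE], 1L, paste, collapse = ",")
  agg <- tapply(p, key, sum)
  full <- as.matrix(expand.grid(lapply(model$arity[targets], function(r) 0:(r - 1L))))
  allkey <- apply(full, 1L, paste, collapse = ",")
  out <- as.numeric(agg[allkey])
  out[is.na(out)] <- 0
  out / sum(out)
}

# marginal likelihood of a single categorical sample vector under a
# symmetric Dirichlet, via the sequential predictive product
oracle_dirichlet_multinomial <- function(x, r, alpha) {
  seen <- rep(0, r)
  p <- 1
  for (t in seq_along(x)) {
    k <- x[t] + 1L
    p <- p * (alpha + seen[k]) / (r * alpha + t - 1)
    seen[k] <- seen[k] + 1
  }
  p
}

# first-degree Markov blanket by direct set algebra on the adjacency matrix
oracle_mb1 <- function(amat, x) {
  nodes <- rownames(amat)
  pa <- nodes[amat[, x] == 1L]
  ch <- nodes[amat[x, ] == 1L]
  co <- unique(unlist(lapply(ch, function(c) nodes[amat[, c] == 1L])))
  setdiff(unique(c(pa, ch, co)), x)
}

# random DAG on n plain nodes via a random topological order
random_test_dag <- function(n, p = 0.3, seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n))
  ord <- sample(nodes)
  d <- dag(nodes)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (stats::runif(1) < p) d$amat[ord[i], ord[j]] <- 1L
  }
  d
}

# random fitted-style model with Dirichlet CPTs over mixed-arity variables
random_test_model <- function(n, seed = 1L, p = 0.35, concentration = 1) {
  d <- random_test_dag(n, p, seed)
  arity <- stats::setNames(rep(3L, n), d$nodes)
  arity[seq(1L, n, by = 3L)] <- 2L  # mix in some binary variables
  set.seed(seed + 1000L)
  cpts <- lapply(d$nodes, function(v) {
    pa <- parents(d, v)
    q <- if (length(pa)) prod(arity[pa]) else 1L
    tab <- matrix(stats::rgamma(q * arity[[v]], concentration), q, arity[[v]])
    tab <- tab / rowSums(tab)
    attr(tab, "parents") <- pa
    tab
  })
  names(cpts) <- d$nodes
  as_bdenet(d, cpts, arity)
}

# small random discrete dataset with given arities
random_test_data <- function(n_samples, arity, seed = 1L) {
  set.seed(seed)
  states <- vapply(arity, function(r) sample.int(r, n_samples, replace = TRUE) - 1L,
                   integer(n_samples))
  discrete_data(states, arity)
}
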