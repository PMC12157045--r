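#' Sample a ground-truth DAG for synthetic expression data
#'
#' Draws a random DAG over `n_genes` gene variables plus one binary condition
#' variable (named `"PiZ"`, last in the node list). The condition node is a
#' root: the experimental genotype is an intervention, never a downstream
#' effect. The structure learner is not told this. Genes receive arcs from the
#' condition node and from genes earlier in a random topological order, each
#' independently with probability `edge_prob`, subject to `max_parents`.
#'
#' @param n_genes number of gene variables (>= 1).
#' @param max_parents cap on each gene's in-degree (condition arcs count).
#' @param edge_prob per-candidate-arc inclusion probability.
#' @param seed integer seed; identical seeds give identical graphs.
#' @return a [dag()] over `n_genes + 1` variables.
#' @export
sample_ground_truth_dag <- function(n_genes, max_parents = 3L, edge_prob = 0.05,
                                    seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be a positive integer")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  if (max_parents < 0) stop("max_parents must be >= 0")
  genes <- sprintf("G%03d", seq_len(n_genes))
  d <- dag(c(genes, "PiZ"))
  with_seed(seed, {
    topo <- c("PiZ", sample(genes))
    for (k in seq_along(topo)[-1L]) {
      child <- topo[k]
      cand <- sample(topo[seq_len(k - 1L)])
      indeg <- 0L
      for (p in cand) {
        if (indeg >= max_parents) break
        if (stats::runif(1L) < edge_prob) {
          d$amat[p, child] <- 1L
          indeg <- indeg + 1L
        }
      }
    }
  })
  d
}

node_arities <- function(d) {
  arity <- ifelse(d$nodes == "PiZ", 2L, 3L)
  names(arity) <- d$nodes
  arity
}

# mixed-radix parent-configuration index, first parent varying fastest;
# `codes` is a samples x parents matrix of 0-based codes
config_index <- function(codes, arity) {
  j <- rep(1L, nrow(codes))
  stride <- 1L
  for (t in seq_along(arity)) {
    j <- j + codes[, t] * stride
    stride <- stride * arity[[t]]
  }
  j
}

#' Sample conditional probability tables from a symmetric Dirichlet
#'
#' For every variable and every parent configuration, draws a probability
#' vector from a symmetric Dirichlet with the given concentration. Large
#' concentrations give near-uniform rows; small ones give skewed,
#' near-deterministic rows. Gene variables have arity 3 (codes 1 = low,
#' 0 = no change, 2 = high), the condition node arity 2.
#'
#' @param d a [dag()] (from [sample_ground_truth_dag()] or built by hand).
#' @param concentration positive Dirichlet concentration parameter.
#' @param seed integer seed.
#' @return named list of CPT matrices, one per node: `q x r` with rows indexed
#'   by parent configuration (mixed-radix, first parent fastest) and columns
#'   by state index; each row sums to 1.
#' @export
sample_cpts <- function(d, concentration = 1, seed = 1L) {
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be > 0")
  if (!is_acyclic(d)) stop("dag must be acyclic")
  arity <- node_arities(d)
  with_seed(seed, {
    cpts <- lapply(d$nodes, function(v) {
      pa <- parents(d, v)
      q <- prod(arity[pa])
      r <- arity[[v]]
      tab <- matrix(stats::rgamma(q * r, shape = concentration), q, r)
      tab <- tab / rowSums(tab)
      attr(tab, "parents") <- pa
      tab
    })
    names(cpts) <- d$nodes
  })
  cpts
}

#' Sample regulatory-style conditional probability tables
#'
#' A structured alternative to [sample_cpts()] that mimics how differential
#' expression presents in bulk RNA-seq: each gene has a characteristic
#' response direction (repressed, code 1, or induced, code 2), sits at
#' baseline ("no change") when all its parents are at baseline, and shifts
#' toward its response state when any parent is perturbed. Rows are supported
#' on \{baseline, response\} only, so a gene never jumps in the direction
#' opposite to its own regulation.
#'
#' @param d a [dag()] whose condition node (if present) is named `"PiZ"`.
#' @param baseline_prob probability of "no change" when all parents are at
#'   baseline.
#' @param response_prob probability of the response state when at least one
#'   parent is perturbed; scalar or named per-gene vector.
#' @param directions optional named vector of response states (1 or 2) per
#'   gene; by default drawn uniformly.
#' @param seed integer seed (used only when `directions` is NULL).
#' @return named list of CPT matrices as in [sample_cpts()].
#' @export
sample_regulatory_cpts <- function(d, baseline_prob = 0.9, response_prob = 0.6,
                                   directions = NULL, seed = 1L) {
  stopifnot(baseline_prob > 0, baseline_prob <= 1,
            all(response_prob > 0), all(response_prob <= 1))
  arity <- node_arities(d)
  genes <- d$nodes[arity == 3L]
  if (is.null(directions)) {
    directions <- with_seed(seed, sample(c(1L, 2L), length(genes), replace = TRUE))
    names(directions) <- genes
  }
  if (!all(genes %in% names(directions)) || !all(directions[genes] %in% c(1L, 2L)))
    stop("directions must assign 1 or 2 to every gene")
  resp <- if (length(response_prob) == 1L) {
    stats::setNames(rep(response_prob, length(genes)), genes)
  } else response_prob
  cpts <- lapply(d$nodes, function(v) {
    pa <- parents(d, v)
    q <- prod(arity[pa])
    r <- arity[[v]]
    if (r == 2L) {
      tab <- matrix(0.5, q, r)  # condition node: balanced two-arm design
    } else {
      dstate <- directions[[v]]
      tab <- matrix(0, q, r)
      if (q == 1L) {
        tab[1L, 0L + 1L] <- baseline_prob
        tab[1L, dstate + 1L] <- 1 - baseline_prob
      } else {
        grid <- as.matrix(expand.grid(lapply(arity[pa], function(rr) 0:(rr - 1L))))
        active <- rowSums(grid != 0L) > 0L  # grid rows follow the mixed-radix order
        tab[!active, 0L + 1L] <- baseline_prob
        tab[!active, dstate + 1L] <- 1 - baseline_prob
        tab[active, dstate + 1L] <- resp[[v]]
        tab[active, 0L + 1L] <- 1 - resp[[v]]
      }
    }
    attr(tab, "parents") <- pa
    tab
  })
  names(cpts) <- d$nodes
  cpts
}

#' Ground truth for synthetic count data
#'
#' Bundles a DAG, its CPTs and the count-generation parameters so that every
#' downstream stage (discretization, structure learning, blanket extraction)
#' can be checked against a known answer.
#'
#' @param dag a [dag()] with condition node `"PiZ"`.
#' @param cpts CPT list from [sample_cpts()] or [sample_regulatory_cpts()].
#' @param baseline_mu named positive vector of per-gene baseline means.
#' @param fold state fold-factor f > 1: counts are drawn around mu/f, mu, or
#'   mu*f for states 1, 0, 2.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha * mu^2); must be > 0 (values below 1e-8 fall back to Poisson).
#' @param seed the seed the truth was built from (metadata).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(dag, cpts, baseline_mu, fold = 4, dispersion = 0.1,
                            seed = NA_integer_) {
  if (!is_acyclic(dag)) stop("truth dag must be acyclic")
  if ("PiZ" %in% dag$nodes && length(parents(dag, "PiZ")))
    stop("condition node must have no parents")
  stopifnot(all(baseline_mu > 0), fold > 1, dispersion > 0)
  genes <- setdiff(dag$nodes, "PiZ")
  if (!all(genes %in% names(baseline_mu))) stop("baseline_mu must cover every gene")
  for (v in dag$nodes) {
    if (max(abs(rowSums(cpts[[v]]) - 1)) > 1e-12)
      stop("CPT rows of ", v, " do not sum to 1")
  }
  structure(list(dag = dag, cpts = cpts,
                 count_params = list(baseline_mu = baseline_mu[genes],
                                     fold = fold, dispersion = dispersion),
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$dag$nodes) - 1L, "genes + condition,",
      n_arcs(x$dag), "arcs, fold =", x$count_params$fold,
      ", dispersion =", x$count_params$dispersion, "\n")
  invisible(x)
}

#' Ancestral sampling of discrete states from a ground truth
#'
#' Samples states variable-by-variable in topological order, so every value is
#' drawn from its CPT given already-sampled parent states (the Markov
#' condition by construction). The condition variable is not sampled: it is
#' fixed to 0 (wildtype) for the first `n_per_condition` samples and 1 (PiZ)
#' for the rest, mirroring a two-group design.
#'
#' @param truth a [synthetic_truth()].
#' @param n_per_condition samples per condition arm (>= 1).
#' @param seed integer seed.
#' @return a [discrete_data()] with `2 * n_per_condition` samples.
#' @export
sample_discrete_states <- function(truth, n_per_condition, seed = 1L) {
  if (n_per_condition < 1) stop("n_per_condition must be >= 1")
  d <- truth$dag
  arity <- node_arities(d)
  n <- 2L * as.integer(n_per_condition)
  states <- matrix(NA_integer_, n, length(d$nodes),
                   dimnames = list(sprintf("S%02d", seq_len(n)), d$nodes))
  states[, "PiZ"] <- rep(c(0L, 1L), each = n_per_condition)
  topo <- topological_sort(d)
  with_seed(seed, {
    for (v in topo) {
      if (v == "PiZ") next
      cpt <- truth$cpts[[v]]
      pa <- attr(cpt, "parents")
      r <- arity[[v]]
      j <- if (length(pa)) config_index(states[, pa, drop = FALSE], arity[pa])
           else rep(1L, n)
      st <- integer(n)
      for (jv in unique(j)) {
        idx <- which(j == jv)
        st[idx] <- sample.int(r, length(idx), replace = TRUE, prob = cpt[jv, ]) - 1L
      }
      states[, v] <- st
    }
  })
  discrete_data(states, arity)
}

#' Turn sampled states into negative-binomial counts
#'
#' The count for gene g in sample s is drawn from a negative binomial with
#' mean `mu_g * fold^m` where m is -1, 0, +1 for states 1 (low), 0 (no
#' change), 2 (high), and variance `mu + dispersion * mu^2`. Dispersions below
#' 1e-8 are treated as Poisson.
#'
#' @param states a [discrete_data()] containing a `"PiZ"` column.
#' @param count_params list with `baseline_mu` (named), `fold`, `dispersion`
#'   (e.g. the `count_params` of a [synthetic_truth()]).
#' @param seed integer seed.
#' @return a [count_matrix()] over the gene variables.
#' @export
states_to_counts <- function(states, count_params, seed = 1L) {
  genes <- setdiff(variables(states), "PiZ")
  mu <- count_params$baseline_mu
  missing <- setdiff(genes, names(mu))
  if (length(missing))
    stop("no count parameters for gene: ", paste(missing, collapse = ", "))
  fold <- count_params$fold
  disp <- count_params$dispersion
  n <- n_samples(states)
  m <- matrix(c(0, -1, 1)[states$states[, genes, drop = FALSE] + 1L],
              n, length(genes))
  mumat <- t(mu[genes] * t(fold^m))  # samples x genes
  counts <- with_seed(seed, {
    if (disp < 1e-8) stats::rpois(length(mumat), lambda = mumat)
    else stats::rnbinom(length(mumat), mu = mumat, size = 1 / disp)
  })
  snames <- rownames(states$states)
  if (is.null(snames)) snames <- sprintf("S%02d", seq_len(n))
  counts <- matrix(as.integer(counts), n, length(genes),
                   dimnames = list(snames, genes))
  count_matrix(t(counts), condition = states$states[, "PiZ"])
}

#' GSE141593-like synthetic dataset preset
#'
#' Convenience preset emulating the scale of the PiZ liver RNA-seq design:
#' 215 gene variables plus the binary condition node, 5 + 5 samples,
#' `max_parents = 3`, fold-factor 4, dispersion 0.1, baseline means
#' log-uniform in \[20, 2000\], and skewed Dirichlet CPTs (concentration
#' 0.5), so that some genes swing between the low and high states across
#' conditions (|log2 fold change| up to 2 log2(f)) while others sit at a
#' constant level and exercise the low-count filter.
#'
#' @param seed integer seed driving every random choice.
#' @param n_genes,n_per_condition override the preset scale (mainly for fast
#'   smoke tests).
#' @return list with elements `counts` (a [count_matrix()]), `states` (the
#'   true [discrete_data()]) and `truth` (the [synthetic_truth()]).
#' @export
make_piz_like_dataset <- function(seed = 1L, n_genes = 215L, n_per_condition = 5L) {
  d <- sample_ground_truth_dag(n_genes, max_parents = 3L, edge_prob = 0.01,
                               seed = derive_seed(seed, 1L))
  cpts <- sample_cpts(d, concentration = 0.5, seed = derive_seed(seed, 2L))
  genes <- setdiff(d$nodes, "PiZ")
  mu <- with_seed(derive_seed(seed, 3L),
                  exp(stats::runif(length(genes), log(20), log(2000))))
  names(mu) <- genes
  truth <- synthetic_truth(d, cpts, mu, fold = 4, dispersion = 0.1, seed = seed)
  states <- sample_discrete_states(truth, n_per_condition, seed = derive_seed(seed, 4L))
  counts <- states_to_counts(states, truth$count_params, seed = derive_seed(seed, 5L))
  list(counts = counts, states = states, truth = truth)
}

#' High-separation recovery benchmark dataset
#'
#' A ground truth designed for testing whether z-score discretization recovers
#' the generating states: every gene is coupled to the condition (directly or
#' through one intermediate), response directions are balanced (half induced,
#' half repressed), deviant states occur in a ~15% minority of samples, and
#' baseline means stay >= 150 so neither shot noise nor the low-count filter
#' bites. The rationale for these choices is a threshold-crossing analysis of
#' the +/-1 z-score boundaries (see the package vignette): a state can only
#' cross |z| = 1 if it is a minority state -- a balanced two-state gene never
#' exceeds |z| = sqrt((n-1)/n) -- and the classification margins are widest
#' when the deviant fraction sits near 0.15.
#'
#' @param n_genes number of genes (>= 2; default 20).
#' @param n_per_condition samples per arm.
#' @param fold state fold-factor (default 8, a high-separation setting).
#' @param dispersion NB dispersion (default 0.05).
#' @param seed integer seed.
#' @return list with `counts`, `states`, `truth` as in [make_piz_like_dataset()].
#' @export
make_recovery_dataset <- function(n_genes = 20L, n_per_condition = 50L, fold = 8,
                                  dispersion = 0.05, seed = 1L) {
  if (n_genes < 2L) stop("n_genes must be >= 2")
  genes <- sprintf("G%03d", seq_len(n_genes))
  n_direct <- ceiling(n_genes * 0.6)
  direct <- genes[seq_len(n_direct)]
  downstream <- setdiff(genes, direct)
  arcs <- cbind(rep("PiZ", n_direct), direct)
  if (length(downstream))
    arcs <- rbind(arcs, cbind(direct[seq_along(downstream)], downstream))
  d <- dag(c(genes, "PiZ"), arcs = arcs)
  directions <- stats::setNames(rep(c(2L, 1L), length.out = n_genes), genes)
  resp <- stats::setNames(ifelse(genes %in% direct, 0.24, 0.5), genes)
  cpts <- sample_regulatory_cpts(d, baseline_prob = 0.94, response_prob = resp,
                                 directions = directions)
  mu <- with_seed(derive_seed(seed, 31L),
                  exp(stats::runif(n_genes, log(150), log(2000))))
  names(mu) <- genes
  truth <- synthetic_truth(d, cpts, mu, fold = fold, dispersion = dispersion,
                           seed = seed)
  states <- sample_discrete_states(truth, n_per_condition, seed = derive_seed(seed, 32L))
  counts <- states_to_counts(states, truth$count_params, seed = derive_seed(seed, 33L))
  list(counts = counts, states = states, truth = truth)
}

#' Fraction of true states recovered by a discretization
#'
#' @param truth_states the generating [discrete_data()].
#' @param recovered a [discrete_data()] over (a subset of) the same variables
#'   and samples, e.g. the output of [preprocess_counts()].
#' @return proportion in \[0, 1\] of matching gene-sample state codes.
#' @export
state_recovery_rate <- function(truth_states, recovered) {
  vars <- setdiff(intersect(variables(truth_states), variables(recovered)), "PiZ")
  if (!length(vars)) stop("no shared gene variables")
  a <- truth_states$states[, vars, drop = FALSE]
  b <- recovered$states[rownames(a), vars, drop = FALSE]
  mean(a == b)
}
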