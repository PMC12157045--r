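#' Family sufficient statistics
#'
#' Exact cross-tabulation N_ijk of a node's states (k) against its parent
#' configurations (j). Parent configurations are indexed mixed-radix over the
#' parents in their declared order, first parent varying fastest; `q` is the
#' product of the parent arities (1 for a parentless node).
#'
#' @param data a [discrete_data()].
#' @param node variable name.
#' @param parents character vector of parent names (excluding `node`).
#' @return list of class `family_counts` with `node`, `parents`, `N`
#'   (`q x r` integer matrix), `q`, `r`.
#' @export
family_counts <- function(data, node, parents = character(0)) {
  vars <- variables(data)
  unknown <- setdiff(c(node, parents), vars)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  if (node %in% parents) stop("node cannot be its own parent")
  arity <- data$arity
  r <- arity[[node]]
  q <- if (length(parents)) prod(arity[parents]) else 1L
  j <- if (length(parents)) {
    config_index(data$states[, parents, drop = FALSE], arity[parents])
  } else rep(1L, n_samples(data))
  k <- data$states[, node] + 1L
  N <- matrix(tabulate((k - 1L) * q + j, nbins = q * r), q, r)
  structure(list(node = node, parents = parents, N = N, q = q, r = r),
            class = "family_counts")
}

#' BDe family score (log Dirichlet-multinomial marginal likelihood)
#'
#' The exact log marginal likelihood of one node's data given its parents
#' under a uniform BDe prior with equivalent sample size `ess`: pseudo-counts
#' `alpha_ijk = ess / (q * r)` and `alpha_ij = ess / q`, summed over parent
#' configurations j as
#' `lnGamma(a_ij) - lnGamma(a_ij + N_ij) + sum_k [lnGamma(a_ijk + N_ijk) - lnGamma(a_ijk)]`.
#'
#' @param counts a [family_counts()].
#' @param ess positive equivalent sample size (prior pseudo-count mass).
#' @return finite log-probability (0 for zero observations).
#' @export
bde_family_score <- function(counts, ess = 1) {
  stopifnot(inherits(counts, "family_counts"), ess > 0)
  a_ijk <- ess / (counts$q * counts$r)
  a_ij <- ess / counts$q
  N_ij <- rowSums(counts$N)
  sum(lgamma(a_ij) - lgamma(a_ij + N_ij)) +
    sum(lgamma(a_ijk + counts$N) - lgamma(a_ijk))
}

# internal: family score for (node, parents) straight from data
family_score <- function(data, node, parents, ess = 1) {
  bde_family_score(family_counts(data, node, parents), ess)
}

#' BDe network score
#'
#' Sum of the family scores of every variable (decomposable), plus the
#' normalized score used by the search protocol's stopping rule: the log score
#' divided by (number of samples x number of variables). Any fixed positive
#' normalization preserves the relative comparisons the stopping rule needs.
#'
#' @param d a [dag()] over exactly the data's variables.
#' @param data a [discrete_data()].
#' @param ess equivalent sample size.
#' @return list with `log_score` and `normalized_score`.
#' @export
bde_network_score <- function(d, data, ess = 1) {
  if (!setequal(d$nodes, variables(data)))
    stop("dag and data must share the same variables")
  log_score <- sum(vapply(d$nodes, function(v)
    family_score(data, v, parents(d, v), ess), numeric(1)))
  list(log_score = log_score,
       normalized_score = log_score / (n_samples(data) * length(d$nodes)))
}

#' Fit a Bayesian network's conditional probability tables
#'
#' Posterior-mean CPTs under the BDe prior:
#' `theta_ijk = (N_ijk + alpha_ijk) / (N_ij + alpha_ij)`. With no data the
#' rows are the prior mean (uniform); as `ess -> 0` they approach the
#' maximum-likelihood frequencies on observed configurations.
#'
#' @param d a [dag()] over the data's variables.
#' @param data a [discrete_data()].
#' @param ess equivalent sample size.
#' @return a fitted network of class `bdenet` (structure, CPTs, scores).
#' @seealso [bdenet()] for structure learning, [annotate_edges()] for edge
#'   strength/sign annotation.
#' @export
fit_cpts <- function(d, data, ess = 1) {
  if (!setequal(d$nodes, variables(data)))
    stop("dag and data must share the same variables")
  arity <- data$arity
  cpts <- lapply(d$nodes, function(v) {
    fc <- family_counts(data, v, parents(d, v))
    a_ijk <- ess / (fc$q * fc$r)
    a_ij <- ess / fc$q
    tab <- (fc$N + a_ijk) / (rowSums(fc$N) + a_ij)
    attr(tab, "parents") <- fc$parents
    tab
  })
  names(cpts) <- d$nodes
  sc <- bde_network_score(d, data, ess)
  structure(list(dag = d, arity = arity[d$nodes], cpts = cpts, ess = ess,
                 log_score = sc$log_score,
                 normalized_score = sc$normalized_score,
                 n_samples = n_samples(data), edges = NULL, trace = NULL),
            class = "bdenet")
}

#' Annotate arcs with strength and sign
#'
#' Strength of arc u -> v is the BDe score drop from deleting it,
#' `score(model) - score(model without u -> v)` (positive when the arc earns
#' its place). Sign is the sign of the Pearson correlation between the
#' ordinal state codes of u and v (low -> -1, no change -> 0, high -> +1;
#' condition 0/1); `"-"` marks inhibition, rendered dashed in graph exports.
#'
#' @param model a fitted `bdenet` (from [fit_cpts()] or [bdenet()]).
#' @param data the [discrete_data()] the model was fitted on.
#' @return the model with an `edges` data.frame (`parent`, `child`,
#'   `strength`, `sign`).
#' @export
annotate_edges <- function(model, data) {
  stopifnot(inherits(model, "bdenet"))
  a <- arcs(model$dag)
  if (nrow(a) == 0L) {
    model$edges <- data.frame(parent = character(0), child = character(0),
                              strength = numeric(0), sign = character(0))
    return(model)
  }
  arity <- data$arity
  strength <- numeric(nrow(a))
  sign_chr <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    u <- a[i, "parent"]; v <- a[i, "child"]
    pa <- parents(model$dag, v)
    with_arc <- family_score(data, v, pa, model$ess)
    without <- family_score(data, v, setdiff(pa, u), model$ess)
    strength[i] <- with_arc - without
    cu <- ordinal_codes(data$states[, u], arity[[u]])
    cv <- ordinal_codes(data$states[, v], arity[[v]])
    rho <- suppressWarnings(stats::cor(cu, cv))
    sign_chr[i] <- if (!is.na(rho) && rho < 0) "-" else "+"
  }
  model$edges <- data.frame(parent = a[, "parent"], child = a[, "child"],
                            strength = strength, sign = sign_chr,
                            stringsAsFactors = FALSE)
  model
}
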