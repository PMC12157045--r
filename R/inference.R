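# ---- factor machinery for exact inference --------------------------------

# a factor is list(vars = character, tab = numeric array over the vars'
# arities, first var fastest); scalar factors have vars = character(0)

model_factors <- function(model) {
  arity <- model$arity
  lapply(model$dag$nodes, function(v) {
    cpt <- model$cpts[[v]]
    pa <- attr(cpt, "parents")
    vars <- c(pa, v)
    list(vars = vars, tab = array(as.vector(cpt), dim = unname(arity[vars])))
  })
}

factor_restrict <- function(f, var, state_idx) {
  if (!var %in% f$vars) return(f)
  pos <- match(var, f$vars)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[pos]] <- state_idx
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  dim(tab) <- if (length(keep)) dim(f$tab)[keep] else NULL
  list(vars = f$vars[keep], tab = tab)
}

factor_product <- function(a, b, arity) {
  if (!length(a$vars)) return(list(vars = b$vars, tab = b$tab * as.numeric(a$tab)))
  if (!length(b$vars)) return(list(vars = a$vars, tab = a$tab * as.numeric(b$tab)))
  vars <- union(a$vars, b$vars)
  dims <- unname(arity[vars])
  n <- prod(dims)
  sub <- arrayInd(seq_len(n), dims)
  lin <- function(f) {
    cols <- match(f$vars, vars)
    strides <- cumprod(c(1L, unname(arity[f$vars])))[seq_along(f$vars)]
    1L + as.vector((sub[, cols, drop = FALSE] - 1L) %*% strides)
  }
  list(vars = vars, tab = array(a$tab[lin(a)] * b$tab[lin(b)], dim = dims))
}

factor_marginalize <- function(f, var, arity) {
  pos <- match(var, f$vars)
  perm <- c(setdiff(seq_along(f$vars), pos), pos)
  tab <- aperm(f$tab, perm)
  keep <- f$vars[perm[-length(perm)]]
  d <- dim(tab)
  tab <- rowSums(matrix(tab, ncol = d[length(d)]))
  if (length(keep)) dim(tab) <- d[-length(d)] else dim(tab) <- NULL
  list(vars = keep, tab = tab)
}

# greedy min-fill elimination ordering over the factors' interaction graph
elimination_order <- function(scopes, elim_vars) {
  order <- character(0)
  scopes <- lapply(scopes, identity)
  remaining <- elim_vars
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- setdiff(unique(unlist(scopes[vapply(scopes, function(s) v %in% s, logical(1))])), v)
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L)) for (j in seq(i + 1L, length(nb))) {
        linked <- any(vapply(scopes, function(s) all(c(nb[i], nb[j]) %in% s), logical(1)))
        if (!linked) cnt <- cnt + 1L
      }
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]
    touched <- vapply(scopes, function(s) v %in% s, logical(1))
    newscope <- setdiff(unique(unlist(scopes[touched])), v)
    scopes <- c(scopes[!touched], list(newscope))
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

validate_evidence <- function(model, evidence) {
  if (is.null(evidence) || length(evidence) == 0L) return(integer(0))
  if (is.null(names(evidence)) || any(names(evidence) == ""))
    stop("evidence must be a named vector of state codes")
  check_node(model$dag, names(evidence))
  ev <- as.integer(evidence)
  names(ev) <- names(evidence)
  bad <- ev < 0L | ev >= model$arity[names(ev)]
  if (any(bad))
    stop("evidence state out of range for: ", paste(names(ev)[bad], collapse = ", "))
  ev
}

impossible_evidence <- function(evidence) {
  stop(structure(class = c("bdenet_impossible_evidence", "error", "condition"),
                 list(message = paste0("evidence has probability zero: ",
                                       paste(names(evidence), evidence,
                                             sep = "=", collapse = ", ")),
                      call = NULL)))
}

# ---- public queries ------------------------------------------------------

#' Joint probability of a complete assignment
#'
#' Product over all variables of the fitted conditional probability of the
#' assigned state given the assigned parent states.
#'
#' @param model a fitted `bdenet`.
#' @param assignment named integer vector of state codes covering every
#'   variable.
#' @return a probability.
#' @export
joint_probability <- function(model, assignment) {
  vars <- model$dag$nodes
  if (!all(vars %in% names(assignment)))
    stop("assignment must cover every variable; missing: ",
         paste(setdiff(vars, names(assignment)), collapse = ", "))
  ev <- validate_evidence(model, assignment[vars])
  p <- 1
  for (v in vars) {
    cpt <- model$cpts[[v]]
    pa <- attr(cpt, "parents")
    j <- if (length(pa)) {
      config_index(matrix(ev[pa], nrow = 1L), model$arity[pa])
    } else 1L
    p <- p * cpt[j, ev[[v]] + 1L]
  }
  unname(p)
}

#' Exact conditional queries on a fitted network
#'
#' Computes `P(targets | evidence)` exactly by variable elimination with a
#' greedy min-fill ordering (identical, within numerical tolerance, to brute
#' force summation over the joint). Clamping a variable and querying it
#' returns a point mass. Evidence of probability zero raises an error of
#' class `bdenet_impossible_evidence`.
#'
#' @param model a fitted `bdenet`.
#' @param targets one or more variable names.
#' @param evidence named integer vector of clamped state codes (or `NULL`).
#' @return for a single target, a named probability vector over its state
#'   codes; for several, an array with one dimension per target.
#' @examples
#' sim <- make_piz_like_dataset(seed = 1, n_genes = 4, n_per_condition = 10)
#' fit <- fit_cpts(sim$truth$dag, sim$states)
#' bn_query(fit, "G001", evidence = c(PiZ = 1))
#' @export
bn_query <- function(model, targets, evidence = NULL) {
  stopifnot(inherits(model, "bdenet"))
  check_node(model$dag, targets)
  if (anyDuplicated(targets)) stop("duplicate targets")
  ev <- validate_evidence(model, evidence)
  arity <- model$arity
  free <- setdiff(targets, names(ev))
  # barren-node removal: only the ancestral closure of targets and evidence
  # matters; the families of all other nodes integrate out to one exactly
  relevant <- ancestors_closure(model$dag, unique(c(targets, names(ev))))
  factors <- model_factors(model)[match(relevant, model$dag$nodes)]
  for (v in names(ev)) {
    factors <- lapply(factors, factor_restrict, var = v, state_idx = ev[[v]] + 1L)
  }
  elim <- setdiff(unlist(lapply(factors, `[[`, "vars")), free)
  ord <- elimination_order(lapply(factors, `[[`, "vars"), unique(elim))
  for (v in ord) {
    touched <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) factor_product(a, b, arity), factors[touched])
    factors <- c(factors[!touched], list(factor_marginalize(prod_f, v, arity)))
  }
  out <- Reduce(function(a, b) factor_product(a, b, arity), factors)
  total <- sum(out$tab)
  if (!is.finite(total) || total <= 0) impossible_evidence(ev)
  # order free-target dims, then append point-mass dims for clamped targets
  if (length(free)) {
    out$tab <- aperm(array(out$tab, dim = unname(arity[out$vars])),
                     match(free, out$vars))
    out$tab <- out$tab / total
  } else {
    out$tab <- 1
  }
  result <- out$tab
  clamped <- intersect(targets, names(ev))
  if (length(clamped)) {
    full_dims <- unname(arity[targets])
    res <- array(0, dim = full_dims)
    idx <- as.matrix(expand.grid(lapply(arity[free], function(r) seq_len(r))))
    if (!length(free)) idx <- matrix(integer(0), nrow = 1L, ncol = 0L)
    full_idx <- matrix(1L, nrow(idx), length(targets))
    full_idx[, match(free, targets)] <- idx
    for (v in clamped) full_idx[, match(v, targets)] <- ev[[v]] + 1L
    res[full_idx] <- as.vector(result)
    result <- res
  }
  dn <- lapply(arity[targets], function(r) as.character(0:(r - 1L)))
  if (length(targets) == 1L) {
    result <- as.vector(result)
    names(result) <- dn[[1L]]
  } else {
    dimnames(result) <- dn
  }
  result
}

#' Probability of an evidence configuration
#'
#' @param model a fitted `bdenet`.
#' @param evidence named integer vector of state codes.
#' @return `P(evidence)` under the fitted joint.
#' @export
prob_of_evidence <- function(model, evidence) {
  ev <- validate_evidence(model, evidence)
  if (!length(ev)) return(1)
  relevant <- ancestors_closure(model$dag, names(ev))
  factors <- model_factors(model)[match(relevant, model$dag$nodes)]
  for (v in names(ev)) {
    factors <- lapply(factors, factor_restrict, var = v, state_idx = ev[[v]] + 1L)
  }
  elim <- unique(unlist(lapply(factors, `[[`, "vars")))
  ord <- elimination_order(lapply(factors, `[[`, "vars"), elim)
  arity <- model$arity
  for (v in ord) {
    touched <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) factor_product(a, b, arity), factors[touched])
    factors <- c(factors[!touched], list(factor_marginalize(prod_f, v, arity)))
  }
  prod(vapply(factors, function(f) as.numeric(f$tab), numeric(1)))
}

#' Evidence-clamping simulation
#'
#' Clamps the scenario's variables to fixed states (e.g. `PiZ = 1` and
#' `Slc39a7 = 2` for "PiZ 100% with Slc39a7 high 100%") and reads the exact
#' conditional marginal of every other variable, in the manner of
#' evidence-setting simulations in graphical-model GUIs. Clamping is
#' observational conditioning, not an intervention.
#'
#' @param model a fitted `bdenet`.
#' @param evidence named integer vector of clamped state codes.
#' @param targets variables to report (default: all unclamped variables).
#' @return data.frame with one row per target: `variable` and columns `p0`,
#'   `p1`, `p2` for P(state code | evidence) (`p2` is `NA` for binary
#'   variables).
#' @export
simulate_scenario <- function(model, evidence, targets = NULL) {
  ev <- validate_evidence(model, evidence)
  if (is.null(targets)) targets <- setdiff(model$dag$nodes, names(ev))
  check_node(model$dag, targets)
  rows <- lapply(targets, function(v) {
    p <- bn_query(model, v, evidence = ev)
    data.frame(variable = v, p0 = p[["0"]], p1 = p[["1"]],
               p2 = if (model$arity[[v]] >= 3L) p[["2"]] else NA_real_)
  })
  do.call(rbind, rows)
}

#' Side-by-side contrast of two evidence scenarios
#'
#' @param model a fitted `bdenet`.
#' @param evidence_a,evidence_b the two scenarios (named state-code vectors),
#'   e.g. `c(PiZ = 1, Slc39a7 = 2)` vs `c(PiZ = 0, Slc39a7 = 2)`.
#' @param targets variables to report (default: unclamped in both).
#' @return data.frame joining the two [simulate_scenario()] tables with
#'   suffixes `_a` and `_b`.
#' @export
scenario_contrast <- function(model, evidence_a, evidence_b, targets = NULL) {
  if (is.null(targets))
    targets <- setdiff(model$dag$nodes,
                       union(names(evidence_a), names(evidence_b)))
  a <- simulate_scenario(model, evidence_a, targets)
  b <- simulate_scenario(model, evidence_b, targets)
  merge(a, b, by = "variable", suffixes = c("_a", "_b"), sort = FALSE)
}

#' Most probable k-gene state combinations
#'
#' Enumerates every size-`k` subset of the candidate variables and every
#' joint state assignment of the subset (`choose(|candidates|, k) * 3^k`
#' assignments for ternary genes), scores each by the exact conditional
#' probability `P(states | evidence)`, and returns the full ranked list. The
#' reverse conditional `P(evidence | states)` is reported per row as well.
#' Ranking ties are broken lexicographically by variable names and states.
#'
#' @param model a fitted `bdenet`.
#' @param candidates candidate variable names (disjoint from the evidence).
#' @param k combination size (e.g. 2 or 3).
#' @param evidence named state-code vector, typically `c(PiZ = 1)` or
#'   `c(PiZ = 0)`; may be `NULL`.
#' @return data.frame of class `combination_result`: `variables`, `states`
#'   (comma-joined), `p_given_evidence`, `p_evidence_given_states`, sorted by
#'   decreasing probability.
#' @export
top_state_combinations <- function(model, candidates, k, evidence = NULL) {
  stopifnot(inherits(model, "bdenet"), k >= 1)
  check_node(model$dag, candidates)
  ev <- validate_evidence(model, evidence)
  if (length(intersect(candidates, names(ev))))
    stop("candidates must be disjoint from the evidence")
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  p_ev <- if (length(ev)) prob_of_evidence(model, ev) else 1
  if (p_ev <= 0) impossible_evidence(ev)
  subsets <- utils::combn(candidates, k, simplify = FALSE)
  rows <- lapply(subsets, function(vars) {
    joint_ev <- bn_query(model, vars, evidence = ev)
    joint_marg <- bn_query(model, vars, evidence = NULL)
    grid <- expand.grid(lapply(model$arity[vars], function(r) 0:(r - 1L)))
    p_cond <- as.vector(joint_ev)
    p_marg <- as.vector(joint_marg)
    p_rev <- ifelse(p_marg > 0, p_cond * p_ev / p_marg, 0)
    data.frame(variables = paste(vars, collapse = ","),
               states = apply(grid, 1L, paste, collapse = ","),
               p_given_evidence = p_cond,
               p_evidence_given_states = p_rev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$p_given_evidence, out$variables, out$states), ]
  rownames(out) <- NULL
  class(out) <- c("combination_result", "data.frame")
  attr(out, "k") <- k
  attr(out, "evidence") <- ev
  out
}

#' @export
print.combination_result <- function(x, n = 10L, ...) {
  ev <- attr(x, "evidence")
  cat(sprintf("top %d-variable state combinations%s (%d ranked)\n", attr(x, "k"),
              if (length(ev)) paste0(" given ", paste(names(ev), ev, sep = "=",
                                                      collapse = ", ")) else "",
              nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Smallest combination size reaching a probability threshold
#'
#' Operationalizes "the minimal set of genes necessary" as the smallest `k`
#' whose top-ranked state assignment has conditional probability above
#' `threshold` given the evidence.
#'
#' @inheritParams top_state_combinations
#' @param threshold probability the top assignment must exceed (default 0.5).
#' @param max_k largest k to try.
#' @return list with `k` (or `NA` if never reached) and the winning
#'   [top_state_combinations()] row.
#' @export
minimal_gene_set <- function(model, candidates, evidence = NULL,
                             threshold = 0.5, max_k = 3L) {
  for (k in seq_len(min(max_k, length(candidates)))) {
    combos <- top_state_combinations(model, candidates, k, evidence)
    if (combos$p_given_evidence[1L] > threshold)
      return(list(k = k, top = combos[1L, ]))
  }
  list(k = NA_integer_, top = NULL)
}
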