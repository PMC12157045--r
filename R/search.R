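# ---- fast internal scoring on raw state matrices -------------------------

# v, pa: integer column indices; states: samples x variables 0-based codes
fam_score_raw <- function(states, arity, v, pa, ess) {
  r <- arity[[v]]
  n <- nrow(states)
  if (length(pa)) {
    q <- 1L
    j <- rep(1L, n)
    for (t in pa) {
      j <- j + states[, t] * q
      q <- q * arity[[t]]
    }
  } else {
    q <- 1L
    j <- rep(1L, n)
  }
  N <- tabulate(states[, v] * q + j, nbins = q * r)
  a_ijk <- ess / (q * r)
  a_ij <- ess / q
  N_ij <- rowSums(matrix(N, q, r))
  sum(lgamma(a_ij) - lgamma(a_ij + N_ij)) + sum(lgamma(a_ijk + N) - lgamma(a_ijk))
}

# ---- move sampling -------------------------------------------------------

# one uniformly-sampled legal move via rejection from the 3 * n * (n-1)
# candidate superset; falls back to full enumeration so "no legal move" is
# detected exactly. Returns list(type, u, v) with integer endpoints, or NULL.
sample_move_raw <- function(amat, max_parents = Inf, max_tries = 500L) {
  n <- ncol(amat)
  if (n < 2L) return(NULL)
  indeg <- colSums(amat)
  for (try in seq_len(max_tries)) {
    u <- sample.int(n, 1L)
    v <- sample.int(n - 1L, 1L)
    if (v >= u) v <- v + 1L
    type <- sample.int(3L, 1L)  # 1 add, 2 delete, 3 reverse
    if (type == 1L) {
      if (amat[u, v] == 0L && indeg[v] < max_parents &&
          !has_path(amat, v, u)) return(list(type = "add", u = u, v = v))
    } else if (type == 2L) {
      if (amat[u, v] == 1L) return(list(type = "delete", u = u, v = v))
    } else {
      if (amat[u, v] == 1L && indeg[u] < max_parents) {
        amat[u, v] <- 0L
        ok <- !has_path(amat, u, v)
        amat[u, v] <- 1L
        if (ok) return(list(type = "reverse", u = u, v = v))
      }
    }
  }
  moves <- legal_moves_raw(amat, max_parents)
  if (length(moves) == 0L) return(NULL)
  moves[[sample.int(length(moves), 1L)]]
}

legal_moves_raw <- function(amat, max_parents = Inf) {
  n <- ncol(amat)
  indeg <- colSums(amat)
  moves <- list()
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    if (amat[u, v] == 0L) {
      if (indeg[v] < max_parents && !has_path(amat, v, u))
        moves[[length(moves) + 1L]] <- list(type = "add", u = u, v = v)
    } else {
      moves[[length(moves) + 1L]] <- list(type = "delete", u = u, v = v)
      if (indeg[u] < max_parents) {
        amat[u, v] <- 0L
        if (!has_path(amat, u, v))
          moves[[length(moves) + 1L]] <- list(type = "reverse", u = u, v = v)
        amat[u, v] <- 1L
      }
    }
  }
  moves
}

#' Propose one random structure move
#'
#' Draws uniformly over the currently legal moves -- arc additions (that keep
#' the graph acyclic and respect `max_parents`), deletions, and reversals --
#' and returns the modified DAG. Uses R's global RNG (seed with `set.seed()`
#' for reproducibility). Returns `NULL` when no legal move exists.
#'
#' @param d a [dag()].
#' @param max_parents in-degree cap (default unlimited).
#' @return a new `dag` with attribute `"move"` (list with `type`, `from`,
#'   `to`), or `NULL`.
#' @export
propose_move <- function(d, max_parents = Inf) {
  mv <- sample_move_raw(d$amat, max_parents)
  if (is.null(mv)) return(NULL)
  u <- d$nodes[mv$u]; v <- d$nodes[mv$v]
  if (mv$type == "add") {
    d$amat[u, v] <- 1L
  } else if (mv$type == "delete") {
    d$amat[u, v] <- 0L
  } else {
    d$amat[u, v] <- 0L
    d$amat[v, u] <- 1L
  }
  attr(d, "move") <- list(type = mv$type, from = u, to = v)
  d
}

#' Simulated annealing over DAG structures
#'
#' Metropolis search maximizing the BDe score: score-improving moves are
#' always accepted, score-decreasing moves (delta < 0) with probability
#' `exp(delta / T)`, and the temperature decays geometrically
#' (`T <- T * cooling`) after every move evaluation. The budget counts scored
#' move evaluations -- a deterministic, reproducible stand-in for wall-clock
#' search time. Returns the best structure ever visited, never just the final
#' one, so the result's score is always >= the start's.
#'
#' @param data a [discrete_data()].
#' @param start starting [dag()] over the data's variables (default empty).
#' @param ess BDe equivalent sample size.
#' @param budget number of move evaluations.
#' @param init_temp initial temperature; `NULL` auto-tunes it to the standard
#'   deviation of the score deltas of 100 random probe moves.
#' @param cooling geometric cooling rate in (0, 1).
#' @param max_parents in-degree cap.
#' @param seed integer seed; identical (data, settings, start, seed) give
#'   identical results.
#' @return list with `dag` (best structure), `log_score`, `normalized_score`,
#'   and `n_evals`.
#' @export
anneal <- function(data, start = NULL, ess = 1, budget = 1000L,
                   init_temp = NULL, cooling = 0.995, max_parents = Inf,
                   seed = 1L) {
  stopifnot(inherits(data, "discrete_data"), budget >= 1,
            cooling > 0, cooling < 1)
  vars <- variables(data)
  if (is.null(start)) start <- dag(vars)
  if (!setequal(start$nodes, vars)) stop("start must cover the data's variables")
  if (!is_acyclic(start)) stop("start structure must be acyclic")
  states <- data$states
  arity <- as.integer(data$arity)
  n <- length(vars)
  amat <- start$amat[vars, vars, drop = FALSE]
  dimnames(amat) <- NULL
  pa_of <- function(v) which(amat[, v] == 1L)
  fam <- vapply(seq_len(n), function(v)
    fam_score_raw(states, arity, v, pa_of(v), ess), numeric(1))
  with_seed(seed, {
    if (is.null(init_temp)) {
      deltas <- numeric(0)
      for (p in seq_len(100L)) {
        mv <- sample_move_raw(amat, max_parents, max_tries = 50L)
        if (is.null(mv)) break
        deltas <- c(deltas, move_delta(states, arity, amat, mv, fam, ess)$delta)
      }
      init_temp <- stats::sd(deltas)
      if (!is.finite(init_temp) || init_temp == 0) init_temp <- 1
    }
    temp <- init_temp
    best_amat <- amat
    best_score <- sum(fam)
    cur_score <- best_score
    evals <- 0L
    while (evals < budget) {
      mv <- sample_move_raw(amat, max_parents)
      if (is.null(mv)) break
      dd <- move_delta(states, arity, amat, mv, fam, ess)
      evals <- evals + 1L
      if (dd$delta > 0 || stats::runif(1L) < exp(dd$delta / temp)) {
        amat <- apply_move(amat, mv)
        fam[dd$nodes] <- dd$new_fam
        cur_score <- cur_score + dd$delta
        if (cur_score > best_score) {
          best_score <- cur_score
          best_amat <- amat
        }
      }
      temp <- temp * cooling
    }
  })
  dimnames(best_amat) <- list(vars, vars)
  best <- structure(list(nodes = vars, amat = best_amat), class = "dag")
  list(dag = best, log_score = best_score,
       normalized_score = best_score / (nrow(states) * n), n_evals = evals)
}

move_delta <- function(states, arity, amat, mv, fam, ess) {
  u <- mv$u; v <- mv$v
  if (mv$type == "add") {
    new_v <- fam_score_raw(states, arity, v, c(which(amat[, v] == 1L), u), ess)
    list(nodes = v, new_fam = new_v, delta = new_v - fam[v])
  } else if (mv$type == "delete") {
    new_v <- fam_score_raw(states, arity, v, setdiff(which(amat[, v] == 1L), u), ess)
    list(nodes = v, new_fam = new_v, delta = new_v - fam[v])
  } else {
    new_v <- fam_score_raw(states, arity, v, setdiff(which(amat[, v] == 1L), u), ess)
    new_u <- fam_score_raw(states, arity, u, c(which(amat[, u] == 1L), v), ess)
    list(nodes = c(v, u), new_fam = c(new_v, new_u),
         delta = new_v + new_u - fam[v] - fam[u])
  }
}

apply_move <- function(amat, mv) {
  if (mv$type == "add") {
    amat[mv$u, mv$v] <- 1L
  } else if (mv$type == "delete") {
    amat[mv$u, mv$v] <- 0L
  } else {
    amat[mv$u, mv$v] <- 0L
    amat[mv$v, mv$u] <- 1L
  }
  amat
}

#' One round of independent annealed searches
#'
#' Runs `searches` independent [anneal()]s from the same starting structure
#' with distinct seeds derived deterministically from `seed`, and returns the
#' champion by normalized score (ties broken by lowest search index).
#'
#' @inheritParams anneal
#' @param searches number of independent searches (default 3).
#' @param round round number, mixed into the derived seeds.
#' @return list with `dag`, `log_score`, `normalized_score` of the champion
#'   and a `records` data.frame (one row per search: seed and best scores).
#' @export
run_round <- function(data, start = NULL, budget = 1000L, searches = 3L,
                      ess = 1, init_temp = NULL, cooling = 0.995,
                      max_parents = Inf, seed = 1L, round = 1L) {
  stopifnot(searches >= 1)
  seeds <- vapply(seq_len(searches), function(s) derive_seed(seed, round, s),
                  integer(1))
  results <- lapply(seeds, function(s)
    anneal(data, start, ess, budget, init_temp, cooling, max_parents, seed = s))
  normalized <- vapply(results, `[[`, numeric(1), "normalized_score")
  champ <- which.max(normalized)
  out <- results[[champ]]
  out$records <- data.frame(search = seq_len(searches), seed = seeds,
                            log_score = vapply(results, `[[`, numeric(1), "log_score"),
                            normalized_score = normalized)
  out$champion <- champ
  out
}

#' Stopping rule of the multi-round search protocol
#'
#' Relative improvement between successive round champions on the normalized
#' score: `(s_new - s_prev) / |s_prev|`. The search concludes when the
#' improvement is no greater than the threshold (default 15%); otherwise the
#' next round doubles the budget.
#'
#' @param s_prev,s_new normalized scores of the previous and current round
#'   champions.
#' @param threshold relative-improvement stopping threshold.
#' @return list with `improvement` and logical `stop`.
#' @export
protocol_stop_decision <- function(s_prev, s_new, threshold = 0.15) {
  improvement <- (s_new - s_prev) / abs(s_prev)
  list(improvement = improvement, stop = improvement <= threshold)
}

#' @rdname protocol_stop_decision
#' @param budget round-1 budget.
#' @param rounds number of rounds.
#' @return `protocol_budgets()`: the doubling budget schedule B, 2B, 4B, ...
#' @export
protocol_budgets <- function(budget, rounds) as.integer(budget * 2^(seq_len(rounds) - 1L))

#' Multi-round doubling search protocol
#'
#' The full structure-search procedure: round 1 runs `searches` independent
#' annealed searches at the base budget from the empty graph; each later
#' round doubles the budget and starts every search from the previous round's
#' champion. From round 2 on, the normalized champion scores of successive
#' rounds are compared and the search concludes when the relative improvement
#' is no greater than `improvement` (or `max_rounds` is hit). The final
#' champion is fitted ([fit_cpts()]) and annotated ([annotate_edges()]).
#'
#' @inheritParams run_round
#' @param improvement stopping threshold on relative normalized-score
#'   improvement between round champions (default 0.15).
#' @param max_rounds maximum number of rounds (>= 2).
#' @param annotate add per-arc strength/sign annotations to the final model.
#' @return a fitted `bdenet` model whose `trace` element records, per round,
#'   the budget, per-search seeds and scores, champion scores, improvement
#'   and stopping decision.
#' @export
run_protocol <- function(data, budget = 1000L, searches = 3L,
                         improvement = 0.15, max_rounds = 6L, ess = 1,
                         init_temp = NULL, cooling = 0.995, max_parents = Inf,
                         seed = 1L, annotate = TRUE) {
  stopifnot(inherits(data, "discrete_data"), max_rounds >= 2, improvement >= 0)
  budgets <- protocol_budgets(budget, max_rounds)
  start <- dag(variables(data))
  rounds <- list()
  champion <- NULL
  for (r in seq_len(max_rounds)) {
    res <- run_round(data, start, budgets[r], searches, ess, init_temp,
                     cooling, max_parents, seed = seed, round = r)
    rec <- list(round = r, budget = budgets[r], records = res$records,
                log_score = res$log_score,
                normalized_score = res$normalized_score,
                improvement = NA_real_, stopped = FALSE)
    if (r >= 2L) {
      dec <- protocol_stop_decision(champion$normalized_score,
                                    res$normalized_score, improvement)
      rec$improvement <- dec$improvement
      rec$stopped <- dec$stop || r == max_rounds
    }
    champion <- res
    rounds[[r]] <- rec
    start <- champion$dag
    if (rec$stopped) break
  }
  model <- fit_cpts(champion$dag, data, ess)
  if (annotate) model <- annotate_edges(model, data)
  model$trace <- structure(list(rounds = rounds, seed = seed,
                                base_budget = as.integer(budget),
                                searches = as.integer(searches),
                                improvement_threshold = improvement),
                           class = "bdenet_trace")
  model
}

#' @export
print.bdenet_trace <- function(x, ...) {
  cat("search protocol:", length(x$rounds), "round(s),", x$searches,
      "searches/round, base budget", x$base_budget, "\n")
  for (r in x$rounds) {
    cat(sprintf("  round %d: budget %d, best normalized %.5f%s%s\n",
                r$round, r$budget, r$normalized_score,
                if (is.na(r$improvement)) ""
                else sprintf(", improvement %.1f%%", 100 * r$improvement),
                if (r$stopped) " [stop]" else ""))
  }
  invisible(x)
}

#' Exhaustive structure search (oracle for small variable sets)
#'
#' Enumerates every DAG on the data's variables (25 DAGs at 3 variables, 543
#' at 4, 29,281 at 5 -- the hard cap), scores each by the BDe score, and
#' returns a global maximizer together with the full score table. Intended as
#' an independent check on the annealed search.
#'
#' @param data a [discrete_data()] with at most 5 variables.
#' @param ess BDe equivalent sample size.
#' @return list with `dag` (a global optimum), `log_score`,
#'   `normalized_score`, `n_dags`, and `scores` (log score of every DAG).
#' @export
exhaustive_search <- function(data, ess = 1) {
  vars <- variables(data)
  n <- length(vars)
  if (n > 5L) stop("exhaustive enumeration refused for more than 5 variables")
  states <- data$states
  arity <- as.integer(data$arity)
  # family score for every (node, parent-set bitmask)
  fam <- vector("list", n)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    fam[[v]] <- rep(NA_real_, 2^n)
    for (S in 0:(2^length(others) - 1L)) {
      pa <- others[bitwAnd(S, 2^(seq_along(others) - 1L)) > 0L]
      mask <- sum(2^(pa - 1L))
      fam[[v]][mask + 1L] <- fam_score_raw(states, arity, v, pa, ess)
    }
  }
  pairs <- which(matrix(TRUE, n, n) & !diag(n) > 0, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  m <- nrow(pairs)
  known <- c(1L, 3L, 25L, 543L, 29281L)[n]
  scores <- numeric(known)
  count <- 0L
  best_score <- -Inf
  best_masks <- NULL
  masks <- integer(n)
  reach <- diag(n) > 0  # reach[i, j]: path i -> j (reflexive)
  recurse <- function(k) {
    if (k > m) {
      count <<- count + 1L
      sc <- 0
      for (v in seq_len(n)) sc <- sc + fam[[v]][masks[v] + 1L]
      scores[count] <<- sc
      if (sc > best_score) {
        best_score <<- sc
        best_masks <<- masks
      }
      return(invisible())
    }
    u <- pairs[k, 1L]; v <- pairs[k, 2L]
    recurse(k + 1L)                      # exclude arc u -> v
    if (!reach[v, u]) {                  # include it if acyclic
      old_reach <- reach
      anc <- which(reach[, u]); dec <- which(reach[v, ])
      reach[anc, dec] <<- TRUE
      masks[v] <<- masks[v] + 2^(u - 1L)
      recurse(k + 1L)
      reach <<- old_reach
      masks[v] <<- masks[v] - 2^(u - 1L)
    }
    invisible()
  }
  recurse(1L)
  best <- dag(vars)
  for (v in seq_len(n)) {
    pa <- which(bitwAnd(best_masks[v], 2^(seq_len(n) - 1L)) > 0L)
    best$amat[pa, v] <- 1L
  }
  list(dag = best, log_score = best_score,
       normalized_score = best_score / (nrow(states) * n),
       n_dags = count, scores = scores[seq_len(count)])
}

#' Refine the variable set around a target and re-search
#'
#' Reduces the dataset to the second-degree Markov blanket of the target in a
#' first-pass model, plus the genes of interest and the target itself, then
#' re-runs the full search protocol on the reduced dataset. This mirrors the
#' two-stage workflow in which a broad first network is pruned to the
#' condition's extended neighborhood before the final search.
#'
#' @param data the full [discrete_data()].
#' @param first_pass a fitted `bdenet` model on `data`.
#' @param target the condition variable name (e.g. `"PiZ"`).
#' @param genes_of_interest variables to retain regardless of the blanket.
#' @param ... passed on to [run_protocol()].
#' @return list with `data` (the reduced [discrete_data()]) and `model` (the
#'   final fitted `bdenet`).
#' @export
refine_and_research <- function(data, first_pass, target = "PiZ",
                                genes_of_interest = character(0), ...) {
  if (!target %in% variables(data)) stop("unknown target variable: ", target)
  keep_interest <- intersect(genes_of_interest, variables(data))
  vars <- union(union(second_degree_mb(first_pass$dag, target), keep_interest),
                target)
  vars <- intersect(variables(data), vars)  # preserve data's column order
  reduced <- discrete_data(data$states[, vars, drop = FALSE], data$arity[vars])
  if (length(vars) < 2L) {
    dots <- list(...)
    ess <- if (is.null(dots$ess)) 1 else dots$ess
    model <- annotate_edges(fit_cpts(dag(vars), reduced, ess), reduced)
    return(list(data = reduced, model = model))
  }
  list(data = reduced, model = run_protocol(reduced, ...))
}

#' Learn a discrete Bayesian network by annealed BDe search
#'
#' The main fitting front-end: runs the multi-round doubling search protocol
#' ([run_protocol()]) on a discretized expression dataset and returns the
#' fitted network as a `bdenet` object with `print()`, `summary()`,
#' `coef()`, `logLik()`, `predict()`, `simulate()` and `plot()` methods.
#'
#' @inheritParams run_protocol
#' @return a fitted model of class `bdenet`.
#' @examples
#' sim <- make_piz_like_dataset(seed = 1, n_genes = 6, n_per_condition = 10)
#' fit <- bdenet(sim$states, budget = 300, seed = 1)
#' fit
#' coef(fit)$PiZ
#' @export
bdenet <- function(data, budget = 2000L, searches = 3L, improvement = 0.15,
                   max_rounds = 6L, ess = 1, init_temp = NULL, cooling = 0.995,
                   max_parents = Inf, seed = 1L, annotate = TRUE) {
  model <- run_protocol(data, budget, searches, improvement, max_rounds, ess,
                        init_temp, cooling, max_parents, seed, annotate)
  model$call <- match.call()
  model
}
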