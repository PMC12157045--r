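#' Fitted discrete Bayesian network
#'
#' Objects of class `bdenet` (from [bdenet()], [run_protocol()] or
#' [fit_cpts()]) hold the learned structure (`$dag`), posterior-mean CPTs
#' (`$cpts`), the BDe log score and normalized score, optional per-arc
#' annotations (`$edges`) and the search trace (`$trace`).
#'
#' @param x,object a `bdenet` model.
#' @param ... unused.
#' @name bdenet-methods
NULL

#' @rdname bdenet-methods
#' @export
print.bdenet <- function(x, ...) {
  cat("Discrete Bayesian network (BDe",
      sprintf("ess = %g):", x$ess),
      length(x$dag$nodes), "variables,", n_arcs(x$dag), "arcs\n")
  cat(sprintf("  log score %.4f | normalized %.5f | fitted on %d samples\n",
              x$log_score, x$normalized_score, x$n_samples))
  if (!is.null(x$trace))
    cat("  learned in", length(x$trace$rounds), "search round(s)\n")
  invisible(x)
}

#' @rdname bdenet-methods
#' @export
summary.bdenet <- function(object, target = "PiZ", ...) {
  mb <- if (target %in% object$dag$nodes) markov_blanket(object$dag, target, 2L)
        else NULL
  structure(list(model = object, target = target, mb = mb),
            class = "summary.bdenet")
}

#' @export
print.summary.bdenet <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$edges) && nrow(x$model$edges)) {
    ed <- x$model$edges
    ed <- ed[order(-ed$strength), ]
    cat("\nStrongest arcs (sign '-' = inhibition):\n")
    print(utils::head(ed, 10L), row.names = FALSE, digits = 4)
  }
  if (!is.null(x$mb)) {
    cat(sprintf("\nMarkov blanket of %s: %d first-degree, %d second-degree\n",
                x$target, length(x$mb$first_degree), length(x$mb$second_degree)))
  }
  if (!is.null(x$model$trace)) {
    cat("\n")
    print(x$model$trace)
  }
  invisible(x)
}

#' @rdname bdenet-methods
#' @export
coef.bdenet <- function(object, ...) object$cpts

#' @rdname bdenet-methods
#' @export
logLik.bdenet <- function(object, ...) {
  df <- sum(vapply(object$cpts, function(tab) nrow(tab) * (ncol(tab) - 1L),
                   numeric(1)))
  structure(object$log_score, df = df, nobs = object$n_samples,
            class = "logLik")
}

#' Predict conditional marginals from a fitted network
#'
#' `predict()` on a `bdenet` returns exact conditional marginals of the
#' requested variables given clamped evidence, i.e. a [simulate_scenario()]
#' table.
#'
#' @param object a `bdenet`.
#' @param evidence named state-code vector (may be `NULL` for prior
#'   marginals).
#' @param targets variables to report (default all unclamped).
#' @param ... unused.
#' @return data.frame of per-variable state probabilities.
#' @export
predict.bdenet <- function(object, evidence = NULL, targets = NULL, ...) {
  if (is.null(evidence)) {
    if (is.null(targets)) targets <- object$dag$nodes
    rows <- lapply(targets, function(v) {
      p <- bn_query(object, v)
      data.frame(variable = v, p0 = p[["0"]], p1 = p[["1"]],
                 p2 = if (object$arity[[v]] >= 3L) p[["2"]] else NA_real_)
    })
    return(do.call(rbind, rows))
  }
  simulate_scenario(object, evidence, targets)
}

#' Ancestral samples from a fitted network
#'
#' Draws complete joint samples (including the condition variable) from the
#' fitted CPTs in topological order.
#'
#' @param object a `bdenet`.
#' @param nsim number of samples.
#' @param seed integer seed.
#' @param ... unused.
#' @return a [discrete_data()] with `nsim` rows.
#' @export
simulate.bdenet <- function(object, nsim = 1L, seed = NULL, ...) {
  topo <- topological_sort(object$dag)
  arity <- object$arity
  states <- matrix(NA_integer_, nsim, length(topo),
                   dimnames = list(sprintf("S%03d", seq_len(nsim)), topo))
  with_seed(seed, {
    for (v in topo) {
      cpt <- object$cpts[[v]]
      pa <- attr(cpt, "parents")
      j <- if (length(pa)) config_index(states[, pa, drop = FALSE], arity[pa])
           else rep(1L, nsim)
      st <- integer(nsim)
      for (jv in unique(j)) {
        idx <- which(j == jv)
        st[idx] <- sample.int(arity[[v]], length(idx), replace = TRUE,
                              prob = cpt[jv, ]) - 1L
      }
      states[, v] <- st
    }
  })
  discrete_data(states[, object$dag$nodes, drop = FALSE], arity)
}

#' Plot a fitted network
#'
#' Draws the learned DAG with igraph (if installed): arc width proportional
#' to annotation strength, dashed arcs for inhibition (sign `"-"`).
#'
#' @param x a `bdenet`.
#' @param highlight variables to color differently (e.g. the condition node).
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.bdenet <- function(x, highlight = "PiZ", ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting needs the igraph package")
  a <- arcs(x$dag)
  g <- igraph::graph_from_data_frame(
    as.data.frame(a), directed = TRUE,
    vertices = data.frame(name = x$dag$nodes))
  lty <- rep(1L, nrow(a))
  width <- rep(1, nrow(a))
  if (!is.null(x$edges) && nrow(x$edges)) {
    key <- paste(x$edges$parent, x$edges$child)
    m <- match(paste(a[, 1L], a[, 2L]), key)
    lty <- ifelse(x$edges$sign[m] == "-", 2L, 1L)
    s <- pmax(x$edges$strength[m], 0)
    width <- 1 + 3 * s / max(s, 1e-9)
  }
  cols <- ifelse(x$dag$nodes %in% highlight, "tomato", "lightsteelblue")
  igraph::plot.igraph(g, edge.lty = lty, edge.width = width,
                      vertex.color = cols, ...)
  invisible(x)
}

#' Assemble a network from explicit structure and CPTs
#'
#' Builds a `bdenet` object directly from a DAG and a list of conditional
#' probability tables (e.g. a known ground truth, or a hand-specified
#' what-if model), without fitting to data. CPT rows must sum to 1; row
#' order is the mixed-radix parent-configuration order (first parent
#' fastest), columns are state indices.
#'
#' @param d a [dag()].
#' @param cpts named list of `q x r` matrices, one per node, each carrying a
#'   `"parents"` attribute (as produced by [sample_cpts()]); for nodes whose
#'   CPT lacks the attribute the DAG's parent set (in node order) is used.
#' @param arity named arities; default 3 per variable, 2 for `"PiZ"`.
#' @return an unfitted `bdenet` (scores `NA`).
#' @export
as_bdenet <- function(d, cpts, arity = NULL) {
  stopifnot(inherits(d, "dag"))
  if (is.null(arity)) arity <- node_arities(d)
  arity <- arity[d$nodes]
  for (v in d$nodes) {
    tab <- cpts[[v]]
    if (is.null(tab)) stop("missing CPT for ", v)
    pa <- attr(tab, "parents")
    if (is.null(pa)) {
      pa <- parents(d, v)
      attr(cpts[[v]], "parents") <- pa
    }
    if (!setequal(pa, parents(d, v))) stop("CPT parents of ", v, " disagree with dag")
    q <- if (length(pa)) prod(arity[pa]) else 1L
    if (nrow(tab) != q || ncol(tab) != arity[[v]])
      stop("CPT of ", v, " has wrong dimensions")
    if (max(abs(rowSums(tab) - 1)) > 1e-9) stop("CPT rows of ", v, " must sum to 1")
  }
  structure(list(dag = d, arity = arity, cpts = cpts[d$nodes], ess = NA_real_,
                 log_score = NA_real_, normalized_score = NA_real_,
                 n_samples = 0L, edges = NULL, trace = NULL),
            class = "bdenet")
}

# ---- serialization -------------------------------------------------------

#' Serialize a fitted network to JSON / edge TSV / DOT
#'
#' `model_to_json()` writes (or returns) a self-contained JSON description:
#' variables, arities, arcs with strength and sign, CPT arrays, scores.
#' `model_from_json()` reconstructs the `bdenet` object.
#' `write_edges_tsv()` exports the annotated arc list; `write_dot()` writes a
#' Graphviz DOT file in which inhibition arcs are dashed and arc pen width
#' scales with strength.
#'
#' @param model a `bdenet`.
#' @param path output file; for `model_to_json()` `NULL` returns the JSON
#'   string instead.
#' @return `model_from_json()` returns a `bdenet`; the writers return their
#'   path invisibly.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "bdenet"))
  a <- arcs(model$dag)
  obj <- list(
    variables = model$dag$nodes,
    arities = as.list(model$arity),
    arcs = if (!is.null(model$edges)) model$edges
           else data.frame(parent = a[, "parent"], child = a[, "child"],
                           stringsAsFactors = FALSE),
    cpts = lapply(model$cpts, function(tab)
      list(parents = as.list(attr(tab, "parents")), table = unclass(tab))),
    ess = model$ess, log_score = model$log_score,
    normalized_score = model$normalized_score, n_samples = model$n_samples)
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vars <- obj$variables
  arity <- unlist(obj$arities)[vars]
  d <- dag(vars)
  if (NROW(obj$arcs) > 0L)
    for (i in seq_len(NROW(obj$arcs)))
      d$amat[obj$arcs$parent[i], obj$arcs$child[i]] <- 1L
  if (!is_acyclic(d)) stop("serialized structure is cyclic")
  cpts <- lapply(vars, function(v) {
    tab <- as.matrix(obj$cpts[[v]]$table)
    dimnames(tab) <- NULL
    attr(tab, "parents") <- as.character(unlist(obj$cpts[[v]]$parents))
    tab
  })
  names(cpts) <- vars
  edges <- NULL
  if (NROW(obj$arcs) > 0L && "strength" %in% names(obj$arcs)) edges <- obj$arcs
  structure(list(dag = d, arity = arity, cpts = cpts, ess = obj$ess,
                 log_score = obj$log_score,
                 normalized_score = obj$normalized_score,
                 n_samples = obj$n_samples, edges = edges, trace = NULL),
            class = "bdenet")
}

#' @rdname model_to_json
#' @export
write_edges_tsv <- function(model, path) {
  edges <- model$edges
  if (is.null(edges)) {
    a <- arcs(model$dag)
    edges <- data.frame(parent = a[, "parent"], child = a[, "child"],
                        strength = NA_real_, sign = NA_character_)
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
write_dot <- function(model, path) {
  a <- arcs(model$dag)
  lines <- c("digraph bdenet {", "  node [shape=ellipse];")
  style <- rep("", nrow(a))
  if (!is.null(model$edges) && nrow(model$edges)) {
    key <- paste(model$edges$parent, model$edges$child)
    m <- match(paste(a[, 1L], a[, 2L]), key)
    smax <- max(c(model$edges$strength, 1e-9), na.rm = TRUE)
    style <- sprintf(" [style=%s, penwidth=%.2f]",
                     ifelse(model$edges$sign[m] == "-", "dashed", "solid"),
                     1 + 3 * pmax(model$edges$strength[m], 0) / max(smax, 1e-9))
  }
  if (nrow(a))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", a[, 1L], a[, 2L], style))
  iso <- setdiff(model$dag$nodes, unique(c(a)))
  if (length(iso)) lines <- c(lines, sprintf("  \"%s\";", iso))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
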