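#' Directed acyclic graph over named variables
#'
#' A `dag` is the structural half of a Bayesian network: an ordered set of
#' variable names plus a binary adjacency matrix `amat` where
#' `amat[parent, child] == 1L` encodes the arc parent -> child.
#'
#' @param nodes character vector of unique variable names.
#' @param arcs optional two-column character matrix (or data.frame) of arcs,
#'   first column parents, second column children.
#' @return an object of class `dag`.
#' @examples
#' d <- dag(c("A", "B", "C"), arcs = cbind(c("A", "B"), c("B", "C")))
#' parents(d, "B")
#' @export
dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1L)
  if (anyDuplicated(nodes)) stop("duplicate node names: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  amat <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  d <- structure(list(nodes = nodes, amat = amat), class = "dag")
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    for (i in seq_len(nrow(arcs))) d <- add_arc(d, arcs[i, 1L], arcs[i, 2L])
  }
  d
}

n_nodes <- function(d) length(d$nodes)

check_node <- function(d, x) {
  if (!all(x %in% d$nodes)) {
    stop("unknown variable(s): ", paste(setdiff(x, d$nodes), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' @rdname dag
#' @param d a `dag`.
#' @param x a node name.
#' @export
parents <- function(d, x) {
  check_node(d, x)
  d$nodes[d$amat[, x] == 1L]
}

#' @rdname dag
#' @export
children <- function(d, x) {
  check_node(d, x)
  d$nodes[d$amat[x, ] == 1L]
}

#' @rdname dag
#' @param from,to arc endpoints.
#' @export
add_arc <- function(d, from, to) {
  check_node(d, c(from, to))
  if (from == to) stop("self-arc ", from, " -> ", to, " not allowed")
  if (d$amat[from, to] == 1L) stop("duplicate arc ", from, " -> ", to)
  d$amat[from, to] <- 1L
  if (!is_acyclic(d)) stop("arc ", from, " -> ", to, " would create a cycle")
  d
}

#' @rdname dag
#' @export
remove_arc <- function(d, from, to) {
  check_node(d, c(from, to))
  if (d$amat[from, to] != 1L) stop("no arc ", from, " -> ", to)
  d$amat[from, to] <- 0L
  d
}

#' @rdname dag
#' @export
arcs <- function(d) {
  idx <- which(d$amat == 1L, arr.ind = TRUE)
  out <- cbind(parent = d$nodes[idx[, 1L]], child = d$nodes[idx[, 2L]])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

n_arcs <- function(d) sum(d$amat)

#' Topological sort and acyclicity
#'
#' `topological_sort()` returns the node names in an order where every parent
#' precedes its children, or `NULL` if the graph has a cycle (Kahn's
#' algorithm). `is_acyclic()` is the corresponding predicate.
#'
#' @param d a `dag` (possibly cyclic, e.g. mid-validation).
#' @return character vector of node names, or `NULL` when cyclic.
#' @export
topological_sort <- function(d) {
  amat <- d$amat
  indeg <- colSums(amat)
  order <- character(0)
  avail <- which(indeg == 0L)
  indeg[avail] <- NA_integer_
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, d$nodes[v])
    ch <- which(amat[v, ] == 1L)
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (!is.na(indeg[w]) && indeg[w] == 0L) {
        avail <- c(avail, w)
        indeg[w] <- NA_integer_
      }
    }
  }
  if (length(order) < n_nodes(d)) NULL else order
}

#' @rdname topological_sort
#' @export
is_acyclic <- function(d) !is.null(topological_sort(d))

#' Validate a DAG and report any cycle
#'
#' Unlike [is_acyclic()] this never throws: it returns a small report that
#' either declares the structure valid or names one offending cycle.
#'
#' @param d a `dag`.
#' @return a list with elements `ok` (logical) and `cycle` (character vector
#'   of node names along one cycle, or `NULL`).
#' @examples
#' d <- dag(c("A", "B"))
#' d$amat["A", "B"] <- 1L; d$amat["B", "A"] <- 1L
#' validate_dag(d)$cycle
#' @export
validate_dag <- function(d) {
  if (is_acyclic(d)) return(list(ok = TRUE, cycle = NULL))
  # strip nodes not on any cycle by repeatedly deleting sources/sinks
  amat <- d$amat
  repeat {
    deg0 <- which(colSums(amat) == 0L | rowSums(amat) == 0L)
    keep <- setdiff(seq_len(ncol(amat)), deg0)
    if (length(deg0) == 0L || length(keep) == 0L) break
    amat <- amat[keep, keep, drop = FALSE]
  }
  nodes <- rownames(amat)
  # walk forward until a node repeats
  path <- nodes[1L]
  repeat {
    nxt <- nodes[amat[path[length(path)], ] == 1L][1L]
    if (nxt %in% path) {
      cyc <- path[seq(match(nxt, path), length(path))]
      return(list(ok = FALSE, cycle = cyc))
    }
    path <- c(path, nxt)
  }
}

# TRUE if a directed path to -> ... -> from exists (adding from->to would cycle)
has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  n <- ncol(amat)
  seen <- logical(n)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(amat[v, ] == 1L & !seen))
  }
  FALSE
}

#' Descendants of a node
#'
#' All variables reachable from `x` along directed arcs, excluding `x`.
#'
#' @param d a `dag`.
#' @param x node name.
#' @return character vector (possibly empty).
#' @export
descendants <- function(d, x) {
  check_node(d, x)
  i <- match(x, d$nodes)
  n <- n_nodes(d)
  seen <- logical(n)
  stack <- which(d$amat[i, ] == 1L)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(d$amat[v, ] == 1L & !seen))
  }
  d$nodes[seen]
}

# ancestral closure: the given nodes plus all their ancestors
ancestors_closure <- function(d, vars) {
  idx <- match(vars, d$nodes)
  n <- n_nodes(d)
  seen <- logical(n)
  stack <- idx
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(d$amat[, v] == 1L & !seen))
  }
  d$nodes[seen]
}

#' @export
print.dag <- function(x, ...) {
  cat("DAG over", n_nodes(x), "variables,", n_arcs(x), "arcs\n")
  a <- arcs(x)
  if (nrow(a)) {
    shown <- min(nrow(a), 20L)
    cat(paste(" ", a[seq_len(shown), 1L], "->", a[seq_len(shown), 2L]), sep = "\n")
    if (nrow(a) > shown) cat("  ... and", nrow(a) - shown, "more\n")
  }
  invisible(x)
}
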