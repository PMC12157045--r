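#' First-degree Markov blanket
#'
#' A node's parents, children, and the parents of its children (co-parents),
#' excluding the node itself. Conditioning on this set renders the node
#' independent of the rest of the network.
#'
#' @param d a [dag()] (or a fitted `bdenet`, whose structure is used).
#' @param x target variable name.
#' @return character vector of blanket members.
#' @export
first_degree_mb <- function(d, x) {
  if (inherits(d, "bdenet")) d <- d$dag
  check_node(d, x)
  ch <- children(d, x)
  co <- unique(unlist(lapply(ch, parents, d = d)))
  setdiff(unique(c(parents(d, x), ch, co)), x)
}

#' Second-degree Markov blanket
#'
#' The first-degree blanket together with the first-degree blanket of each of
#' its members, excluding the target itself.
#'
#' @inheritParams first_degree_mb
#' @return character vector of blanket members.
#' @export
second_degree_mb <- function(d, x) {
  if (inherits(d, "bdenet")) d <- d$dag
  mb <- first_degree_mb(d, x)
  ext <- unique(unlist(lapply(mb, first_degree_mb, d = d)))
  setdiff(unique(c(mb, ext)), x)
}

#' Markov blanket report with member roles
#'
#' Names each blanket member's relation to the target: `parent`, `child`,
#' `spouse` (co-parent sharing a child), or `second-degree` (reached only
#' through a first-degree member). A member with several roles gets the first
#' applicable one in that order.
#'
#' @inheritParams first_degree_mb
#' @param degree 1 or 2.
#' @return list of class `mb_report` with `target`, `degree`, `first_degree`,
#'   `second_degree`, and a `roles` data.frame.
#' @export
markov_blanket <- function(d, x, degree = 2L) {
  if (inherits(d, "bdenet")) d <- d$dag
  stopifnot(degree %in% c(1L, 2L))
  mb1 <- first_degree_mb(d, x)
  mb2 <- if (degree == 2L) second_degree_mb(d, x) else mb1
  pa <- parents(d, x)
  ch <- children(d, x)
  members <- if (degree == 2L) mb2 else mb1
  role <- vapply(members, function(v) {
    if (v %in% pa) "parent"
    else if (v %in% ch) "child"
    else if (v %in% mb1) "spouse"
    else "second-degree"
  }, character(1))
  structure(list(target = x, degree = degree, first_degree = mb1,
                 second_degree = mb2,
                 roles = data.frame(variable = members, role = unname(role),
                                    stringsAsFactors = FALSE)),
            class = "mb_report")
}

#' @export
print.mb_report <- function(x, ...) {
  cat(sprintf("Markov blanket of %s (degree %d): %d member(s)\n", x$target,
              x$degree, nrow(x$roles)))
  if (nrow(x$roles)) print(x$roles, row.names = FALSE)
  invisible(x)
}

#' Numerical check of the Markov condition
#'
#' For a target `x` and a non-descendant `y`, verifies on the fitted joint
#' distribution -- by exact inference -- that
#' `P(x | given, y) = P(x | given)` for every configuration of positive
#' probability, where the conditioning set defaults to `parents(x)` (the
#' Markov condition). Pass `given = character(0)` to test marginal
#' independence instead (e.g. to demonstrate that a child is *not*
#' independent of its parent). When `y` is a descendant of `x` the check is
#' not applicable and the report says so instead of erroring.
#'
#' @param model a fitted `bdenet`.
#' @param x,y variable names.
#' @param given conditioning variables; `NULL` means `parents(x)`.
#' @param tol numerical tolerance on the probability differences.
#' @return list with `applicable`, `independent`, `max_deviation`.
#' @export
conditional_independence_check <- function(model, x, y, given = NULL,
                                           tol = 1e-9) {
  stopifnot(inherits(model, "bdenet"))
  check_node(model$dag, c(x, y))
  if (y %in% descendants(model$dag, x))
    return(list(applicable = FALSE, independent = NA,
                max_deviation = NA_real_))
  pa <- if (is.null(given)) parents(model$dag, x) else given
  check_node(model$dag, pa)
  if (y %in% pa)  # conditioning set already contains y
    return(list(applicable = TRUE, independent = TRUE, max_deviation = 0))
  arity <- model$arity
  rx <- arity[[x]]
  qpa <- if (length(pa)) prod(arity[pa]) else 1L
  ry <- arity[[y]]
  # one exact joint over (x, parents(x), y); conditionals are then ratios
  joint <- bn_query(model, c(x, pa, y))
  with_y <- matrix(as.vector(joint), nrow = rx)      # cols: (pa, y) configs
  p_cfg <- colSums(with_y)
  flat <- matrix(as.vector(joint), nrow = rx * qpa)  # marginalize y out
  wo_y <- matrix(rowSums(flat), nrow = rx)           # cols: pa configs
  p_pa <- colSums(wo_y)
  max_dev <- 0
  for (col in which(p_cfg > 0)) {
    ipa <- (col - 1L) %% qpa + 1L
    dev <- abs(with_y[, col] / p_cfg[col] - wo_y[, ipa] / p_pa[ipa])
    max_dev <- max(max_dev, dev)
  }
  list(applicable = TRUE, independent = max_dev <= tol, max_deviation = max_dev)
}
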