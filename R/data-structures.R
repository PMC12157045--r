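#' Gene-by-sample count matrix with condition labels
#'
#' Container for raw RNA-seq counts: a non-negative integer matrix with genes
#' in rows and samples in columns, plus a per-sample condition label coded
#' 0 = wildtype, 1 = PiZ (or any two-group design).
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param condition per-sample labels: either integers in \{0, 1\} or the
#'   strings `"wildtype"` / `"PiZ"`; named by sample or in column order.
#' @return object of class `count_matrix`.
#' @examples
#' m <- count_matrix(matrix(rpois(20, 50), 4, 5,
#'                          dimnames = list(paste0("g", 1:4), paste0("s", 1:5))),
#'                   condition = c(0, 0, 0, 1, 1))
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  condition <- normalize_condition(condition, colnames(counts))
  structure(list(counts = counts, condition = condition), class = "count_matrix")
}

normalize_condition <- function(condition, samples) {
  if (is.character(condition) || is.factor(condition)) {
    condition <- as.character(condition)
    bad <- setdiff(unique(condition), c("wildtype", "PiZ"))
    if (length(bad)) stop("condition labels must be 'wildtype'/'PiZ' or 0/1, got: ",
                          paste(bad, collapse = ", "))
    condition <- ifelse(condition == "PiZ", 1L, 0L)
  }
  condition <- as.integer(condition)
  if (!all(condition %in% c(0L, 1L))) stop("condition codes must be 0 or 1")
  if (is.null(names(condition))) {
    if (length(condition) != length(samples))
      stop("need one condition label per sample")
    names(condition) <- samples
  } else {
    missing <- setdiff(samples, names(condition))
    if (length(missing))
      stop("no condition label for sample: ", paste(missing, collapse = ", "))
    condition <- condition[samples]
  }
  condition
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples",
      sprintf("(%d wildtype, %d PiZ)\n", sum(x$condition == 0L), sum(x$condition == 1L)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Discretized expression dataset
#'
#' The input to all network operations: an integer matrix of per-sample state
#' codes with samples in rows and variables in columns. Gene variables use the
#' three-state code 1 = low, 0 = no change, 2 = high; the binary condition
#' variable (conventionally named `"PiZ"`) uses 0 = wildtype, 1 = PiZ. Codes
#' for a variable of arity r always lie in `0:(r-1)`, so code + 1 is a valid
#' 1-based state index.
#'
#' @param states integer matrix, samples x variables, with column names.
#' @param arity named integer vector of variable arities (default: 3 for every
#'   variable except a variable named `"PiZ"`, which gets 2).
#' @return object of class `discrete_data`.
#' @export
discrete_data <- function(states, arity = NULL) {
  states <- as.matrix(states)
  if (is.null(colnames(states))) stop("states must have variable column names")
  if (anyDuplicated(colnames(states)))
    stop("duplicate variable name: ",
         paste(unique(colnames(states)[duplicated(colnames(states))]), collapse = ", "))
  storage.mode(states) <- "integer"
  if (is.null(arity)) {
    arity <- ifelse(colnames(states) == "PiZ", 2L, 3L)
    names(arity) <- colnames(states)
  }
  arity <- arity[colnames(states)]
  if (any(is.na(arity)) || any(arity < 2L)) stop("every variable needs an arity >= 2")
  for (v in colnames(states)) {
    bad <- states[, v] < 0L | states[, v] >= arity[[v]]
    if (any(is.na(states[, v])) || any(bad))
      stop("states of ", v, " outside 0:", arity[[v]] - 1L)
  }
  structure(list(states = states, arity = arity), class = "discrete_data")
}

#' @export
print.discrete_data <- function(x, ...) {
  cat("discrete_data:", nrow(x$states), "samples x", ncol(x$states), "variables\n")
  invisible(x)
}

#' @export
dim.discrete_data <- function(x) dim(x$states)

variables <- function(data) colnames(data$states)

n_samples <- function(data) nrow(data$states)

# ordinal recoding used for edge signs: low -> -1, no change -> 0, high -> +1;
# binary variables keep 0/1
ordinal_codes <- function(states, arity) {
  if (arity == 3L) c(0, -1, 1)[states + 1L] else as.numeric(states)
}
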