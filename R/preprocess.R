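#' Remove genes with consistently low counts
#'
#' A gene is dropped iff its raw count is below `min_count` in at least
#' `min_samples` samples (default: counts under 10 in five or more samples).
#' Sample set and gene order are preserved.
#'
#' @param x a [count_matrix()].
#' @param min_count threshold a count must reach (strict `<` comparison).
#' @param min_samples how many low samples condemn a gene.
#' @return a filtered [count_matrix()].
#' @export
filter_low_counts <- function(x, min_count = 10L, min_samples = 5L) {
  stopifnot(inherits(x, "count_matrix"), min_count >= 0, min_samples >= 1)
  if (nrow(x$counts) == 0L || ncol(x$counts) == 0L) stop("empty count matrix")
  low <- rowSums(x$counts < min_count)
  keep <- low < min_samples
  count_matrix(x$counts[keep, , drop = FALSE], x$condition)
}

#' Median-of-ratios size factors
#'
#' The per-sample scale factor is the median, across reference genes, of the
#' sample's count divided by the gene's geometric mean across all samples.
#' Reference genes are those with strictly positive counts in every sample
#' (positive geometric mean). With an even number of reference genes the
#' median is the midpoint of the two central ratios.
#'
#' @param x a [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  ref <- rowSums(counts > 0L) == ncol(counts)
  if (!any(ref)) stop("degenerate input: no gene with positive counts in every sample")
  logc <- log(counts[ref, , drop = FALSE])
  geomean <- exp(rowMeans(logc))
  factors <- apply(counts[ref, , drop = FALSE] / geomean, 2L, stats::median)
  if (any(factors <= 0)) stop("non-positive size factor")
  factors
}

#' Divide counts by per-sample size factors
#'
#' @param x a [count_matrix()].
#' @param factors positive numeric vector, one per sample (e.g. from
#'   [size_factors_median_of_ratios()]).
#' @return real-valued matrix of normalized counts (genes x samples).
#' @export
normalize_counts <- function(x, factors = size_factors_median_of_ratios(x)) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(factors) != ncol(x$counts)) stop("need one factor per sample")
  if (any(factors <= 0)) stop("size factors must be positive")
  sweep(x$counts, 2L, factors, "/")
}

#' Per-gene log2 fold change (PiZ over wildtype)
#'
#' `log2((mean_PiZ + pseudocount) / (mean_wildtype + pseudocount))` on the
#' normalized scale. With `shrink = TRUE` the estimate is moderated toward 0
#' by the factor `n_eff / (n_eff + 1)` with `n_eff` the smaller group size --
#' a light-touch stand-in for Bayesian shrinkage estimators that pulls
#' small-sample fold changes in without changing their sign or order.
#'
#' @param normalized genes x samples matrix from [normalize_counts()].
#' @param condition per-sample 0/1 codes (0 = wildtype, 1 = PiZ).
#' @param pseudocount added to both group means before the ratio.
#' @param shrink logical; apply the multiplicative moderation.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(normalized, condition, pseudocount = 1,
                             shrink = FALSE) {
  condition <- as.integer(condition)
  if (!any(condition == 0L) || !any(condition == 1L))
    stop("both conditions must be present")
  m1 <- rowMeans(normalized[, condition == 1L, drop = FALSE])
  m0 <- rowMeans(normalized[, condition == 0L, drop = FALSE])
  lfc <- log2((m1 + pseudocount) / (m0 + pseudocount))
  if (shrink) {
    n_eff <- min(sum(condition == 0L), sum(condition == 1L))
    lfc <- lfc * n_eff / (n_eff + 1)
  }
  lfc
}

#' Select genes by fold change and interest list
#'
#' Keeps genes with `|lfc| > cutoff` (strict) plus any genes of interest that
#' survived filtering, in the input gene order. Interest genes absent from the
#' universe produce a warning, never a failure.
#'
#' @param lfc named per-gene log2 fold changes (the selection universe).
#' @param cutoff strict absolute threshold (default 2).
#' @param genes_of_interest character vector of gene ids always retained.
#' @return character vector of selected gene ids.
#' @export
select_genes <- function(lfc, cutoff = 2, genes_of_interest = character(0)) {
  universe <- names(lfc)
  absent <- setdiff(genes_of_interest, universe)
  if (length(absent))
    warning("genes of interest absent after filtering: ",
            paste(absent, collapse = ", "))
  universe[abs(lfc) > cutoff | universe %in% genes_of_interest]
}

#' Per-gene z-score standardization
#'
#' Each gene is centered and scaled across all samples pooled (both
#' conditions), using the sample (n - 1) standard deviation. Genes with zero
#' variance get all-zero z-scores ("no change" everywhere) with a warning
#' rather than an error, so constant genes of interest stay in the table.
#'
#' @param normalized genes x samples matrix.
#' @return z-score matrix of the same shape.
#' @export
zscore_standardize <- function(normalized) {
  if (ncol(normalized) < 2L) stop("need at least 2 samples")
  mu <- rowMeans(normalized)
  sd <- apply(normalized, 1L, stats::sd)
  flat <- sd == 0 | is.na(sd)
  if (any(flat)) {
    warning("zero-variance gene(s) set to z = 0: ",
            paste(rownames(normalized)[flat], collapse = ", "))
    sd[flat] <- 1
  }
  (normalized - mu) / sd
}

#' Discretize z-scores into three expression states
#'
#' States follow the convention: `z < z_low` is low expression (code 1),
#' `z_low <= z <= z_high` is no change (code 0, boundaries inclusive), and
#' `z > z_high` is high expression (code 2). The binary condition variable
#' `"PiZ"` is appended from the sample labels (wildtype -> 0, PiZ -> 1).
#'
#' @param z genes x samples z-score matrix.
#' @param condition per-sample 0/1 codes.
#' @param z_low,z_high state boundaries (defaults -1 and +1).
#' @return a [discrete_data()] (samples x variables) with variables = genes
#'   plus `"PiZ"`.
#' @export
discretize_expression <- function(z, condition, z_low = -1, z_high = 1) {
  if (z_low >= z_high) stop("z_low must be < z_high")
  codes <- matrix(0L, nrow(z), ncol(z), dimnames = dimnames(z))
  codes[z < z_low] <- 1L
  codes[z > z_high] <- 2L
  states <- cbind(t(codes), PiZ = as.integer(condition))
  discrete_data(states)
}

#' Counts-to-states preprocessing pipeline
#'
#' Runs the fixed stage order filter -> normalize -> log2 fold change ->
#' gene selection -> z-score -> discretize and returns every intermediate.
#' Re-running on already-discrete input (all values in \{0, 1, 2\}) is
#' rejected.
#'
#' @param x a [count_matrix()].
#' @param genes_of_interest gene ids always retained (besides the fold-change
#'   selection).
#' @param min_count,min_samples low-count filter, see [filter_low_counts()].
#' @param lfc_cutoff strict `|lfc|` selection threshold.
#' @param pseudocount,shrink fold-change options, see [log2_fold_change()].
#' @param z_low,z_high discretization boundaries.
#' @return list of class `bdenet_preprocessed` with elements `filtered`,
#'   `size_factors`, `normalized`, `lfc`, `selected`, `z`, `data` (the
#'   [discrete_data()] over selected genes + `"PiZ"`) and `params`.
#' @export
preprocess_counts <- function(x, genes_of_interest = character(0),
                              min_count = 10L, min_samples = 5L,
                              lfc_cutoff = 2, pseudocount = 1, shrink = TRUE,
                              z_low = -1, z_high = 1) {
  stopifnot(inherits(x, "count_matrix"))
  if (all(x$counts %in% 0:2))
    stop("input looks already discretized (all values in {0,1,2}); ",
         "preprocess_counts() expects raw counts")
  filtered <- filter_low_counts(x, min_count, min_samples)
  factors <- size_factors_median_of_ratios(filtered)
  normalized <- normalize_counts(filtered, factors)
  lfc <- log2_fold_change(normalized, filtered$condition, pseudocount, shrink)
  selected <- select_genes(lfc, lfc_cutoff, genes_of_interest)
  if (!length(selected)) stop("no genes selected; lower lfc_cutoff or supply interest genes")
  z <- zscore_standardize(normalized[selected, , drop = FALSE])
  data <- discretize_expression(z, filtered$condition, z_low, z_high)
  structure(list(filtered = filtered, size_factors = factors,
                 normalized = normalized, lfc = lfc, selected = selected,
                 z = z, data = data,
                 params = list(min_count = min_count, min_samples = min_samples,
                               lfc_cutoff = lfc_cutoff, pseudocount = pseudocount,
                               shrink = shrink, z_low = z_low, z_high = z_high)),
            class = "bdenet_preprocessed")
}

#' @export
print.bdenet_preprocessed <- function(x, ...) {
  cat("bdenet preprocessing:", nrow(x$filtered$counts), "genes kept,",
      length(x$selected), "selected ->",
      ncol(x$data$states), "network variables x", nrow(x$data$states), "samples\n")
  invisible(x)
}
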