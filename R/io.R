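#' Read and write count matrices as TSV
#'
#' The canonical interchange format: a tab-separated table whose first column
#' is `gene_id` and remaining columns are sample ids, plus a two-column
#' condition file (`sample_id`, `condition`) mapping every sample to
#' `wildtype`/`PiZ` (or 0/1). CSV input is accepted on read.
#'
#' @param path counts file.
#' @param conditions_path condition-label file.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, conditions_path) {
  tab <- read_delim_auto(path)
  if (names(tab)[1L] != "gene_id")
    stop("format error: first column must be 'gene_id', found '", names(tab)[1L], "'")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("format error: duplicate gene row: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(is.na(counts)) || any(counts != round(counts)))
    stop("format error: counts must be integers")
  rownames(counts) <- genes
  cond <- read_delim_auto(conditions_path)
  if (!all(c("sample_id", "condition") %in% names(cond)))
    stop("format error: condition file needs 'sample_id' and 'condition' columns")
  labels <- stats::setNames(as.character(cond$condition), cond$sample_id)
  missing <- setdiff(colnames(counts), names(labels))
  if (length(missing))
    stop("format error: no condition for sample: ", paste(missing, collapse = ", "))
  count_matrix(counts, labels[colnames(counts)])
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' @rdname read_count_matrix
#' @param x a [count_matrix()].
#' @param counts_path,out_dir output locations.
#' @export
write_count_matrix <- function(x, counts_path, conditions_path) {
  tab <- data.frame(gene_id = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cond <- data.frame(sample_id = colnames(x$counts),
                     condition = ifelse(x$condition == 1L, "PiZ", "wildtype"))
  utils::write.table(cond, conditions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Parse a GEO-style supplementary counts table
#'
#' Reads a locally available counts file as deposited with GEO series (genes
#' in rows, one id column, samples in columns), auto-detecting the gene id
#' column among common header synonyms (`gene_id`, `geneid`, `gene`,
#' `symbol`, `gene_symbol`, `name`, `id`, `ensembl_id`), and assigns
#' conditions by matching regular-expression rules against the sample column
#' titles (e.g. titles containing `"PiZ"`).
#'
#' @param path counts file (TSV or CSV). Never downloaded: callers fetch the
#'   file themselves.
#' @param condition_rules named character vector of regular expressions; the
#'   names must be `PiZ` and `wildtype`. Every sample must match exactly one
#'   rule, and every rule must match at least one sample.
#' @return a [count_matrix()].
#' @export
geo_series_to_counts <- function(path,
                                 condition_rules = c(PiZ = "PiZ",
                                                     wildtype = "WT|wildtype|C57")) {
  if (!setequal(names(condition_rules), c("PiZ", "wildtype")))
    stop("condition_rules must be named 'PiZ' and 'wildtype'")
  tab <- read_delim_auto(path)
  synonyms <- c("gene_id", "geneid", "gene", "symbol", "gene_symbol", "name",
                "id", "ensembl_id")
  hit <- which(tolower(names(tab)) %in% synonyms)
  if (!length(hit)) stop("format error: no gene id column found (looked for: ",
                         paste(synonyms, collapse = ", "), ")")
  idcol <- hit[1L]
  counts <- as.matrix(tab[, -idcol, drop = FALSE])
  rownames(counts) <- as.character(tab[[idcol]])
  samples <- colnames(counts)
  cond <- rep(NA_integer_, length(samples))
  for (lab in names(condition_rules)) {
    m <- grepl(condition_rules[[lab]], samples)
    if (!any(m)) stop("format error: condition rule '", lab,
                      "' matched no sample")
    cond[m] <- if (lab == "PiZ") 1L else 0L
  }
  if (any(is.na(cond)))
    stop("format error: no condition rule matched sample: ",
         paste(samples[is.na(cond)], collapse = ", "))
  count_matrix(counts, stats::setNames(cond, samples))
}

#' Read and write discretized datasets as TSV
#'
#' Genes-in-rows integer-coded table (first column `variable`), the same
#' orientation as the count TSV.
#'
#' @param data a [discrete_data()].
#' @param path output file.
#' @export
write_discrete_tsv <- function(data, path) {
  tab <- data.frame(variable = variables(data), t(data$states),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_discrete_tsv
#' @export
read_discrete_tsv <- function(path) {
  tab <- read_delim_auto(path)
  vars <- as.character(tab[[1L]])
  states <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(states) <- vars
  discrete_data(states)
}

#' Serialize a synthetic ground truth to JSON
#'
#' @param truth a [synthetic_truth()].
#' @param path output file, or `NULL` to return the JSON string.
#' @export
truth_to_json <- function(truth, path = NULL) {
  a <- arcs(truth$dag)
  obj <- list(nodes = truth$dag$nodes,
              arcs = data.frame(parent = a[, "parent"], child = a[, "child"],
                                stringsAsFactors = FALSE),
              cpts = lapply(truth$cpts, function(tab)
                list(parents = as.list(attr(tab, "parents")),
                     table = unclass(tab))),
              count_params = list(
                baseline_mu = as.list(truth$count_params$baseline_mu),
                fold = truth$count_params$fold,
                dispersion = truth$count_params$dispersion),
              seed = truth$seed)
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname truth_to_json
#' @export
truth_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  d <- dag(obj$nodes)
  if (NROW(obj$arcs) > 0L)
    for (i in seq_len(NROW(obj$arcs)))
      d$amat[obj$arcs$parent[i], obj$arcs$child[i]] <- 1L
  cpts <- lapply(obj$nodes, function(v) {
    tab <- as.matrix(obj$cpts[[v]]$table)
    dimnames(tab) <- NULL
    attr(tab, "parents") <- as.character(unlist(obj$cpts[[v]]$parents))
    tab
  })
  names(cpts) <- obj$nodes
  synthetic_truth(d, cpts, unlist(obj$count_params$baseline_mu),
                  fold = obj$count_params$fold,
                  dispersion = obj$count_params$dispersion,
                  seed = obj$seed)
}

# tiny FNV-1a hash for self-describing outputs (no digest dependency);
# 32-bit arithmetic done exactly in doubles via 16-bit limbs
fnv1a <- function(text) {
  bytes <- utf8ToInt(text)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Collects every threshold and seed of the end-to-end pipeline in one
#' object. The defaults reproduce the published analysis settings: low-count
#' filter 10 in >= 5 samples, strict |lfc| > 2 selection, z boundaries -1 and
#' +1, uniform BDe prior (ess 1), 3 searches per round, 15% stopping rule,
#' condition variable `"PiZ"`.
#'
#' @param min_count,min_samples low-count filter.
#' @param lfc_cutoff,pseudocount,shrink fold-change selection.
#' @param z_low,z_high discretization boundaries.
#' @param ess BDe equivalent sample size.
#' @param budget round-1 move-evaluation budget per search.
#' @param searches searches per round.
#' @param improvement stopping threshold.
#' @param max_rounds maximum rounds.
#' @param max_parents in-degree cap during the search. The pipeline default
#'   is 3: with a handful of samples per condition, families with more
#'   parents have more configurations than observations, and the unbounded
#'   search wanders into them.
#' @param seed master seed for all randomness.
#' @param target condition variable name.
#' @param genes_of_interest always-retained gene ids.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_count = 10L, min_samples = 5L, lfc_cutoff = 2,
                            pseudocount = 1, shrink = TRUE, z_low = -1,
                            z_high = 1, ess = 1, budget = 2000L, searches = 3L,
                            improvement = 0.15, max_rounds = 6L,
                            max_parents = 3L, seed = 1L, target = "PiZ",
                            genes_of_interest = character(0)) {
  cfg <- list(min_count = min_count, min_samples = min_samples,
              lfc_cutoff = lfc_cutoff, pseudocount = pseudocount,
              shrink = shrink, z_low = z_low, z_high = z_high, ess = ess,
              budget = budget, searches = searches, improvement = improvement,
              max_rounds = max_rounds, max_parents = max_parents, seed = seed,
              target = target, genes_of_interest = genes_of_interest)
  if (cfg$z_low >= cfg$z_high || cfg$ess <= 0 || cfg$budget < 1 ||
      cfg$searches < 1 || cfg$improvement < 0 || cfg$max_rounds < 2)
    stop("invalid pipeline configuration")
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  fnv1a(paste(deparse(unclass(cfg)), collapse = ""))
}

#' Run the full counts-to-inference pipeline
#'
#' Executes the complete workflow: preprocessing (filter, normalize, select,
#' discretize), a first-pass structure search over all selected genes,
#' refinement to the target's second-degree Markov blanket plus genes of
#' interest, a final search on the reduced variable set, Markov-blanket
#' report, evidence-clamping scenario contrast (condition 1 vs 0), and top
#' 2-gene state combinations within the first-degree blanket.
#'
#' @param counts a [count_matrix()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every artifact is written
#'   there (TSV/JSON/DOT) with the configuration and its hash embedded in
#'   `config.json`.
#' @param verbose print one progress line per stage.
#' @return list of class `bdenet_bundle`: `config`, `config_hash`,
#'   `preprocessed`, `first_pass`, `refined_data`, `model`, `mb`,
#'   `scenarios`, `combinations`, `log`.
#' @export
run_full_pipeline <- function(counts, config = pipeline_config(),
                              out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(counts, "count_matrix"), inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...))
    if (verbose) message(line)
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  say("preprocess: %d genes x %d samples in", nrow(counts$counts),
      ncol(counts$counts))
  prep <- stage("preprocess", preprocess_counts(
    counts, config$genes_of_interest, config$min_count, config$min_samples,
    config$lfc_cutoff, config$pseudocount, config$shrink, config$z_low,
    config$z_high))
  say("preprocess: %d variables selected", ncol(prep$data$states))
  first_pass <- stage("first_pass", run_protocol(
    prep$data, budget = config$budget, searches = config$searches,
    improvement = config$improvement, max_rounds = config$max_rounds,
    ess = config$ess, max_parents = config$max_parents,
    seed = derive_seed(config$seed, 101L)))
  say("first pass: %d arcs, normalized score %.5f; rounds: budgets %s",
      n_arcs(first_pass$dag), first_pass$normalized_score,
      paste(vapply(first_pass$trace$rounds, `[[`, integer(1), "budget"),
            collapse = ", "))
  refined <- stage("refine", refine_and_research(
    prep$data, first_pass, target = config$target,
    genes_of_interest = config$genes_of_interest, budget = config$budget,
    searches = config$searches, improvement = config$improvement,
    max_rounds = config$max_rounds, ess = config$ess,
    max_parents = config$max_parents, seed = derive_seed(config$seed, 102L)))
  model <- refined$model
  say("refined search: %d variables, %d arcs, normalized score %.5f; stop: %s",
      length(model$dag$nodes), n_arcs(model$dag), model$normalized_score,
      if (is.null(model$trace)) "single-variable shortcut"
      else paste0("round ", length(model$trace$rounds), ", improvement ",
                  sprintf("%.3f", model$trace$rounds[[length(model$trace$rounds)]]$improvement %||% NA)))
  mb <- stage("blanket", markov_blanket(model$dag, config$target, 2L))
  say("blanket: %d first-degree, %d second-degree members",
      length(mb$first_degree), length(mb$second_degree))
  scenarios <- stage("inference", scenario_contrast(
    model, stats::setNames(1L, config$target), stats::setNames(0L, config$target)))
  combos <- NULL
  if (length(mb$first_degree) >= 2L) {
    combos <- stage("inference", top_state_combinations(
      model, mb$first_degree, k = 2L,
      evidence = stats::setNames(1L, config$target)))
  }
  say("pipeline complete")
  bundle <- structure(list(config = config, config_hash = config_hash(config),
                           preprocessed = prep, first_pass = first_pass,
                           refined_data = refined$data, model = model, mb = mb,
                           scenarios = scenarios, combinations = combos,
                           log = log),
                      class = "bdenet_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.bdenet_bundle <- function(x, ...) {
  cat("bdenet pipeline bundle (config", x$config_hash, ")\n")
  cat(" ", length(x$preprocessed$selected), "selected genes ->",
      length(x$model$dag$nodes), "refined variables\n")
  cat("  final model:", n_arcs(x$model$dag), "arcs, normalized score",
      sprintf("%.5f\n", x$model$normalized_score))
  cat("  MB(", x$config$target, "): ", length(x$mb$first_degree),
      " first-degree / ", length(x$mb$second_degree), " second-degree\n",
      sep = "")
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)
  cfg <- unclass(bundle$config)
  cfg$config_hash <- bundle$config_hash
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), fp("config.json"))
  writeLines(bundle$preprocessed$selected, fp("selected_genes.txt"))
  write_discrete_tsv(bundle$preprocessed$data, fp("discrete_data.tsv"))
  model_to_json(bundle$first_pass, fp("first_pass_model.json"))
  model_to_json(bundle$model, fp("final_model.json"))
  write_edges_tsv(bundle$model, fp("final_edges.tsv"))
  write_dot(bundle$model, fp("final_model.dot"))
  writeLines(jsonlite::toJSON(list(
    target = bundle$config$target,
    first_degree = bundle$mb$first_degree,
    second_degree = bundle$mb$second_degree,
    config_hash = bundle$config_hash), auto_unbox = TRUE),
    fp("markov_blanket.json"))
  utils::write.table(bundle$scenarios, fp("scenario_contrast.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$combinations))
    utils::write.table(as.data.frame(bundle$combinations),
                       fp("combinations_k2.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  writeLines(c(paste("# config", bundle$config_hash), bundle$log),
             fp("pipeline.log"))
  invisible(out_dir)
}
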