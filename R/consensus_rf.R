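#' Configuration for consensus random-forest signature extraction
#'
#' Defaults reproduce the published procedure exactly: 100 models, each a
#' 1000-tree random forest fit on a random 50% training half of the cohort
#' and evaluated on the other half, with the 200 most important genes
#' collected per model and aggregated by occurrence count.
#'
#' @param n_models number of independently split-and-fit models.
#' @param n_trees trees per forest.
#' @param train_fraction fraction of samples in the training half.
#' @param top_k genes kept per model and length of the consensus signature.
#' @param exclude_target drop the target gene's row from the feature matrix
#'   before training (the leave-target-out robustness check).
#' @param stratify stratify the 50/50 split by class (default TRUE; with a
#'   few percent positives, unstratified splits risk degenerate training
#'   halves — set FALSE for the literal unstratified reading).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param max_bins histogram bins per feature for split search.
#' @param seed base seed; model i uses `seed + i`.
#' @return an `RFConfig` list.
#' @export
rf_config <- function(n_models = 100L, n_trees = 1000L, train_fraction = 0.5,
                      top_k = 200L, exclude_target = FALSE, stratify = TRUE,
                      mtry = NULL, max_bins = 64L, seed = 1L) {
  cfg <- list(n_models = as.integer(n_models), n_trees = as.integer(n_trees),
              train_fraction = train_fraction, top_k = as.integer(top_k),
              exclude_target = isTRUE(exclude_target),
              stratify = isTRUE(stratify), mtry = mtry,
              max_bins = as.integer(max_bins), seed = as.integer(seed))
  stopifnot(cfg$n_models >= 1L, cfg$n_trees >= 1L, cfg$top_k >= 1L,
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  class(cfg) <- "RFConfig"
  cfg
}

# Draw a train/eval split (0-based indices for the C++ core).  Stratified
# splits take train_fraction within each class; unstratified splits are
# redrawn (up to 100 times) if a class is missing from the training half.
draw_split <- function(y, config) {
  n <- length(y)
  if (config$stratify) {
    train <- integer(0)
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_tr <- max(1L, floor(length(idx) * config$train_fraction))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
  } else {
    for (attempt in 1:100) {
      train <- sort(sample(n, max(2L, floor(n * config$train_fraction))))
      if (length(unique(y[train])) == 2L) break
      if (attempt == 100L) stop("could not draw a training half with both classes")
    }
  }
  list(train = train - 1L, eval = setdiff(seq_len(n), train) - 1L)
}

# Shared worker: Xt is samples x genes; y is 0/1 in row order of Xt.
train_model_worker <- function(Xt, gene_ids, sample_ids, y, config, model_seed) {
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("need at least 2 samples per class")
  }
  p <- ncol(Xt)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  split <- with_seed(model_seed, draw_split(y, config))
  fit <- .rf_fit_cpp(Xt, y, split$train, split$eval, config$n_trees,
                     as.integer(mtry), as.numeric(model_seed), config$max_bins)
  eval_idx <- split$eval + 1L
  pred <- ifelse(fit$prediction == 1L, "high", "rest")
  names(pred) <- sample_ids[eval_idx]
  acc <- mean(fit$prediction == y[eval_idx])
  k <- min(config$top_k, p)
  ord <- order(-fit$importance, gene_ids)[seq_len(k)]
  structure(list(model_index = NA_integer_,
                 model_seed = model_seed,
                 eval_sample_ids = sample_ids[eval_idx],
                 eval_predictions = pred,
                 eval_accuracy = acc,
                 topk_genes = data.frame(gene_id = gene_ids[ord],
                                         importance = fit$importance[ord],
                                         stringsAsFactors = FALSE)),
            class = "ModelRun")
}

#' Fit one random-forest model on a fresh 50/50 split
#'
#' Fits a bagged decision-tree ensemble (Gini impurity splits, impurity
#' importances summing to 1 across features) on the training half of the
#' cohort, on raw unlogged expression values, and evaluates it on the held
#' out half.  Fully reproducible from `model_seed`.
#'
#' @param expr an [expression_matrix()] (genes x samples).
#' @param labels a `DichotomyLabels` from [select_high_expressers()].
#' @param config an [rf_config()].
#' @param model_seed integer seed for split, bootstrap and feature sampling.
#' @return a `ModelRun`: held-out sample ids and predictions, evaluation
#'   accuracy, and the importance-ranked `top_k` gene table (ties at the
#'   boundary broken by gene id).
#' @export
train_single_model <- function(expr, labels, config = rf_config(),
                               model_seed = config$seed) {
  validate_expression_matrix(expr)
  y <- labels_as_int(labels, colnames(expr))
  train_model_worker(t(unclass(expr)), rownames(expr), colnames(expr), y,
                     config, model_seed)
}

#' Aggregate per-model top-k gene lists into a consensus ranking
#'
#' Occurrences of each gene across the per-model top-k lists are summed;
#' genes are ranked by occurrence (descending), then mean importance over
#' the models where they appear (descending), then gene id (ascending), and
#' the ranking is truncated to `top_k`.
#'
#' @param topk_lists list of data.frames with columns `gene_id`,
#'   `importance` (one per model, all of equal length).
#' @param top_k length of the returned ranking.
#' @return data.frame `rank`, `gene_id`, `occurrences`, `mean_importance`.
#' @export
rank_by_occurrence <- function(topk_lists, top_k) {
  if (!length(topk_lists)) stop("no model lists to aggregate")
  lens <- vapply(topk_lists, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("per-model lists differ in length")
  all_genes <- unlist(lapply(topk_lists, `[[`, "gene_id"), use.names = FALSE)
  all_imp <- unlist(lapply(topk_lists, `[[`, "importance"), use.names = FALSE)
  occ <- tapply(all_imp, all_genes, length)
  mimp <- tapply(all_imp, all_genes, mean)
  genes <- names(occ)
  ord <- order(-as.integer(occ), -as.numeric(mimp), genes)
  k <- min(top_k, length(genes))
  sel <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), gene_id = genes[sel],
             occurrences = as.integer(occ[sel]),
             mean_importance = as.numeric(mimp[sel]),
             stringsAsFactors = FALSE)
}

#' Extract a consensus signature from repeated random-forest fits
#'
#' Trains `n_models` forests on independent splits (model i seeded with
#' `seed + i`), collects each model's `top_k` genes by impurity importance,
#' and aggregates them with [rank_by_occurrence()].  With
#' `exclude_target = TRUE` the target gene (taken from `labels$gene`) is
#' removed from the feature matrix first.
#'
#' @inheritParams train_single_model
#' @param verbose log per-model progress to stderr.
#' @return list with `signature` (a `ConsensusSignature`: ranked `entries`
#'   plus accuracy summary and config snapshot) and `runs` (list of
#'   `ModelRun`s).
#' @export
run_consensus <- function(expr, labels, config = rf_config(),
                          verbose = FALSE) {
  validate_expression_matrix(expr)
  if (config$exclude_target) {
    target <- labels$gene
    if (is.null(target)) stop("exclude_target requires labels$gene")
    if (target %in% rownames(expr)) {
      expr <- expression_matrix(unclass(expr)[rownames(expr) != target, ,
                                              drop = FALSE])
    }
  }
  if (config$top_k > nrow(expr)) {
    # saturation: every feature ends up in every per-model list
    top_k_eff <- nrow(expr)
  } else {
    top_k_eff <- config$top_k
  }
  y <- labels_as_int(labels, colnames(expr))
  Xt <- t(unclass(expr))
  runs <- vector("list", config$n_models)
  for (i in seq_len(config$n_models)) {
    run <- train_model_worker(Xt, rownames(expr), colnames(expr), y, config,
                              config$seed + i)
    run$model_index <- i
    runs[[i]] <- run
    if (verbose) {
      message(sprintf("model %d/%d: eval accuracy %.4f", i, config$n_models,
                      run$eval_accuracy))
    }
  }
  accs <- vapply(runs, `[[`, numeric(1), "eval_accuracy")
  entries <- rank_by_occurrence(lapply(runs, `[[`, "topk_genes"), top_k_eff)
  signature <- structure(
    list(entries = entries,
         accuracy_mean = mean(accs),
         accuracy_sd = if (length(accs) > 1L) sd(accs) else 0,
         accuracy_min = min(accs), accuracy_max = max(accs),
         target = labels$gene, config = config),
    class = "ConsensusSignature")
  list(signature = signature, runs = runs)
}

#' @export
print.ConsensusSignature <- function(x, ...) {
  cat(sprintf("ConsensusSignature (target '%s'): %d genes, %d models x %d trees\n",
              x$target %||% "?", nrow(x$entries), x$config$n_models,
              x$config$n_trees))
  cat(sprintf("  eval accuracy %.4f +/- %.4f (min %.4f, max %.4f)\n",
              x$accuracy_mean, x$accuracy_sd, x$accuracy_min, x$accuracy_max))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Leave-target-out robustness check
#'
#' Re-runs [run_consensus()] with the target gene removed from the feature
#' matrix and reports the fraction of the original signature retained —
#' an estimate of the selection bias introduced by training on labels that
#' were derived from the target's own expression.
#'
#' @inheritParams run_consensus
#' @param original the `ConsensusSignature` computed with the identical
#'   config except `exclude_target = FALSE`.
#' @return list with `signature` (the rerun signature), `runs`, and
#'   `overlap_fraction` = |original ∩ rerun| / top_k.
#' @export
leave_target_out_overlap <- function(expr, labels, config, original,
                                     verbose = FALSE) {
  config$exclude_target <- TRUE
  rerun <- run_consensus(expr, labels, config, verbose = verbose)
  shared <- intersect(original$entries$gene_id, rerun$signature$entries$gene_id)
  list(signature = rerun$signature, runs = rerun$runs,
       overlap_fraction = length(shared) / config$top_k)
}

#' Write a consensus signature to TSV
#'
#' @param signature a `ConsensusSignature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(signature, path) {
  df <- signature$entries
  df$mean_importance <- format(df$mean_importance, digits = 17, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = c(gene_id = "character"))
  stopifnot(all(c("rank", "gene_id", "occurrences", "mean_importance") %in%
                  colnames(df)))
  df
}
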