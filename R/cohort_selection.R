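#' Z-score configuration for high-expresser selection
#'
#' Controls how per-sample standardized expression is computed before
#' thresholding.  The default — log2(x+1) transform, z relative to all
#' samples of the same entity, sample sd (n-1 denominator) — mirrors the
#' conventional mRNA z-score of interactive cohort browsers; every choice is
#' exposed because published selection rules rarely print the formula.
#'
#' @param threshold z cut-off, default 1.5; the comparison is inclusive
#'   (`z >= threshold` is "high").
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param per_entity standardize within each entity (default) or globally.
#' @param sd_mode `"sample"` (n-1, default) or `"population"` (n).
#' @return a `ZScoreConfig` list.
#' @export
zscore_config <- function(threshold = 1.5,
                          transform = c("log2p1", "none"),
                          per_entity = TRUE,
                          sd_mode = c("sample", "population")) {
  cfg <- list(threshold = threshold, transform = match.arg(transform),
              per_entity = isTRUE(per_entity), sd_mode = match.arg(sd_mode))
  stopifnot(is.numeric(cfg$threshold), !is.na(cfg$threshold))
  class(cfg) <- "ZScoreConfig"
  cfg
}

#' Per-entity z-scores of one gene
#'
#' Within each entity, `z = (t(x) - mean) / sd` over that entity's samples,
#' where `t` is the configured transform.  Degenerate entities — a single
#' sample, or zero spread — get z = 0 for all their samples, with a warning:
#' no overexpression signal is definable there.
#'
#' @param expr an [expression_matrix()].
#' @param ann sample annotation covering every sample of `expr`.
#' @param gene gene identifier (must be present).
#' @param config a [zscore_config()].
#' @return named per-sample numeric vector (attributes: `gene`, `entity`).
#' @export
compute_entity_z <- function(expr, ann, gene, config = zscore_config()) {
  validate_expression_matrix(expr)
  if (!gene %in% rownames(expr)) stop("gene not in matrix: ", gene)
  idx <- match(colnames(expr), ann$sample_id)
  if (anyNA(idx)) {
    stop("unannotated sample(s): ",
         paste(utils::head(colnames(expr)[is.na(idx)], 5L), collapse = ", "))
  }
  entity <- ann$entity[idx]
  x <- unclass(expr)[gene, ]
  tx <- switch(config$transform, log2p1 = log2(x + 1), none = x)
  groups <- if (config$per_entity) entity else rep("all", length(tx))
  z <- numeric(length(tx))
  names(z) <- colnames(expr)
  for (e in unique(groups)) {
    in_e <- groups == e
    xe <- tx[in_e]
    n_e <- sum(in_e)
    s <- if (n_e < 2L) 0 else if (config$sd_mode == "sample") sd(xe) else
      sqrt(mean((xe - mean(xe))^2))
    if (n_e < 2L || s == 0) {
      warning("entity '", e, "': degenerate spread for gene '", gene,
              "'; z set to 0", call. = FALSE)
      z[in_e] <- 0
    } else {
      z[in_e] <- (xe - mean(xe)) / s
    }
  }
  attr(z, "gene") <- gene
  attr(z, "entity") <- entity
  z
}

#' Dichotomize samples into target-high vs. rest
#'
#' A sample is labelled `"high"` iff its z-score is at or above the
#' configured threshold, `"rest"` otherwise.
#'
#' @param z per-sample z vector (from [compute_entity_z()], or any finite
#'   numeric vector with sample names).
#' @param config a [zscore_config()]; only `threshold` is used here.
#' @return a `DichotomyLabels` object: named label vector plus counts
#'   (`n_high`, `n_total`, `fraction_high`) and the originating `gene`.
#' @export
select_high_expressers <- function(z, config = zscore_config()) {
  if (anyNA(z) || any(!is.finite(z))) stop("z contains non-finite values")
  lab <- ifelse(z >= config$threshold, "high", "rest")
  names(lab) <- names(z)
  structure(list(labels = lab,
                 gene = attr(z, "gene"),
                 n_high = sum(lab == "high"),
                 n_total = length(lab),
                 fraction_high = mean(lab == "high"),
                 threshold = config$threshold),
            class = "DichotomyLabels")
}

#' @export
print.DichotomyLabels <- function(x, ...) {
  cat(sprintf("DichotomyLabels for gene '%s': %d high / %d total (%.2f%%), z >= %g\n",
              x$gene %||% "?", x$n_high, x$n_total, 100 * x$fraction_high,
              x$threshold))
  invisible(x)
}

#' One-call dichotomization of a target gene
#'
#' Convenience wrapper: [compute_entity_z()] then
#' [select_high_expressers()].
#'
#' @inheritParams compute_entity_z
#' @return a `DichotomyLabels`.
#' @export
dichotomize_target <- function(expr, ann, gene, config = zscore_config()) {
  select_high_expressers(compute_entity_z(expr, ann, gene, config), config)
}

# internal: labels as 0/1 integer in matrix column order
labels_as_int <- function(labels, sample_ids) {
  lab <- labels$labels[sample_ids]
  if (anyNA(lab)) stop("labels missing for some samples")
  as.integer(lab == "high")
}
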