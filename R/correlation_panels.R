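#' Pearson correlation with a t-based p-value
#'
#' Standard product-moment correlation; two-sided p from the t distribution
#' with n-2 degrees of freedom.  Needs at least 3 paired observations and
#' non-zero variance on both sides; a degenerate input returns `r = NA`
#' with `flag = "zero_variance"` instead of an error so panel code can emit
#' flagged rows.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`, and `flag` (`NA` when well-defined).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n, flag = "n_too_small"))
  if (var(x) == 0 || var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "zero_variance"))
  }
  r <- cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, flag = NA_character_)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); p-value
#' from the same t approximation as [pearson_r()] applied to the ranks.
#'
#' @inheritParams pearson_r
#' @return list with `rho`, `p`, `n`, `flag`.
#' @export
spearman_r <- function(x, y) {
  res <- pearson_r(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average"))
  list(rho = res$r, p = res$p, n = res$n, flag = res$flag)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in the ranked raw p and capped at 1.
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  # p = 0 is tolerated: perfect correlations underflow the t tail
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Per-entity correlation panel of a target gene against candidate genes
#'
#' One row per (entity, panel gene) with the correlation of the target's
#' expression against the panel gene's expression within that entity, on the
#' raw unlogged scale by default.  BH adjustment is applied jointly across
#' all rows of the panel.  Entities with fewer than 3 samples, or degenerate
#' variance, yield flagged rows without p-values.
#'
#' @param expr an [expression_matrix()].
#' @param ann sample annotation covering all samples.
#' @param target target gene id.
#' @param panel character vector of panel gene ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log2p1 correlate log2(x+1)-transformed values instead of raw.
#' @return data.frame `entity`, `gene`, `r`, `p`, `q`, `n`, `flag`,
#'   sorted by entity then gene.
#' @export
entity_panel <- function(expr, ann, target, panel,
                         method = c("pearson", "spearman"), log2p1 = FALSE) {
  method <- match.arg(method)
  validate_expression_matrix(expr)
  missing <- setdiff(c(target, panel), rownames(expr))
  if (length(missing)) stop("gene(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  idx <- match(colnames(expr), ann$sample_id)
  if (anyNA(idx)) stop("unannotated sample(s) in matrix")
  entity <- ann$entity[idx]
  vals <- unclass(expr)
  if (log2p1) vals <- log2(vals + 1)
  entities <- sort(unique(entity))
  panel <- sort(panel)
  rows <- vector("list", length(entities) * length(panel))
  k <- 0L
  for (e in entities) {
    in_e <- entity == e
    tx <- vals[target, in_e]
    for (g in panel) {
      res <- if (method == "pearson") {
        pearson_r(tx, vals[g, in_e])
      } else {
        r <- spearman_r(tx, vals[g, in_e])
        list(r = r$rho, p = r$p, n = r$n, flag = r$flag)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(entity = e, gene = g, r = res$r, p = res$p,
                              n = res$n, flag = res$flag,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out[, c("entity", "gene", "r", "p", "q", "n", "flag")]
}

#' Two-group expression test with group summaries
#'
#' Compares the feature's values in `"high"` vs `"rest"` samples and reports
#' raw-scale group means and standard deviations alongside a two-sided
#' p-value.  The default test is Kruskal-Wallis (equivalent to a
#' Mann-Whitney test for two groups up to the tie/continuity handling);
#' Welch's t is available for comparison.
#'
#' @param feature_values named per-sample numeric vector.
#' @param labels a `DichotomyLabels`.
#' @param test `"kruskal"`, `"mannwhitney"` or `"welch"`.
#' @param feature optional feature name for the output row.
#' @return one-row data.frame `feature`, `mean_high`, `sd_high`, `mean_low`,
#'   `sd_low`, `p`, `flag`.
#' @export
group_mean_test <- function(feature_values, labels,
                            test = c("kruskal", "mannwhitney", "welch"),
                            feature = NA_character_) {
  test <- match.arg(test)
  lab <- labels$labels[names(feature_values)]
  if (anyNA(lab)) stop("labels missing for some samples")
  hi <- feature_values[lab == "high"]
  lo <- feature_values[lab == "rest"]
  if (!length(hi) || !length(lo)) stop("both groups must be non-empty")
  flag <- NA_character_
  if (length(hi) < 2L || length(lo) < 2L) flag <- "group_too_small"
  p <- if (var(feature_values) == 0) {
    1  # all values identical: no evidence against equality
  } else {
    switch(test,
           kruskal = kruskal.test(list(hi, lo))$p.value,
           mannwhitney = wilcox.test(hi, lo, exact = FALSE)$p.value,
           welch = t.test(hi, lo, var.equal = FALSE)$p.value)
  }
  data.frame(feature = feature,
             mean_high = mean(hi),
             sd_high = if (length(hi) > 1L) sd(hi) else NA_real_,
             mean_low = mean(lo),
             sd_low = if (length(lo) > 1L) sd(lo) else NA_real_,
             p = p, flag = flag, stringsAsFactors = FALSE)
}

#' Split a signature into over- and under-expressed genes
#'
#' A signature gene is "up" iff its mean raw expression in target-high
#' samples strictly exceeds the mean in the rest AND the two-group test is
#' significant at `alpha`; everything else (including mean-equal genes) is
#' "down".  The partition is exhaustive and disjoint.
#'
#' @param signature a `ConsensusSignature` or character vector of gene ids.
#' @param expr an [expression_matrix()] containing the signature genes.
#' @param labels a `DichotomyLabels`.
#' @param alpha significance level, default 0.05.
#' @param test passed to [group_mean_test()].
#' @return list with character vectors `up` and `down`.
#' @export
split_signature_by_direction <- function(signature, expr, labels,
                                         alpha = 0.05, test = "kruskal") {
  genes <- if (is.character(signature)) signature else signature$entries$gene_id
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("signature gene(s) not in matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  vals <- unclass(expr)
  up <- vapply(genes, function(g) {
    row <- group_mean_test(vals[g, ], labels, test = test, feature = g)
    isTRUE(row$mean_high > row$mean_low) && isTRUE(row$p < alpha)
  }, logical(1))
  list(up = genes[up], down = genes[!up])
}

#' Group-statistics table for the top signature features
#'
#' Reproduces the published miR-table layout from a consensus signature over
#' a (miR) expression matrix: per-feature raw-scale group means and sds in
#' target-high vs rest samples plus a two-group p-value, in signature rank
#' order.
#'
#' @param signature a `ConsensusSignature` over the features of `expr`.
#' @param expr the (miR) [expression_matrix()].
#' @param labels a `DichotomyLabels`.
#' @param n_top number of top-ranked features to report, default 10.
#' @param test passed to [group_mean_test()].
#' @return data.frame `rank`, `feature`, `mean_high`, `sd_high`, `mean_low`,
#'   `sd_low`, `p`.
#' @export
mir_group_table <- function(signature, expr, labels, n_top = 10L,
                            test = "kruskal") {
  entries <- if (is.data.frame(signature)) signature else signature$entries
  feats <- utils::head(entries$gene_id, n_top)
  vals <- unclass(expr)
  rows <- lapply(seq_along(feats), function(i) {
    row <- group_mean_test(vals[feats[i], ], labels, test = test,
                           feature = feats[i])
    cbind(rank = i, row)
  })
  out <- do.call(rbind, rows)
  out$flag <- NULL
  out
}
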