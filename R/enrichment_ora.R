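#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` belong to the set, the probability of an
#' overlap at least as large as the one observed.  Evaluated via
#' `phyper(..., lower.tail = FALSE, log.p)` which accumulates the tail in
#' log space.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return p in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("hypergeometric bounds violated (need 0 <= k <= min(K, n), K <= N, n <= N)")
  }
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Over-representation analysis of a gene list against a GMT collection
#'
#' The local, self-contained equivalent of web-based enrichment queries:
#' each set is intersected with the universe, the overlap with the
#' (de-duplicated) query is scored with the upper-tail hypergeometric test,
#' and BH adjustment is applied across the reported rows.  By default only
#' sets with non-zero overlap are reported.  The recommended universe is the
#' full gene complement of the expression matrix the query was derived from.
#'
#' @param query character vector of query gene ids.
#' @param sets a `GeneSetCollection` from [read_gmt()].
#' @param universe character vector of background gene ids.
#' @param include_empty also report sets with zero overlap.
#' @return data.frame `set_name`, `k`, `K`, `n`, `N`, `p`, `q`, sorted by
#'   p ascending (ties by set name).
#' @export
ora_table <- function(query, sets, universe, include_empty = FALSE) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  if (!length(query)) stop("query is empty after intersection with universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               p = if (K > 0) hypergeom_pvalue(k, K, n, N) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!include_empty) out <- out[out$k >= 1L, , drop = FALSE]
  if (!nrow(out)) return(cbind(out, q = numeric(0)))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
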