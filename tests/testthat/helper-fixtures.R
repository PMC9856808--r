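# Shared fixtures and independent oracle implementations.
# Unit tests run on a scaled-down cohort (2 entities x 100 samples, 300
# genes, module 30) so the whole suite stays fast; the acceptance file uses
# the full calibration cohort.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        n_entities = 2L, samples_per_entity = 100L, n_genes = 300L,
        module_size = 30L, seed = 101L))
    }
    cache
  }
})

small_labels <- function(sim = small_sim()) {
  dichotomize_target(sim$expr, sim$ann, sim$truth$config$target_gene_id)
}

random_expression <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(round(2^rnorm(n_genes * n_samples, mean = 4, sd = 2), 6),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m)
}

# naive product-moment correlation straight from the definition
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# mid-ranks by exhaustive position averaging (no rank())
naive_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# BH step-up computed literally from the definition
naive_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    q[i] <- min(1, min(p[ord][rank_i:n] * n / (rank_i:n)))
  }
  q
}

# hypergeometric upper tail by enumerating all C(N, n) draws
enumerate_hypergeom <- function(k, K, n, N) {
  universe <- seq_len(N)
  in_set <- universe <= K
  draws <- utils::combn(N, n)
  mean(colSums(matrix(in_set[draws], nrow = n)) >= k)
}

# confusion counts recomputed by an explicit per-sample loop over the votes
brute_confusion <- function(votes) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(votes))) {
    if (votes$votes_total[i] == 0L) next
    pred <- if (votes$votes_high[i] / votes$votes_total[i] > 0.5) "high" else "rest"
    truth <- votes$label[i]
    if (pred == "high" && truth == "high") tp <- tp + 1L
    else if (pred == "high" && truth == "rest") fp <- fp + 1L
    else if (pred == "rest" && truth == "rest") tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}
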