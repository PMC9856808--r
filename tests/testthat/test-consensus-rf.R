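# Unit-level forest tests run few models and few trees; statistical claims
# about the full calibration cohort live in test-acceptance.R.

make_separable <- function(n = 500, p = 60, seed = 11) {
  set.seed(seed)
  m <- matrix(2^rnorm(p * n, mean = 4), p, n,
              dimnames = list(c("SEP", sprintf("n%03d", seq_len(p - 1))),
                              sprintf("s%03d", seq_len(n))))
  # the separating gene has a clear margin around the cut so quantile
  # binning cannot blur the boundary
  high <- seq_len(n) %in% sample(n, round(0.3 * n))
  m["SEP", ] <- ifelse(high, 40 + runif(n, 2, 10), 40 - runif(n, 2, 10))
  lab <- structure(list(labels = stats::setNames(ifelse(high, "high", "rest"),
                                                 colnames(m)),
                        gene = "SEP", n_high = sum(high), n_total = n,
                        fraction_high = mean(high), threshold = NA),
                   class = "DichotomyLabels")
  list(expr = expression_matrix(m), labels = lab)
}

test_that("a single model solves the separable case and is deterministic", {
  fx <- make_separable()
  cfg <- rf_config(n_models = 1, n_trees = 100, seed = 1)
  run <- train_single_model(fx$expr, fx$labels, cfg, model_seed = 99)
  expect_gte(run$eval_accuracy, 0.99)
  expect_identical(run$topk_genes$gene_id[1], "SEP")
  # importances sorted non-increasing and non-negative
  expect_true(all(diff(run$topk_genes$importance) <= 1e-12))
  expect_true(all(run$topk_genes$importance >= 0))
  # train/eval partition the cohort
  expect_length(run$eval_sample_ids, 250)

  run2 <- train_single_model(fx$expr, fx$labels, cfg, model_seed = 99)
  expect_identical(run, run2)
  run3 <- train_single_model(fx$expr, fx$labels, cfg, model_seed = 100)
  expect_false(identical(run$topk_genes, run3$topk_genes))
})

test_that("permuted labels give chance-level accuracy", {
  fx <- make_separable(n = 400)
  set.seed(21)
  perm <- fx$labels
  perm$labels[] <- sample(perm$labels)
  cfg <- rf_config(n_models = 5, n_trees = 100, seed = 3)
  res <- run_consensus(fx$expr, perm, cfg)
  maj <- max(perm$fraction_high, 1 - perm$fraction_high)
  # no signal: accuracy within a few points of the majority-class rate
  expect_lt(abs(res$signature$accuracy_mean - maj), 0.06)
})

test_that("rank_by_occurrence counts, orders and breaks ties as specified", {
  lst <- function(genes, imps) data.frame(gene_id = genes, importance = imps)
  # {[A,B],[A,C],[A,B]} -> A:3, B:2, C:1
  out <- rank_by_occurrence(list(lst(c("A", "B"), c(0.5, 0.3)),
                                 lst(c("A", "C"), c(0.6, 0.2)),
                                 lst(c("A", "B"), c(0.4, 0.1))), top_k = 10)
  expect_identical(out$gene_id, c("A", "B", "C"))
  expect_identical(out$occurrences, c(3L, 2L, 1L))
  expect_equal(out$mean_importance, c(0.5, 0.2, 0.2))

  # single model: its list with occurrences 1
  one <- rank_by_occurrence(list(lst(c("X", "Y"), c(0.9, 0.1))), top_k = 5)
  expect_identical(one$occurrences, c(1L, 1L))

  # tie on count and mean importance -> lexicographically smaller id first
  tie <- rank_by_occurrence(list(lst(c("B", "A"), c(0.5, 0.5))), top_k = 5)
  expect_identical(tie$gene_id, c("A", "B"))

  expect_error(rank_by_occurrence(list(), 5), "no model lists")
  expect_error(rank_by_occurrence(list(lst("A", 1), lst(c("A", "B"), c(1, 2))), 5),
               "differ in length")
})

test_that("consensus conserves occurrence mass and saturates below top_k", {
  fx <- make_separable(n = 200, p = 50)
  cfg <- rf_config(n_models = 4, n_trees = 50, top_k = 20, seed = 5)
  res <- run_consensus(fx$expr, fx$labels, cfg)
  all_lists <- lapply(res$runs, `[[`, "topk_genes")
  occ_all <- table(unlist(lapply(all_lists, `[[`, "gene_id")))
  expect_equal(sum(occ_all), cfg$n_models * cfg$top_k)
  expect_true(all(diff(res$signature$entries$occurrences) <= 0))
  expect_true(all(res$signature$entries$occurrences >= 1,
                  res$signature$entries$occurrences <= cfg$n_models))

  # saturation: fewer features than top_k -> every gene in every list
  cfg_sat <- rf_config(n_models = 3, n_trees = 50, top_k = 200, seed = 5)
  res_sat <- run_consensus(fx$expr, fx$labels, cfg_sat)
  expect_equal(nrow(res_sat$signature$entries), 50L)
  expect_true(all(res_sat$signature$entries$occurrences == 3L))
})

test_that("consensus runs are deterministic and exclude_target removes the target", {
  fx <- make_separable(n = 200, p = 40)
  cfg <- rf_config(n_models = 3, n_trees = 60, top_k = 15, seed = 8)
  a <- run_consensus(fx$expr, fx$labels, cfg)
  b <- run_consensus(fx$expr, fx$labels, cfg)
  expect_identical(a$signature$entries, b$signature$entries)
  expect_identical(a$signature$accuracy_mean, b$signature$accuracy_mean)

  lto <- leave_target_out_overlap(fx$expr, fx$labels, cfg, a$signature)
  expect_false("SEP" %in% lto$signature$entries$gene_id)
  expect_true(lto$overlap_fraction >= 0 && lto$overlap_fraction <= 1)
})

test_that("class requirements are enforced", {
  fx <- make_separable(n = 100, p = 20)
  one_pos <- fx$labels
  one_pos$labels[] <- "rest"
  one_pos$labels[1] <- "high"
  expect_error(train_single_model(fx$expr, one_pos, rf_config(n_trees = 10)),
               "2 samples per class")
})
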