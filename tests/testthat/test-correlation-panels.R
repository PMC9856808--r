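test_that("pearson_r matches the naive reference on random fixtures", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_r(x, y)$r, naive_pearson(x, y), tolerance = 1e-12)
  }

  expect_identical(pearson_r(c(1, 1, 1), c(1, 2, 3))$flag, "zero_variance")
  expect_identical(pearson_r(1:2, 2:3)$flag, "n_too_small")
})

test_that("spearman_r equals pearson of exhaustively computed mid-ranks", {
  expect_equal(spearman_r(1:8, exp(1:8))$rho, 1.0)
  expect_equal(spearman_r(1:8, -(1:8)^3)$rho, -1.0)

  # tie handling against position-averaged ranks
  x <- c(1, 2, 3, 4); y <- c(1, 1, 3, 4)
  expect_equal(spearman_r(x, y)$rho,
               naive_pearson(naive_midrank(x), naive_midrank(y)),
               tolerance = 1e-12)
  set.seed(32)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    x <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- sample(1:6, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearman_r(x, y)$rho,
                 naive_pearson(naive_midrank(x), naive_midrank(y)),
                 tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces the step-up by hand and its invariants", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))

  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
  }
})

test_that("entity_panel emits one BH-adjusted row per entity-gene pair", {
  sim <- small_sim()
  panel <- c(sim$truth$module_gene_ids[1:3], "G0001", "G0002")
  tab <- entity_panel(sim$expr, sim$ann, "TG1", panel)
  expect_equal(nrow(tab), 2 * 5)
  expect_identical(tab$entity, rep(c("ENT01", "ENT02"), each = 5))
  expect_true(all(tab$q >= tab$p - 1e-15))

  # planted genes positively correlated in every entity; noise centred near 0
  planted <- tab[tab$gene %in% sim$truth$module_gene_ids, ]
  expect_true(all(planted$r > 0.3))
  noise <- tab[tab$gene %in% c("G0001", "G0002"), ]
  expect_true(all(abs(noise$r) < 0.3))

  # self-correlation is 1 in every entity (up to floating point)
  self <- entity_panel(sim$expr, sim$ann, "TG1", "TG1")
  expect_equal(self$r, rep(1, 2), tolerance = 1e-12)

  expect_error(entity_panel(sim$expr, sim$ann, "TG1", "missing_gene"),
               "not in matrix")

  # a correlation planted in one entity only survives BH only there
  set.seed(44)
  n <- 80
  f <- rnorm(n)
  vals <- rbind(tgt = 2^(4 + c(f[1:40], rnorm(40, sd = 1)) * 1 + rnorm(n, sd = .2)),
                g1 = 2^(4 + c(f[1:40], rep(0, 40)) + rnorm(n, sd = .2)),
                g2 = 2^rnorm(n, 4))
  colnames(vals) <- sprintf("s%02d", 1:n)
  ann2 <- data.frame(sample_id = colnames(vals),
                     entity = rep(c("A", "B"), each = 40))
  tab2 <- entity_panel(expression_matrix(vals), ann2, "tgt", c("g1", "g2"),
                       log2p1 = TRUE)
  expect_lt(tab2$q[tab2$entity == "A" & tab2$gene == "g1"], 0.05)
  expect_gt(min(tab2$q[tab2$entity == "B"]), 0.05)
})

test_that("group_mean_test reports raw-scale summaries and sane p-values", {
  lab <- structure(list(labels = stats::setNames(
    rep(c("high", "rest"), each = 200), sprintf("s%03d", 1:400))),
    class = "DichotomyLabels")

  # identical groups: equal means, p ~ 1
  v <- stats::setNames(rep(c(5, 7, 9, 11), 100), sprintf("s%03d", 1:400))
  row <- group_mean_test(v, lab)
  expect_equal(row$mean_high, row$mean_low)
  expect_gt(row$p, 0.9)

  # strongly shifted high group
  set.seed(55)
  v2 <- stats::setNames(c(rnorm(200, 10), rnorm(200, 0)), names(v))
  for (tst in c("kruskal", "mannwhitney", "welch")) {
    row2 <- group_mean_test(v2, lab, test = tst)
    expect_lt(row2$p, 1e-10)
    expect_gt(row2$mean_high, row2$mean_low + 9)
  }

  # constant vector: defined as p = 1
  vc <- stats::setNames(rep(3, 400), names(v))
  expect_equal(group_mean_test(vc, lab)$p, 1)
})

test_that("direction split is exhaustive, disjoint, and finds planted genes", {
  sim <- small_sim()
  lab <- small_labels(sim)
  genes <- c(sim$truth$module_gene_ids[1:10], "G0001", "G0002", "G0003")
  split <- split_signature_by_direction(genes, sim$expr, lab)
  expect_setequal(c(split$up, split$down), genes)
  expect_length(intersect(split$up, split$down), 0)
  # positive loadings: planted genes are overexpressed in target-high samples
  expect_setequal(intersect(split$up, sim$truth$module_gene_ids[1:10]),
                  sim$truth$module_gene_ids[1:10])

  # mean-equal gene fails the strict inequality -> down
  vals <- unclass(sim$expr)
  vals["G0001", ] <- 5
  split2 <- split_signature_by_direction("G0001", expression_matrix(vals), lab)
  expect_identical(split2$down, "G0001")
})

test_that("mir_group_table mirrors the published table layout", {
  sim <- small_sim()
  lab <- small_labels(sim)
  mir <- simulate_mir_matrix(sim, n_mirs = 80L, mir_module_size = 10L)
  res <- run_consensus(mir$expr, lab, rf_config(n_models = 5, n_trees = 100,
                                                top_k = 20, seed = 77))
  tab <- mir_group_table(res$signature, mir$expr, lab, n_top = 10)
  expect_equal(nrow(tab), 10)
  expect_identical(colnames(tab), c("rank", "feature", "mean_high", "sd_high",
                                    "mean_low", "sd_low", "p"))
  expect_identical(tab$feature, res$signature$entries$gene_id[1:10])
  planted <- tab[tab$feature %in% mir$truth$module_gene_ids, ]
  expect_true(all(planted$mean_high > planted$mean_low))
  expect_true(all(planted$p < 0.01))
})
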