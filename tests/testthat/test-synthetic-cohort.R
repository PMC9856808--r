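test_that("simulated cohorts satisfy matrix invariants and are seed-deterministic", {
  sim <- small_sim()
  expect_s3_class(sim$expr, "ExpressionMatrix")
  expect_true(all(unclass(sim$expr) >= 0))
  expect_identical(colnames(sim$expr), sim$ann$sample_id)
  expect_length(sim$truth$module_gene_ids, 30L)
  expect_false(sim$truth$config$target_gene_id %in% sim$truth$module_gene_ids)
  # loadings non-zero exactly on module genes and the target
  nz <- names(sim$truth$loadings)[sim$truth$loadings != 0]
  expect_setequal(nz, c("TG1", sim$truth$module_gene_ids))

  sim2 <- simulate_cohort(sim$truth$config)
  expect_identical(unclass(sim2$expr), unclass(sim$expr))

  expect_error(sim_config(n_genes = 10, module_size = 10), "module_size")
})

test_that("realized target-module correlation matches the latent-factor closed form", {
  cfg <- sim_config(seed = 202L)  # calibration defaults: 4 x 250, loading 0.8
  sim <- simulate_cohort(cfg)
  logx <- log2(unclass(sim$expr))
  expected <- latent_model_correlation(cfg$target_loading, cfg$loading,
                                       cfg$noise_sd)
  # within-entity correlations: entity baselines are constants there
  rs <- unlist(lapply(unique(sim$ann$entity), function(e) {
    cols <- sim$ann$sample_id[sim$ann$entity == e]
    tx <- logx[cfg$target_gene_id, cols]
    vapply(sim$truth$module_gene_ids, function(g) naive_pearson(tx, logx[g, cols]),
           numeric(1))
  }))
  expect_lt(abs(mean(rs) - expected), 0.1)

  # independence limit: zero loading decorrelates module genes
  sim0 <- simulate_cohort(sim_config(n_entities = 1L, samples_per_entity = 400L,
                                     n_genes = 50L, module_size = 10L,
                                     loading = 1e-12, entity_shift_sd = 0,
                                     seed = 7L))
  logx0 <- log2(unclass(sim0$expr))
  rs0 <- vapply(sim0$truth$module_gene_ids, function(g) {
    naive_pearson(logx0["TG1", ], logx0[g, ])
  }, numeric(1))
  expect_lt(abs(mean(rs0)), 3 / sqrt(400))  # ~3 MC standard errors of r = 0
})

test_that("entity baselines create between-entity structure exceeding within-entity noise", {
  sim <- small_sim()
  logx <- log2(unclass(sim$expr))
  noise_genes <- setdiff(rownames(sim$expr),
                         c("TG1", sim$truth$module_gene_ids))[1:50]
  by_entity <- split(sim$ann$sample_id, sim$ann$entity)
  between <- vapply(noise_genes, function(g) {
    var(vapply(by_entity, function(cols) mean(logx[g, cols]), numeric(1)))
  }, numeric(1))
  within <- vapply(noise_genes, function(g) {
    mean(vapply(by_entity, function(cols) var(logx[g, cols]), numeric(1)))
  }, numeric(1))
  expect_gt(mean(between), mean(within))
})

test_that("miR matrix shares the latent factor and sample set", {
  sim <- small_sim()
  mir <- simulate_mir_matrix(sim, n_mirs = 60L, mir_module_size = 10L)
  expect_identical(colnames(mir$expr), colnames(sim$expr))

  logt <- log2(unclass(sim$expr)["TG1", ])
  logm <- log2(unclass(mir$expr))
  by_entity <- split(seq_len(nrow(sim$ann)), sim$ann$entity)
  rs <- unlist(lapply(by_entity, function(ix) {
    vapply(mir$truth$module_gene_ids, function(g) {
      naive_pearson(logt[ix], logm[g, ix])
    }, numeric(1))
  }))
  expected <- latent_model_correlation(1, 0.8, 0.5)
  expect_lt(abs(mean(rs) - expected), 0.1)

  # zero-sized miR module: nothing correlates beyond MC error
  mir0 <- simulate_mir_matrix(sim, n_mirs = 40L, mir_module_size = 0L)
  rs0 <- apply(log2(unclass(mir0$expr))[, sim$ann$entity == "ENT01"], 1,
               function(v) naive_pearson(logt[sim$ann$entity == "ENT01"], v))
  expect_lt(max(abs(rs0)), 5 / sqrt(100))

  # determinism
  mir2 <- simulate_mir_matrix(sim, n_mirs = 60L, mir_module_size = 10L)
  expect_identical(unclass(mir2$expr), unclass(mir$expr))

  broken <- sim
  broken$expr <- expression_matrix(unclass(sim$expr)[, 1:50])
  expect_error(simulate_mir_matrix(broken), "sample set")
})

test_that("recovery_score counts module recall and excludes the target", {
  truth <- small_sim()$truth
  module <- truth$module_gene_ids
  expect_equal(recovery_score(module, truth), 1.0)
  expect_equal(recovery_score(c("TG1", module), truth), 1.0)
  expect_equal(recovery_score(sprintf("ZZZ%d", 1:10), truth), 0.0)
  expect_equal(recovery_score(module[1:24], truth), 0.8)
  expect_error(recovery_score(character(0), truth), "empty")
})
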