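#' Configuration for the synthetic multi-entity cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: several tumor entities with entity-specific baseline expression,
#' right-skewed non-negative abundance values, one designated target gene,
#' a planted module of genes correlated with the target through a shared
#' per-sample latent factor, and a majority of uncorrelated noise genes.
#'
#' The generative model works on the log2 scale.  For sample j with latent
#' factor `f_j ~ N(0, 1)`:
#' \deqn{log2 x_{gj} = \mu + b_{e(j),g} + \lambda_g f_j + \epsilon_{gj}}
#' with entity baselines `b ~ N(0, entity_shift_sd)` drawn once per
#' (entity, gene), residual noise `\epsilon ~ N(0, noise_sd)`, loading
#' `\lambda = target_loading` for the target, `loading` for module genes and
#' 0 elsewhere.  The matrix is exponentiated (`2^`) to the raw scale, so all
#' values are non-negative and log-normal (right-skewed, FPKM-like).
#'
#' Defaults are the calibration cohort used throughout the test suite:
#' 4 entities x 250 samples, 2000 genes, a planted module of 100 genes,
#' loading 0.8 and residual sd 0.5.
#'
#' @param n_entities number of entities (cohorts).
#' @param samples_per_entity samples per entity.
#' @param n_genes total number of genes, including target and module.
#' @param module_size number of planted module genes (excludes the target).
#' @param target_gene_id identifier of the target gene.
#' @param loading latent-factor loading of module genes, in (0, 1).
#' @param target_loading latent-factor loading of the target gene itself.
#' @param entity_shift_sd sd of per-(entity, gene) baseline shifts (log2
#'   scale); 0 removes entity structure.
#' @param noise_sd residual sd on the log2 scale.
#' @param base_log_mean grand mean of log2 expression; 4 gives typical raw
#'   values around 16, comfortably FPKM-like.
#' @param seed integer seed; the whole generation is reproducible from it.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_entities = 4L, samples_per_entity = 250L,
                       n_genes = 2000L, module_size = 100L,
                       target_gene_id = "TG1", loading = 0.8,
                       target_loading = 1.0, entity_shift_sd = 1.0,
                       noise_sd = 0.5, base_log_mean = 4, seed = 1L) {
  cfg <- list(n_entities = as.integer(n_entities),
              samples_per_entity = as.integer(samples_per_entity),
              n_genes = as.integer(n_genes),
              module_size = as.integer(module_size),
              target_gene_id = as.character(target_gene_id),
              loading = loading, target_loading = target_loading,
              entity_shift_sd = entity_shift_sd, noise_sd = noise_sd,
              base_log_mean = base_log_mean, seed = as.integer(seed))
  stopifnot(cfg$n_entities >= 1L, cfg$samples_per_entity >= 1L,
            cfg$n_genes >= 2L, cfg$module_size >= 0L,
            is.finite(cfg$loading), is.finite(cfg$entity_shift_sd),
            cfg$entity_shift_sd >= 0, cfg$noise_sd > 0)
  if (cfg$module_size >= cfg$n_genes) {
    stop("module_size must be smaller than n_genes")
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a multi-entity expression cohort with a planted module
#'
#' See [sim_config()] for the generative model.  Gene 1 is the target gene
#' (named `config$target_gene_id`), genes 2..(module_size+1) form the planted
#' module (`MOD0001`, ...), the remainder are noise genes (`G0001`, ...).
#'
#' @param config a [sim_config()].
#' @return list with elements `expr` ([expression_matrix()]),
#'   `ann` (sample annotation data.frame), and `truth` (a `SimTruth`:
#'   `module_gene_ids`, per-gene `loadings`, `entity_baselines`, the latent
#'   factor `latent`, and the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n_entities * config$samples_per_entity
  g <- config$n_genes
  entities <- sprintf("ENT%02d", seq_len(config$n_entities))
  gene_ids <- c(config$target_gene_id,
                sprintf("MOD%04d", seq_len(config$module_size)),
                sprintf("G%04d", seq_len(g - config$module_size - 1L)))
  sample_ids <- sprintf("S%05d", seq_len(n))
  entity_of <- rep(entities, each = config$samples_per_entity)

  loadings <- c(config$target_loading,
                rep(config$loading, config$module_size),
                rep(0, g - config$module_size - 1L))
  names(loadings) <- gene_ids

  out <- with_seed(config$seed, {
    f <- rnorm(n)
    baselines <- matrix(rnorm(config$n_entities * g,
                              sd = config$entity_shift_sd),
                        nrow = config$n_entities, ncol = g,
                        dimnames = list(entities, gene_ids))
    logx <- config$base_log_mean +
      baselines[entity_of, , drop = FALSE] +
      outer(f, loadings) +
      matrix(rnorm(n * g, sd = config$noise_sd), n, g)
    list(f = f, baselines = baselines, logx = logx)
  })

  values <- t(2^out$logx)  # genes x samples, raw scale
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  expr <- expression_matrix(values)
  ann <- data.frame(sample_id = sample_ids, entity = entity_of,
                    stringsAsFactors = FALSE)
  truth <- structure(
    list(module_gene_ids = gene_ids[seq_len(config$module_size) + 1L],
         loadings = loadings,
         entity_baselines = out$baselines,
         latent = stats::setNames(out$f, sample_ids),
         config = config),
    class = "SimTruth")
  list(expr = expr, ann = ann, truth = truth)
}

#' Simulate a companion microRNA matrix over the same samples
#'
#' Generates a second, smaller feature space (miR-like, RPM-scale) over the
#' identical sample set, with its own planted module tied to the *same*
#' per-sample latent factor as the mRNA cohort — so planted miRs correlate
#' with the mRNA target gene.  Must be called on the output of
#' [simulate_cohort()]; reusing its stored latent factor is what shares the
#' seed stream.
#'
#' @param sim result of [simulate_cohort()].
#' @param n_mirs number of miR features.
#' @param mir_module_size number of planted miRs (0 allowed).
#' @param loading latent loading of planted miRs; defaults to the cohort's.
#' @return list with `expr` (miR [expression_matrix()]) and `truth`.
#' @export
simulate_mir_matrix <- function(sim, n_mirs = 300L, mir_module_size = 20L,
                                loading = NULL) {
  if (is.null(sim$truth$latent)) {
    stop("sim must be the output of simulate_cohort() (latent factor missing)")
  }
  config <- sim$truth$config
  loading <- loading %||% config$loading
  n_mirs <- as.integer(n_mirs)
  mir_module_size <- as.integer(mir_module_size)
  if (mir_module_size >= n_mirs) stop("mir_module_size must be < n_mirs")
  f <- sim$truth$latent
  if (!identical(names(f), colnames(sim$expr))) {
    stop("sample set of sim$expr does not match the stored latent factor")
  }
  n <- length(f)
  entities <- rownames(sim$truth$entity_baselines)
  entity_of <- sim$ann$entity
  mir_ids <- c(sprintf("miR-M%03d", seq_len(mir_module_size)),
               sprintf("miR-%04d", seq_len(n_mirs - mir_module_size)))
  loadings <- c(rep(loading, mir_module_size),
                rep(0, n_mirs - mir_module_size))
  names(loadings) <- mir_ids

  out <- with_seed(config$seed + 1000003L, {
    baselines <- matrix(rnorm(length(entities) * n_mirs,
                              sd = config$entity_shift_sd),
                        nrow = length(entities), ncol = n_mirs,
                        dimnames = list(entities, mir_ids))
    logx <- config$base_log_mean +
      baselines[entity_of, , drop = FALSE] +
      outer(unname(f), loadings) +
      matrix(rnorm(n * n_mirs, sd = config$noise_sd), n, n_mirs)
    list(baselines = baselines, logx = logx)
  })

  values <- t(2^out$logx)
  rownames(values) <- mir_ids
  colnames(values) <- names(f)
  truth <- structure(
    list(module_gene_ids = mir_ids[seq_len(mir_module_size)],
         loadings = loadings,
         entity_baselines = out$baselines,
         latent = f,
         config = config),
    class = "SimTruth")
  list(expr = expression_matrix(values), truth = truth)
}

#' Fraction of the planted module recovered by a signature
#'
#' Recall of the planted module genes in a consensus signature's gene list.
#' The target gene is excluded from both numerator and denominator (it
#' trivially tops its own signature).
#'
#' @param signature a [run_consensus()] signature (or a character vector of
#'   gene ids).
#' @param truth a `SimTruth` from [simulate_cohort()].
#' @return recall in \[0, 1\].
#' @export
recovery_score <- function(signature, truth) {
  genes <- if (is.character(signature)) signature else signature$entries$gene_id
  if (!length(genes)) stop("signature is empty")
  target <- truth$config$target_gene_id
  module <- setdiff(truth$module_gene_ids, target)
  if (!length(module)) stop("truth has no planted module genes")
  mean(module %in% setdiff(genes, target))
}

#' Closed-form latent-model correlation
#'
#' Log-scale Pearson correlation between the target gene (loading `a`) and a
#' module gene (loading `lambda`) implied by the single-latent-factor model:
#' `a * lambda / sqrt((a^2 + s^2) * (lambda^2 + s^2))` with residual sd `s`.
#' Exact within an entity (baseline shifts are constants there).
#'
#' @param a target loading.
#' @param lambda module loading.
#' @param noise_sd residual sd.
#' @return expected correlation.
#' @export
latent_model_correlation <- function(a, lambda, noise_sd) {
  a * lambda / sqrt((a^2 + noise_sd^2) * (lambda^2 + noise_sd^2))
}
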