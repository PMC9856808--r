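#' Per-sample vote table from model runs
#'
#' For every cohort sample, the number of models that held it out for
#' evaluation (`votes_total`) and how many of those predicted `"high"`
#' (`votes_high`), alongside its true label.  [aggregate_votes()] is the
#' majority-vote collapse of this table; it is also the input of the
#' standalone `validate` CLI stage.
#'
#' @param runs list of `ModelRun`s.
#' @param labels a `DichotomyLabels`.
#' @return data.frame `sample_id`, `votes_high`, `votes_total`, `label`.
#' @export
votes_table <- function(runs, labels) {
  all_ids <- names(labels$labels)
  votes_high <- votes_total <- stats::setNames(integer(length(all_ids)), all_ids)
  for (run in runs) {
    ids <- run$eval_sample_ids
    votes_total[ids] <- votes_total[ids] + 1L
    votes_high[ids] <- votes_high[ids] +
      as.integer(run$eval_predictions[ids] == "high")
  }
  data.frame(sample_id = all_ids, votes_high = unname(votes_high),
             votes_total = unname(votes_total),
             label = unname(labels$labels[all_ids]),
             stringsAsFactors = FALSE)
}

#' Confusion matrix from a vote table
#'
#' Majority vote per sample (ties to `"rest"`); samples with zero votes are
#' excluded.
#'
#' @param votes data.frame as produced by [votes_table()].
#' @return a [confusion_summary()].
#' @export
confusion_from_votes <- function(votes) {
  v <- votes[votes$votes_total > 0L, , drop = FALSE]
  pred <- ifelse(2L * v$votes_high > v$votes_total, "high", "rest")
  confusion_summary(tp = sum(pred == "high" & v$label == "high"),
                    fp = sum(pred == "high" & v$label == "rest"),
                    tn = sum(pred == "rest" & v$label == "rest"),
                    fn = sum(pred == "rest" & v$label == "high"))
}

workflow_keys <- c("seed", "out_dir", "simulate", "expression", "annotation",
                   "min_entity_size", "select", "signature", "validate",
                   "correlate", "mir_table", "enrich")

#' Run the full workflow from one configuration
#'
#' Executes the requested stages in order — simulate (or load), select,
#' signature, validate, correlate, enrich — writing each stage's outputs
#' under `out_dir` and finishing with a reproducibility manifest
#' (`manifest.json`: config snapshot, seed, output paths and MD5 digests,
#' package version, timestamps).  A stage failure aborts the run with the
#' failing stage named; outputs of completed stages are retained.
#'
#' The configuration is a flat named list (or a path to a JSON file with the
#' same structure).  Top-level keys: `seed`, `out_dir`, either `simulate`
#' (a list of [sim_config()] arguments) or `expression`/`annotation` file
#' paths, `min_entity_size`, `select` (needs `gene`), `signature`
#' ([rf_config()] arguments; `leave_target_out = TRUE` adds the rerun),
#' `validate`, `correlate` (`panel`, `method`, `log2p1`), `enrich`
#' (`gmt` path; on simulated data a synthetic collection is built from the
#' planted truth when omitted).  Unknown keys are an error.
#'
#' One top-level seed fans out to the stages by fixed offsets, so stage
#' results are reproducible independently of which stages run.
#'
#' @param config named list or path to a JSON config file.
#' @param verbose log progress.
#' @return the manifest, invisibly.
#' @export
run_workflow <- function(config, verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), workflow_keys)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  t_start <- Sys.time()
  truth <- NULL

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(stage_name, ...) {
    outputs[[stage_name]] <<- c(outputs[[stage_name]], ...)
  }

  # ---- stage 1: simulate or load ------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      sim_cfg <- do.call(sim_config, args[setdiff(names(args),
                                                  c("n_mirs", "mir_module_size"))])
      simulate_cohort(sim_cfg)
    })
    truth <- sim$truth
    expr <- sim$expr
    ann <- sim$ann
    stage("simulate", {
      write_expression_tsv(expr, file.path(out_dir, "expression.tsv"))
      write_sample_annotation(ann, file.path(out_dir, "annotation.tsv"))
      jsonlite::write_json(
        list(target_gene_id = truth$config$target_gene_id,
             module_gene_ids = truth$module_gene_ids,
             loadings = as.list(truth$loadings[truth$loadings != 0])),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    })
    emit("simulate", file.path(out_dir, c("expression.tsv", "annotation.tsv",
                                          "truth.json")))
  } else {
    expr <- stage("load", read_expression_tsv(config$expression %||%
                                                stop("need 'expression' or 'simulate'")))
    ann <- stage("load", read_sample_annotation(config$annotation %||%
                                                  stop("need 'annotation'")))
    aligned <- stage("load", align_cohort(expr, ann,
                                          config$min_entity_size %||% 60L))
    expr <- aligned$expr
    ann <- aligned$ann
  }

  # ---- stage 2: select ----------------------------------------------------
  sel <- config$select %||% stop("config needs 'select' with a target gene")
  gene <- sel$gene %||% truth$config$target_gene_id %||%
    stop("select stage needs 'gene'")
  zcfg <- zscore_config(threshold = sel$threshold %||% 1.5,
                        transform = sel$transform %||% "log2p1")
  labels <- stage("select", {
    z <- compute_entity_z(expr, ann, gene, zcfg)
    labels <- select_high_expressers(z, zcfg)
    df <- data.frame(sample_id = names(z),
                     entity = attr(z, "entity"),
                     gene = gene, z = z,
                     label = unname(labels$labels),
                     stringsAsFactors = FALSE)
    write.table(df, file.path(out_dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    labels
  })
  emit("select", file.path(out_dir, "labels.tsv"))
  if (verbose) message(sprintf("select: %d/%d samples high (%.2f%%)",
                               labels$n_high, labels$n_total,
                               100 * labels$fraction_high))

  # ---- stage 3: signature -------------------------------------------------
  sig_args <- config$signature %||% list()
  lto <- isTRUE(sig_args$leave_target_out)
  sig_args$leave_target_out <- NULL
  sig_args$seed <- sig_args$seed %||% (seed + 10000L)
  rcfg <- do.call(rf_config, sig_args)
  res <- stage("signature", run_consensus(expr, labels, rcfg, verbose = verbose))
  stage("signature", {
    write_signature_tsv(res$signature, file.path(out_dir, "signature.tsv"))
    accs <- data.frame(
      model_index = vapply(res$runs, `[[`, integer(1), "model_index"),
      eval_accuracy = vapply(res$runs, `[[`, numeric(1), "eval_accuracy"))
    write.table(accs, file.path(out_dir, "model_accuracies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(votes_table(res$runs, labels),
                file.path(out_dir, "votes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  emit("signature", file.path(out_dir, c("signature.tsv",
                                         "model_accuracies.tsv", "votes.tsv")))
  if (lto) {
    lto_res <- stage("signature", leave_target_out_overlap(
      expr, labels, rcfg, res$signature, verbose = verbose))
    stage("signature", {
      write_signature_tsv(lto_res$signature,
                          file.path(out_dir, "signature_lto.tsv"))
      jsonlite::write_json(list(overlap_fraction = lto_res$overlap_fraction),
                           file.path(out_dir, "lto_overlap.json"),
                           auto_unbox = TRUE, digits = NA)
    })
    emit("signature", file.path(out_dir, c("signature_lto.tsv",
                                           "lto_overlap.json")))
  }

  # ---- stage 4: validate --------------------------------------------------
  if (!isFALSE(config$validate)) {
    stage("validate", {
      cm <- aggregate_votes(res$runs, labels)
      acc <- accuracy_summary(res$runs)
      jsonlite::write_json(
        list(tn = cm$tn, tp = cm$tp, fn = cm$fn, fp = cm$fp,
             n_covered = cm$n_covered,
             accuracy_mean = acc$mean, accuracy_sd = acc$sd,
             accuracy_min = acc$min, accuracy_max = acc$max,
             f1 = f1_score(cm), mcc = mcc_score(cm),
             f1_2dp = round2(f1_score(cm)), mcc_2dp = round2(mcc_score(cm))),
        file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    })
    emit("validate", file.path(out_dir, "metrics.json"))
  }

  # ---- stage 5: correlate -------------------------------------------------
  if (!is.null(config$correlate) || !is.null(truth)) {
    cor_args <- config$correlate %||% list()
    panel <- cor_args$panel %||% utils::head(truth$module_gene_ids, 5L)
    stage("correlate", {
      tab <- entity_panel(expr, ann, gene, panel,
                          method = cor_args$method %||% "pearson",
                          log2p1 = isTRUE(cor_args$log2p1))
      write.table(tab, file.path(out_dir, "correlations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
    emit("correlate", file.path(out_dir, "correlations.tsv"))
  }

  # ---- stage 6: enrich ----------------------------------------------------
  if (!is.null(config$enrich) || !is.null(truth)) {
    enr_args <- config$enrich %||% list()
    stage("enrich", {
      if (!is.null(enr_args$gmt)) {
        sets <- read_gmt(enr_args$gmt)
      } else if (!is.null(truth)) {
        sets <- synthetic_gene_sets(truth, rownames(expr), seed = seed + 20000L)
        write_gmt(sets, file.path(out_dir, "sets.gmt"))
      } else {
        stop("enrich stage needs a 'gmt' path when not simulating")
      }
      split <- split_signature_by_direction(res$signature, expr, labels)
      tab <- ora_table(split$up, sets, universe = rownames(expr))
      write.table(tab, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
    emit("enrich", file.path(out_dir, "enrichment.tsv"))
  }

  manifest <- list(
    config = config,
    seed = seed,
    stages = lapply(outputs, function(paths) {
      list(paths = paths, md5 = unname(tools::md5sum(paths)))
    }),
    package_version = as.character(packageVersion("pansig")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Synthetic gene-set collection from planted truth
#'
#' Builds a small GMT-style collection for exercising the enrichment stage
#' on simulated data: the planted module as one set plus random decoy sets
#' drawn from the gene universe.
#'
#' @param truth a `SimTruth`.
#' @param universe gene universe (matrix row names).
#' @param n_decoys number of random sets.
#' @param decoy_size genes per random set.
#' @param seed RNG seed.
#' @return a `GeneSetCollection`.
#' @export
synthetic_gene_sets <- function(truth, universe, n_decoys = 5L,
                                decoy_size = 100L, seed = 1L) {
  sets <- list(planted_module = list(description = "planted target-correlated module",
                                     genes = truth$module_gene_ids))
  decoys <- with_seed(seed, {
    lapply(seq_len(n_decoys), function(i) {
      list(description = sprintf("random decoy set %d", i),
           genes = sample(universe, min(decoy_size, length(universe))))
    })
  })
  names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoys))
  structure(c(sets, decoys), class = "GeneSetCollection")
}
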