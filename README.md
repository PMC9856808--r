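# pansig

Consensus random-forest gene signatures for target-defined tumor
microenvironments.

## The problem

Theranostic PET targets such as CXCR4 and FAP are imaged (and treated)
across many solid-tumor entities, but it is often unclear what kind of
microenvironment a strongly target-positive tumor represents. A
target-agnostic way to ask the question with bulk transcriptomics is:

1. **Dichotomize** a multi-entity cohort into *target-high* vs *rest*
   samples using per-entity expression z-scores (`z ≥ 1.5` on
   log2-transformed abundance, computed within each entity so that the
   label means "high *for its entity*").
2. **Extract a consensus signature**: train `M = 100` random-forest
   classifiers (1000 trees each) on independent 50/50 train/evaluation
   splits of the cohort, using raw unlogged expression as features; from
   each model take the `K = 200` genes with the largest impurity
   importances; rank genes by how many of the `M` models included them
   (occurrence count), breaking ties by mean importance, then gene id.
   The top-`K` of that ranking is the consensus signature.
3. **Validate**: (a) per-sample majority vote over each model's held-out
   predictions gives one cohort-level confusion matrix, from which
   `F1 = 2TP/(2TP+FP+FN)` and
   `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
   are computed — both matter because the positive class is only a few
   percent of the cohort; (b) the *leave-target-out overlap*: re-run the
   whole procedure with the target gene deleted from the feature matrix
   and report the fraction of the signature that survives.
4. **Characterize**: per-entity Pearson/Spearman panels of the target
   against candidate microenvironment genes (BH-adjusted across the whole
   panel), splitting of the signature into over-/under-expressed halves
   (Kruskal–Wallis at α = 0.05), group-mean tables for a companion miR
   matrix, and local hypergeometric over-representation analysis against
   user-supplied GMT collections.

Every stage is testable without downloads through a synthetic cohort
generator that plants a known gene module correlated with the target via a
per-sample latent factor (log-normal marginals, entity-specific baselines),
so signature recovery can be scored against ground truth.

## Worked example

```r
library(pansig)

sim    <- simulate_cohort(sim_config(seed = 1))          # 4 entities x 250 samples, 2000 genes
labels <- dichotomize_target(sim$expr, sim$ann, "TG1")   # per-entity z >= 1.5
print(labels)
#> DichotomyLabels for gene 'TG1': 81 high / 1000 total (8.10%), z >= 1.5

res <- run_consensus(sim$expr, labels, rf_config(n_models = 20, n_trees = 200, seed = 42))
print(res$signature)
#> ConsensusSignature (target 'TG1'): 200 genes, 20 models x 200 trees
#>   eval accuracy 0.9361 +/- 0.0060 (min 0.9222, max 0.9441)
#>   rank gene_id occurrences mean_importance
#> 1    1     TG1          20     0.026960169
#> 2    2 MOD0095          20     0.011753759
#> 3    3 MOD0092          20     0.011712527
#> 4    4 MOD0012          20     0.011275825
#> 5    5 MOD0020          20     0.009858336

recovery_score(res$signature, sim$truth)                 # planted-module recall
#> [1] 1

print(aggregate_votes(res$runs, labels))
#> ConfusionSummary: TP 22, FP 3, TN 916, FN 59 (n = 1000)
#>   accuracy 0.9380, F1 0.4151, MCC 0.4689

entity_panel(sim$expr, sim$ann, "TG1", sim$truth$module_gene_ids[1:2])[1:2, ]
#>   entity    gene         r            p            q   n flag
#> 1  ENT01 MOD0001 0.6825338 9.540105e-36 9.540105e-36 250 <NA>
#> 2  ENT01 MOD0002 0.6906368 9.063953e-37 1.035880e-36 250 <NA>
```

Reading the output: the target gene tops its own signature with occurrence
20/20 (it is the label-defining feature), the planted 100-gene module is
fully recovered, accuracy sits a little above the 91.9 % majority-class
rate, and the low F1/MCC relative to accuracy is the expected signature of
a heavily imbalanced classifier. At the production configuration
(100 models × 1000 trees, `rf_config()` defaults) the leave-target-out
overlap on this cohort is 0.89; with only 20 models the tail of the
ranking churns and the overlap drops — use the defaults for real analyses.

The full pipeline (simulate → select → signature → validate → correlate →
enrich) runs from one JSON config via `run_workflow()` or the CLI wrapper
(`inst/cli/pansig`), writing TSV/JSON stage outputs plus a reproducibility
manifest with MD5 digests; see `?run_workflow` and `?pansig_cli`.

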