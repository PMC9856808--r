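#' Confusion-matrix container
#'
#' Plain integer counts; `"high"` is the positive class.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @param n_covered samples contributing at least one evaluation-set
#'   prediction (defaults to the total).
#' @return a `ConfusionSummary` list.
#' @export
confusion_summary <- function(tp, fp, tn, fn, n_covered = tp + fp + tn + fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 n_covered = as.integer(n_covered)),
            class = "ConfusionSummary")
}

#' @export
print.ConfusionSummary <- function(x, ...) {
  cat(sprintf("ConfusionSummary: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_covered))
  cat(sprintf("  accuracy %.4f, F1 %.4f, MCC %.4f\n",
              (x$tp + x$tn) / x$n_covered, f1_score(x), mcc_score(x)))
  invisible(x)
}

#' Aggregate per-model held-out predictions into one confusion matrix
#'
#' Each sample lands in the evaluation half of roughly half the models; its
#' final prediction is the majority vote over those models' predictions,
#' with ties going to the negative class (`"rest"`).  Samples never held out
#' by any model are excluded from the counts and reported via [message()].
#'
#' @param runs list of `ModelRun`s from [run_consensus()].
#' @param labels the `DichotomyLabels` the models were trained against.
#' @return a [confusion_summary()].
#' @export
aggregate_votes <- function(runs, labels) {
  if (!length(runs)) stop("no model runs")
  all_ids <- names(labels$labels)
  votes_high <- votes_total <- stats::setNames(integer(length(all_ids)), all_ids)
  for (run in runs) {
    ids <- run$eval_sample_ids
    votes_total[ids] <- votes_total[ids] + 1L
    is_high <- run$eval_predictions[ids] == "high"
    votes_high[ids] <- votes_high[ids] + as.integer(is_high)
  }
  covered <- votes_total > 0L
  if (any(!covered)) {
    message("aggregate_votes: ", sum(!covered),
            " sample(s) never appeared in an evaluation half; excluded")
  }
  pred <- ifelse(2L * votes_high[covered] > votes_total[covered],
                 "high", "rest")  # tie -> rest
  truth <- labels$labels[all_ids][covered]
  confusion_summary(tp = sum(pred == "high" & truth == "high"),
                    fp = sum(pred == "high" & truth == "rest"),
                    tn = sum(pred == "rest" & truth == "rest"),
                    fn = sum(pred == "rest" & truth == "high"))
}

#' F1 score from a confusion matrix
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`.  The degenerate case
#' `TP = FP = FN = 0` (nothing positive anywhere) is defined as 1, with a
#' warning.
#'
#' @param c a [confusion_summary()].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) {
    warning("no positives in truth or prediction; F1 defined as 1")
    return(1)
  }
  2 * c$tp / denom
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, computed in
#' double precision with the products taken stepwise to avoid integer
#' overflow.  Any zero factor in the denominator yields 0 by convention.
#'
#' @param c a [confusion_summary()].
#' @return MCC in \[-1, 1\].
#' @export
mcc_score <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  denom_factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(denom_factors == 0)) return(0)
  (tp * tn - fp * fn) / exp(sum(log(denom_factors)) / 2)
}

#' Summary statistics of per-model evaluation accuracies
#'
#' @param runs list of `ModelRun`s.
#' @return list with `mean`, `sd` (n-1 denominator; 0 for a single run),
#'   `min`, `max`.
#' @export
accuracy_summary <- function(runs) {
  if (!length(runs)) stop("no model runs")
  accs <- vapply(runs, `[[`, numeric(1), "eval_accuracy")
  list(mean = mean(accs),
       sd = if (length(accs) > 1L) sd(accs) else 0,
       min = min(accs), max = max(accs))
}

# two-decimal, round-half-even report rounding used by the CLI metrics JSON
round2 <- function(x) round(x, 2)
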