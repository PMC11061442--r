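# ROC evaluation: tie-aware AUC, percentile-bootstrap CIs, operating
# points at a fixed specificity (false-positive-rate) target, and the
# DeLong test for correlated AUCs.

#' Tie-aware AUC
#'
#' The Mann-Whitney statistic divided by n_case x n_control; ties count
#' one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = case / positive class).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples the pooled sample set with replacement at the original size;
#' degenerate resamples containing a single class are redrawn (their
#' count is reported as an attribute).
#'
#' @param scores,labels As in [auc()].
#' @param n_boot Number of bootstrap resamples (reference protocol: 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return `c(low, high)` percentile bounds; attributes `aucs` (the
#'   bootstrap draws) and `n_redrawn`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000, seed = 1L,
                             level = 0.95) {
  labels <- as.integer(labels)
  n <- length(scores)
  with_seed(seed, {
    aucs <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[i])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      aucs[b] <- auc(scores[i], labels[i])
    }
    lo_hi <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                             names = FALSE)
    structure(c(low = lo_hi[1], high = lo_hi[2]),
              aucs = aucs, n_redrawn = n_redrawn)
  })
}

#' Operating point and metrics at a specificity target
#'
#' Chooses the smallest score cutoff whose specificity on the evaluated
#' data is at least `spec_target` (equivalently, false positive rate at
#' most `1 - spec_target`), then reports the full confusion-matrix
#' metrics at that threshold (positive call: `score >= threshold`).
#'
#' @param scores,labels As in [auc()].
#' @param spec_target Specificity target (default 0.90, i.e. 10% FPR).
#' @param threshold Optional fixed threshold (e.g. transferred from
#'   training); when supplied the sweep is skipped.
#' @return list(threshold, acc, sen, spe, ppv, npv, tp, fp, fn, tn,
#'   achieved_spec).
#' @export
metrics_at_specificity <- function(scores, labels, spec_target = 0.90,
                                   threshold = NULL) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes must be present")
  }
  t <- threshold %||% threshold_at_specificity(scores, labels, spec_target)
  call <- as.integer(scores >= t)
  tp <- sum(call == 1 & labels == 1)
  fp <- sum(call == 1 & labels == 0)
  fn <- sum(call == 0 & labels == 1)
  tn <- sum(call == 0 & labels == 0)
  list(threshold = t,
       acc = (tp + tn) / (tp + tn + fp + fn),
       sen = tp / (tp + fn),
       spe = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn,
       achieved_spec = tn / (tn + fp))
}

#' ROC curve points
#'
#' One (fpr, tpr) point per distinct threshold step (equal scores form a
#' single step), from (0, 0) to (1, 1).
#'
#' @param scores,labels As in [auc()].
#' @return data.frame: threshold, fpr, tpr.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  steps <- which(!duplicated(s))  # first index of each distinct score
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(steps[-1] - 1L, length(s))
  data.frame(threshold = c(Inf, s[steps]),
             fpr = c(0, fp[last] / n0),
             tpr = c(0, tp[last] / n1))
}

# mid-rank placement values for the DeLong variance estimate
placements <- function(scores, labels) {
  cs <- scores[labels == 1]
  ks <- scores[labels == 0]
  v10 <- vapply(cs, function(x) mean((x > ks) + 0.5 * (x == ks)), numeric(1))
  v01 <- vapply(ks, function(x) mean((cs > x) + 0.5 * (cs == x)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two score vectors computed
#' on the same samples, using the placement-value covariance estimate.
#' A zero variance of the AUC difference (e.g. identical score vectors)
#' is degenerate: p = 1 with a flag.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels (1 = case).
#' @return list(p_value, z, auc_a, auc_b, degenerate).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores and labels must be paired on identical samples")
  }
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present")
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  a1 <- mean(pa$v10); a2 <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- s10 / m + s01 / n
  var_diff <- v[1, 1] + v[2, 2] - 2 * v[1, 2]
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    # zero variance of the AUC difference: identical performance (p = 1,
    # e.g. identical score vectors) or perfectly separated disagreement
    # (the z statistic diverges; p -> 0)
    same <- abs(a1 - a2) <= .Machine$double.eps^0.5
    return(list(p_value = if (same) 1 else 0, z = if (same) 0 else Inf,
                auc_a = a1, auc_b = a2, degenerate = TRUE))
  }
  z <- (a1 - a2) / sqrt(var_diff)
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z, auc_a = a1, auc_b = a2,
       degenerate = FALSE)
}

#' Evaluate a classifier on one dataset
#'
#' Computes scores, AUC with percentile-bootstrap CI, the ROC curve and
#' the operating point at the specificity target, under either the
#' per-dataset threshold policy (re-anchor the threshold on the evaluated
#' dataset; default) or the fixed policy (transfer the training
#' threshold).
#'
#' @param model A `pe_classifier`.
#' @param features Feature table for the dataset.
#' @param labels Binary labels (1 = case); default `features$y`.
#' @param dataset_id Identifier recorded in the report.
#' @param protocol `"per-dataset"` or `"fixed"`.
#' @param spec_target Specificity target for the operating point.
#' @param n_boot,seed Bootstrap CI parameters.
#' @return An `eval_report`: list(dataset_id, n_cases, n_controls, auc,
#'   auc_ci, metrics, roc, protocol, scores).
#' @export
evaluate_dataset <- function(model, features, labels = NULL,
                             dataset_id = "dataset",
                             protocol = c("per-dataset", "fixed"),
                             spec_target = 0.90, n_boot = 1000, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(labels)) labels <- features$y
  if (NROW(features) == 0) stop("empty dataset: ", dataset_id)
  scores <- pe_predict(model, features)
  a <- auc(scores, labels)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, seed = seed)
  thr <- if (protocol == "fixed") model$threshold else NULL
  met <- metrics_at_specificity(scores, labels, spec_target = spec_target,
                                threshold = thr)
  structure(list(dataset_id = dataset_id,
                 n_cases = sum(labels == 1), n_controls = sum(labels == 0),
                 auc = a, auc_ci = c(ci[["low"]], ci[["high"]]),
                 metrics = met, roc = roc_points(scores, labels),
                 protocol = protocol, scores = scores),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: AUC %.3f (%.3f-%.3f), acc %.2f sen %.2f spe %.2f ppv %.2f npv %.2f [%d cases / %d controls]\n",
    x$dataset_id, x$auc, x$auc_ci[1], x$auc_ci[2], x$metrics$acc,
    x$metrics$sen, x$metrics$spe, x$metrics$ppv, x$metrics$npv,
    x$n_cases, x$n_controls))
  invisible(x)
}

#' Map a p-value to the NS/*/**/*** star scheme
#'
#' @param p Numeric p-values.
#' @return Character vector of significance marks.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "NS"))))
}

#' Flatten evaluation reports into a performance table
#'
#' @param reports List of `eval_report`s.
#' @return data.frame with one row per report: dataset, n_cases,
#'   n_controls, auc, ci_low, ci_high, acc, sen, spe, ppv, npv, threshold.
#' @export
eval_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(dataset = r$dataset_id, n_cases = r$n_cases,
               n_controls = r$n_controls, auc = r$auc,
               ci_low = r$auc_ci[1], ci_high = r$auc_ci[2],
               acc = r$metrics$acc, sen = r$metrics$sen,
               spe = r$metrics$spe, ppv = r$metrics$ppv,
               npv = r$metrics$npv, threshold = r$metrics$threshold,
               stringsAsFactors = FALSE)
  }))
}
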