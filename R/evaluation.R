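#' ROC curve and AUC of connection scores against ground truth
#'
#' Sweeps a threshold over the scores (larger = more strongly connected) and
#' reports the ROC polygon together with the AUC computed by the rank
#' statistic `P(score+ > score-) + 0.5 P(score+ = score-)`; the trapezoidal
#' area of the tie-grouped ROC equals this rank value exactly.
#'
#' @param scores per-pair real scores.
#' @param truth per-pair logical ground truth (same order).
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`,
#'   `sensitivity`, `specificity`; starts at (0,0), ends at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0L || nN == 0L)
    stop("ROC needs at least one positive and one negative pair")
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[truth]) - nP * (nP + 1) / 2) / (nP * nN)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(s) sum(scores >= s & truth), 0)
  fp <- vapply(thr, function(s) sum(scores >= s & !truth), 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / nN),
                    tpr = c(0, tp / nP))
  roc$sensitivity <- roc$tpr
  roc$specificity <- 1 - roc$fpr
  list(roc = roc, auc = auc)
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Best classification accuracy over score thresholds
#'
#' Maximum of `(TP + TN) / n` over all thresholds of the score sweep.
#'
#' @inheritParams roc_auc
#' @return list with `accuracy` (in `[0, 1]`) and `threshold` attaining it.
#' @export
best_accuracy <- function(scores, truth) {
  truth <- as.logical(truth)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  acc <- vapply(thr, function(s)
    (sum(scores >= s & truth) + sum(scores < s & !truth)) / length(truth), 0)
  i <- which.max(acc)
  list(accuracy = acc[i], threshold = thr[i])
}

#' False discovery proportion against q-value thresholds
#'
#' For each threshold `tau`, declares pairs with `q <= tau` discovered and
#' reports the realized proportion of false discoveries,
#' `FDP = #false / max(1, #discoveries)` (0 when nothing is discovered).
#' Plotted against `tau`, a curve below the diagonal means the q-value
#' estimation is conservative.
#'
#' @param q per-pair q-values in `[0, 1]`.
#' @param truth per-pair logical ground truth.
#' @param thresholds q-value thresholds.
#' @return data.frame `threshold`, `discoveries`, `false_discoveries`, `fdp`.
#' @export
fdp_curve <- function(q, truth, thresholds = c(0.05, 0.1, 0.2, 0.3)) {
  truth <- as.logical(truth)
  stopifnot(length(q) == length(truth), all(q >= 0 & q <= 1))
  res <- lapply(thresholds, function(tau) {
    disc <- q <= tau
    nf <- sum(disc & !truth)
    data.frame(threshold = tau, discoveries = sum(disc),
               false_discoveries = nf, fdp = nf / max(1L, sum(disc)))
  })
  do.call(rbind, res)
}

#' Ground-truth labels of the ordered real pairs of a simulation
#'
#' @param sim a [simulate_network()] result.
#' @return data.frame `dest`, `source`, `connected` over all ordered
#'   non-self real pairs, in the row order used by [run_test_suite()].
#' @export
pair_truth <- function(sim) {
  C <- sim$spec$C
  pairs <- expand.grid(source = seq_len(C), dest = seq_len(C))[, 2:1]
  pairs <- pairs[pairs$dest != pairs$source, ]
  rownames(pairs) <- NULL
  pairs$connected <- sim$truth[cbind(pairs$source, pairs$dest)]
  pairs
}
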