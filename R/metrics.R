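# Evaluation suite: protein-centric F-max and micro-averaged AUPRC for
# multilabel function prediction, concordance index and the RMSE /
# Pearson / r^2 / r0^2 / rm^2 family for affinity regression, and the
# adduct / position accuracies of the covalent seq2seq task.

check_label_matrices <- function(truth, scores) {
  truth <- as.matrix(truth)
  scores <- as.matrix(scores)
  stopifnot(all(dim(truth) == dim(scores)), is.numeric(scores))
  truth <- truth != 0
  if (!any(truth)) stop("truth contains no positive labels")
  list(truth = truth, scores = scores)
}

#' Protein-centric F-max
#'
#' Sweeps all distinct score values as thresholds; at each threshold t a
#' label is predicted when its score is strictly above t (so a score of
#' zero never becomes a prediction). Precision is averaged only
#' over items with at least one prediction (CAFA convention), recall over
#' all items with at least one true label; F-max is the maximum harmonic
#' mean over the sweep.
#'
#' @param truth Items x classes logical/0-1 matrix of true labels.
#' @param scores Items x classes numeric score matrix.
#' @return List with `f_max`, `threshold` (argmax), and `sweep` (data
#'   frame of threshold, precision, recall, f1).
#' @export
f_max <- function(truth, scores) {
  z <- check_label_matrices(truth, scores)
  truth <- z$truth; scores <- z$scores
  thresholds <- sort(unique(as.vector(scores)))
  has_truth <- rowSums(truth) > 0
  sweep <- do.call(rbind, lapply(thresholds, function(t) {
    pred <- scores > t
    tp <- rowSums(pred & truth)
    npred <- rowSums(pred)
    covered <- npred > 0
    precision <- if (any(covered)) mean(tp[covered] / npred[covered]) else NA_real_
    recall <- mean(tp[has_truth] / rowSums(truth)[has_truth])
    f1 <- if (is.na(precision) || precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    data.frame(threshold = t, precision = precision, recall = recall, f1 = f1)
  }))
  best <- which.max(sweep$f1)
  list(f_max = sweep$f1[best], threshold = sweep$threshold[best], sweep = sweep)
}

#' Micro-averaged area under the precision-recall curve
#'
#' All (item, class) pairs are pooled; the step-wise precision-recall
#' curve is integrated over distinct score thresholds (ties grouped).
#'
#' @inheritParams f_max
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(truth, scores) {
  z <- check_label_matrices(truth, scores)
  y <- as.vector(z$truth)
  s <- as.vector(z$scores)
  P <- sum(y)
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  grp_last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y)[grp_last]
  np <- seq_along(y)[grp_last]
  recall <- tp / P
  precision <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Concordance index for affinity ranking
#'
#' Over all pairs whose true affinities are strictly ordered, credits 1
#' when the predictions are ordered the same way, 0.5 when the
#' predictions are tied, 0 otherwise, normalized by the number of
#' ordered pairs.
#'
#' @param y_true Numeric vector of true affinities.
#' @param y_pred Numeric vector of predicted affinities.
#' @return Concordance index in `[0, 1]`.
#' @export
concordance_index <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2,
            is.numeric(y_true), is.numeric(y_pred),
            all(is.finite(y_true)), all(is.finite(y_pred)))
  dt <- outer(y_true, y_true, "-")
  dp <- outer(y_pred, y_pred, "-")
  sel <- dt > 0
  Z <- sum(sel)
  if (Z == 0) stop("all true affinities are tied; concordance undefined")
  (sum(dp[sel] > 0) + 0.5 * sum(dp[sel] == 0)) / Z
}

#' Regression metrics for affinity prediction
#'
#' Computes RMSE, the Pearson correlation r, r^2 (squared Pearson
#' correlation, QSAR convention), r0^2 (coefficient of determination of
#' the through-origin regression of observed on predicted, after Roy et
#' al.), and rm^2 = r^2 * (1 - sqrt(r^2 - r0^2)) with the radicand
#' clamped at zero.
#'
#' @inheritParams concordance_index
#' @return List with `rmse`, `pearson_r`, `r_squared`, `r0_squared`,
#'   `rm_squared`.
#' @export
regression_suite <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance in observations or predictions")
  }
  rmse <- sqrt(mean((y_true - y_pred)^2))
  r <- stats::cor(y_true, y_pred)
  r2 <- r^2
  k <- sum(y_true * y_pred) / sum(y_pred^2)
  r02 <- 1 - sum((y_true - k * y_pred)^2) / sum((y_true - mean(y_true))^2)
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r02)))
  list(rmse = rmse, pearson_r = r, r_squared = r2,
       r0_squared = r02, rm_squared = rm2)
}

#' Accuracy of adduct and position predictions
#'
#' Each prediction and reference is parsed with
#' [parse_adduct_prediction()] (already-parsed lists are accepted). The
#' adduct is correct when the predicted SMILES canonicalizes to the same
#' molecule as the reference; the position is correct when the parsed
#' indices match. Malformed predictions count as incorrect on both.
#'
#' @param predictions List of predicted outputs (token vectors, strings,
#'   or parsed lists).
#' @param references List of reference outputs, parallel to
#'   `predictions`; must all be well-formed.
#' @return List with `adduct_accuracy` and `position_accuracy`.
#' @export
adduct_task_accuracy <- function(predictions, references) {
  if (length(predictions) != length(references)) {
    stop("predictions and references have different lengths")
  }
  as_parsed <- function(x) {
    if (is.list(x) && !is.null(x$malformed)) x else parse_adduct_prediction(x)
  }
  preds <- lapply(predictions, as_parsed)
  refs <- lapply(references, as_parsed)
  if (any(vapply(refs, function(r) r$malformed, logical(1)))) {
    stop("malformed reference output")
  }
  ok <- !vapply(preds, function(p) p$malformed, logical(1))
  pos_ok <- ok
  add_ok <- ok
  if (any(ok)) {
    pos_ok[ok] <- vapply(preds[ok], function(p) p$position, integer(1)) ==
      vapply(refs[ok], function(r) r$position, integer(1))
    pcan <- canonical_smiles(vapply(preds[ok], function(p) p$adduct_smiles,
                                    character(1)))
    rcan <- canonical_smiles(vapply(refs[ok], function(r) r$adduct_smiles,
                                    character(1)))
    add_ok[ok] <- !is.na(pcan) & pcan == rcan
  }
  list(adduct_accuracy = mean(add_ok), position_accuracy = mean(pos_ok))
}
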