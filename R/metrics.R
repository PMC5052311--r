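#' Round percentages half-up, matching clinical reporting style
#' @param x Numeric vector of percentages.
#' @return Integer-valued numeric, ties rounded away from zero.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Confusion matrix at a score threshold
#'
#' Predicts HNSCC (the positive class) iff `score > threshold` (strict, so
#' a threshold of 1 predicts nothing positive).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels `"HNSCC"`/`"LUNG"` or logical (`TRUE` = positive).
#' @param threshold Score cut.
#' @return A `confusion_matrix`: list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (!length(scores)) stop("empty input", call. = FALSE)
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(scores >= 0 & scores <= 1))
  pred <- scores > threshold
  confusion_matrix(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
                   tn = sum(!pred & y == 0), fn = sum(!pred & y == 1))
}

#' Construct a confusion matrix from counts
#' @param tp,fp,tn,fn Non-negative integer counts (positive class = HNSCC).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cm <- list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
             fn = as.integer(fn))
  stopifnot(all(unlist(cm) >= 0), sum(unlist(cm)) >= 1)
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Proportions on `[0, 1]`; the reporting layer rounds percentages half-up
#' to integers ([round_half_up()]), matching how such studies print rates.
#'
#' @param cm A [confusion_matrix()] with at least one actual positive and
#'   one actual negative.
#' @return Named numeric: `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec_acc <- function(cm) {
  if (cm$tp + cm$fn < 1 || cm$tn + cm$fp < 1) {
    stop("both class margins must be non-empty", call. = FALSE)
  }
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp),
    accuracy = (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$tn + cm$fn))
}

#' Matthews correlation coefficient
#'
#' \eqn{(tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}; defined as
#' 0 when any marginal is zero (the common convention for the degenerate
#' case). Reported values are conventionally rounded to 2 decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Reconstruct the confusion matrix behind printed diagnostic rates
#'
#' Given class sizes and the printed (integer-rounded) sensitivity and
#' specificity percentages, returns the unique integer confusion matrix
#' consistent with them: `tp = round(sens/100 * n_pos)`,
#' `tn = round(spec/100 * n_neg)`, complements for `fn`/`fp`. This is how
#' headline counts (total misclassified patients, accuracy, MCC) are
#' recovered from a published report that prints only rates.
#'
#' @param n_pos,n_neg Actual positives (HNSCC) and negatives (lung).
#' @param sens_pct,spec_pct Printed percentages in `[0, 100]`.
#' @return A [confusion_matrix()].
#' @export
reconstruct_confusion <- function(n_pos, n_neg, sens_pct, spec_pct) {
  stopifnot(sens_pct >= 0, sens_pct <= 100, spec_pct >= 0, spec_pct <= 100)
  tp <- round_half_up(sens_pct / 100 * n_pos)
  tn <- round_half_up(spec_pct / 100 * n_neg)
  confusion_matrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Threshold maximising a diagnostic criterion
#'
#' Scans the midpoints between adjacent sorted unique scores plus the
#' endpoints 0 and 1, and returns the cut maximising the criterion
#' (`accuracy` or Youden's J = sensitivity + specificity - 1) under the
#' strict `score > threshold` rule. Ties are broken towards the lowest
#' threshold; with all scores equal this returns whichever endpoint
#' classifies the majority class correctly (0 when positives dominate).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Class labels, both classes present.
#' @param criterion `"accuracy"` or `"youden"`.
#' @return The optimal threshold.
#' @export
optimal_threshold <- function(scores, labels, criterion = c("accuracy", "youden")) {
  criterion <- match.arg(criterion)
  y <- as_binary_labels(labels)
  stopifnot(any(y == 1), any(y == 0))
  u <- sort(unique(scores))
  cuts <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  val <- vapply(cuts, function(th) {
    cm <- confusion_at_threshold(scores, labels, th)
    if (criterion == "accuracy") {
      (cm$tp + cm$tn) / length(y)
    } else {
      cm$tp / (cm$tp + cm$fn) + cm$tn / (cm$tn + cm$fp) - 1
    }
  }, numeric(1))
  cuts[which.max(val)] # which.max takes the first, i.e. lowest, maximiser
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with ties counted half: the
#' probability that a random HNSCC score exceeds a random lung score. The
#' 95 % CI uses DeLong's placement-variance estimator, truncated to
#' `[0, 1]`. Curve points are evaluated at every distinct score cut under
#' the strict `score > threshold` rule, so sensitivity is non-increasing
#' and specificity non-decreasing as the threshold rises.
#'
#' @param scores Numeric scores.
#' @param labels Class labels, both classes present.
#' @return A `roc_curve`: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `ci95`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(any(y == 1), any(y == 0), length(scores) == length(y))
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong placements
  psi <- function(x, ys) mean((x > ys) + 0.5 * (x == ys))
  v10 <- vapply(pos, psi, numeric(1), ys = neg)
  v01 <- vapply(neg, function(yv) mean((pos > yv) + 0.5 * (pos == yv)),
                numeric(1))
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  th <- sort(unique(c(-Inf, scores, Inf)))
  sens <- vapply(th, function(t) mean(pos > t), numeric(1))
  spec <- vapply(th, function(t) mean(neg <= t), numeric(1))
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, ci95 = ci), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (95%% CI %.3f-%.3f), %d cuts\n",
              x$auc, x$ci95[1], x$ci95[2], length(x$thresholds)))
  invisible(x)
}
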