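#' Confusion counts with disordered as the positive class
#'
#' @param predicted,truth parallel vectors in `{"disordered","ordered"}`.
#' @return A list of class `confusion_counts` with integer `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(predicted) == 0L) stop("empty input")
  ok <- c("disordered", "ordered")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be 'disordered' or 'ordered'")
  structure(list(
    TP = sum(predicted == "disordered" & truth == "disordered"),
    TN = sum(predicted == "ordered"    & truth == "ordered"),
    FP = sum(predicted == "disordered" & truth == "ordered"),
    FN = sum(predicted == "ordered"    & truth == "disordered")
  ), class = "confusion_counts")
}

#' Imbalanced-data classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall on disorder), specificity, balanced
#' accuracy, PPV (precision), NPV, F-score and Matthews correlation
#' coefficient. Any metric whose denominator is zero is reported as `NA`
#' (an explicit undefined marker), never silently 0.
#'
#' @param counts a `confusion_counts`, or a list/vector with elements `TP`,
#'   `TN`, `FP`, `FN`.
#' @return A list of class `metrics_report`.
#' @export
#' @examples
#' ch_metrics(list(TP = 8, FN = 2, TN = 9, FP = 1))$balanced_acc  # 0.85
ch_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); TN <- as.numeric(counts[["TN"]])
  FP <- as.numeric(counts[["FP"]]); FN <- as.numeric(counts[["FN"]])
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  total <- TP + TN + FP + FN
  if (total == 0) stop("all-zero confusion counts")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- sdiv(TP, TP + FN)
  spec <- sdiv(TN, TN + FP)
  ppv  <- sdiv(TP, TP + FP)
  npv  <- sdiv(TN, TN + FN)
  bal  <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  f <- if (!is.na(ppv) && !is.na(sens)) {
    if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  } else NA_real_
  mcc_den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (mcc_den > 0) (TP * TN - FP * FN) / sqrt(mcc_den) else NA_real_
  structure(list(acc = sdiv(TP + TN, total), sensitivity = sens,
                 specificity = spec, balanced_acc = bal, ppv = ppv,
                 npv = npv, f = f, mcc = mcc,
                 counts = list(TP = TP, TN = TN, FP = FP, FN = FN)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x[c("sensitivity", "specificity", "balanced_acc", "auc",
                  "f", "mcc", "ppv", "npv")])
  v <- v[!vapply(v, is.null, logical(1))]
  cat("Classification metrics (positive class = disordered):\n")
  print(round(v, digits))
  invisible(x)
}

#' Area under the ROC curve
#'
#' AUC computed as the rank-sum (Mann-Whitney) statistic: the probability
#' that a randomly chosen disordered score exceeds a randomly chosen ordered
#' score, with ties credited 0.5. Scores must be oriented so larger means
#' more disordered. Equivalent to the trapezoidal area under the ROC curve.
#'
#' @param scores numeric ranking scores.
#' @param labels parallel vector in `{"disordered","ordered"}`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == "disordered"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score threshold maximizing the F-score
#'
#' Sweeps every cut position over the sorted unique scores (candidate
#' thresholds are midpoints between adjacent distinct values, plus guards
#' below the minimum and above the maximum) and returns the threshold
#' maximizing F with disordered as the positive class (predict disordered iff
#' score > threshold). Ties are broken toward the higher threshold (higher
#' specificity).
#'
#' @param scores numeric, larger means more disordered.
#' @param labels parallel `{"disordered","ordered"}` vector.
#' @return The optimal threshold; attributes `"f"` holds the achieved
#'   F-score.
#' @export
optimize_threshold_for_f <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == "disordered"
  if (all(pos) || !any(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best_t <- NA_real_; best_f <- -Inf
  for (t in cand) {
    pred <- scores > t
    TP <- sum(pred & pos); FP <- sum(pred & !pos); FN <- sum(!pred & pos)
    f <- if (TP + FP == 0 || TP + FN == 0) NA_real_ else {
      prec <- TP / (TP + FP); rec <- TP / (TP + FN)
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    if (!is.na(f) && f >= best_f) {  # >= breaks ties toward higher threshold
      best_f <- f; best_t <- t
    }
  }
  structure(best_t, f = best_f)
}

#' Evaluate predictions into a full metrics report
#'
#' @param predicted,truth parallel label vectors.
#' @param scores optional ranking scores (larger = more disordered) for AUC.
#' @return A `metrics_report` with an `auc` element when scores are given.
#' @export
evaluate_predictions <- function(predicted, truth, scores = NULL) {
  rep <- ch_metrics(confusion(predicted, truth))
  if (!is.null(scores)) rep$auc <- roc_auc(scores, truth)
  rep
}

#' Serialize a metrics report to JSON
#'
#' Keys follow the conventional short names (acc, sens, spec, bal_acc, ppv,
#' npv, f, mcc, auc); undefined metrics render as null.
#'
#' @param report a `metrics_report`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
metrics_json <- function(report, path = NULL) {
  obj <- list(acc = report$acc, sens = report$sensitivity,
              spec = report$specificity, bal_acc = report$balanced_acc,
              ppv = report$ppv, npv = report$npv, f = report$f,
              mcc = report$mcc, auc = report$auc)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
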