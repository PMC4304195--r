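#' Derive a hydropathy scale from a labelled protein corpus
#'
#' The central fitting routine. Each protein is chopped into fixed-width
#' windows (default 41 residues); every window contributes one row of 20
#' composition fractions plus the signed normalized net charge, with target
#' -1 for disordered and +1 for ordered windows. A class-weighted linear
#' max-margin classifier is trained within a protein-level k-fold
#' cross-validation repeated `repeats` times, and the 21 weights and bias are
#' averaged over all k x repeats fold models. The averaged first 20 weights
#' are the derived scale: under the sign convention used here a negative
#' weight is disorder-promoting and a positive weight order-promoting
#' (hydrophobic), so the scale reads directly as a hydropathy scale.
#'
#' Held-out windows in every fold are scored by the fold's model; the
#' classification threshold is chosen on the training windows to maximize the
#' F-score (disordered positive), and the full imbalanced-data metric suite
#' is reported per fold and pooled.
#'
#' @param seqs named character vector of protein sequences.
#' @param labels parallel vector in `{"disordered","ordered"}`.
#' @param window window width in residues (default 41).
#' @param k folds (default 10).
#' @param repeats cross-validation repetitions (default 5).
#' @param class_weights `NULL` for inverse class count (equal total penalty
#'   per class), or named numeric.
#' @param cost regularization strength C (default 1).
#' @param charge `"signed"` (default) or `"absolute"` net charge as the 21st
#'   training feature.
#' @param seed master seed; per-repeat fold seeds are derived from it.
#' @return An object of class `derived_scale` with elements
#'   `residue_weights` (named 20-vector), `charge_weight`, `bias`, `models`
#'   (per-fold weight matrix), `cv` (per-fold metric table), `pooled`
#'   (pooled held-out `metrics_report`), `folds` (per-repeat assignments),
#'   and the call parameters.
#' @export
derive_scale <- function(seqs, labels, window = 41L, k = 10L, repeats = 5L,
                         class_weights = NULL, cost = 1.0,
                         charge = c("signed", "absolute"), seed = 1L) {
  charge <- match.arg(charge)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (length(labels) != length(seqs)) stop("'labels' must parallel 'seqs'")
  labels <- as.character(labels)

  win <- lapply(seqs, chop_windows, width = window)
  n_windows <- vapply(win, nrow, integer(1))
  rng <- .local_rng(seed)
  rep_seeds <- rng$rint(repeats, max = 2147483L) # fold-assignment seeds

  all_w <- list(); cv_rows <- list(); fold_assign <- list()
  pooled_pred <- character(0); pooled_truth <- character(0)
  pooled_score <- numeric(0)

  for (r in seq_len(repeats)) {
    folds <- assign_folds(names(seqs), labels, n_windows, k = k,
                          seed = rep_seeds[r])
    fold_assign[[r]] <- folds
    for (f in seq_len(k)) {
      test_ids <- names(folds)[folds == f]
      train_ids <- names(folds)[folds != f]
      tm_tr <- .windows_matrix(seqs[train_ids], labels[match(train_ids, names(seqs))],
                               win[train_ids], charge)
      model <- train_weighted_linear(tm_tr, class_weights = class_weights,
                                     cost = cost)
      all_w[[length(all_w) + 1L]] <- c(model$w, bias = model$b)

      tm_te <- .windows_matrix(seqs[test_ids], labels[match(test_ids, names(seqs))],
                               win[test_ids], charge)
      # disorder-positive ranking scores: negate (positive decision = ordered)
      tr_scores <- -linear_decision(model, tm_tr$X)
      te_scores <- -linear_decision(model, tm_te$X)
      thr <- optimize_threshold_for_f(tr_scores, tm_tr$labels)
      pred <- ifelse(te_scores > thr, "disordered", "ordered")
      rep_m <- tryCatch(
        evaluate_predictions(pred, tm_te$labels, scores = te_scores),
        error = function(e) NULL)
      cv_rows[[length(cv_rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, n_test = nrow(tm_te$X),
        acc = .m(rep_m, "acc"), sensitivity = .m(rep_m, "sensitivity"),
        specificity = .m(rep_m, "specificity"),
        balanced_acc = .m(rep_m, "balanced_acc"), ppv = .m(rep_m, "ppv"),
        npv = .m(rep_m, "npv"), f = .m(rep_m, "f"), mcc = .m(rep_m, "mcc"),
        auc = .m(rep_m, "auc"))
      pooled_pred <- c(pooled_pred, pred)
      pooled_truth <- c(pooled_truth, tm_te$labels)
      pooled_score <- c(pooled_score, te_scores)
    }
  }
  W <- do.call(rbind, all_w)
  avg <- colMeans(W)
  pooled <- evaluate_predictions(pooled_pred, pooled_truth, pooled_score)
  structure(list(
    residue_weights = avg[AA], charge_weight = unname(avg["charge"]),
    bias = unname(avg["bias"]), models = W,
    cv = do.call(rbind, cv_rows), pooled = pooled, folds = fold_assign,
    params = list(window = window, k = k, repeats = repeats, cost = cost,
                  charge = charge, seed = seed,
                  n_proteins = length(seqs),
                  n_disordered = sum(labels == "disordered"),
                  n_ordered = sum(labels == "ordered"))
  ), class = "derived_scale")
}

.m <- function(rep, key) {
  if (is.null(rep) || is.null(rep[[key]])) NA_real_ else rep[[key]]
}

# build a training_matrix from pre-chopped windows of a set of proteins
.windows_matrix <- function(seqs, labels, win, charge) {
  w <- unlist(lapply(win, function(d) d$window), use.names = FALSE)
  l <- rep(labels, vapply(win, nrow, integer(1)))
  ids <- rep(names(seqs), vapply(win, nrow, integer(1)))
  build_training_matrix(w, l, ids = ids, charge = charge)
}

#' Convert a derived scale into an `aa_scale`
#'
#' The raw averaged weights are kept as-is (hydrophobic-positive by the
#' training sign convention); use [prepare_scale()] for the unit-normalized
#' view used on C-H plots.
#'
#' @param x a `derived_scale`.
#' @param id identifier for the resulting scale.
#' @return An `aa_scale`.
#' @export
as_aa_scale <- function(x, id = "derived") {
  stopifnot(inherits(x, "derived_scale"))
  aa_scale(id, x$residue_weights, orientation = "hydrophobic_positive",
           source = "derived by chplot::derive_scale")
}

#' @export
coef.derived_scale <- function(object, ...) {
  c(object$residue_weights, charge = object$charge_weight,
    bias = object$bias)
}

#' @export
print.derived_scale <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Derived hydropathy scale: %d proteins (%d disordered / %d ordered)\n",
    p$n_proteins, p$n_disordered, p$n_ordered))
  cat(sprintf("  window %d, %d-fold CV x %d repeats, cost %g, %s charge\n",
              p$window, p$k, p$repeats, p$cost, p$charge))
  cat("Residue weights (negative = disorder-promoting):\n")
  print(round(sort(x$residue_weights, decreasing = TRUE), 3))
  cat(sprintf("charge weight %.3f, bias %.3f\n", x$charge_weight, x$bias))
  invisible(x)
}

#' @export
summary.derived_scale <- function(object, ...) {
  cv <- object$cv
  cols <- c("acc", "sensitivity", "specificity", "balanced_acc", "ppv",
            "npv", "f", "mcc", "auc")
  per_fold <- sapply(cols, function(cn) {
    v <- cv[[cn]]
    c(mean = mean(v, na.rm = TRUE), sd_folds = stats::sd(v, na.rm = TRUE))
  })
  rep_means <- stats::aggregate(cv[cols], by = list(repeat_ = cv$repeat_),
                                FUN = mean, na.rm = TRUE)
  sd_repeats <- vapply(cols, function(cn) stats::sd(rep_means[[cn]]),
                       numeric(1))
  out <- list(per_fold = t(per_fold), sd_repeats = sd_repeats,
              pooled = object$pooled, params = object$params)
  class(out) <- "summary.derived_scale"
  out
}

#' @export
print.summary.derived_scale <- function(x, ...) {
  cat("Window-level held-out metrics (mean +/- sd over folds x repeats):\n")
  pf <- x$per_fold
  for (cn in rownames(pf))
    cat(sprintf("  %-13s %.3f +/- %.3f (sd over repeat means %.3f)\n",
                cn, pf[cn, "mean"], pf[cn, "sd_folds"], x$sd_repeats[cn]))
  cat("Pooled held-out:\n")
  print(x$pooled)
  invisible(x)
}

#' @export
plot.derived_scale <- function(x, ...) {
  w <- sort(x$residue_weights)
  graphics::barplot(w, col = ifelse(w < 0, "firebrick", "steelblue"),
                    las = 2, ylab = "weight (negative = disorder-promoting)",
                    main = "Derived hydropathy scale", ...)
  invisible(x)
}

#' Predict order/disorder for sequences from a derived scale
#'
#' Maps sequences to the C-H plane under the derived scale (oriented and
#' unit-normalized) and classifies them against `boundary`; if no boundary is
#' given, one attached by [refit_whole_protein_boundary()] is used.
#'
#' @param object a `derived_scale`.
#' @param seqs named character vector of sequences.
#' @param boundary optional `ch_boundary`.
#' @param ... unused.
#' @return data.frame `id`, `H`, `R`, `score`, `predicted_label`.
#' @export
predict.derived_scale <- function(object, seqs, boundary = NULL, ...) {
  if (is.null(boundary)) boundary <- object$boundary
  if (is.null(boundary))
    stop("no boundary: pass one or run refit_whole_protein_boundary() first")
  predict(boundary, seqs, as_aa_scale(object))
}

#' Refit the whole-protein C-H boundary for a derived scale
#'
#' The derived residue weights are oriented and unit-normalized into a
#' hydropathy scale, every protein is mapped to its whole-protein C-H point,
#' and a linear boundary is fitted within a protein-level k-fold
#' cross-validation; the returned boundary's slope and intercept are the
#' means over the per-fold boundaries, and held-out whole-protein predictions
#' (each protein scored by the boundary of the fold that excluded it) give
#' the attached metric report.
#'
#' @param derived a `derived_scale`.
#' @param seqs,labels the labelled corpus (whole proteins).
#' @param k folds (default 10); `k = 1` fits once on all points with
#'   in-sample metrics.
#' @param class_weights,cost passed to [fit_boundary()].
#' @param seed fold-assignment seed.
#' @return A `ch_boundary` with attributes `per_fold` (per-fold a, b),
#'   `heldout` (pooled held-out `metrics_report`) and `points` (the labelled
#'   C-H points with held-out predictions).
#' @export
refit_whole_protein_boundary <- function(derived, seqs, labels, k = 10L,
                                         class_weights = NULL, cost = 1.0,
                                         seed = 1L) {
  stopifnot(inherits(derived, "derived_scale"))
  benchmark_scale(as_aa_scale(derived), seqs, labels, k = k,
                  class_weights = class_weights, cost = cost, seed = seed)
}

#' Cross-validated C-H boundary for a fixed scale
#'
#' Maps the labelled proteins to C-H points under the given scale and fits a
#' linear boundary within protein-level k-fold cross-validation; the returned
#' boundary averages the per-fold slopes and intercepts, and held-out
#' predictions give the attached metric report. This is the per-scale
#' benchmark used to compare hydropathy scales.
#'
#' @param scale an `aa_scale` (oriented/normalized internally).
#' @inheritParams refit_whole_protein_boundary
#' @return A `ch_boundary` with attributes `per_fold`, `heldout`, `points`.
#' @export
benchmark_scale <- function(scale, seqs, labels, k = 10L,
                            class_weights = NULL, cost = 1.0, seed = 1L) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  pts <- ch_points(seqs, prepare_scale(scale), labels = labels)
  if (k == 1L) {
    bd <- fit_boundary(pts, class_weights = class_weights, cost = cost)
    pts$score <- decision_score(pts, bd)
    pts$predicted_label <- classify_ch(pts, bd)
    attr(bd, "per_fold") <- data.frame(fold = 1L, a = bd$a, b = bd$b)
    attr(bd, "heldout") <- evaluate_predictions(pts$predicted_label,
                                                pts$label, pts$score)
    attr(bd, "points") <- pts
    return(bd)
  }
  folds <- assign_folds(pts$id, pts$label, rep(1L, nrow(pts)), k = k,
                        seed = seed)
  ab <- matrix(NA_real_, nrow = k, ncol = 2, dimnames = list(NULL, c("a", "b")))
  pts$score <- NA_real_; pts$predicted_label <- NA_character_
  for (f in seq_len(k)) {
    tr <- pts[folds[pts$id] != f, ]
    te_idx <- which(folds[pts$id] == f)
    bd_f <- fit_boundary(tr, class_weights = class_weights, cost = cost)
    ab[f, ] <- c(bd_f$a, bd_f$b)
    pts$score[te_idx] <- decision_score(pts[te_idx, ], bd_f)
    pts$predicted_label[te_idx] <- classify_ch(pts[te_idx, ], bd_f)
  }
  bd <- ch_boundary(mean(ab[, "a"]), mean(ab[, "b"]))
  attr(bd, "per_fold") <- data.frame(fold = seq_len(k), a = ab[, "a"],
                                     b = ab[, "b"])
  attr(bd, "heldout") <- evaluate_predictions(pts$predicted_label, pts$label,
                                              pts$score)
  attr(bd, "points") <- pts
  bd
}
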