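# Class-weighted linear max-margin fit with a fixed sign convention.
#
# Wraps e1071::svm (linear kernel, C-classification, no internal feature
# scaling) and extracts the primal weight vector w and bias b of the decision
# function f(x) = x . w + b. The sign is normalized so that f(x) > 0 always
# means "ordered" (equivalently, disordered carries the -1 target), by
# checking the recovered w, b against the model's own class predictions.
#
# labels: character/factor in {"disordered","ordered"}.
# class_weights: NULL (inverse class count, equal total penalty per class)
# or named numeric.
.fit_linear_svm <- function(X, labels, class_weights = NULL, cost = 1.0) {
  X <- as.matrix(X)
  y <- factor(as.character(labels), levels = c("disordered", "ordered"))
  if (anyNA(y)) stop("labels must be 'disordered' or 'ordered'")
  tab <- table(y)
  if (any(tab == 0)) stop("both classes must be present to train")
  if (is.null(class_weights)) {
    # inverse class count scaled to a fixed reference class size: each class
    # carries the same total slack penalty (cost * 1000) however imbalanced
    # the data, replicating every row (with weights recomputed) leaves the
    # solution unchanged, and per-point penalties stay O(1) for corpora in
    # the hundreds-to-thousands of windows so the solver is well conditioned
    class_weights <- setNames(as.numeric(1000 / tab), names(tab))
  }
  # tight termination tolerance: the solution then honours exact model
  # identities (e.g. duplication invariance) to ~1e-7 at negligible runtime
  # cost for problems of this size
  fit <- e1071::svm(x = X, y = y, kernel = "linear", scale = FALSE,
                    cost = cost, class.weights = class_weights,
                    tolerance = 1e-7)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # enforce: decision > 0 <=> predicted "ordered"
  pred <- predict(fit, X)
  dec <- drop(X %*% w) + b
  agree_ordered <- mean((dec > 0) == (pred == "ordered"))
  if (agree_ordered < 0.5) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b, class_weights = class_weights, cost = cost,
       n_sv = nrow(fit$SV))
}

#' Build the n-by-21 training matrix from labelled windows
#'
#' Each row holds the 20 composition fractions of one sequence window plus its
#' signed normalized net charge; targets are -1 for disordered and +1 for
#' ordered windows (the Kyte-Doolittle energy-transfer convention, under which
#' a negative learned weight is disorder-promoting).
#'
#' @param windows character vector of window sequences.
#' @param labels parallel vector in `{"disordered","ordered"}`.
#' @param ids optional parallel provenance ids.
#' @param charge `"signed"` (default) or `"absolute"` for the 21st column.
#' @return A list of class `training_matrix` with `X` (n x 21 matrix), `Y`
#'   (+/-1), `labels`, `ids`.
#' @export
build_training_matrix <- function(windows, labels, ids = NULL,
                                  charge = c("signed", "absolute")) {
  charge <- match.arg(charge)
  if (length(windows) == 0L) stop("no windows supplied")
  if (length(labels) != length(windows))
    stop("'labels' must parallel 'windows'")
  if (anyNA(labels) || !all(labels %in% c("disordered", "ordered")))
    stop("labels must be 'disordered' or 'ordered' (no missing values)")
  if (is.null(ids)) ids <- sprintf("w%d", seq_along(windows))
  rows <- lapply(windows, function(s) {
    cv <- composition(s)
    ch <- if (charge == "signed") cv$net_charge_signed else abs(cv$net_charge_signed)
    c(cv$comp, charge = ch)
  })
  X <- do.call(rbind, rows)
  colnames(X) <- c(AA, "charge")
  Y <- ifelse(labels == "disordered", -1, 1)
  structure(list(X = X, Y = Y, labels = as.character(labels), ids = ids),
            class = "training_matrix")
}

#' Train a class-weighted linear classifier on window features
#'
#' Fits a linear max-margin classifier on the 21-feature window matrix with
#' per-class misclassification weights (default: inverse class count, so
#' the minority disordered class is up-weighted). The decision function is
#' `x . w + b` with positive values meaning ordered; the first 20 weights,
#' once averaged over cross-validation fits, are the derived hydropathy
#' scale.
#'
#' @param tm a `training_matrix` from [build_training_matrix()].
#' @param class_weights `NULL` (inverse class count, equal total penalty per
#'   class) or a named numeric
#'   vector over `c(disordered=, ordered=)`.
#' @param cost regularization strength C (default 1).
#' @return A list of class `linear_model` with `w` (21 named weights), `b`,
#'   `class_weights`, `cost`.
#' @export
train_weighted_linear <- function(tm, class_weights = NULL, cost = 1.0) {
  stopifnot(inherits(tm, "training_matrix"))
  fit <- .fit_linear_svm(tm$X, tm$labels, class_weights = class_weights,
                         cost = cost)
  structure(list(w = setNames(fit$w, colnames(tm$X)), b = fit$b,
                 class_weights = fit$class_weights, cost = fit$cost,
                 n = nrow(tm$X)),
            class = "linear_model")
}

#' Decision values of a linear window model
#' @param model a `linear_model`.
#' @param X feature matrix with the model's 21 columns.
#' @return Numeric decision values; positive means ordered.
#' @export
linear_decision <- function(model, X) {
  stopifnot(inherits(model, "linear_model"))
  drop(as.matrix(X)[, names(model$w), drop = FALSE] %*% model$w) + model$b
}
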