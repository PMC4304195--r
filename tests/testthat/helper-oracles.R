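# Independent oracles and fixture builders shared across the suite.

# Plain-formula confusion-matrix metrics, coded independently of ch_metrics().
oracle_metrics <- function(TP, TN, FP, FN) {
  und <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- und(TP, TP + FN)
  spec <- und(TN, TN + FP)
  ppv <- und(TP, TP + FP)
  npv <- und(TN, TN + FN)
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  f <- if (is.na(ppv) || is.na(sens)) NA_real_
       else if (ppv + sens == 0) NA_real_
       else 2 * ppv * sens / (ppv + sens)
  d <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (d == 0) NA_real_ else (TP * TN - FP * FN) / d
  list(acc = und(TP + TN, TP + TN + FP + FN), sensitivity = sens,
       specificity = spec, balanced_acc = bal, ppv = ppv, npv = npv,
       f = f, mcc = mcc)
}

# AUC by exhaustive concordant/discordant pair counting (ties credited 0.5).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "disordered"]
  neg <- scores[labels == "ordered"]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive F-optimal threshold: try every cut position over sorted scores
# and return the best achievable F (for comparison against the sweep).
oracle_best_f <- function(scores, labels) {
  u <- sort(unique(scores))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- -Inf
  for (t in cuts) {
    pred <- scores > t
    pos <- labels == "disordered"
    TP <- sum(pred & pos); FP <- sum(pred & !pos); FN <- sum(!pred & pos)
    if (TP + FP == 0 || TP + FN == 0) next
    prec <- TP / (TP + FP); rec <- TP / (TP + FN)
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f > best) best <- f
  }
  best
}

# Random valid amino-acid scale.
random_scale <- function(seed, id = "rnd") {
  set.seed(seed)
  v <- round(stats::rnorm(20, sd = 2), 6)
  v[1] <- v[1] + 5  # guarantee max > min
  chplot::aa_scale(id, stats::setNames(v, names(get_builtin_scale("guy")$values)))
}

# Small labelled corpus for derivation tests (fast; beta = 2 separable-ish).
tiny_corpus <- function(n = 16, seed = 11, beta = 2) {
  chplot::generate_corpus(n_disordered = n, n_ordered = n,
                          length_range = c(82L, 200L), beta = beta,
                          seed = seed)
}
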