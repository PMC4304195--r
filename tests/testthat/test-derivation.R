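AA20 <- names(get_builtin_scale("guy")$values)

test_that("training matrix has 21 columns, -1 disordered targets, Eq-2 charge", {
  tm <- build_training_matrix(c(strrep("K", 41), strrep("A", 41), "KRED"),
                              c("disordered", "ordered", "ordered"))
  expect_equal(dim(tm$X), c(3L, 21L))
  expect_equal(tm$Y, c(-1, 1, 1))
  expect_equal(unname(tm$X[1, "K"]), 1)
  expect_equal(unname(tm$X[1, "charge"]), 1)
  expect_equal(unname(tm$X[3, "charge"]), 0)
  expect_equal(unname(rowSums(tm$X[, AA20])), rep(1, 3), tolerance = 1e-9)
  expect_error(build_training_matrix(character(0), character(0)), "no windows")
  expect_error(build_training_matrix("AAA", NA_character_), "missing|labels")
  # absolute-charge variant
  tm2 <- build_training_matrix(c(strrep("E", 41), strrep("A", 41)),
                               c("disordered", "ordered"), charge = "absolute")
  expect_equal(unname(tm2$X[1, "charge"]), 1)
})

test_that("weighted linear training separates a separable toy exactly", {
  set.seed(2)
  win_dis <- replicate(20, paste(sample(c("P", "E", "S", "K"), 41,
                                        replace = TRUE), collapse = ""))
  win_ord <- replicate(20, paste(sample(c("I", "L", "V", "F"), 41,
                                        replace = TRUE), collapse = ""))
  tm <- build_training_matrix(c(win_dis, win_ord),
                              rep(c("disordered", "ordered"), each = 20))
  mod <- train_weighted_linear(tm)
  dec <- linear_decision(mod, tm$X)
  pred <- ifelse(dec > 0, "ordered", "disordered")
  expect_identical(pred, tm$labels)
  # hydrophobic residues get positive (order-promoting) weights
  expect_true(all(mod$w[c("I", "L", "V", "F")] > 0))
  expect_true(all(mod$w[c("P", "E", "S", "K")] < 0))
  expect_error(train_weighted_linear(
    build_training_matrix(win_dis, rep("disordered", 20))), "both classes")
})

test_that("duplicating every row leaves the decision direction unchanged", {
  co <- tiny_corpus(n = 10, seed = 5)
  tm <- build_training_matrix(
    unlist(lapply(co$seqs, function(s) chop_windows(s)$window)),
    rep(co$labels, vapply(co$seqs, function(s) nrow(chop_windows(s)),
                          integer(1))))
  m1 <- train_weighted_linear(tm)
  tm2 <- tm
  tm2$X <- rbind(tm$X, tm$X); tm2$Y <- c(tm$Y, tm$Y)
  tm2$labels <- c(tm$labels, tm$labels); tm2$ids <- c(tm$ids, tm$ids)
  m2 <- train_weighted_linear(tm2)
  u1 <- c(m1$w, m1$b); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(m2$w, m2$b); u2 <- u2 / sqrt(sum(u2^2))
  expect_equal(u1, u2, tolerance = 1e-6)
})

test_that("label flip negates the learned direction on separable data", {
  set.seed(6)
  win_dis <- replicate(15, paste(sample(c("P", "E", "S"), 41, replace = TRUE),
                                 collapse = ""))
  win_ord <- replicate(15, paste(sample(c("I", "L", "W"), 41, replace = TRUE),
                                 collapse = ""))
  labs <- rep(c("disordered", "ordered"), each = 15)
  tm <- build_training_matrix(c(win_dis, win_ord), labs)
  flipped <- ifelse(labs == "disordered", "ordered", "disordered")
  tmf <- build_training_matrix(c(win_dis, win_ord), flipped)
  w1 <- train_weighted_linear(tm)$w
  w2 <- train_weighted_linear(tmf)$w
  cosine <- sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
  expect_lte(cosine, -0.99)
})

test_that("fold assignment is protein-level, balanced, class-complete, seeded", {
  ids <- sprintf("p%02d", 1:20)
  labs <- rep(c("disordered", "ordered"), each = 10)
  f <- assign_folds(ids, labs, rep(4L, 20), k = 10, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 10))
  for (k in 1:10)
    expect_setequal(labs[match(names(f)[f == k], ids)],
                    c("disordered", "ordered"))
  expect_identical(assign_folds(ids, labs, rep(4L, 20), k = 10, seed = 3), f)
  expect_false(identical(assign_folds(ids, labs, rep(4L, 20), k = 10,
                                      seed = 4), f))
  expect_error(assign_folds(ids[1:12], labs[1:12], rep(1L, 12), k = 10),
               "at least k")

  # balance property: totals within one max-protein window count
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(24:60, 1)
    labs <- sample(rep(c("disordered", "ordered"), c(10, n - 10)))
    if (sum(labs == "ordered") < 10) next
    wins <- sample(2:10, n, replace = TRUE)
    ids <- sprintf("q%03d", seq_len(n))
    f <- assign_folds(ids, labs, wins, k = 10, seed = seed)
    totals <- tapply(wins[match(names(f), ids)], f, sum)
    expect_lte(max(totals) - min(totals), max(wins))
    for (k in 1:10)
      expect_setequal(labs[match(names(f)[f == k], ids)],
                      c("disordered", "ordered"))
  }
})

test_that("derive_scale stores per-fold models whose average is the scale", {
  co <- tiny_corpus(n = 6, seed = 19)
  ds <- derive_scale(co$seqs, co$labels, k = 2, repeats = 1, seed = 1)
  expect_equal(nrow(ds$models), 2L)
  expect_equal(ds$residue_weights, colMeans(ds$models)[AA20])
  expect_equal(ds$charge_weight, unname(mean(ds$models[, "charge"])))
  expect_equal(ds$bias, unname(mean(ds$models[, "bias"])))
  expect_equal(nrow(ds$cv), 2L)
  # determinism: identical seeds give bitwise-identical results
  ds2 <- derive_scale(co$seqs, co$labels, k = 2, repeats = 1, seed = 1)
  expect_identical(ds$residue_weights, ds2$residue_weights)
  expect_identical(ds$models, ds2$models)
})

test_that("derived weights carry the disorder-promoting sign structure", {
  co <- tiny_corpus(n = 20, seed = 23)
  ds <- derive_scale(co$seqs, co$labels, k = 5, repeats = 1, seed = 2)
  # planted direction: residues above/below its mean are order/disorder
  # promoting; signs must agree for at least 16 of 20 residues
  pl <- orient_hydrophobic_positive(planted_scale(co))$values
  agreement <- sum(sign(ds$residue_weights) == sign(pl - mean(pl)))
  expect_gte(agreement, 16)
  # and the derived scale correlates strongly with the planted one
  expect_gte(abs(pearson_r(ds$residue_weights, pl)), 0.8)
})

test_that("coef/print/summary/plot methods work on a derived scale", {
  co <- tiny_corpus(n = 6, seed = 19)
  ds <- derive_scale(co$seqs, co$labels, k = 2, repeats = 2, seed = 1)
  cf <- coef(ds)
  expect_length(cf, 22L)
  expect_named(cf, c(AA20, "charge", "bias"))
  expect_output(print(ds), "Derived hydropathy scale")
  expect_output(print(summary(ds)), "Pooled held-out")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(ds); grDevices::dev.off()
  expect_true(file.exists(f))
  s <- as_aa_scale(ds)
  expect_s3_class(s, "aa_scale")
  expect_identical(s$values, ds$residue_weights)
})

test_that("whole-protein boundary refit averages folds and classifies held out", {
  co <- tiny_corpus(n = 12, seed = 29)
  ds <- derive_scale(co$seqs, co$labels, k = 3, repeats = 1, seed = 7)
  bd <- refit_whole_protein_boundary(ds, co$seqs, co$labels, k = 3, seed = 7)
  pf <- attr(bd, "per_fold")
  expect_equal(bd$a, mean(pf$a))
  expect_equal(bd$b, mean(pf$b))
  m <- attr(bd, "heldout")
  expect_s3_class(m, "metrics_report")
  expect_gte(m$balanced_acc, 0.8)  # beta = 2 separates the classes well
  # slope positive: disordered class sits at low H / high R
  expect_gt(bd$a, 0)
  # k = 1 degenerate run equals a direct fit
  bd1 <- refit_whole_protein_boundary(ds, co$seqs, co$labels, k = 1)
  pts <- ch_points(co$seqs, prepare_scale(as_aa_scale(ds)),
                   labels = co$labels)
  direct <- fit_boundary(pts)
  expect_equal(bd1$a, direct$a)
  expect_equal(bd1$b, direct$b)
  # predict through the derived scale + boundary
  res <- predict(ds, co$seqs, boundary = bd)
  expect_named(res, c("id", "H", "R", "score", "predicted_label"))
  expect_error(predict(ds, co$seqs), "no boundary")
})
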