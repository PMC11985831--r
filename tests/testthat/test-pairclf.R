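test_that("a 40-gene panel yields exactly 780 pair features", {
  co <- default_cohort(seed = 1)
  F <- pair_features(co$expr, pyroptosis_panel())
  expect_equal(nrow(F), 780L)
  expect_equal(ncol(F), 132L)
  expect_true(all(unclass(F) %in% c(0L, 1L)))
})

test_that("the pair definition and tie rule are as documented", {
  expr <- matrix(c(5, 3,
                   3, 5,
                   4, 4), nrow = 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  F <- pair_features(expr, c("gA", "gB"))
  expect_equal(unname(unclass(F)[1, ]), c(1L, 0L, 0L))
  expect_identical(rownames(F), "gA>gB")
})

test_that("pair features are invariant to monotone transforms", {
  set.seed(2)
  expr <- matrix(rnorm(200), 10, 20,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  F1 <- pair_features(expr, rownames(expr))
  F2 <- pair_features(2^expr, rownames(expr))
  expect_identical(unclass(F1)[, ], unclass(F2)[, ])
})

test_that("missing and duplicate panel genes are rejected by name", {
  co <- default_cohort(seed = 1, n_c1 = 3, n_c2 = 3)
  expect_error(pair_features(co$expr, c("ELANE", "NOTHERE")), "NOTHERE")
  expect_error(pair_features(co$expr, c("ELANE", "ELANE")), "duplicate")
})

test_that("a perfectly separating feature dominates the forest", {
  set.seed(4)
  n <- 60
  y <- rep(c("C1", "C2"), each = n / 2)
  F <- matrix(rbinom(30 * n, 1, 0.5), 30, n,
              dimnames = list(paste0("p", 1:30), paste0("s", 1:n)))
  F[1, ] <- as.integer(y == "C2")
  m <- train_classifier(F, stats::setNames(y, colnames(F)),
                        n_trees = 200, seed = 1)
  expect_lte(m$oob_error, 0.05)
  imp <- m$importance
  expect_equal(imp$pair[which.max(imp$mean_decrease_accuracy)], "p1")
  expect_equal(imp$pair[which.max(imp$mean_decrease_gini)], "p1")

  # training samples are recovered exactly on a separable problem
  pr <- predict(m, F)
  expect_identical(pr$subtype, y)
})

test_that("a constant feature has importance within the permutation null", {
  set.seed(5)
  n <- 50
  y <- rep(c("C1", "C2"), each = n / 2)
  F <- matrix(rbinom(20 * n, 1, 0.5), 20, n,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:n)))
  F[1, ] <- as.integer(y == "C2")  # signal
  F[2, ] <- 0L                     # constant
  m <- train_classifier(F, stats::setNames(y, colnames(F)),
                        n_trees = 200, seed = 2)
  null_imp <- unlist(lapply(1:5, function(r) {
    set.seed(100 + r)
    yp <- sample(y)
    mp <- train_classifier(F, stats::setNames(yp, colnames(F)),
                           n_trees = 200, seed = r)
    mp$importance$mean_decrease_accuracy
  }))
  thresh <- stats::quantile(abs(null_imp), 0.95)
  expect_lte(abs(m$importance$mean_decrease_accuracy[2]), thresh)
})

test_that("training is deterministic for a fixed seed and has strong OOB AUC", {
  co <- default_cohort(seed = 3)
  F <- pair_features(co$expr, pyroptosis_panel())
  lab <- stats::setNames(co$truth$subtype, co$truth$sample_id)
  m1 <- train_classifier(F, lab, n_trees = 300, seed = 9)
  m2 <- train_classifier(F, lab, n_trees = 300, seed = 9)
  expect_identical(m1$oob_error, m2$oob_error)
  expect_identical(m1$importance, m2$importance)
  expect_identical(predict(m1, F)$score, predict(m2, F)$score)
  oob_auc <- pair_auc(m1$oob_votes[, "C2"], co$truth$subtype)
  expect_gte(oob_auc, 0.75)
  expect_lte(oob_auc, 1)
})

test_that("prediction demands the training pair set in order", {
  set.seed(6)
  F <- matrix(rbinom(60, 1, 0.5), 3, 20,
              dimnames = list(c("a>b", "a>c", "b>c"), paste0("s", 1:20)))
  y <- stats::setNames(rep(c("C1", "C2"), 10), colnames(F))
  F[1, ] <- as.integer(y == "C2")
  m <- train_classifier(F, y, n_trees = 100, seed = 1)
  expect_error(predict(m, F[c(2, 1, 3), ]), "reordered")
  expect_error(predict(m, F[1:2, ]), "missing")
})

test_that("flipping the informative features flips the predicted class", {
  # two informative features; all others absent
  n <- 40
  y <- rep(c("C1", "C2"), each = n / 2)
  F <- rbind(`f1` = as.integer(y == "C2"), `f2` = as.integer(y == "C2"))
  colnames(F) <- paste0("s", 1:n)
  m <- train_classifier(F, stats::setNames(y, colnames(F)),
                        n_trees = 100, seed = 3)
  flipped <- 1L - F
  colnames(flipped) <- colnames(F)
  pr <- predict(m, flipped)
  expect_identical(pr$subtype, ifelse(y == "C1", "C2", "C1"))
})

test_that("AUC follows the Mann-Whitney convention including ties", {
  labels <- c("C1", "C1", "C2", "C2")
  expect_equal(pair_auc(c(0.1, 0.2, 0.8, 0.9), labels), 1)
  expect_equal(pair_auc(c(0.9, 0.8, 0.2, 0.1), labels), 0)
  expect_equal(pair_auc(rep(0.5, 4), labels), 0.5)
  expect_error(pair_auc(1:3, c("C1", "C1", "C1")), "both classes")

  set.seed(7)
  for (rep in 1:10) {
    scores <- sample(seq(0, 1, 0.25), 8, replace = TRUE)  # forces ties
    labels <- sample(rep(c("C1", "C2"), 4))
    expect_equal(pair_auc(scores, labels),
                 auc_pairwise_oracle(scores, labels, "C2"))
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(50)
  labels <- sample(rep(c("C1", "C2"), 25))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("C1", "C2"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(pair_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("trained models transfer unchanged across monotone platforms", {
  co <- default_cohort(seed = 12, n_c1 = 20, n_c2 = 20)
  panel <- pyroptosis_panel()
  m <- train_classifier(pair_features(co$expr, panel), co$truth,
                        n_trees = 200, seed = 1)
  co2 <- default_cohort(seed = 13, n_c1 = 15, n_c2 = 15)
  shifted <- platform_shift(co2$expr,
                            platform_spec("monotone-nonlinear",
                                          gain = 2, curvature = 1.4))
  p_plain <- predict(m, pair_features(co2$expr, panel))
  p_shift <- predict(m, pair_features(shifted, panel))
  expect_identical(p_plain$score, p_shift$score)
  expect_identical(p_plain$subtype, p_shift$subtype)
})
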