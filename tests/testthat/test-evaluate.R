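test_that("kappa and balanced accuracy reproduce the worked confusion matrix", {
  perfect <- matrix(c(50, 0, 0, 50), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(kappa_statistic(perfect), 1)
  expect_equal(balanced_accuracy(perfect), 1)

  chance <- matrix(25, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(kappa_statistic(chance), 0)

  worked <- matrix(c(40, 20, 10, 30), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(kappa_statistic(worked), 0.4)      # Po 0.7, Pe 0.5
  expect_equal(balanced_accuracy(worked), 0.7)    # (0.8 + 0.6)/2
  expect_equal(specificity_macro(worked), 0.7)    # symmetric here

  # constant predictor on balanced 2-class truth
  const <- matrix(c(50, 50, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(balanced_accuracy(const), 0.5)
  degenerate <- matrix(c(10, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(k <- kappa_statistic(degenerate), "Pe = 1")
  expect_equal(k, 0)
})

test_that("kappa and balanced accuracy match reference implementations on 1000 matrices", {
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    cm <- random_confusion(k, seed = i)
    if (sum(cm) == 0) next
    # independent references: e1071's classAgreement kappa and a direct
    # per-class recall average computed from first principles
    ref_kappa <- e1071::classAgreement(cm)$kappa
    rs <- rowSums(cm)
    ref_ba <- mean(ifelse(rs > 0, diag(cm) / rs, 0))
    if (is.finite(ref_kappa))
      expect_equal(kappa_statistic(cm), ref_kappa, tolerance = 1e-10)
    expect_equal(suppressWarnings(balanced_accuracy(cm)), ref_ba,
                 tolerance = 1e-10)
  }
})

test_that("kappa is 1 exactly when the off-diagonal mass vanishes", {
  for (i in 1:50) {
    cm <- random_confusion(3, seed = 1000 + i)
    diag_only <- sum(cm) - sum(diag(cm)) == 0
    expect_identical(isTRUE(all.equal(kappa_statistic(cm), 1)), diag_only)
  }
})

test_that("weighted F1 and one-vs-rest AUC behave at the extremes", {
  truth <- factor(rep(c("a", "b", "c"), c(5, 3, 2)))
  expect_equal(f1_weighted(truth, truth), 1)

  set.seed(1)
  scores <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  perfect <- 1 * outer(as.character(truth), c("a", "b", "c"), "==")
  colnames(perfect) <- c("a", "b", "c")
  expect_equal(auc_weighted(truth, perfect), 1)
  expect_equal(auc_weighted(truth, matrix(0.5, 10, 3,
               dimnames = list(NULL, c("a", "b", "c")))), 0.5)

  # absent class skipped with renormalized weights
  truth2 <- factor(rep(c("a", "b"), 5), levels = c("a", "b", "c"))
  expect_warning(auc <- auc_weighted(truth2, scores), "absent")
  expect_true(auc >= 0 && auc <= 1)
})

test_that("AUC agrees with pROC on random binary scores", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:20) {
    truth <- factor(sample(c("a", "b"), 40, replace = TRUE))
    s <- runif(40)
    scores <- cbind(a = s, b = 1 - s)
    ref_a <- as.numeric(pROC::auc(pROC::roc(truth == "a", s, quiet = TRUE,
                                            direction = "<")))
    ref_b <- as.numeric(pROC::auc(pROC::roc(truth == "b", 1 - s, quiet = TRUE,
                                            direction = "<")))
    w <- table(truth) / length(truth)
    expect_equal(auc_weighted(truth, scores),
                 ref_a * w[["a"]] + ref_b * w[["b"]], tolerance = 1e-10)
  }
})

test_that("Evalue rewards high means and penalizes spread", {
  # mean kappa 0 gives 0 regardless of spread
  expect_equal(evalue(c(-0.1, 0.1), c(0.5, 0.7)), 0)

  # means 0.8/0.7 with SDs 0.01/0.01: -100 * 0.56 * ln(1e-4)
  d <- 0.01 / sqrt(2)
  ev <- evalue(c(0.8 - d, 0.8 + d), c(0.7 - d, 0.7 + d))
  expect_equal(ev, -100 * 0.8 * 0.7 * log(1e-4), tolerance = 1e-8)
  expect_equal(ev, 515.78, tolerance = 1e-2)

  # identical repeats hit the eps clamp and stay finite
  ev0 <- evalue(c(0.8, 0.8), c(0.7, 0.7))
  expect_true(is.finite(ev0))
  expect_equal(ev0, -100 * 0.8 * 0.7 * log(1e-12))

  # monotone decreasing in the SD product; halving both SDs increases it
  sds <- c(0.08, 0.04, 0.02, 0.01)
  evs <- vapply(sds, function(s) {
    dd <- s / sqrt(2)
    evalue(c(0.8 - dd, 0.8 + dd), c(0.7 - dd, 0.7 + dd))
  }, numeric(1))
  expect_true(all(diff(evs) > 0))
})

test_that("metric sets aggregate into means, SDs and a recomputable Evalue", {
  truth <- factor(rep(c("a", "b"), each = 10))
  pred1 <- truth
  pred2 <- factor(c(rep("a", 9), "b", rep("b", 8), "a", "a"),
                  levels = c("a", "b"))
  m1 <- metric_set(truth, pred1, class_order = c("a", "b"))
  m2 <- metric_set(truth, pred2, class_order = c("a", "b"))
  agg <- aggregate_repeats(list(m1, m2))
  expect_equal(agg$mean[["kappa"]], mean(c(m1$kappa, m2$kappa)))
  expect_equal(agg$evalue,
               evalue(agg$per_repeat$kappa, agg$per_repeat$balanced_accuracy))
})
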