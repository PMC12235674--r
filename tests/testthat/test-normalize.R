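test_that("log transform maps the textbook values and rejects negatives", {
  x <- make_expr(matrix(c(0, 3, 1023), 3, 1))
  out <- log_transform(x)
  expect_equal(as.numeric(unclass(out)), c(0, 2, 10))
  expect_identical(attr(out, "scale"), "log")
  expect_error(log_transform(make_expr(matrix(-1, 1, 1))), "negative")
})

test_that("z-score centres by population SD and zeroes constant rows", {
  x <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5)))
  out <- unclass(zscore(x))
  expect_equal(out[1, ], c(s1 = -1.2247, s2 = 0, s3 = 1.2247), tolerance = 1e-4)
  expect_equal(unname(out[2, ]), c(0, 0, 0))
  set.seed(1)
  r <- unclass(zscore(random_expr(20, 7)))
  expect_true(all(abs(rowMeans(r)) < 1e-12))
  expect_equal(unname(sqrt(rowMeans(r^2))), rep(1, 20))
})

test_that("normal scores invert percentiles through the standard normal", {
  x <- make_expr(matrix(c(10, 20, 30), 1, 3))
  expect_equal(as.numeric(unclass(normal_scores(x))),
               qnorm(c(0.25, 0.5, 0.75)))
  tie <- make_expr(matrix(c(7, 7), 1, 2))
  expect_equal(as.numeric(unclass(normal_scores(tie))), c(0, 0))
  # monotone input rows stay monotone
  r <- random_expr(10, 8, seed = 5)
  out <- unclass(normal_scores(r))
  v <- unclass(r)
  for (i in 1:10) expect_identical(order(out[i, ]), order(v[i, ]))
})

test_that("NPN equals normal scores for the normal target, percentiles for uniform", {
  r <- random_expr(6, 5, seed = 9)
  expect_identical(unclass(npn(r, "normal")), unclass(normal_scores(r)))
  x <- make_expr(matrix(c(10, 20, 30), 1, 3))
  expect_equal(as.numeric(unclass(npn(x, "uniform"))), c(0.25, 0.5, 0.75))
  const <- make_expr(matrix(4, 1, 3))
  expect_equal(as.numeric(unclass(npn(const, "uniform"))), rep(0.5, 3))
  expect_error(npn(x, "cauchy"))
})

test_that("quantile normalization equalizes columns via rank-position means", {
  m <- make_expr(matrix(c(2, 4, 6, 1, 3, 5), 3, 2))
  out <- unclass(quantile_normalize(m))
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

  single <- random_expr(5, 1, seed = 2)
  expect_equal(unclass(quantile_normalize(single)), unclass(single))

  ident <- make_expr(cbind(c(3, 1, 2), c(3, 1, 2)))
  expect_equal(unclass(quantile_normalize(ident)), unclass(ident))

  # postcondition: identical value multisets across columns
  r <- random_expr(40, 6, seed = 3)
  q <- unclass(quantile_normalize(r))
  for (j in 2:6) expect_equal(sort(q[, j]), sort(q[, 1]), tolerance = 1e-12,
                              ignore_attr = TRUE)
})

test_that("quantile normalization agrees with limma's implementation", {
  skip_if_not_installed("limma")
  r <- random_expr(60, 5, seed = 11)
  mine <- unclass(quantile_normalize(r))
  ref <- limma::normalizeQuantiles(unclass(r), ties = TRUE)
  expect_equal(mine, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reference target fitting sorts and averages the reference rows", {
  toy <- make_expr(matrix(c(2, 4, 6, 1, 3, 5), 3, 2))
  fit <- fit_reference_target(toy, rownames(toy))
  expect_equal(fit$target, c(1.5, 3.5, 5.5))
  expect_false(is.unsorted(fit$target))

  one <- fit_reference_target(toy, "g2")
  expect_equal(one$target, mean(c(4, 3)))

  same <- make_expr(cbind(c(9, 2, 5), c(9, 2, 5)))
  expect_equal(fit_reference_target(same, rownames(same))$target, c(2, 5, 9))
  expect_error(fit_reference_target(toy, character(0)), "empty reference")
  expect_error(fit_reference_target(toy, "nope"), "nope")
})

test_that("RQN percentile-maps onto the reference quantile function", {
  # G = 4, m = 2, target (0, 10): u = (.125,.375,.625,.875) against grid
  # (.25,.75) -> clamped/interpolated to (0, 2.5, 7.5, 10) in rank order
  x <- make_expr(matrix(c(5, 1, 9, 3), 4, 1))
  fit <- structure(list(target = c(0, 10)), class = "fitted_normalizer")
  out <- as.numeric(unclass(apply_rqn(x, fit)))
  expect_equal(out, c(7.5, 0, 10, 2.5))   # ranks of (5,1,9,3) are (3,1,4,2)

  expect_error(apply_rqn(x, structure(list(target = 1),
                                      class = "fitted_normalizer")), "at least 2")

  # reference = all genes with G = m reduces exactly to QN
  r <- random_expr(30, 4, seed = 13)
  fit_all <- fit_reference_target(r, rownames(r))
  expect_equal(unclass(apply_rqn(r, fit_all)),
               unclass(quantile_normalize(r)), tolerance = 1e-10)

  # rank-only dependence: columns with identical rank order map identically
  a <- c(1, 5, 2, 8); b <- rank(a) * 100
  both <- make_expr(cbind(a, b))
  fit2 <- fit_reference_target(random_expr(10, 2, seed = 21),
                               sprintf("g%d", 1:10))
  outs <- unclass(apply_rqn(both, fit2))
  expect_equal(unname(outs[, 1]), unname(outs[, 2]))
  # and the reference-mapping alias shares the machinery
  expect_identical(unclass(apply_npn_reference(both, fit2)), outs)
})

test_that("NICG zeroes each sample's reference-gene mean in log space", {
  x <- make_expr(matrix(rnorm(40, 8), 8, 5), scale = "log")
  ref <- sprintf("g%d", 1:3)
  out <- nicg_scale(x, ref)
  expect_true(all(abs(colMeans(unclass(out)[ref, ])) < 1e-12))
  allref <- nicg_scale(x, rownames(x))
  expect_true(all(abs(colMeans(unclass(allref))) < 1e-12))
  expect_error(nicg_scale(make_expr(matrix(1, 2, 2)), "g1"), "log-scale")
})

test_that("composite dispatch chains the elementary transforms", {
  zeros <- make_expr(matrix(0, 4, 3))
  expect_equal(unclass(normalize_expression(zeros, "LOG")),
               matrix(0, 4, 3), ignore_attr = TRUE)

  r <- random_expr(30, 6, seed = 17)
  ref <- sprintf("g%d", 21:30)
  z <- unclass(normalize_expression(r, "LOG_RQN_Z", reference_genes = ref))
  expect_true(all(abs(rowMeans(z)) < 1e-12))

  lrqn_all <- normalize_expression(r, "LOG_RQN", reference_genes = rownames(r))
  log_qn <- quantile_normalize(log_transform(r))
  expect_equal(unclass(lrqn_all), unclass(log_qn), tolerance = 1e-10)

  expect_identical(unclass(normalize_expression(r, "RAW")), unclass(r))
  expect_error(normalize_expression(r, "LOG_RQN"), "reference")
  expect_error(normalize_expression(r, "SPECIAL"), "unknown")
})

test_that("every scheme preserves the ordering of strictly distinct values", {
  r <- random_expr(25, 8, seed = 23)
  ref <- sprintf("g%d", 16:25)
  within_gene <- c("Z", "NST", "NPN")
  within_sample <- c("QN", "LOG_RQN")
  for (m in within_gene) {
    out <- unclass(normalize_expression(r, m, reference_genes = ref))
    for (i in 1:25) expect_identical(order(out[i, ]), order(unclass(r)[i, ]))
  }
  for (m in within_sample) {
    out <- unclass(normalize_expression(r, m, reference_genes = ref))
    for (j in 1:8) expect_identical(order(out[, j]), order(unclass(r)[, j]))
  }
  # NICG is a per-sample shift, hence also within-sample order preserving
  nic <- unclass(nicg_scale(log_transform(r), ref))
  for (j in 1:8) expect_identical(order(nic[, j]), order(unclass(r)[, j]))
})

test_that("reference quantile normalization shrinks the cross-platform gap", {
  sim <- small_sim(n_genes = 200, n_deg = 20,
                   class_sizes = c(A = 25, B = 25, C = 25), seed = 29)
  shared <- sim$truth$shared_ids
  a <- sim$platform_a
  b <- sim$platform_b[, shared]
  ks_gene <- function(m1, m2) {
    mean(vapply(seq_len(nrow(m1)), function(i)
      suppressWarnings(stats::ks.test(m1[i, ], m2[i, ])$statistic), numeric(1)))
  }
  before <- ks_gene(unclass(a), unclass(b))
  ref <- sim$truth$ndeg_gene_ids
  # the reference target fitted on one platform is shared with the other,
  # so both are mapped onto a common reference distribution
  fitted <- fit_reference_target(log_transform(sim$platform_b), ref)
  na <- unclass(normalize_expression(a, "LOG_RQN", fitted = fitted))
  nb <- unclass(normalize_expression(sim$platform_b, "LOG_RQN",
                                     fitted = fitted))[, shared]
  after <- ks_gene(na, nb)
  expect_lt(after, before)
})
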