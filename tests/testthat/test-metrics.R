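test_that("perfectly ranked scores give AUC 1, flat scores give 0.5", {
  truth <- c(1L, 2L, 3L, 1L, 2L, 3L)
  perfect <- matrix(0.1, 6, 3)
  perfect[cbind(seq_along(truth), truth)] <- 0.8
  expect_equal(auc_micro(perfect, truth), 1)
  expect_equal(auc_macro(perfect, truth), 1)
  flat <- matrix(1 / 3, 6, 3)
  expect_equal(auc_micro(flat, truth), 0.5)
  expect_equal(auc_macro(flat, truth), 0.5)
})

test_that("micro-AUC equals the pairwise-ranking oracle on random matrices", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(6:12, 1)
    sm <- random_score_matrix(n, 3)
    truth <- sample(1:3, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pe <- pooled_expansion(sm, truth)
    expect_equal(auc_micro(sm, truth), pairwise_auc(pe$scores, pe$positive),
                 tolerance = 1e-9)
  }
})

test_that("micro-AUC handles heavy score ties as half-concordant pairs", {
  sm <- matrix(c(0.5, 0.5, 0.5, 0.3,
                 0.25, 0.25, 0.25, 0.4,
                 0.25, 0.25, 0.25, 0.3), 4, 3)
  truth <- c(1L, 1L, 2L, 3L)
  pe <- pooled_expansion(sm, truth)
  expect_equal(auc_micro(sm, truth), pairwise_auc(pe$scores, pe$positive),
               tolerance = 1e-9)
})

test_that("binary macro-AUC collapses to the plain binary AUC", {
  set.seed(52)
  s1 <- runif(20)
  sm <- cbind(s1, 1 - s1)
  truth <- sample(1:2, 20, replace = TRUE)
  oracle <- pairwise_auc(s1, truth == 1L)
  expect_equal(auc_macro(sm, truth, variant = "curve"), oracle,
               tolerance = 1e-9)
  expect_equal(auc_macro(sm, truth, variant = "mean"), oracle,
               tolerance = 1e-9)
  # micro pools cross pairs between the two one-vs-rest expansions, so it
  # matches the binary AUC only approximately on finite samples
  expect_lt(abs(auc_micro(sm, truth) - oracle), 0.1)
})

test_that("averaged-curve macro-AUC equals the mean of per-class AUCs", {
  set.seed(53)
  for (i in 1:10) {
    sm <- random_score_matrix(12, 3)
    truth <- if (i %% 2) rep(1:3, each = 4) else
      c(rep(1L, 6), rep(2L, 4), rep(3L, 2))  # also for unbalanced support
    per_class <- mean(vapply(1:3, function(k)
      pairwise_auc(sm[, k], truth == k), numeric(1)))
    expect_equal(auc_macro(sm, truth, variant = "curve"), per_class,
                 tolerance = 1e-9)
    expect_equal(auc_macro(sm, truth, variant = "mean"), per_class,
                 tolerance = 1e-9)
  }
})

test_that("both AUCs are invariant under strictly monotone score transforms", {
  set.seed(54)
  sm <- random_score_matrix(15, 3)
  truth <- sample(1:3, 15, replace = TRUE)
  truth[1:3] <- 1:3
  warp <- function(x) exp(3 * x) / 10
  expect_equal(auc_micro(sm, truth), auc_micro(warp(sm), truth),
               tolerance = 1e-12)
  expect_equal(auc_macro(sm, truth), auc_macro(warp(sm), truth),
               tolerance = 1e-12)
})

test_that("micro-AUC concentrates at chance level under permuted truth", {
  set.seed(55)
  n <- 500
  sm <- random_score_matrix(n, 3)
  truth <- sample(rep(1:3, length.out = n))
  expect_lt(abs(auc_micro(sm, truth) - 0.5), 0.05)
})

test_that("degenerate AUC inputs raise informative errors", {
  sm <- random_score_matrix(6, 3)
  expect_error(auc_macro(sm, rep(1L, 6)), "absent")
  expect_error(auc_micro(sm, c(0L, 1L, 2L, 1L, 1L, 1L)), "truth")
})

test_that("confusion counts match a hand-counted binary grid", {
  # 4x4 toy with epithelium = 2: tp=4, fp=2, fn=2, tn=8 for class 2
  truth <- matrix(1L, 4, 4)
  truth[1, ] <- 2L
  truth[2, 1:2] <- 2L
  pred <- matrix(1L, 4, 4)
  pred[1, ] <- 2L
  pred[3, 3:4] <- 2L
  cc <- confusion_counts(pred, truth, 2L)
  row2 <- cc[cc$class == 2L, ]
  expect_identical(c(row2$tp, row2$fp, row2$fn, row2$tn), c(4L, 2L, 2L, 8L))
  expect_true(all(rowSums(cc[, c("tp", "fp", "fn", "tn")]) == 16L))
})

test_that("confusion is exact on agreement and antisymmetric in pred/truth", {
  set.seed(56)
  m <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
  cc <- confusion_counts(m, m, 3L)
  expect_true(all(cc$fp == 0L) && all(cc$fn == 0L))
  m2 <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
  ab <- confusion_counts(m, m2, 3L)
  ba <- confusion_counts(m2, m, 3L)
  expect_identical(ab$fp, ba$fn)
  expect_identical(ab$fn, ba$fp)
  expect_error(confusion_counts(m, m2[1:5, 1:5], 3L), "shape")
  expect_error(confusion_counts(m - 1L, m2, 3L), "range")
})

test_that("segmentation suite matches direct substitution on the toy counts", {
  cc <- structure(data.frame(class = 1L, tp = 4L, fp = 2L, fn = 2L, tn = 8L),
                  class = c("confusion_counts", "data.frame"))
  s <- segmentation_suite(cc)
  expect_equal(s$per_class$iou, 0.5)
  expect_equal(s$per_class$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(s$per_class$acc, 0.75)
  expect_equal(s$per_class$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(s$per_class$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(s$per_class$specificity, 0.8)
  expect_equal(s$miou, 0.5)
})

test_that("identical masks score 1 on every metric", {
  set.seed(57)
  m <- matrix(sample(1:2, 64, replace = TRUE), 8, 8)
  s <- segmentation_suite(confusion_counts(m, m, 2L))
  expect_true(all(abs(as.matrix(s$per_class[, -1]) - 1) < 1e-12))
  expect_equal(s$miou, 1)
})

test_that("F1 obeys the algebraic identity 2*IOU/(1+IOU) and ranges hold", {
  set.seed(58)
  for (i in 1:20) {
    pred <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
    truth <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
    s <- segmentation_suite(confusion_counts(pred, truth, 3L))
    ok <- !is.na(s$per_class$iou)
    expect_equal(s$per_class$f1[ok],
                 2 * s$per_class$iou[ok] / (1 + s$per_class$iou[ok]),
                 tolerance = 1e-12)
    vals <- as.matrix(s$per_class[, -1])
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
    expect_lte(s$miou, max(s$per_class$iou, na.rm = TRUE))
    expect_gte(s$miou, min(s$per_class$iou, na.rm = TRUE))
  }
})

test_that("zero-denominator metrics are undefined with a warning, not zero", {
  pred <- matrix(1L, 4, 4)
  truth <- matrix(1L, 4, 4)
  cc <- confusion_counts(pred, truth, 2L)
  w <- capture_warnings(s <- segmentation_suite(cc))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(s$per_class$precision[s$per_class$class == 2L]))
  expect_equal(s$miou, 1)  # class-2 IOU (0/0) excluded from the mean
})

test_that("Cohen's kappa matches the hand-computed 2x2 oracle", {
  # agreement table a=20 (yes/yes), b=5 (yes/no), c=10 (no/yes), d=15:
  # p_o = 0.7, p_e = 0.5*0.6 + 0.5*0.4 = 0.5, kappa = 0.4
  a <- c(rep("y", 25), rep("n", 25))
  b <- c(rep("y", 20), rep("n", 5), rep("y", 10), rep("n", 15))
  expect_equal(cohen_kappa(a, b), 0.4, tolerance = 1e-12)
})

test_that("kappa is 1 on identical lists and near 0 for independent ones", {
  r <- sample(c("I", "II", "III"), 60, replace = TRUE)
  expect_equal(cohen_kappa(r, r), 1)
  set.seed(59)
  a <- sample(1:3, 4000, replace = TRUE)
  b <- sample(1:3, 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  expect_equal(cohen_kappa(rep("x", 5), rep("x", 5)), 1)
  expect_error(cohen_kappa(1:3, 1:4), "equal")
})

test_that("fold aggregation reports mean and population sigma", {
  one <- aggregate_folds(list(c(auc = 0.9)))
  expect_equal(one$sigma, 0)
  five <- aggregate_folds(rep(list(c(auc = 0.9)), 5))
  expect_equal(five$mean, 0.9)
  expect_equal(five$sigma, 0)
  two <- aggregate_folds(list(c(auc = 0.8), c(auc = 1.0)))
  expect_equal(two$mean, 0.9)
  expect_equal(two$sigma, 0.1)  # population form, not 0.1414
  expect_error(aggregate_folds(list(c(a = 1), c(b = 1))), "inconsistent")
})
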