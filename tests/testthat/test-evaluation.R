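test_that("confusion counts match direct enumeration", {
  pred <- c(rep(1, 10), rep(0, 90))
  expect_equal(confusion(pred, pred),
               c(TP = 10, FP = 0, FN = 0, TN = 90))
  expect_equal(confusion(rep(0, 5), c(1, 1, 0, 0, 0))[c("TP", "FP")],
               c(TP = 0, FP = 0))
  withr::with_seed(4, {
    for (i in 1:5) {
      p <- rbinom(50, 1, 0.4)
      t <- rbinom(50, 1, 0.3)
      brute <- c(TP = 0, FP = 0, FN = 0, TN = 0)
      for (j in 1:50) {
        key <- if (p[j] == 1 && t[j] == 1) "TP"
        else if (p[j] == 1) "FP"
        else if (t[j] == 1) "FN"
        else "TN"
        brute[key] <- brute[key] + 1
      }
      expect_equal(confusion(p, t), brute)
    }
  })
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "lengths")
  expect_error(confusion(c(0, 2), c(0, 1)), "binary")
})

test_that("precision/recall/F1 follow the formulas with zero conventions", {
  expect_equal(prf1(8, 2, 2),
               c(precision = 0.8, recall = 0.8, f1 = 0.8))
  expect_equal(prf1(10, 0, 0), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(prf1(0, 0, 5), c(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf1(0, 3, 0)[["f1"]], 0)
  # F1 is invariant to the TN count by construction (TN never enters)
  cm1 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  cm2 <- confusion(c(1, 1, 0, 0, 0, 0), c(1, 0, 1, 0, 0, 0))
  expect_equal(prf1(cm1["TP"], cm1["FP"], cm1["FN"]),
               prf1(cm2["TP"], cm2["FP"], cm2["FN"]))
})

test_that("PR curves sweep thresholds with grouped ties", {
  # perfect ranking: precision 1 everywhere
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  truth <- c(1, 1, 1, 0, 0)
  curve <- pr_curve(scores, truth)
  expect_true(all(curve$precision[curve$recall <= 1 &
                                    curve$threshold >= 0.7] == 1))
  expect_true(all(diff(curve$recall) >= 0))
  # inverted ranking: precision at full recall is p/n
  inv <- pr_curve(rev(scores), truth)
  expect_equal(inv$precision[inv$recall == 1][1], 3 / 5)
  # ties grouped at one threshold
  tied <- pr_curve(c(0.5, 0.5, 0.3), c(1, 0, 0))
  expect_equal(nrow(tied), 2)
  expect_equal(tied$precision[1], 0.5)
  expect_error(pr_curve(scores, rep(0, 5)), "no positive")
})

test_that("average precision matches hand enumeration and brute force", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 1, 1)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2)
  withr::with_seed(9, {
    for (i in 1:10) {
      scores <- round(runif(20), 2) # some ties
      truth <- rbinom(20, 1, 0.4)
      if (sum(truth) == 0) truth[1] <- 1
      expect_equal(average_precision(scores, truth),
                   brute_force_ap(scores, truth), tolerance = 1e-12)
    }
  })
  # trapezoidal variant stays within [0, 1] and close to the step form
  s <- c(0.9, 0.7, 0.5, 0.3)
  t <- c(1, 0, 1, 0)
  expect_lte(average_precision(s, t, method = "trapezoid"), 1)
})

test_that("mAP is the arithmetic mean of run APs", {
  expect_equal(mean_ap(0.7), 0.7)
  expect_equal(mean_ap(c(1, 0.5)), 0.75)
  expect_equal(mean_ap(rep(0.9, 10)), 0.9)
  expect_equal(mean_ap(c(0.8, NA)), 0.8)
  expect_error(mean_ap(numeric(0)), "no AP")
})

test_that("the harness reports per-repeat runs and is reproducible", {
  p <- small_params(seed = 22)
  train_pairs <- generate_groundtruth_pack(p, 8, seed = 22)
  rep1 <- compare_algorithms(
    train_pairs, algorithms = "rf", k = 4, n_repeats = 10, seed = 5,
    sp_params = list(n_superpixels = 60)
  )
  val <- rep1$runs[rep1$runs$split == "validation", ]
  # 10 repeats x 4 folds
  expect_equal(nrow(val), 40)
  expect_equal(length(unique(val$rep)), 10)
  # runtimes are recorded (but never asserted against any bound)
  expect_true(all(is.finite(val$train_time)))
  rep2 <- compare_algorithms(
    train_pairs, algorithms = "rf", k = 4, n_repeats = 10, seed = 5,
    sp_params = list(n_superpixels = 60)
  )
  expect_identical(rep1$runs$f1, rep2$runs$f1)
  # single algorithm, single repeat reduces to one cross-validation
  rep3 <- compare_algorithms(
    train_pairs, algorithms = "rf", k = 4, n_repeats = 1, seed = 5,
    sp_params = list(n_superpixels = 60)
  )
  expect_equal(nrow(rep3$runs), 4)
})

test_that("a colour-shifted test split never beats validation", {
  p <- small_params(seed = 23)
  train_pairs <- generate_groundtruth_pack(p, 10, seed = 23)
  test_pairs <- generate_groundtruth_pack(
    p, 8, variation = list(bg_blend = 0.4, illum = c(0.70, 0.95)),
    seed = 230
  )
  rep <- compare_algorithms(
    train_pairs, test_pairs, algorithms = c("rf", "svm"), k = 5,
    n_repeats = 2, seed = 7, sp_params = list(n_superpixels = 60)
  )
  s <- rep$summary
  for (alg in c("rf", "svm")) {
    expect_lte(s$mean_f1[s$algorithm == alg & s$split == "test"],
               s$mean_f1[s$algorithm == alg & s$split == "validation"])
  }
})
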