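test_that("superpixel labels follow the majority rule with ties background", {
  labels <- matrix(1L, 10, 10)
  labels[, 6:10] <- 2L
  sp <- manual_sp(labels)
  # superpixel 1 fully plant, 2 fully background
  mask <- matrix(0L, 10, 10)
  mask[, 1:5] <- 1L
  expect_equal(superpixel_labels(sp, mask), c(1L, 0L))
  # 60% overlap -> 1; exactly 50% -> 0
  mask60 <- matrix(0L, 10, 10)
  mask60[1:6, 1:5] <- 1L
  mask50 <- matrix(0L, 10, 10)
  mask50[1:5, 1:5] <- 1L
  expect_equal(superpixel_labels(sp, mask60), c(1L, 0L))
  expect_equal(superpixel_labels(sp, mask50), c(0L, 0L))
  expect_error(superpixel_labels(sp, matrix(2, 10, 10)), "binary")
  expect_error(superpixel_labels(sp, matrix(0L, 4, 4)), "shape")
})

test_that("assemble concatenates features and labels across images", {
  p <- small_params(seed = 12)
  pack <- generate_groundtruth_pack(p, 2, seed = 12)
  one <- assemble(pack[1], sp_params = list(n_superpixels = 60))
  two <- assemble(pack, sp_params = list(n_superpixels = 60))
  expect_equal(nrow(two$x), length(two$y))
  expect_equal(nrow(two$provenance), length(two$y))
  expect_equal(sum(two$provenance$image == 1), length(one$y))
  expect_error(assemble(list()), "at least one")
  bad <- pack
  bad[[2]]$mask <- bad[[2]]$mask[1:10, 1:10]
  expect_error(assemble(bad), "pair 2")
})

test_that("an all-background pot yields all-zero labels", {
  p <- small_params(seed = 13)
  p$growth <- list(a0 = 0, amax = 1, rate = 0)
  pack <- generate_groundtruth_pack(p, 2, seed = 13)
  data <- assemble(pack, sp_params = list(n_superpixels = 60))
  expect_true(all(data$y == 0))
})

test_that("k-fold splits partition images without leakage", {
  prov <- data.frame(image = rep(1:10, each = 7), sp_id = 1:70)
  data <- structure(
    list(x = matrix(0, 70, 3), y = rep(0:1, 35), provenance = prov),
    class = "labeled_features"
  )
  splits <- kfold_splits(data, k = 5, seed = 3)
  expect_length(splits, 5)
  val_images <- lapply(splits, function(s) {
    unique(prov$image[s$val])
  })
  expect_true(all(lengths(val_images) == 2))
  expect_setequal(unlist(val_images), 1:10)
  expect_equal(sum(lengths(val_images)), 10) # pairwise disjoint
  for (s in splits) {
    expect_length(intersect(prov$image[s$train], prov$image[s$val]), 0)
    expect_setequal(c(s$train, s$val), 1:70)
  }
  expect_identical(splits, kfold_splits(data, k = 5, seed = 3))
  expect_false(identical(splits, kfold_splits(data, k = 5, seed = 4)))
  expect_error(kfold_splits(data, k = 11), "exceeds")
})

test_that("classifiers separate a linearly separable fixture perfectly", {
  fix <- separable_features(60, seed = 5)
  probe <- separable_features(30, seed = 6)
  for (alg in c("rf", "svm", "mlp")) {
    hp <- if (alg == "mlp") list(epochs = 60, hidden = c(32, 32)) else list()
    m <- train_classifier(fix$x, fix$y, algorithm = alg,
                          hyperparams = hp, seed = 1)
    pred <- classify(probe$x, m)
    cm <- confusion(pred$labels, probe$y)
    f1 <- prf1(cm["TP"], cm["FP"], cm["FN"])["f1"]
    expect_equal(unname(f1), 1.0)
  }
})

test_that("random forest defaults to 100 trees and seeded determinism", {
  fix <- separable_features(40, seed = 7)
  m <- train_classifier(fix$x, fix$y, algorithm = "rf", seed = 2)
  expect_equal(m$fit$ntree, 100)
  probe <- separable_features(20, seed = 8)
  m2 <- train_classifier(fix$x, fix$y, algorithm = "rf", seed = 2)
  expect_identical(classify(probe$x, m)$scores,
                   classify(probe$x, m2)$scores)
  expect_error(
    train_classifier(fix$x, rep(1L, nrow(fix$x)), algorithm = "rf"),
    "both classes"
  )
})

test_that("model selection takes the best mean F1 with rf-first tie-break", {
  mk <- function(alg, f1s) {
    list(model = structure(
      list(algorithm = alg, hyperparams = list(a = 1), seed = 1),
      class = "seg_model"
    ), fold_f1 = f1s)
  }
  best <- select_model(list(mk("svm", c(0.92, 0.92)),
                            mk("mlp", c(0.88, 0.88))))
  expect_equal(best$model$algorithm, "svm")
  expect_equal(best$mean_f1, 0.92)
  single <- mk("mlp", 0.5)
  expect_equal(select_model(list(single))$model$algorithm, "mlp")
  # exact tie between rf and svm -> rf
  tie <- select_model(list(mk("svm", c(0.9, 0.9)), mk("rf", c(0.9, 0.9))))
  expect_equal(tie$model$algorithm, "rf")
  expect_error(select_model(list()), "no candidates")
})

test_that("models round-trip through disk with a JSON sidecar", {
  fix <- separable_features(30, seed = 9)
  m <- train_classifier(fix$x, fix$y, algorithm = "rf", seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  sidecar <- save_model(m, path)
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$algorithm, "rf")
  expect_equal(meta$seed, 3)
  m2 <- load_model(path)
  probe <- separable_features(10, seed = 10)
  expect_identical(classify(probe$x, m)$scores,
                   classify(probe$x, m2)$scores)
})

test_that("validation F1 is high on simulator data and drops under shift", {
  p <- small_params(seed = 14)
  pack <- generate_groundtruth_pack(p, 12, seed = 14)
  data <- assemble(pack, sp_params = list(n_superpixels = 80))
  cv <- cross_validate(data, "rf", k = 4, seed = 2)
  expect_gte(mean(cv$fold_f1), 0.95)
  shifted <- generate_groundtruth_pack(
    p, 8, variation = list(bg_blend = 0.4, illum = c(0.70, 0.95)),
    seed = 140
  )
  test_data <- assemble(shifted, sp_params = list(n_superpixels = 80))
  m <- train_classifier(data, algorithm = "rf", seed = 2)
  pred <- classify(test_data$x, m)
  cm <- confusion(pred$labels, test_data$y)
  test_f1 <- prf1(cm["TP"], cm["FP"], cm["FN"])["f1"]
  expect_lte(unname(test_f1), mean(cv$fold_f1))
})
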