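test_that("classification returns one label and score per superpixel", {
  fix <- separable_features(50, seed = 2)
  m <- train_classifier(fix$x, fix$y, algorithm = "rf", seed = 1)
  probe <- separable_features(350, seed = 3) # 700 rows
  pred <- classify(probe$x, m)
  expect_length(pred$labels, 700)
  expect_length(pred$scores, 700)
  expect_true(all(pred$labels %in% 0:1))
  # labels are exactly the 0.5-thresholded scores
  expect_identical(pred$labels, as.integer(pred$scores > 0.5))
  expect_error(classify(matrix(0, 5, 4), m), "3 columns")
})

test_that("masks rebuilt from labels resolve whole superpixels", {
  labels <- matrix(rep(1:4, each = 25), 10, 10)
  sp <- manual_sp(labels)
  full <- mask_from_labels(sp, rep(1L, 4))
  expect_true(all(full == 1))
  empty <- mask_from_labels(sp, rep(0L, 4))
  expect_true(all(empty == 0))
  some <- mask_from_labels(sp, c(1L, 0L, 1L, 0L))
  expect_equal(sum(some), sum(tabulate(labels, 4)[c(1, 3)]))
  expect_equal(attr(some, "stage"), "raw")
  expect_error(mask_from_labels(sp, c(1L, 0L)), "label count")
})

test_that("erosion shrinks squares by the structuring element", {
  m <- matrix(0L, 30, 30)
  m[6:25, 6:25] <- 1L # 20 x 20 square
  e <- erode_mask(m, radius = 1, iterations = 1)
  expect_equal(sum(e), 18 * 18)
  expect_true(all(e[7:24, 7:24] == 1))
  # single pixel vanishes; empty stays empty; output subset of input
  single <- matrix(0L, 9, 9)
  single[5, 5] <- 1L
  expect_equal(sum(erode_mask(single)), 0)
  expect_equal(sum(erode_mask(matrix(0L, 5, 5))), 0)
  expect_true(all(e[m == 0] == 0))
})

test_that("only the centre component survives retention", {
  m <- matrix(0L, 40, 40)
  m[18:23, 18:23] <- 1L # centred blob
  m[1:4, 1:4] <- 1L # corner blob
  kept <- retain_center(m)
  expect_equal(sum(kept), 36)
  expect_true(all(kept[1:4, 1:4] == 0))
  expect_equal(attr(kept, "stage"), "center-retained")
  expect_equal(sum(retain_center(matrix(0L, 8, 8))), 0)
})

test_that("a larger edge intrusion is still removed: size is not the rule", {
  m <- matrix(0L, 60, 60)
  m[28:33, 28:33] <- 1L # small centre plant (36 px)
  m[1:60, 1:8] <- 1L # big blob entering from the left edge (480 px)
  kept <- retain_center(m)
  expect_equal(sum(kept), 36)
  expect_true(all(kept[, 1:8] == 0))
  # centre pixel background: nearest-centroid component wins
  m2 <- matrix(0L, 40, 40)
  m2[14:17, 14:17] <- 1L # near centre
  m2[1:10, 30:40] <- 1L # far corner, larger
  kept2 <- retain_center(m2)
  expect_equal(sum(kept2), 16)
})

test_that("segment_pot returns monotone stage areas and exact zero case", {
  p <- small_params(seed = 15)
  pack <- generate_groundtruth_pack(p, 10, seed = 15)
  data <- assemble(pack, sp_params = list(n_superpixels = 80))
  model <- train_classifier(data, algorithm = "rf", seed = 1)
  sp_par <- segment_params(n_superpixels = 80)
  for (q in pack[1:4]) {
    seg <- segment_pot(q$image, model, sp_par)
    a <- seg$stages$areas
    expect_lte(a[["final"]], a[["eroded"]])
    expect_lte(a[["eroded"]], a[["raw"]])
    expect_equal(seg$area, sum(seg$mask))
  }
  # no plant at all
  p0 <- small_params(seed = 16)
  p0$growth <- list(a0 = 0, amax = 1, rate = 0)
  bare <- generate_groundtruth_pack(p0, 1, seed = 16)[[1]]
  seg0 <- segment_pot(bare$image, model, sp_par)
  expect_equal(seg0$area, 0)
})

test_that("segmentation is deterministic and the raw mask is sp-resolved", {
  p <- small_params(seed = 17)
  q <- generate_groundtruth_pack(p, 1, seed = 17)[[1]]
  data <- assemble(generate_groundtruth_pack(p, 8, seed = 18),
                   sp_params = list(n_superpixels = 80))
  model <- train_classifier(data, algorithm = "rf", seed = 1)
  s1 <- segment_pot(q$image, model, segment_params(n_superpixels = 80))
  s2 <- segment_pot(q$image, model, segment_params(n_superpixels = 80))
  expect_identical(s1$mask, s2$mask)
  # raw mask area equals the summed pixel counts of plant superpixels
  lab <- to_lab(q$image)
  sp <- superpixels(lab, n_target = 80)
  pred <- classify(mean_features(lab, sp), model)
  raw <- mask_from_labels(sp, pred$labels)
  counts <- tabulate(sp$labels, sp$n)
  expect_equal(sum(raw), sum(counts[pred$labels == 1]))
  # every superpixel is all-in or all-out of the raw mask
  frac <- as.vector(rowsum(as.vector(raw), as.vector(sp$labels))) / counts
  expect_true(all(frac %in% c(0, 1)))
})

test_that("off-centre moss and intrusions are excluded from the final mask", {
  p <- small_params(seed = 19)
  q <- generate_groundtruth_pack(p, 1, seed = 19)[[1]]
  # paint a moss-free plant-coloured intruder blob at the image corner
  img <- q$image
  img[2:10, 2:10, 1] <- p$plant_rgb_mean[1]
  img[2:10, 2:10, 2] <- p$plant_rgb_mean[2]
  img[2:10, 2:10, 3] <- p$plant_rgb_mean[3]
  data <- assemble(generate_groundtruth_pack(p, 8, seed = 20),
                   sp_params = list(n_superpixels = 80))
  model <- train_classifier(data, algorithm = "rf", seed = 1)
  seg <- segment_pot(img, model, segment_params(n_superpixels = 80))
  expect_true(all(seg$mask[1:11, 1:11] == 0))
})

test_that("mask IoU behaves at the boundaries", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, b), 1 / 3)
  expect_equal(mask_iou(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
})
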