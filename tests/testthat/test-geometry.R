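test_that("target points sit on the marker grid lines", {
  geom <- tray_geometry(pot_w = 224, pot_h = 224)
  tp <- target_points(geom)
  expect_equal(tp$x, c(448, 1344, 448, 1344))
  expect_equal(tp$y, c(224, 224, 672, 672))
  unit <- target_points(tray_geometry(1, 1))
  expect_equal(unit$x, c(2, 6, 2, 6))
  expect_equal(unit$y, c(1, 1, 3, 3))
  # marker spans: 4 pot widths horizontally, 2 pot heights vertically
  for (pw in c(64, 100, 224)) {
    tp <- target_points(tray_geometry(pw, pw + 8))
    expect_equal(tp$x[2] - tp$x[1], 4 * pw)
    expect_equal(tp$y[3] - tp$y[1], 2 * (pw + 8))
  }
})

test_that("markers are found among sub-threshold distractors", {
  # four 18 px squares (324 px) plus three 10 px blobs (100 px, below the
  # 150 px area filter)
  img <- marker_fixture(distractors = cbind(
    c(100, 900, 1500), c(500, 100, 800), 10, 10
  ))
  m <- detect_markers(img)
  expect_s3_class(m, "marker_set")
  expect_equal(nrow(m), 4)
  tp <- target_points(tray_geometry())
  expect_lt(max(abs(m$x - tp$x)), 0.5)
  expect_lt(max(abs(m$y - tp$y)), 0.5)
})

test_that("an image without red pixels raises a detection error", {
  img <- flat_rgb(80, 120, c(0.3, 0.5, 0.3))
  err <- tryCatch(detect_markers(img), error = function(e) e)
  expect_s3_class(err, "marker_detection_error")
})

test_that("partial detections carry candidates and recovery fills roles", {
  geom <- tray_geometry()
  img <- marker_fixture(geom)
  # blank out the TL marker
  img[150:300, 350:550, 1] <- 0.42
  img[150:300, 350:550, 2] <- 0.31
  img[150:300, 350:550, 3] <- 0.20
  err <- tryCatch(detect_markers(img), error = function(e) e)
  expect_s3_class(err, "marker_detection_error")
  expect_equal(nrow(err$candidates), 3)
  prev <- marker_set(c(410, 1340, 450, 1345), c(250, 226, 670, 671))
  rec <- recover_missing_markers(err$candidates, prev = prev)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$x[rec$role == "TL"], 410)
  expect_equal(rec$y[rec$role == "TL"], 250)
  expect_equal(rec$provenance[rec$role == "TL"], "recovered")
  expect_true(all(rec$provenance[rec$role != "TL"] == "detected"))
})

test_that("recovery prefers the previous visit and is identity on full sets", {
  full <- marker_set(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_identical(recover_missing_markers(full), full)
  prev <- marker_set(c(10, 20, 30, 40), c(1, 1, 2, 2))
  nxt <- marker_set(c(11, 21, 31, 41), c(1, 1, 2, 2))
  rec <- recover_missing_markers(NULL, prev = prev, nxt = nxt)
  expect_equal(rec$x, prev$x)
  expect_error(recover_missing_markers(NULL), "neighbour")
})

test_that("homography solves identity, translation and composition", {
  tp <- target_points(tray_geometry())
  h_id <- estimate_homography(tp, tp)
  expect_equal(unclass(h_id), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  src <- marker_set(tp$x + 10, tp$y + 5)
  h_tr <- estimate_homography(src, tp)
  expect_equal(unclass(h_tr),
               matrix(c(1, 0, -10, 0, 1, -5, 0, 0, 1), 3, 3,
                      byrow = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
  # src = P(targets) => H is P^{-1} up to scale: H %*% P ~ lambda I
  p <- matrix(c(1.02, 0.03, 5, -0.01, 0.98, -7, 1e-5, -2e-5, 1), 3, 3,
              byrow = TRUE)
  src2 <- apply_homography(structure(p, class = "homography"),
                           cbind(tp$x, tp$y))
  h <- estimate_homography(marker_set(src2[, 1], src2[, 2]), tp)
  m <- unclass(h) %*% p
  m <- m / m[3, 3]
  expect_lt(max(abs(m - diag(3))), 1e-6)
})

test_that("collinear marker points are rejected", {
  src <- marker_set(c(0, 1, 2, 3), c(0, 1, 2, 3))
  dst <- target_points(tray_geometry())
  expect_error(estimate_homography(src, dst), "degenerate")
})

test_that("identity warp reproduces a canvas-sized image exactly", {
  geom <- tray_geometry(pot_w = 16, pot_h = 16, n_rows = 3, n_cols = 5)
  img <- array(runif(geom$canvas_h * geom$canvas_w * 3),
               dim = c(geom$canvas_h, geom$canvas_w, 3))
  h <- structure(diag(3), class = "homography")
  out <- warp_tray(img, h, geom)
  expect_equal(out, img, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("detect-estimate-warp round trip lands markers on targets", {
  geom <- tray_geometry()
  tp <- target_points(geom)
  residuals <- c()
  for (seed in 1:5) {
    g <- generate_tray(sim_params(seed = seed), day = 10, seed = seed)
    rect <- rectify_tray(g$image$image, geom)
    expect_equal(dim(rect$image)[1:2], c(geom$canvas_h, geom$canvas_w))
    m <- detect_markers(rect$image)
    residuals <- c(residuals,
                   sqrt((m$x - tp$x)^2 + (m$y - tp$y)^2))
  }
  expect_lt(max(residuals), 1.5)
})

test_that("pot crops tile the canvas without overlap", {
  geom <- tray_geometry(pot_w = 224, pot_h = 224)
  img <- array(runif(geom$canvas_h * geom$canvas_w * 3),
               dim = c(geom$canvas_h, geom$canvas_w, 3))
  crops <- crop_pots(img, geom)
  expect_length(crops, 32)
  expect_named(crops, sprintf("Pot%02d", 1:32))
  expect_true(all(vapply(crops, function(cr) {
    all(dim(cr) == c(224, 224, 3))
  }, logical(1))))
  expect_equal(sum(vapply(crops, length, numeric(1))), length(img))
  # reassembling the crops reproduces the canvas
  recon <- array(NA_real_, dim = dim(img))
  for (cr in crops) {
    r <- attr(cr, "row")
    cc <- attr(cr, "col")
    recon[(r * 224 + 1):((r + 1) * 224),
          (cc * 224 + 1):((cc + 1) * 224), ] <- cr
  }
  expect_equal(recon, img, ignore_attr = TRUE)
  # single-pot geometry: crop equals the image
  g1 <- tray_geometry(pot_w = 40, pot_h = 30, n_rows = 1, n_cols = 1)
  img1 <- array(runif(30 * 40 * 3), dim = c(30, 40, 3))
  expect_equal(crop_pots(img1, g1)[[1]], img1, ignore_attr = TRUE)
  expect_error(crop_pots(img1, geom), "mismatch")
})

test_that("raising the contour area threshold never raises candidate count", {
  img <- marker_fixture(distractors = cbind(
    c(100, 900, 1500, 300), c(500, 100, 800, 850), 10, 10
  ))
  # count area-filtered components directly on the red mask
  red <- img[, , 1] > 0.6 & img[, , 2] < 0.2
  lab <- phenotray:::.label_components(matrix(as.integer(red), nrow(red)),
                                       8L)
  st <- phenotray:::component_stats(lab)
  counts <- vapply(c(1, 50, 150, 400),
                   function(thr) sum(st$area >= thr), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
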