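# Shared fixture builders; everything is generated in code at test time.

# A superpixel_map built by hand from a label matrix.
manual_sp <- function(labels) {
  structure(list(labels = labels, n = max(labels)),
            class = "superpixel_map")
}

# Uniform-colour RGB array.
flat_rgb <- function(h, w, rgb) {
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}

# A soil-coloured canvas with four 18 px red marker squares at the
# geometry's target points, plus optional extra red blobs, with no
# noise: a minimal deterministic marker-detection fixture.
marker_fixture <- function(geom = tray_geometry(), side = 18,
                           distractors = NULL) {
  img <- flat_rgb(geom$canvas_h, geom$canvas_w, c(0.42, 0.31, 0.20))
  tp <- target_points(geom)
  half <- side / 2
  paint_square <- function(img, cx, cy, half_w, half_h) {
    rows <- max(1, ceiling(cy - half_h + 0.5)):floor(cy + half_h + 0.5)
    cols <- max(1, ceiling(cx - half_w + 0.5)):floor(cx + half_w + 0.5)
    img[rows, cols, 1] <- 0.85
    img[rows, cols, 2] <- 0.06
    img[rows, cols, 3] <- 0.06
    img
  }
  for (i in 1:4) {
    img <- paint_square(img, tp$x[i], tp$y[i], half, half)
  }
  if (!is.null(distractors)) {
    for (i in seq_len(nrow(distractors))) {
      img <- paint_square(img, distractors[i, 1], distractors[i, 2],
                          distractors[i, 3] / 2, distractors[i, 4] / 2)
    }
  }
  img
}

# Linearly separable two-cluster Lab-like features: "plant" around
# (40, -45, 40) and "soil" around (55, 12, 25).
separable_features <- function(n_per_class = 60, seed = 1) {
  withr::with_seed(seed, {
    plant <- cbind(rnorm(n_per_class, 40, 2), rnorm(n_per_class, -45, 2),
                   rnorm(n_per_class, 40, 2))
    soil <- cbind(rnorm(n_per_class, 55, 2), rnorm(n_per_class, 12, 2),
                  rnorm(n_per_class, 25, 2))
    list(x = rbind(plant, soil),
         y = rep(c(1L, 0L), each = n_per_class))
  })
}

# Small, fast simulation parameters: 64 px pots keep rendering cheap
# while preserving all scene elements.
small_params <- function(seed = 1, ...) {
  sim_params(pot_w_px = 64, pot_h_px = 64, frame_w = 640, frame_h = 360,
             marker_side_px = 14,
             growth = list(a0 = 20, amax = 900, rate = 0.3),
             seed = seed, ...)
}

# Independent brute-force average precision: explicit threshold sweep
# over descending unique scores, precision at each new recall level.
brute_force_ap <- function(scores, truth) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth == 1)
  prev_r <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(truth[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}
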