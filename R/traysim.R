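#' Simulation parameters for the synthetic tray generator
#'
#' Defines the scene the generator renders: a 4 x 8 grid of pots on a
#' soil-coloured tray with four red fiducial markers on the pot-grid
#' lines, green rosettes growing on a logistic curve, moss-like green
#' background noise, a horizontal illumination (shadow) ramp,
#' neighbour-leaf intrusion across pot boundaries, and a projective
#' camera distortion mapping the ideal tray plane into the acquired
#' frame.
#'
#' @param n_rows,n_cols Pot grid (default 4 x 8, i.e. 32 pots).
#' @param pot_w_px,pot_h_px Pot size in pixels in the ideal (rectified)
#'   scene; default 224 x 224.
#' @param marker_side_px Side of the red square markers (default 18 px,
#'   area 324 px, comfortably above the 150-px marker area filter).
#' @param frame_w,frame_h Size of the acquired camera frame (default
#'   1920 x 1080).
#' @param soil_rgb_mean,soil_rgb_std Soil background colour model (RGB in
#'   \[0, 1\]; per-pixel gaussian noise).
#' @param plant_rgb_mean,plant_rgb_std Rosette colour model.
#' @param moss_rgb_mean Moss blob colour (green hue, lower saturation and
#'   lightness than the plant).
#' @param moss_density Fraction of background area covered by moss blobs,
#'   in \[0, 1\].
#' @param shadow_strength Amplitude of the multiplicative horizontal
#'   luminance ramp, in \[0, 1\] (0 = flat illumination).
#' @param intrusion_prob Per-pot probability that a neighbour leaf crosses
#'   the pot boundary.
#' @param distortion Either `NULL` (a random in-frame projective
#'   distortion is sampled per tray from the seed), `"identity"` (the
#'   tray is centred in the frame without perspective), or an invertible
#'   3 x 3 matrix mapping ideal-scene coordinates to frame coordinates.
#' @param growth Logistic growth-curve parameters: `a0` initial area (px),
#'   `amax` asymptotic area (px), `rate` per day. Per-pot `amax` is
#'   jittered by up to +/-15 percent so pots differ.
#' @param seed Default seed used when the generating functions are called
#'   without one.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_rows = 4, n_cols = 8, pot_w_px = 224,
                       pot_h_px = 224, marker_side_px = 18,
                       frame_w = 1920, frame_h = 1080,
                       soil_rgb_mean = c(0.42, 0.31, 0.20),
                       soil_rgb_std = 0.035,
                       plant_rgb_mean = c(0.16, 0.52, 0.13),
                       plant_rgb_std = 0.04,
                       moss_rgb_mean = c(0.28, 0.38, 0.22),
                       moss_density = 0.02,
                       shadow_strength = 0.25,
                       intrusion_prob = 0.10,
                       distortion = NULL,
                       growth = list(a0 = 50, amax = 5000, rate = 0.3),
                       seed = 1L) {
  stopifnot(
    n_rows >= 1, n_cols >= 1, pot_w_px > 0, pot_h_px > 0,
    marker_side_px > 0, frame_w > 0, frame_h > 0,
    moss_density >= 0, moss_density <= 1,
    shadow_strength >= 0, shadow_strength <= 1,
    intrusion_prob >= 0, intrusion_prob <= 1,
    growth$a0 >= 0, growth$amax >= growth$a0
  )
  if (is.matrix(distortion)) {
    if (!all(dim(distortion) == 3) || abs(det(distortion)) < 1e-12) {
      stop("distortion must be an invertible 3 x 3 matrix")
    }
  } else if (!is.null(distortion) && !identical(distortion, "identity")) {
    stop("distortion must be NULL, \"identity\" or a 3 x 3 matrix")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      pot_w_px = as.integer(pot_w_px), pot_h_px = as.integer(pot_h_px),
      marker_side_px = as.integer(marker_side_px),
      frame_w = as.integer(frame_w), frame_h = as.integer(frame_h),
      soil_rgb_mean = soil_rgb_mean, soil_rgb_std = soil_rgb_std,
      plant_rgb_mean = plant_rgb_mean, plant_rgb_std = plant_rgb_std,
      moss_rgb_mean = moss_rgb_mean, moss_density = moss_density,
      shadow_strength = shadow_strength, intrusion_prob = intrusion_prob,
      distortion = distortion, growth = growth, seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

sim_geometry <- function(params) {
  tray_geometry(params$pot_w_px, params$pot_h_px, params$n_rows,
                params$n_cols)
}

#' Closed-form logistic growth curve
#'
#' `area(t) = amax * a0 * exp(rate * t) / (amax + a0 * (exp(rate * t) - 1))`,
#' the solution of logistic growth with initial area `a0`, carrying
#' capacity `amax` and intrinsic rate `rate` per day.
#'
#' @param day Time in days (numeric vector).
#' @param a0,amax,rate Curve parameters (areas in pixels, rate per day).
#' @return Area in pixels (continuous).
#' @export
logistic_area <- function(day, a0, amax, rate) {
  if (a0 <= 0) {
    return(rep(0, length(day)))
  }
  e <- exp(rate * day)
  amax * a0 * e / (amax + a0 * (e - 1))
}

# --- rosette geometry -------------------------------------------------------

# Per-pot leaf layout in unit scale: each rosette is the union of 4-12
# elliptical leaves anchored at the pot centre (one ellipse end touches the
# centre), so the union is star-shaped and grows monotonically under
# scaling. Depends only on (seed, pot index), never on the day, so a time
# series shows one plant growing.
rosette_geometry <- function(seed, pot_index) {
  with_seed(child_seed(seed, 1000L + pot_index), {
    n_leaves <- sample(4:12, 1)
    angles <- sort(
      (seq_len(n_leaves) - 1) / n_leaves * 2 * pi +
        stats::runif(n_leaves, -0.25, 0.25)
    )
    list(
      n_leaves = n_leaves,
      angles = angles,
      len = stats::runif(n_leaves, 0.65, 1.0),   # relative leaf length
      aspect = stats::runif(n_leaves, 0.45, 0.65), # width / length
      amax_jitter = stats::runif(1, 0.85, 1.15)
    )
  })
}

# Coverage raster (fraction of each pixel inside the rosette) in a
# h x w pot frame for leaves scaled so the longest leaf has length
# `scale` pixels. Uses 2 x 2 subsampling.
rosette_coverage <- function(geom_leaf, scale, h, w) {
  cov <- matrix(0, h, w)
  if (scale <= 0) {
    return(cov)
  }
  cx <- w / 2
  cy <- h / 2
  sub <- c(-0.25, 0.25)
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  acc <- numeric(h * w)
  for (dx in sub) {
    for (dy in sub) {
      x <- px + dx - cx
      y <- py + dy - cy
      inside <- rep(FALSE, h * w)
      for (i in seq_len(geom_leaf$n_leaves)) {
        len <- geom_leaf$len[i] * scale
        a <- len / 2
        b <- geom_leaf$aspect[i] * len / 2
        th <- geom_leaf$angles[i]
        ecx <- a * cos(th)
        ecy <- a * sin(th)
        u <- (x - ecx) * cos(th) + (y - ecy) * sin(th)
        v <- -(x - ecx) * sin(th) + (y - ecy) * cos(th)
        inside <- inside | (u * u / (a * a) + v * v / (b * b) <= 1)
      }
      acc <- acc + inside
    }
  }
  matrix(acc / 4, h, w)
}

# Exact-area rosette mask: scale the rosette so its continuous area matches
# `target_area`, then keep exactly round(target_area) pixels, ordered by
# coverage. The reported truth area is therefore the mask popcount.
rosette_mask <- function(geom_leaf, target_area, h, w) {
  k <- round(target_area)
  if (k <= 0) {
    return(matrix(FALSE, h, w))
  }
  # continuous area scales as scale^2; calibrate once per geometry
  ref_scale <- min(h, w) * 0.4
  ref_area <- sum(rosette_coverage(geom_leaf, ref_scale, h, w))
  if (ref_area <= 0) {
    return(matrix(FALSE, h, w))
  }
  scale <- ref_scale * sqrt(target_area / ref_area)
  scale <- min(scale, min(h, w) * 0.54) # keep the rosette inside the pot
  cov <- rosette_coverage(geom_leaf, scale, h, w)
  pos <- which(cov > 0)
  if (length(pos) < k) {
    # saturated at the pot boundary: take everything there is
    k <- length(pos)
  }
  keep <- pos[order(cov[pos], decreasing = TRUE)[seq_len(k)]]
  m <- matrix(FALSE, h, w)
  m[keep] <- TRUE
  m
}

# --- scene rendering --------------------------------------------------------

# Linear pixel indices (into an h x w matrix) covered by an ellipse.
ellipse_indices <- function(cx, cy, a, b, theta, h, w) {
  r0 <- max(1, floor(cy - a))
  r1 <- min(h, ceiling(cy + a))
  c0 <- max(1, floor(cx - a))
  c1 <- min(w, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) {
    return(integer(0))
  }
  cc <- rep(c0:c1, each = r1 - r0 + 1)
  rr <- rep(r0:r1, times = c1 - c0 + 1)
  x <- cc - 0.5 - cx
  y <- rr - 0.5 - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  inside <- u * u / (a * a) + v * v / (b * b) <= 1
  rr[inside] + (cc[inside] - 1L) * h
}

# Paint pixel sets onto a canvas in one pass per channel. `layers` is a
# list of list(idx, color, noise_sd); later layers overpaint earlier ones.
paint_layers <- function(canvas, layers) {
  if (length(layers) == 0) {
    return(canvas)
  }
  idx <- unlist(lapply(layers, `[[`, "idx"), use.names = FALSE)
  if (length(idx) == 0) {
    return(canvas)
  }
  hw <- dim(canvas)[1] * dim(canvas)[2]
  for (ch in 1:3) {
    vals <- unlist(lapply(layers, function(l) {
      clamp01(l$color[ch] + stats::rnorm(length(l$idx), 0, l$noise_sd))
    }), use.names = FALSE)
    canvas[idx + (ch - 1) * hw] <- vals
  }
  canvas
}

# Sample a random projective distortion mapping the ideal canvas into the
# acquired frame: the canvas corners go to their centred positions plus a
# uniform jitter. The jitter bound keeps all four markers (which are well
# inside the canvas) in-frame.
random_distortion <- function(params, max_jitter = 30) {
  geom <- sim_geometry(params)
  ox <- (params$frame_w - geom$canvas_w) / 2
  oy <- (params$frame_h - geom$canvas_h) / 2
  src <- cbind(
    c(0, geom$canvas_w, 0, geom$canvas_w),
    c(0, 0, geom$canvas_h, geom$canvas_h)
  )
  dst <- src + cbind(ox + stats::runif(4, -max_jitter, max_jitter),
                     oy + stats::runif(4, -max_jitter, max_jitter))
  unclass(estimate_homography(src, dst))
}

identity_distortion <- function(params) {
  geom <- sim_geometry(params)
  ox <- (params$frame_w - geom$canvas_w) / 2
  oy <- (params$frame_h - geom$canvas_h) / 2
  matrix(c(1, 0, ox, 0, 1, oy, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Render the ideal (undistorted) tray canvas plus exact truth.
# `day` sets the growth stage. The returned masks are geometric: plant
# pixels are defined before any colour is drawn, so truth never depends
# on rendering.
render_ideal_tray <- function(params, day, seed) {
  geom <- sim_geometry(params)
  h <- geom$canvas_h
  w <- geom$canvas_w
  ph <- params$pot_h_px
  pw <- params$pot_w_px
  n_pots <- params$n_rows * params$n_cols

  masks <- vector("list", n_pots)
  areas <- integer(n_pots)
  g <- params$growth
  for (p in seq_len(n_pots)) {
    leaf <- rosette_geometry(seed, p)
    target <- logistic_area(day, g$a0, g$amax * leaf$amax_jitter, g$rate)
    masks[[p]] <- rosette_mask(leaf, target, ph, pw)
    areas[p] <- sum(masks[[p]])
  }

  with_seed(child_seed(seed, 7000L + round(day * 97)), {
    canvas <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      canvas[, , ch] <- clamp01(
        params$soil_rgb_mean[ch] +
          matrix(stats::rnorm(h * w, 0, params$soil_rgb_std), h, w)
      )
    }
    layers <- list()
    # moss blobs: small green low-saturation ellipses
    mean_blob <- 40
    n_blobs <- round(params$moss_density * h * w / mean_blob)
    for (i in seq_len(n_blobs)) {
      col <- clamp01(params$moss_rgb_mean + stats::rnorm(3, 0, 0.03))
      idx <- ellipse_indices(
        cx = stats::runif(1, 0, w), cy = stats::runif(1, 0, h),
        a = stats::runif(1, 2.5, 6), b = stats::runif(1, 1.5, 4),
        theta = stats::runif(1, 0, pi), h, w
      )
      layers[[length(layers) + 1]] <-
        list(idx = idx, color = col, noise_sd = 0.02)
    }
    # rosettes
    for (p in seq_len(n_pots)) {
      if (areas[p] == 0) next
      r0 <- ((p - 1) %/% params$n_cols) * ph
      c0 <- ((p - 1) %% params$n_cols) * pw
      sel <- which(masks[[p]])
      rr <- ((sel - 1) %% ph) + 1 + r0
      cc <- ((sel - 1) %/% ph) + 1 + c0
      layers[[length(layers) + 1]] <- list(
        idx = rr + (cc - 1) * h, color = params$plant_rgb_mean,
        noise_sd = params$plant_rgb_std
      )
    }
    # neighbour-leaf intrusion: an elliptical leaf poking across a pot
    # boundary, attributed to no pot's truth mask (its parent rosette is
    # in the neighbouring pot).
    for (p in seq_len(n_pots)) {
      if (stats::runif(1) >= params$intrusion_prob) next
      r <- (p - 1) %/% params$n_cols
      cc <- (p - 1) %% params$n_cols
      sides <- c(
        if (cc > 0) "left", if (cc < params$n_cols - 1) "right",
        if (r > 0) "top", if (r < params$n_rows - 1) "bottom"
      )
      if (is.null(sides)) next
      side <- sides[sample.int(length(sides), 1)]
      off <- stats::runif(1, 0.25, 0.75)
      bx <- switch(side,
        left = cc * pw, right = (cc + 1) * pw,
        top = cc * pw + off * pw, bottom = cc * pw + off * pw
      )
      by <- switch(side,
        left = r * ph + off * ph, right = r * ph + off * ph,
        top = r * ph, bottom = (r + 1) * ph
      )
      th <- switch(side, left = 0, right = pi, top = pi / 2,
                   bottom = -pi / 2) + stats::runif(1, -0.4, 0.4)
      a <- stats::runif(1, 12, 20)
      idx <- ellipse_indices(
        bx + a * 0.8 * cos(th), by + a * 0.8 * sin(th),
        a, a * stats::runif(1, 0.4, 0.6), th, h, w
      )
      layers[[length(layers) + 1]] <- list(
        idx = idx, color = params$plant_rgb_mean,
        noise_sd = params$plant_rgb_std
      )
    }
    # markers: filled red squares centred on the marker grid points
    tp <- target_points(geom)
    half <- params$marker_side_px / 2
    for (i in 1:4) {
      cols <- max(1, ceiling(tp$x[i] - half + 0.5)):
        min(w, floor(tp$x[i] + half + 0.5))
      rows <- max(1, ceiling(tp$y[i] - half + 0.5)):
        min(h, floor(tp$y[i] + half + 0.5))
      idx <- as.vector(outer(rows, (cols - 1L) * h, "+"))
      layers[[length(layers) + 1]] <- list(
        idx = idx, color = c(0.82, 0.07, 0.07), noise_sd = 0.015
      )
    }
    canvas <- paint_layers(canvas, layers)
    # horizontal illumination ramp (shadow), applied to the whole scene
    if (params$shadow_strength > 0) {
      ramp <- 1 + params$shadow_strength *
        (0.5 - (seq_len(w) - 0.5) / w)
      for (ch in 1:3) {
        canvas[, , ch] <- clamp01(canvas[, , ch] *
                                    rep(ramp, each = h))
      }
    }
    list(canvas = canvas, masks = masks, areas = areas,
         markers_ideal = tp)
  })
}

#' Generate one synthetic tray image with exact ground truth
#'
#' Renders the ideal tray scene at growth stage `day`, applies the
#' projective camera distortion, and returns the acquired frame together
#' with a `scene_truth` object holding the exact per-pot plant masks
#' (pot-frame coordinates), the true marker centres before and after
#' distortion, the distortion matrix, and the true per-pot areas (always
#' equal to the mask pixel counts).
#'
#' @param params A [sim_params()].
#' @param day Growth stage in days (time since the start of the logistic
#'   curve).
#' @param seed Integer seed; identical `(params, day, seed)` reproduce the
#'   output bit-exactly.
#' @param tray Tray label attached to the frame.
#' @return A list with elements `image` (a `tray_image`: list of `image`
#'   array, `tray`, `day`) and `truth` (a `scene_truth`).
#' @export
generate_tray <- function(params, day = 0, seed = params$seed,
                          tray = "F11") {
  stopifnot(inherits(params, "sim_params"))
  scene <- render_ideal_tray(params, day, seed)
  dmat <- if (is.matrix(params$distortion)) {
    params$distortion
  } else if (identical(params$distortion, "identity")) {
    identity_distortion(params)
  } else {
    with_seed(child_seed(seed, 31L), random_distortion(params))
  }
  frame <- .warp_projective(
    scene$canvas, solve(dmat), params$frame_h, params$frame_w,
    c(0.52, 0.52, 0.53) # neutral table background, no red content
  )
  mi <- apply_homography(structure(dmat, class = "homography"),
                         cbind(scene$markers_ideal$x,
                               scene$markers_ideal$y))
  truth <- structure(
    list(
      masks = scene$masks,
      areas = scene$areas,
      markers_ideal = scene$markers_ideal,
      markers_image = marker_set(mi[, 1], mi[, 2], provenance = "true"),
      distortion = dmat
    ),
    class = "scene_truth"
  )
  image <- structure(
    list(image = frame, tray = tray, day = day),
    class = "tray_image"
  )
  list(image = image, truth = truth)
}

#' Generate a time series of synthetic tray frames
#'
#' One frame per schedule entry, sharing pot layouts, rosette geometries
#' and camera distortion (the tray and camera do not move between visits);
#' per-frame noise (soil texture, moss, intrusions) varies. True areas are
#' non-decreasing over the series whenever the growth rate is
#' non-negative.
#'
#' @param params A [sim_params()].
#' @param schedule Strictly increasing numeric vector of acquisition times
#'   in days.
#' @param seed Integer seed.
#' @param tray Tray label.
#' @return A list of `list(image, truth)` pairs, one per schedule entry.
#' @export
generate_timeseries <- function(params, schedule, seed = params$seed,
                                tray = "F11") {
  stopifnot(inherits(params, "sim_params"))
  if (length(schedule) == 0) {
    stop("schedule must be non-empty")
  }
  if (any(diff(schedule) <= 0)) {
    stop("schedule must be strictly increasing")
  }
  # one distortion for the whole series
  fixed <- params
  if (is.null(fixed$distortion)) {
    fixed$distortion <- with_seed(child_seed(seed, 31L),
                                  random_distortion(params))
  }
  lapply(seq_along(schedule), function(i) {
    generate_tray(fixed, day = schedule[i], seed = seed, tray = tray)
  })
}

# Render a single pot image (pot-frame) with its exact mask; used by the
# ground-truth pack. `illum` is a scalar luminance factor, `a_shift` an
# additive CIE a* shift applied to the finished image (emulating a colour
# distribution shift between acquisition environments).
render_pot_pair <- function(params, day, seed, illum = 1, a_shift = 0,
                            bg_blend = 0, pot_index = 1L,
                            noise_seed = NULL) {
  ph <- params$pot_h_px
  pw <- params$pot_w_px
  leaf <- rosette_geometry(seed, pot_index)
  g <- params$growth
  target <- logistic_area(day, g$a0, g$amax * leaf$amax_jitter, g$rate)
  mask <- rosette_mask(leaf, target, ph, pw)
  with_seed(noise_seed %||% child_seed(seed, 57L), {
    canvas <- array(0, dim = c(ph, pw, 3))
    for (ch in 1:3) {
      canvas[, , ch] <- clamp01(
        params$soil_rgb_mean[ch] +
          matrix(stats::rnorm(ph * pw, 0, params$soil_rgb_std), ph, pw)
      )
    }
    layers <- list()
    n_blobs <- round(params$moss_density * ph * pw / 40)
    for (i in seq_len(n_blobs)) {
      col <- clamp01(params$moss_rgb_mean + stats::rnorm(3, 0, 0.03))
      idx <- ellipse_indices(
        stats::runif(1, 0, pw), stats::runif(1, 0, ph),
        stats::runif(1, 2.5, 6), stats::runif(1, 1.5, 4),
        stats::runif(1, 0, pi), ph, pw
      )
      layers[[length(layers) + 1]] <-
        list(idx = idx, color = col, noise_sd = 0.02)
    }
    if (any(mask)) {
      layers[[length(layers) + 1]] <- list(
        idx = which(mask), color = params$plant_rgb_mean,
        noise_sd = params$plant_rgb_std
      )
    }
    canvas <- paint_layers(canvas, layers)
    if (params$shadow_strength > 0) {
      ramp <- 1 + params$shadow_strength * (0.5 - (seq_len(pw) - 0.5) / pw)
      for (ch in 1:3) {
        canvas[, , ch] <- canvas[, , ch] * rep(ramp, each = ph)
      }
    }
    canvas <- clamp01(canvas * illum)
    if (a_shift != 0 || bg_blend > 0) {
      canvas <- shift_background(canvas, !mask, a_shift, bg_blend,
                                 params$plant_rgb_mean)
    }
    list(image = canvas, mask = mask, area = sum(mask), day = day)
  })
}

# Colour-distribution shift of the background pixels of an RGB image,
# emulating soil/moss appearance differences between acquisition
# environments: an additive CIE a* shift, plus an optional blend of the
# background Lab values toward the plant colour (wet, mossy soil that
# resembles vegetation). `where` selects the background pixels.
shift_background <- function(img, where, a_shift = 0, bg_blend = 0,
                             plant_rgb = NULL) {
  d <- dim(img)
  rgb <- matrix(as.vector(img), ncol = 3) * 255
  lab <- farver::convert_colour(rgb, from = "rgb", to = "lab")
  sel <- as.vector(where)
  if (bg_blend > 0) {
    ref <- farver::convert_colour(matrix(plant_rgb * 255, 1), "rgb",
                                  "lab")
    lab[sel, ] <- lab[sel, , drop = FALSE] * (1 - bg_blend) +
      rep(bg_blend * ref, each = sum(sel))
  }
  lab[sel, 2] <- lab[sel, 2] + a_shift
  out <- farver::convert_colour(lab, from = "lab", to = "rgb") / 255
  array(clamp01(out), dim = d)
}

#' Generate a per-pot image time series with exact truth
#'
#' Renders one pot over a schedule of days: the rosette geometry is fixed
#' (the same plant grows along the logistic curve) while soil/moss noise
#' varies per frame. Cheaper than rendering whole trays when only growth
#' readout is being studied.
#'
#' @param params A [sim_params()].
#' @param schedule Strictly increasing numeric vector of days.
#' @param seed Integer seed.
#' @param pot_index Index selecting the plant's rosette geometry (and
#'   per-pot growth jitter), so different indices give different plants.
#' @return List of `list(image, mask, area, day)`, one per schedule
#'   entry.
#' @export
generate_pot_timeseries <- function(params, schedule, seed = params$seed,
                                    pot_index = 1L) {
  stopifnot(inherits(params, "sim_params"), length(schedule) >= 1)
  if (any(diff(schedule) <= 0)) {
    stop("schedule must be strictly increasing")
  }
  lapply(seq_along(schedule), function(i) {
    render_pot_pair(
      params, schedule[i], seed, pot_index = as.integer(pot_index),
      noise_seed = child_seed(seed, 400000L + pot_index * 1000L + i)
    )
  })
}

#' Generate a pack of ground-truth pot image/mask pairs
#'
#' Samples pot images across the full range of growth stages with
#' per-image illumination variation (and optionally a constant a*-channel
#' colour shift, emulating images acquired in a different environment),
#' each paired with its exact binary plant mask. This stands in for a
#' manual ground-truth annotation tool; around 100 pairs are a reasonable
#' training set for the colour classifier.
#'
#' @param params A [sim_params()].
#' @param n_images Number of pairs (>= 1).
#' @param variation List with `illum`, a length-2 range of multiplicative
#'   luminance factors sampled per image (default `c(0.85, 1.15)`), and
#'   `a_shift`, a constant additive CIE a* shift applied to the
#'   background (soil and moss) pixels of every image (default 0),
#'   emulating the soil-colour differences seen between acquisition
#'   environments; and `bg_blend` in \[0, 1\] (default 0), which blends
#'   the background Lab values toward the plant colour, emulating wet,
#'   mossy soil whose appearance approaches the vegetation's.
#' @param seed Integer seed.
#' @return List of `n_images` lists with elements `image` (RGB array),
#'   `mask` (logical matrix of the same height/width), `area`, `day`.
#' @export
generate_groundtruth_pack <- function(params, n_images,
                                      variation = list(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), n_images >= 1)
  illum_range <- variation$illum %||% c(0.85, 1.15)
  a_shift <- variation$a_shift %||% 0
  bg_blend <- variation$bg_blend %||% 0
  g <- params$growth
  # sample days uniformly up to the time the curve reaches 99% of amax
  t99 <- if (g$a0 <= 0 || g$rate <= 0) {
    30
  } else {
    log(99 * (g$amax - g$a0) / g$a0) / g$rate
  }
  with_seed(child_seed(seed, 77L), {
    days <- stats::runif(n_images, 0, t99)
    illums <- stats::runif(n_images, illum_range[1], illum_range[2])
    seeds <- sample.int(2^30, n_images)
    lapply(seq_len(n_images), function(i) {
      render_pot_pair(params, days[i], seeds[i], illums[i], a_shift,
                      bg_blend)
    })
  })
}

#' Write a generated dataset to disk
#'
#' Writes tray frames (or pot pairs) as PNG images plus a JSON manifest
#' with the parameters, seed and truth summary, and a CSV of true areas.
#'
#' @param frames Output of [generate_timeseries()].
#' @param dir Output directory (created if needed).
#' @param params The [sim_params()] used.
#' @param seed The seed used.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(frames, dir, params, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  areas <- list()
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    name <- sprintf("%s_day%07.2f.png", f$image$tray, f$image$day)
    png::writePNG(f$image$image, file.path(dir, name))
    areas[[i]] <- data.frame(
      tray = f$image$tray, day = f$image$day,
      pot = seq_along(f$truth$areas), area_px = f$truth$areas
    )
  }
  areas <- do.call(rbind, areas)
  utils::write.csv(areas, file.path(dir, "true_areas.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_frames = length(frames),
    seed = seed,
    params = params[setdiff(names(params), "distortion")],
    total_true_area = sum(areas$area_px)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
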