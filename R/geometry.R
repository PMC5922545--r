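#' Tray geometry
#'
#' Describes the pot grid of a tray in the rectified ("corrected") image:
#' pot width/height in pixels and the number of pot rows and columns. The
#' rectified canvas is exactly `n_cols * pot_w` by `n_rows * pot_h` pixels,
#' and the four fiducial markers sit on pot-grid lines, inset two pot
#' widths from the left/right canvas edges and one pot height from the
#' top/bottom (see [target_points()]).
#'
#' Coordinates throughout the package are continuous and 0-based: x grows
#' rightward, y downward, and the pixel in array row r / column c (1-based)
#' is centered at (c - 0.5, r - 0.5).
#'
#' @param pot_w,pot_h Pot width and height in pixels in the corrected image.
#' @param n_rows,n_cols Number of pot rows (default 4) and columns (8).
#' @return An object of class `tray_geometry`.
#' @examples
#' geom <- tray_geometry()
#' target_points(geom)
#' @export
tray_geometry <- function(pot_w = 224, pot_h = 224, n_rows = 4, n_cols = 8) {
  stopifnot(pot_w > 0, pot_h > 0, n_rows >= 1, n_cols >= 1)
  structure(
    list(
      pot_w = as.integer(pot_w), pot_h = as.integer(pot_h),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      canvas_w = as.integer(n_cols * pot_w),
      canvas_h = as.integer(n_rows * pot_h)
    ),
    class = "tray_geometry"
  )
}

#' @export
print.tray_geometry <- function(x, ...) {
  cat(sprintf(
    "tray_geometry: %d x %d pots of %d x %d px (canvas %d x %d)\n",
    x$n_rows, x$n_cols, x$pot_w, x$pot_h, x$canvas_w, x$canvas_h
  ))
  invisible(x)
}

#' Construct a set of four fiducial-marker points
#'
#' @param x,y Numeric length-4 coordinates in corner-role order TL, TR,
#'   BL, BR.
#' @param provenance Character vector ("detected" or "recovered"), recycled.
#' @return A `marker_set` data frame with columns `role`, `x`, `y`,
#'   `provenance`.
#' @export
marker_set <- function(x, y, provenance = "detected") {
  stopifnot(length(x) == 4, length(y) == 4)
  structure(
    data.frame(
      role = c("TL", "TR", "BL", "BR"),
      x = as.numeric(x), y = as.numeric(y),
      provenance = rep_len(provenance, 4),
      stringsAsFactors = FALSE
    ),
    class = c("marker_set", "data.frame")
  )
}

#' Target marker coordinates in the corrected image
#'
#' The four markers map to fixed grid-line positions on the rectified
#' canvas: the top-left marker to `(2 * pot_w, pot_h)`, the top-right to
#' `((n_cols - 2) * pot_w, pot_h)`, and the bottom pair one pot height above
#' the bottom edge. For the default 4 x 8 grid this places the markers at
#' (2Pw, Ph), (6Pw, Ph), (2Pw, 3Ph), (6Pw, 3Ph), so the horizontal marker
#' span is 4Pw and the vertical span 2Ph.
#'
#' @param geom A [tray_geometry()].
#' @return A `marker_set` with the four target coordinates.
#' @export
target_points <- function(geom) {
  stopifnot(inherits(geom, "tray_geometry"))
  pw <- geom$pot_w
  ph <- geom$pot_h
  xr <- (geom$n_cols - 2) * pw
  yb <- (geom$n_rows - 1) * ph
  marker_set(
    x = c(2 * pw, xr, 2 * pw, xr),
    y = c(ph, ph, yb, yb),
    provenance = "target"
  )
}

#' Marker-detection configuration
#'
#' Red fiducial markers are found by an HSV colour threshold (a hue window
#' around red plus saturation/value floors), refined by a binary (Otsu)
#' threshold on the grayscale of the colour-masked image, followed by a
#' contour area filter and a merge step for fragmented contours.
#'
#' @param hue_lo,hue_hi Red hue window in \[0, 1\]; the window wraps around
#'   0, i.e. a pixel matches when hue >= hue_lo OR hue <= hue_hi.
#' @param sat_min,val_min Minimum HSV saturation and value.
#' @param area_min Minimum contour area in pixels; smaller contours are
#'   discarded (default 150).
#' @param merge_dist When more than four contours survive the area filter,
#'   contours whose bounding boxes are within this many pixels are merged,
#'   iteratively, while more than four remain.
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(hue_lo = 0.97, hue_hi = 0.03, sat_min = 0.55,
                          val_min = 0.25, area_min = 150, merge_dist = 5) {
  structure(
    list(
      hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
      val_min = val_min, area_min = area_min, merge_dist = merge_dist
    ),
    class = "marker_config"
  )
}

marker_detection_error <- function(message, candidates) {
  structure(
    class = c("marker_detection_error", "error", "condition"),
    list(message = message, call = sys.call(-1), candidates = candidates)
  )
}

# Otsu threshold over a numeric vector in [0, 1] using a 256-bin histogram.
# Applied to the grayscale image in which non-red pixels are zeroed, it
# separates marker pixels from the zero background.
otsu_threshold <- function(v, levels = 256L) {
  h <- tabulate(pmin(levels, floor(v * levels) + 1L), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  (which.max(sigma)) / levels
}

#' Detect the four red fiducial markers in a tray image
#'
#' Pixels are first selected by a red HSV threshold, then re-classified by
#' a binary Otsu threshold on the grayscale of the colour-masked image.
#' Connected contours are extracted, contours with area below
#' `config$area_min` pixels are removed, and adjacent contours are merged
#' while more than four remain. Corner roles are assigned by splitting the
#' four centroids into top/bottom pairs by y, then left/right by x.
#'
#' @param image RGB array (H x W x 3, values in \[0, 1\]), or a `tray_image`.
#' @param config A [marker_config()].
#' @return A [marker_set()] with centroids and roles, provenance
#'   `"detected"`.
#' @section Errors: if fewer than four candidate contours are found a
#'   condition of class `marker_detection_error` is signalled; its
#'   `candidates` field carries the partial centroid set (possibly empty),
#'   which [recover_missing_markers()] can complete from a temporal
#'   neighbour.
#' @export
detect_markers <- function(image, config = marker_config()) {
  img <- as_rgb_array(image)
  h <- dim(img)[1]
  w <- dim(img)[2]
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]), maxColorValue = 1
  )
  red <- (hsv[1, ] >= config$hue_lo | hsv[1, ] <= config$hue_hi) &
    hsv[2, ] >= config$sat_min & hsv[3, ] >= config$val_min
  if (!any(red)) {
    stop(marker_detection_error("no red pixels found (0 candidates)",
                                candidates = NULL))
  }
  gray <- 0.299 * as.vector(img[, , 1]) + 0.587 * as.vector(img[, , 2]) +
    0.114 * as.vector(img[, , 3])
  gray[!red] <- 0
  thr <- otsu_threshold(gray)
  mask <- matrix(as.integer(gray > min(thr, max(gray[red]) - 1e-9)), h, w)

  lab <- .label_components(mask, 8L)
  comps <- component_stats(lab)
  comps <- comps[comps$area >= config$area_min, , drop = FALSE]
  if (nrow(comps) > 4) {
    comps <- merge_adjacent(comps, config$merge_dist)
  }
  if (nrow(comps) > 4) { # still too many: keep the four largest
    comps <- comps[order(-comps$area)[1:4], , drop = FALSE]
  }
  if (nrow(comps) < 4) {
    stop(marker_detection_error(
      sprintf("only %d marker candidate(s) found", nrow(comps)),
      candidates = comps
    ))
  }
  assign_roles(comps$cx, comps$cy)
}

# Per-component area, centroid (0-based continuous) and bounding box.
component_stats <- function(lab) {
  k <- max(lab)
  if (k == 0) {
    return(data.frame(
      area = integer(0), cx = numeric(0), cy = numeric(0),
      rmin = integer(0), rmax = integer(0), cmin = integer(0),
      cmax = integer(0)
    ))
  }
  idx <- which(lab > 0)
  g <- lab[idx]
  r <- ((idx - 1) %% nrow(lab)) + 1
  cc <- ((idx - 1) %/% nrow(lab)) + 1
  data.frame(
    area = as.integer(tabulate(g, k)),
    cx = as.vector(tapply(cc - 0.5, g, mean)),
    cy = as.vector(tapply(r - 0.5, g, mean)),
    rmin = as.vector(tapply(r, g, min)),
    rmax = as.vector(tapply(r, g, max)),
    cmin = as.vector(tapply(cc, g, min)),
    cmax = as.vector(tapply(cc, g, max))
  )
}

# Iteratively merge components whose bounding boxes are within `dist` px
# while more than four remain.
merge_adjacent <- function(comps, dist) {
  repeat {
    n <- nrow(comps)
    if (n <= 4) break
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        gap_r <- max(comps$rmin[i], comps$rmin[j]) -
          min(comps$rmax[i], comps$rmax[j])
        gap_c <- max(comps$cmin[i], comps$cmin[j]) -
          min(comps$cmax[i], comps$cmax[j])
        if (max(gap_r, gap_c) <= dist) {
          ai <- comps$area[i]
          aj <- comps$area[j]
          comps$cx[i] <- (comps$cx[i] * ai + comps$cx[j] * aj) / (ai + aj)
          comps$cy[i] <- (comps$cy[i] * ai + comps$cy[j] * aj) / (ai + aj)
          comps$area[i] <- ai + aj
          comps$rmin[i] <- min(comps$rmin[i], comps$rmin[j])
          comps$rmax[i] <- max(comps$rmax[i], comps$rmax[j])
          comps$cmin[i] <- min(comps$cmin[i], comps$cmin[j])
          comps$cmax[i] <- max(comps$cmax[i], comps$cmax[j])
          comps <- comps[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  comps
}

# Assign TL/TR/BL/BR roles: split into top/bottom pairs by y, order each
# pair by x.
assign_roles <- function(x, y) {
  o <- order(y)
  top <- o[1:2]
  bot <- o[3:4]
  top <- top[order(x[top])]
  bot <- bot[order(x[bot])]
  idx <- c(top[1], top[2], bot[1], bot[2])
  marker_set(x = x[idx], y = y[idx], provenance = "detected")
}

#' Recover missing markers from a temporal neighbour
#'
#' When fewer than four markers are detected on a visit, the missing
#' positions are filled in from the same tray's previous visit, or failing
#' that the next visit. Detected centers are matched to the reference
#' set's roles by nearest distance; unfilled roles are copied from the
#' reference and flagged `"recovered"`.
#'
#' @param partial A `marker_set`, a partial data frame with `x`/`y`
#'   columns (as carried by a `marker_detection_error`), or `NULL`.
#' @param prev,nxt The full `marker_set` from the previous / next visit
#'   (either may be `NULL`). When both are present the previous visit is
#'   used.
#' @return A complete `marker_set`; recovered entries have provenance
#'   `"recovered"`.
#' @export
recover_missing_markers <- function(partial, prev = NULL, nxt = NULL) {
  if (inherits(partial, "marker_set") && nrow(partial) == 4) {
    return(partial)
  }
  ref <- prev %||% nxt
  if (is.null(ref)) {
    stop("markers missing and no temporal neighbour available")
  }
  stopifnot(inherits(ref, "marker_set"))
  out <- ref
  out$provenance <- "recovered"
  if (!is.null(partial) && NROW(partial) > 0) {
    px <- partial$cx %||% partial$x
    py <- partial$cy %||% partial$y
    for (i in seq_along(px)) {
      d <- (ref$x - px[i])^2 + (ref$y - py[i])^2
      j <- which.min(d)
      out$x[j] <- px[i]
      out$y[j] <- py[i]
      out$provenance[j] <- "detected"
    }
  }
  out
}

#' Estimate the homography mapping source markers to target points
#'
#' Solves the direct linear transform for the exact 4-point correspondence
#' problem; the returned 3 x 3 matrix is normalized so its bottom-right
#' entry is 1.
#'
#' @param src,dst `marker_set`s (rows matched by role order TL, TR, BL,
#'   BR) or 4 x 2 coordinate matrices in the same order.
#' @return A 3 x 3 matrix of class `homography`.
#' @export
estimate_homography <- function(src, dst) {
  s <- as_coord_matrix(src)
  d <- as_coord_matrix(dst)
  a <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- s[i, 1]
    y <- s[i, 2]
    u <- d[i, 1]
    v <- d[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    a[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  hvec <- tryCatch(solve(a, b), error = function(e) {
    stop("degenerate marker configuration: homography estimation failed (",
         conditionMessage(e), ")")
  })
  h <- matrix(c(hvec, 1), 3, 3, byrow = TRUE)
  if (!all(is.finite(h)) || abs(det(h)) < 1e-12) {
    stop("degenerate marker configuration: homography is singular")
  }
  structure(h, class = c("homography", "matrix", "array"))
}

as_coord_matrix <- function(p) {
  if (inherits(p, "marker_set") || is.data.frame(p)) {
    cbind(p$x, p$y)
  } else {
    m <- as.matrix(p)
    stopifnot(nrow(m) == 4, ncol(m) == 2)
    m
  }
}

#' Apply a homography to points
#'
#' @param h A `homography` (3 x 3 matrix).
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(h, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  p <- h %*% rbind(t(pts), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

#' Perspective-warp a tray image onto the corrected canvas
#'
#' Applies the homography mapping source marker coordinates to their
#' [target_points()], producing a rectified image of exactly
#' `n_cols * pot_w` by `n_rows * pot_h` pixels, ready for grid cropping.
#' Resampling is bilinear via inverse mapping.
#'
#' @param image RGB array or `tray_image`.
#' @param h `homography` from [estimate_homography()].
#' @param geom [tray_geometry()] defining the output canvas.
#' @param fill Fill value(s) for output pixels that map outside the source.
#' @return Corrected RGB array (`canvas_h` x `canvas_w` x 3).
#' @export
warp_tray <- function(image, h, geom, fill = 0) {
  img <- as_rgb_array(image)
  stopifnot(inherits(h, "homography") || (is.matrix(h) && all(dim(h) == 3)))
  out <- .warp_projective(
    img, solve(unclass(h)), geom$canvas_h, geom$canvas_w,
    as.numeric(fill)
  )
  out
}

#' Crop a corrected tray image into per-pot images
#'
#' Pot (r, c) (0-based) occupies the half-open window
#' `[c * pot_w, (c + 1) * pot_w) x [r * pot_h, (r + 1) * pot_h)`; the
#' windows tile the canvas exactly, without overlap. Pots are returned in
#' row-major order and named by [pot_label()].
#'
#' @param corrected Corrected RGB array from [warp_tray()].
#' @param geom [tray_geometry()].
#' @return Named list of `n_rows * n_cols` RGB arrays (`pot_h` x `pot_w`
#'   x 3), each with attributes `row` and `col` (0-based).
#' @export
crop_pots <- function(corrected, geom) {
  d <- dim(corrected)
  if (d[1] != geom$canvas_h || d[2] != geom$canvas_w) {
    stop(sprintf(
      "canvas size mismatch: image is %d x %d, geometry expects %d x %d",
      d[1], d[2], geom$canvas_h, geom$canvas_w
    ))
  }
  out <- vector("list", geom$n_rows * geom$n_cols)
  nms <- character(length(out))
  i <- 0
  for (r in seq_len(geom$n_rows) - 1L) {
    for (cc in seq_len(geom$n_cols) - 1L) {
      i <- i + 1
      crop <- corrected[
        (r * geom$pot_h + 1):((r + 1) * geom$pot_h),
        (cc * geom$pot_w + 1):((cc + 1) * geom$pot_w), ,
        drop = FALSE
      ]
      attr(crop, "row") <- r
      attr(crop, "col") <- cc
      out[[i]] <- crop
      nms[i] <- pot_label(r, cc, geom)
    }
  }
  names(out) <- nms
  out
}

#' Rectify a tray image end to end
#'
#' Convenience wrapper: detect markers (recovering missing ones from
#' `prev`/`nxt` if supplied), estimate the homography to the geometry's
#' target points, and warp.
#'
#' @inheritParams detect_markers
#' @inheritParams warp_tray
#' @param prev,nxt Optional neighbouring-visit `marker_set`s for recovery.
#' @return List with `image` (corrected array), `markers`, `homography`.
#' @export
rectify_tray <- function(image, geom = tray_geometry(),
                         config = marker_config(), prev = NULL, nxt = NULL) {
  markers <- tryCatch(
    detect_markers(image, config),
    marker_detection_error = function(e) {
      recover_missing_markers(e$candidates, prev = prev, nxt = nxt)
    }
  )
  h <- estimate_homography(markers, target_points(geom))
  list(image = warp_tray(image, h, geom), markers = markers, homography = h)
}

# Accept tray_image objects or plain arrays.
as_rgb_array <- function(image) {
  if (inherits(image, "tray_image")) image <- image$image
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)) {
    stop("expected an RGB array (H x W x 3)")
  }
  image
}
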