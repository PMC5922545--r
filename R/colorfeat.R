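#' Convert an RGB image to CIE L*a*b*
#'
#' sRGB (D65) to CIE L*a*b*; L* in \[0, 100\], a*/b* signed, stored as
#' floating point (never re-quantized to 8 bit). The L*a*b* space is used
#' both for SLIC over-segmentation and as the classifier feature space:
#' it separates the green-red axis (a*) that distinguishes vegetation
#' from soil far better than raw RGB.
#'
#' @param image RGB array (H x W x 3, values in \[0, 1\]).
#' @return Array H x W x 3 with channels L*, a*, b*.
#' @export
to_lab <- function(image) {
  img <- as_rgb_array(image)
  d <- dim(img)
  rgb <- matrix(as.vector(img), ncol = 3) * 255
  lab <- farver::convert_colour(rgb, from = "rgb", to = "lab")
  array(lab, dim = d)
}

#' SLIC superpixel over-segmentation
#'
#' Partitions the image into approximately `n_target` compact superpixels
#' by localized k-means in the joint (L*, a*, b*, x, y) space, with the
#' spatial distance weighted by `compactness / S` (S the grid step).
#' Connectivity is enforced afterwards: stray fragments below a quarter of
#' the nominal superpixel area are merged into an adjacent superpixel, so
#' the final count N generally differs from `n_target` and varies by
#' image.
#'
#' @param lab L*a*b* array from [to_lab()] (an RGB array is converted
#'   automatically).
#' @param n_target Requested number of superpixels (default 700 for a
#'   224 x 224 pot image).
#' @param compactness Spatial regularity weight (default 10); larger
#'   values give squarer superpixels, smaller ones better colour boundary
#'   adherence.
#' @param max_iter k-means iterations (default 10).
#' @return An object of class `superpixel_map`: list with `labels`
#'   (H x W integer matrix, ids 1..N covering every pixel) and `n`.
#' @export
superpixels <- function(lab, n_target = 700, compactness = 10,
                        max_iter = 10) {
  if (length(dim(lab)) != 3 || dim(lab)[3] != 3) {
    stop("expected an H x W x 3 L*a*b* array")
  }
  h <- dim(lab)[1]
  w <- dim(lab)[2]
  if (n_target < 1) {
    stop("n_target must be >= 1")
  }
  if (n_target > h * w) {
    stop("n_target exceeds the pixel count")
  }
  res <- .slic_superpixels(
    lab[, , 1], lab[, , 2], lab[, , 3],
    as.integer(n_target), as.numeric(compactness), as.integer(max_iter)
  )
  structure(list(labels = res$labels, n = res$n), class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("superpixel_map: %d superpixels over %d x %d px\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Mean L*a*b* features per superpixel
#'
#' Row i of the result is the arithmetic mean of (L*, a*, b*) over all
#' pixels with superpixel id i: the N x 3 feature matrix consumed by the
#' plant/background classifiers.
#'
#' @param lab L*a*b* array matching the superpixel map's size.
#' @param sp A `superpixel_map` from [superpixels()].
#' @return N x 3 numeric matrix with columns `L`, `a`, `b`.
#' @export
mean_features <- function(lab, sp) {
  stopifnot(inherits(sp, "superpixel_map"))
  if (!all(dim(lab)[1:2] == dim(sp$labels))) {
    stop("label image and Lab image shapes differ")
  }
  g <- as.vector(sp$labels)
  counts <- tabulate(g, sp$n)
  if (any(counts == 0)) {
    stop("internal error: empty superpixel id")
  }
  sums <- rowsum(matrix(as.vector(lab), ncol = 3), g)
  feats <- sums / counts
  colnames(feats) <- c("L", "a", "b")
  feats
}
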