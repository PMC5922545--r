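#' Classify superpixels with a trained model
#'
#' One binary label (0 background, 1 plant) and one continuous score per
#' feature row; labels are the scores thresholded at 0.5 for every
#' algorithm, so label/score consistency holds uniformly.
#'
#' @param features N x 3 mean-L*a*b* matrix.
#' @param model A `seg_model` from [train_classifier()].
#' @return List with `labels` (integer N) and `scores` (numeric N, the
#'   model's plant-class probability).
#' @export
classify <- function(features, model) {
  stopifnot(inherits(model, "seg_model"))
  features <- as.matrix(features)
  if (ncol(features) != 3) {
    stop("feature matrix must have exactly 3 columns (mean L, a, b)")
  }
  colnames(features) <- c("L", "a", "b")
  scores <- switch(model$algorithm,
    rf = stats::predict(model$fit, features, type = "prob")[, "1"],
    svm = {
      p <- stats::predict(model$fit, features, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    mlp = mlp_predict(model$fit, features)
  )
  scores <- as.numeric(scores)
  list(labels = as.integer(scores > 0.5), scores = scores)
}

seg_mask <- function(mask, stage) {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  attr(mask, "stage") <- stage
  mask
}

#' Rebuild a pixel mask from superpixel labels
#'
#' Every pixel of a superpixel labelled 1 becomes foreground, so the raw
#' mask is a union of whole superpixels and its boundary follows
#' superpixel boundaries.
#'
#' @param sp A `superpixel_map`.
#' @param labels Integer vector of length N.
#' @return Binary integer matrix with attribute `stage = "raw"`.
#' @export
mask_from_labels <- function(sp, labels) {
  stopifnot(inherits(sp, "superpixel_map"))
  if (length(labels) != sp$n) {
    stop("label count does not match the number of superpixels")
  }
  m <- matrix(as.integer(labels)[sp$labels], nrow(sp$labels),
              ncol(sp$labels))
  seg_mask(m, "raw")
}

#' Morphological erosion of a segmentation mask
#'
#' Removes small noise specks caused by stray misclassified superpixel
#' fragments; the default structuring element is a 3 x 3 square (radius
#' 1), applied once. No dilation follows, so measured areas are slightly
#' conservative.
#'
#' @param mask Binary matrix.
#' @param radius Structuring-element radius; the element is a
#'   `(2 * radius + 1)` square.
#' @param iterations Number of erosion passes.
#' @return Binary matrix with attribute `stage = "eroded"`.
#' @export
erode_mask <- function(mask, radius = 1, iterations = 1) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "box")
  for (i in seq_len(iterations)) {
    m <- EBImage::erode(m, brush)
  }
  seg_mask(m > 0.5, "eroded")
}

#' Retain only the centred plant component
#'
#' Keeps exactly the connected component containing the image centre
#' pixel; when the centre pixel is background the component whose
#' centroid is nearest the image centre is kept instead. Size is never
#' the criterion, so a large leaf intruding from a neighbouring pot is
#' removed even when it outweighs the centre plant. An empty mask stays
#' empty.
#'
#' @param mask Binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return Binary matrix with attribute `stage = "center-retained"`.
#' @export
retain_center <- function(mask, connectivity = 8) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) {
    return(seg_mask(m, "center-retained"))
  }
  lab <- .label_components(m, as.integer(connectivity))
  h <- nrow(m)
  w <- ncol(m)
  cr <- floor(h / 2) + 1L
  cc <- floor(w / 2) + 1L
  keep <- lab[cr, cc]
  if (keep == 0) {
    st <- component_stats(lab)
    d <- (st$cx - w / 2)^2 + (st$cy - h / 2)^2
    keep <- which.min(d)
  }
  seg_mask(lab == keep, "center-retained")
}

#' Segmentation pipeline parameters
#'
#' @param n_superpixels,compactness SLIC parameters (defaults 700, 10).
#' @param erode_radius,erode_iterations Erosion parameters (defaults 1, 1).
#' @param connectivity Component connectivity for [retain_center()].
#' @return List of class `segment_params`.
#' @export
segment_params <- function(n_superpixels = 700, compactness = 10,
                           erode_radius = 1, erode_iterations = 1,
                           connectivity = 8) {
  structure(
    list(
      n_superpixels = n_superpixels, compactness = compactness,
      erode_radius = erode_radius, erode_iterations = erode_iterations,
      connectivity = connectivity
    ),
    class = "segment_params"
  )
}

#' Segment one pot image
#'
#' Full pipeline: L*a*b* conversion, SLIC superpixels, mean-colour
#' features, superpixel classification, mask reconstruction, erosion,
#' centre-component retention. Errors in any stage are re-signalled with
#' the stage name attached.
#'
#' @param image RGB pot image (H x W x 3).
#' @param model A `seg_model`.
#' @param params A [segment_params()].
#' @return List with `mask` (final binary matrix), `area` (its pixel
#'   count), and `stages`: the raw and eroded masks plus the areas of all
#'   three stages.
#' @export
segment_pot <- function(image, model, params = segment_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  lab <- stage("to_lab", to_lab(image))
  sp <- stage("superpixels", superpixels(
    lab, n_target = params$n_superpixels, compactness = params$compactness
  ))
  feats <- stage("mean_features", mean_features(lab, sp))
  cls <- stage("classify", classify(feats, model))
  raw <- stage("mask_from_labels", mask_from_labels(sp, cls$labels))
  eroded <- stage("erode", erode_mask(raw, params$erode_radius,
                                      params$erode_iterations))
  final <- stage("retain_center", retain_center(eroded,
                                                params$connectivity))
  list(
    mask = final,
    area = sum(final),
    stages = list(
      raw = raw, eroded = eroded,
      areas = c(raw = sum(raw), eroded = sum(eroded), final = sum(final))
    )
  )
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Binary matrices of identical shape.
#' @return IoU in \[0, 1\]; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) {
    return(1)
  }
  sum(a & b) / u
}
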