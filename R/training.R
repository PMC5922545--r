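#' Superpixel labels from a ground-truth mask
#'
#' A superpixel is labelled plant (1) when the majority (strictly more
#' than half) of its pixels are foreground in the ground-truth mask;
#' exact ties are background (0).
#'
#' @param sp A `superpixel_map`.
#' @param truth Binary mask (logical or 0/1) matching the label image.
#' @return Integer vector of length N with values in `{0, 1}`.
#' @export
superpixel_labels <- function(sp, truth) {
  stopifnot(inherits(sp, "superpixel_map"))
  if (!all(dim(truth) == dim(sp$labels))) {
    stop("mask shape does not match the superpixel label image")
  }
  v <- as.vector(truth)
  if (is.logical(v)) {
    v <- as.integer(v)
  }
  if (!all(v %in% c(0L, 1L))) {
    stop("ground-truth mask must be binary")
  }
  g <- as.vector(sp$labels)
  frac <- as.vector(rowsum(v, g)) / tabulate(g, sp$n)
  as.integer(frac > 0.5)
}

#' Assemble a labelled feature set from image/mask pairs
#'
#' Runs [to_lab()], [superpixels()], [mean_features()] and
#' [superpixel_labels()] on every pair and concatenates the results,
#' keeping per-row provenance (image index and superpixel id) so that
#' cross-validation can split by source image.
#'
#' @param pairs List of `list(image, mask)` pairs (e.g. from
#'   [generate_groundtruth_pack()]).
#' @param sp_params List with `n_superpixels` (default 700) and
#'   `compactness` (default 10).
#' @return An object of class `labeled_features`: list with `x` (M x 3
#'   matrix), `y` (length-M 0/1 integer), `provenance` (data frame with
#'   `image`, `sp_id`).
#' @export
assemble <- function(pairs, sp_params = list()) {
  if (length(pairs) < 1) {
    stop("at least one image/mask pair is required")
  }
  n_sp <- sp_params$n_superpixels %||% 700
  comp <- sp_params$compactness %||% 10
  xs <- vector("list", length(pairs))
  ys <- vector("list", length(pairs))
  prov <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!all(dim(p$image)[1:2] == dim(p$mask))) {
      stop(sprintf("image/mask shape mismatch in pair %d", i))
    }
    lab <- to_lab(p$image)
    sp <- superpixels(lab, n_target = n_sp, compactness = comp)
    xs[[i]] <- mean_features(lab, sp)
    ys[[i]] <- superpixel_labels(sp, p$mask)
    prov[[i]] <- data.frame(image = i, sp_id = seq_len(sp$n))
  }
  structure(
    list(
      x = do.call(rbind, xs),
      y = unlist(ys, use.names = FALSE),
      provenance = do.call(rbind, prov)
    ),
    class = "labeled_features"
  )
}

#' @export
print.labeled_features <- function(x, ...) {
  cat(sprintf(
    "labeled_features: %d superpixels from %d image(s), %.1f%% plant\n",
    length(x$y), length(unique(x$provenance$image)), 100 * mean(x$y)
  ))
  invisible(x)
}

#' Image-grouped k-fold splits
#'
#' Folds partition the source images, never the superpixels: all rows
#' from one image fall on the same side of every split, so no image leaks
#' features across train and validation. Each image validates exactly
#' once.
#'
#' @param data A `labeled_features` from [assemble()].
#' @param k Number of folds (default 5; must not exceed the image count).
#' @param seed Seed for the image shuffle.
#' @return List of k lists with integer row indices `train` and `val`.
#' @export
kfold_splits <- function(data, k = 5, seed = 1L) {
  stopifnot(inherits(data, "labeled_features"), k >= 2)
  images <- unique(data$provenance$image)
  if (k > length(images)) {
    stop("k exceeds the number of images")
  }
  shuffled <- with_seed(seed, sample(images))
  fold_of <- rep_len(seq_len(k), length(images))
  lapply(seq_len(k), function(f) {
    val_imgs <- shuffled[fold_of == f]
    val <- which(data$provenance$image %in% val_imgs)
    list(train = setdiff(seq_along(data$y), val), val = val)
  })
}

default_hyperparams <- function(algorithm) {
  switch(algorithm,
    rf = list(ntree = 100),
    svm = list(kernel = "radial"),
    mlp = list(
      hidden = c(256, 256), epochs = 200, learning_rate = 1e-3,
      keep_prob = 0.7, batch_size = 128
    )
  )
}

#' Train a plant/background superpixel classifier
#'
#' Supported algorithms: `"rf"` (random forest, 100 trees), `"svm"`
#' (radial-basis-function kernel, library defaults, Platt-scaled
#' probabilities), and `"mlp"` (two sigmoid hidden layers of 256 nodes,
#' Adam at learning rate 0.001, dropout keep-probability 0.7 during
#' training and 1.0 at inference; the default epoch budget is 200 and is
#' configurable up to much larger budgets). All stochastic components are
#' seeded, and the seed is recorded in the model metadata.
#'
#' @param x M x 3 matrix of mean-L*a*b* features, or a `labeled_features`
#'   (in which case `y` is taken from it).
#' @param y Binary labels (0 background, 1 plant); both classes must be
#'   present.
#' @param algorithm `"rf"`, `"svm"` or `"mlp"`.
#' @param hyperparams Named list overriding the algorithm defaults.
#' @param seed Integer seed.
#' @return An object of class `seg_model` with fields `algorithm`, `fit`,
#'   `hyperparams`, `seed`, `n_train`.
#' @export
train_classifier <- function(x, y = NULL,
                             algorithm = c("rf", "svm", "mlp"),
                             hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (inherits(x, "labeled_features")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  colnames(x) <- c("L", "a", "b")
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes")
  }
  hp <- utils::modifyList(default_hyperparams(algorithm), hyperparams)
  fit <- switch(algorithm,
    rf = with_seed(seed, randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = hp$ntree
    )),
    svm = with_seed(seed, e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)), kernel = hp$kernel,
      probability = TRUE
    )),
    mlp = mlp_train(
      x, y, hidden = hp$hidden, epochs = hp$epochs,
      learning_rate = hp$learning_rate, keep_prob = hp$keep_prob,
      batch_size = hp$batch_size, seed = seed
    )
  )
  structure(
    list(algorithm = algorithm, fit = fit, hyperparams = hp,
         seed = as.integer(seed), n_train = nrow(x)),
    class = "seg_model"
  )
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("seg_model: %s trained on %d superpixels (seed %d)\n",
              x$algorithm, x$n_train, x$seed))
  invisible(x)
}

#' Select the best classifier from cross-validation results
#'
#' Returns the candidate with the highest mean validation F1. Ties are
#' broken by fewer hyperparameters, then by algorithm preference
#' rf > mlp > svm.
#'
#' @param candidates List of candidates, each a list with `model` (a
#'   `seg_model`) and `fold_f1` (numeric vector of per-fold validation F1
#'   scores).
#' @return The winning candidate, with `mean_f1` added.
#' @export
select_model <- function(candidates) {
  if (length(candidates) == 0) {
    stop("no candidates to select from")
  }
  mean_f1 <- vapply(candidates, function(c) mean(c$fold_f1), numeric(1))
  n_par <- vapply(candidates, function(c) {
    length(c$model$hyperparams)
  }, numeric(1))
  pref <- vapply(candidates, function(c) {
    match(c$model$algorithm, c("rf", "mlp", "svm"))
  }, numeric(1))
  best <- order(-mean_f1, n_par, pref)[1]
  out <- candidates[[best]]
  out$mean_f1 <- mean_f1[best]
  out
}

#' Cross-validate one algorithm on a labelled feature set
#'
#' Trains on each fold's training images and scores the validation
#' images; returns per-fold (micro-averaged) precision, recall and F1
#' plus the fitted fold models.
#'
#' @param data A `labeled_features`.
#' @param algorithm Passed to [train_classifier()].
#' @param k,seed Passed to [kfold_splits()].
#' @param hyperparams Passed to [train_classifier()].
#' @return List with `fold_f1`, `fold_precision`, `fold_recall`,
#'   `fold_ap`, `models`, `elapsed` (training seconds per fold).
#' @export
cross_validate <- function(data, algorithm, k = 5, seed = 1L,
                           hyperparams = list()) {
  splits <- kfold_splits(data, k = k, seed = seed)
  f1 <- prec <- rec <- ap <- elapsed <- numeric(k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    s <- splits[[f]]
    t0 <- proc.time()[["elapsed"]]
    m <- train_classifier(
      data$x[s$train, , drop = FALSE], data$y[s$train],
      algorithm = algorithm, hyperparams = hyperparams,
      seed = child_seed(seed, f)
    )
    elapsed[f] <- proc.time()[["elapsed"]] - t0
    pred <- classify(data$x[s$val, , drop = FALSE], m)
    cm <- confusion(pred$labels, data$y[s$val])
    pr <- prf1(cm["TP"], cm["FP"], cm["FN"])
    prec[f] <- pr["precision"]
    rec[f] <- pr["recall"]
    f1[f] <- pr["f1"]
    ap[f] <- if (any(data$y[s$val] == 1)) {
      average_precision(pred$scores, data$y[s$val])
    } else {
      NA_real_
    }
    models[[f]] <- m
  }
  list(fold_f1 = f1, fold_precision = prec, fold_recall = rec,
       fold_ap = ap, models = models, elapsed = elapsed)
}

#' Save / load a segmentation model
#'
#' The model is serialized to an RDS file with a JSON sidecar recording
#' the algorithm, hyperparameters, seed and training-set size.
#'
#' @param model A `seg_model`.
#' @param path Output path (`.rds`); the sidecar gets `.json` appended.
#' @return `save_model`: invisibly, the sidecar path. `load_model`: the
#'   `seg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(
      format_version = 1L, algorithm = model$algorithm,
      hyperparams = model$hyperparams, seed = model$seed,
      n_train = model$n_train
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
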