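#' Confusion counts for binary superpixel predictions
#'
#' Positive class is plant (1).
#'
#' @param pred,truth Equal-length binary vectors.
#' @return Named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("prediction and truth lengths differ")
  }
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)")
  }
  c(
    TP = sum(pred == 1 & truth == 1),
    FP = sum(pred == 1 & truth == 0),
    FN = sum(pred == 0 & truth == 1),
    TN = sum(pred == 0 & truth == 0)
  )
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; any zero denominator yields 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
prf1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = unname(p), recall = unname(r), f1 = unname(f1))
}

#' Precision-recall curve
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order (tied scores are grouped at one threshold) and reports the
#' (recall, precision) operating point at each.
#'
#' @param scores Continuous scores, higher meaning more plant-like.
#' @param truth Binary labels with at least one positive.
#' @return Data frame with `threshold`, `recall` (non-decreasing along
#'   the sweep) and `precision`.
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1)
  if (n_pos == 0) {
    stop("no positive labels: PR curve undefined")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- truth[o]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  # last index of each tied-score group
  last <- which(!duplicated(s, fromLast = TRUE))
  data.frame(
    threshold = s[last],
    recall = cum_tp[last] / n_pos,
    precision = cum_tp[last] / (cum_tp[last] + cum_fp[last])
  )
}

#' Average precision
#'
#' Default estimator is positive-rank averaging: the mean of the
#' precision at each positive's position in the descending-score ranking
#' (tied scores grouped), equivalently the step-wise sum
#' `sum((R_i - R_{i-1}) * P_i)` over the PR sweep. A trapezoidal
#' alternative over the same points is available.
#'
#' @inheritParams pr_curve
#' @param method `"step"` (positive-rank average, default) or
#'   `"trapezoid"`.
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(scores, truth, method = c("step",
                                                        "trapezoid")) {
  method <- match.arg(method)
  curve <- pr_curve(scores, truth)
  r <- c(0, curve$recall)
  p <- curve$precision
  if (method == "step") {
    sum(diff(r) * p)
  } else {
    p0 <- c(p[1], p)
    sum(diff(r) * (p0[-length(p0)] + p0[-1]) / 2)
  }
}

#' Mean average precision over repeated runs
#'
#' @param aps Numeric vector of per-run AP values (non-empty; NAs
#'   dropped).
#' @return Arithmetic mean.
#' @export
mean_ap <- function(aps) {
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0) {
    stop("no AP values to average")
  }
  mean(aps)
}

#' Compare classifier algorithms under repeated cross-validation
#'
#' For each repeat the image-grouped folds are resampled, each algorithm
#' is trained per fold and scored on its validation fold
#' (micro-averaged precision/recall/F1 and AP over the pooled validation
#' superpixels), and one model trained on the full training set is scored
#' on the held-out test set (typically drawn from a shifted colour
#' distribution). A failed run is recorded with `NA` metrics, not fatal.
#' Training wall-times are recorded for reference but nothing is asserted
#' about them.
#'
#' @param train_pairs List of `(image, mask)` pairs for
#'   training/validation.
#' @param test_pairs Optional list of pairs for the distribution-shifted
#'   test split.
#' @param algorithms Character subset of `c("rf", "svm", "mlp")`.
#' @param k Folds per repeat (default 5).
#' @param n_repeats Number of repeats (default 10).
#' @param seed Base seed; repeat r uses a seed derived from `seed` and r.
#' @param sp_params Passed to [assemble()].
#' @param hyperparams Named list of per-algorithm hyperparameter
#'   overrides, e.g. `list(mlp = list(epochs = 50))`.
#' @return An object of class `eval_report`: list with `runs` (one row
#'   per fold/repeat/split with precision, recall, F1, AP, train time)
#'   and `summary` (per algorithm and split: mean F1, mean precision,
#'   mean recall, mAP).
#' @export
compare_algorithms <- function(train_pairs, test_pairs = NULL,
                               algorithms = c("rf", "svm", "mlp"),
                               k = 5, n_repeats = 10, seed = 1L,
                               sp_params = list(), hyperparams = list()) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  data <- assemble(train_pairs, sp_params)
  test_data <- if (!is.null(test_pairs)) {
    assemble(test_pairs, sp_params)
  }
  runs <- list()
  add_run <- function(algorithm, rep, fold, split, pr, ap, tt) {
    runs[[length(runs) + 1]] <<- data.frame(
      algorithm = algorithm, rep = rep, fold = fold, split = split,
      precision = pr[["precision"]], recall = pr[["recall"]],
      f1 = pr[["f1"]], ap = ap, train_time = tt,
      stringsAsFactors = FALSE
    )
  }
  for (r in seq_len(n_repeats)) {
    rep_seed <- child_seed(seed, r)
    for (alg in algorithms) {
      hp <- hyperparams[[alg]] %||% list()
      cv <- tryCatch(
        cross_validate(data, alg, k = k, seed = rep_seed,
                       hyperparams = hp),
        error = function(e) {
          warning(sprintf("cv run failed (%s, repeat %d): %s", alg, r,
                          conditionMessage(e)))
          NULL
        }
      )
      if (is.null(cv)) {
        add_run(alg, r, NA, "validation",
                c(precision = NA_real_, recall = NA_real_, f1 = NA_real_),
                NA_real_, NA_real_)
      } else {
        for (f in seq_len(k)) {
          add_run(alg, r, f, "validation",
                  c(precision = cv$fold_precision[f],
                    recall = cv$fold_recall[f], f1 = cv$fold_f1[f]),
                  cv$fold_ap[f], cv$elapsed[f])
        }
      }
      if (!is.null(test_data)) {
        res <- tryCatch({
          t0 <- proc.time()[["elapsed"]]
          m <- train_classifier(data$x, data$y, algorithm = alg,
                                hyperparams = hp,
                                seed = child_seed(rep_seed, 999L))
          tt <- proc.time()[["elapsed"]] - t0
          pred <- classify(test_data$x, m)
          cm <- confusion(pred$labels, test_data$y)
          list(pr = prf1(cm["TP"], cm["FP"], cm["FN"]),
               ap = average_precision(pred$scores, test_data$y),
               tt = tt)
        }, error = function(e) {
          warning(sprintf("test run failed (%s, repeat %d): %s", alg, r,
                          conditionMessage(e)))
          NULL
        })
        if (is.null(res)) {
          add_run(alg, r, NA, "test",
                  c(precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_), NA_real_, NA_real_)
        } else {
          add_run(alg, r, NA, "test", res$pr, res$ap, res$tt)
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(
    split(runs, list(runs$algorithm, runs$split), drop = TRUE),
    function(g) {
      data.frame(
        algorithm = g$algorithm[1], split = g$split[1],
        mean_f1 = mean(g$f1, na.rm = TRUE),
        mean_precision = mean(g$precision, na.rm = TRUE),
        mean_recall = mean(g$recall, na.rm = TRUE),
        map = if (all(is.na(g$ap))) NA_real_ else mean_ap(g$ap),
        mean_train_time = mean(g$train_time, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  ))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
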