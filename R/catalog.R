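#' Capture schedule
#'
#' Models the acquisition cadence: images are taken every `interval_min`
#' minutes from `start` to `end` inclusive (default hourly from 09:00 to
#' 21:00, i.e. 13 captures per day), for each labelled tray, over `days`
#' days. The default tray labels cover a 4 x 7 room grid, F11 through F47,
#' row-major (28 trays).
#'
#' @param start,end Times of day as `"HH:MM"` strings.
#' @param interval_min Capture interval in minutes (> 0).
#' @param tray_labels Character vector of unique tray labels.
#' @param days Number of days.
#' @return An object of class `capture_schedule`.
#' @export
capture_schedule <- function(start = "09:00", end = "21:00",
                             interval_min = 60,
                             tray_labels = default_tray_labels(),
                             days = 1) {
  s <- parse_hm(start)
  e <- parse_hm(end)
  if (s > e) {
    stop("schedule start must not be after end")
  }
  stopifnot(interval_min > 0, days >= 0)
  if (anyDuplicated(tray_labels)) {
    stop("tray labels must be unique")
  }
  structure(
    list(
      start_min = s, end_min = e, interval_min = interval_min,
      tray_labels = tray_labels, days = as.integer(days)
    ),
    class = "capture_schedule"
  )
}

#' Default tray labels for a 4 x 7 phenotyping-room grid
#'
#' Trays are labelled `F<row><col>` with rows 1-4 and columns 1-7,
#' row-major: F11, F12, ..., F17, F21, ..., F47 (28 labels).
#'
#' @param n_rows,n_cols Room grid dimensions.
#' @return Character vector of labels.
#' @export
default_tray_labels <- function(n_rows = 4, n_cols = 7) {
  as.vector(t(outer(seq_len(n_rows), seq_len(n_cols),
                    function(r, c) sprintf("F%d%d", r, c))))
}

parse_hm <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(x))
  }
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(p) != 2) {
    stop("times must be \"HH:MM\" strings")
  }
  as.integer(p[1]) * 60L + as.integer(p[2])
}

format_hm <- function(minutes) {
  sprintf("%02d%02d", minutes %/% 60, minutes %% 60)
}

#' Capture times within one day
#'
#' Inclusive of both endpoints; the defaults (hourly, 09:00 to 21:00)
#' yield 13 times.
#'
#' @param sched A [capture_schedule()].
#' @return Character vector of times rendered `"HHMM"`.
#' @export
capture_times <- function(sched) {
  stopifnot(inherits(sched, "capture_schedule"))
  format_hm(seq(sched$start_min, sched$end_min, by = sched$interval_min))
}

#' Tray-image counts implied by a schedule
#'
#' @param sched A [capture_schedule()].
#' @return List with `per_day` (captures per day times trays) and `total`
#'   (`per_day * days`). The default schedule gives 13 x 28 = 364 tray
#'   images per day, 32,760 over 90 days.
#' @export
count_tray_images <- function(sched) {
  n_times <- length(capture_times(sched))
  per_day <- n_times * length(sched$tray_labels)
  list(per_day = per_day, total = per_day * sched$days)
}

#' Cropped pot-image counts implied by a schedule
#'
#' @param sched A [capture_schedule()].
#' @param pots_per_tray Pots per tray (default 32).
#' @return List with `per_cycle` (trays x pots; one cycle visits every
#'   tray once) and `per_day` (`per_cycle` x captures per day). Defaults:
#'   896 per cycle, 11,648 per day.
#' @export
count_pot_images <- function(sched, pots_per_tray = 32) {
  stopifnot(pots_per_tray > 0)
  per_cycle <- length(sched$tray_labels) * pots_per_tray
  list(
    per_cycle = per_cycle,
    per_day = per_cycle * length(capture_times(sched))
  )
}

#' Pot label from grid position
#'
#' Pots are numbered row-major from the top-left of the tray, 1-based,
#' zero-padded to two digits: (0, 0) is `"Pot01"`, (1, 0) is `"Pot09"`
#' on the default 8-column grid, and (3, 7) is `"Pot32"`.
#'
#' @param row,col 0-based grid position.
#' @param geom A [tray_geometry()].
#' @return Pot label string.
#' @export
pot_label <- function(row, col, geom = tray_geometry()) {
  if (any(row < 0) || any(row >= geom$n_rows) ||
      any(col < 0) || any(col >= geom$n_cols)) {
    stop("pot position out of range")
  }
  sprintf("Pot%02d", row * geom$n_cols + col + 1)
}

#' Grid position from pot label
#'
#' Inverse of [pot_label()].
#'
#' @param label Pot label such as `"Pot09"`.
#' @param geom A [tray_geometry()].
#' @return List with 0-based `row` and `col`.
#' @export
pot_position <- function(label, geom = tray_geometry()) {
  idx <- as.integer(sub("^Pot", "", label)) - 1L
  if (is.na(idx) || idx < 0 || idx >= geom$n_rows * geom$n_cols) {
    stop("pot label out of range: ", label)
  }
  list(row = idx %/% geom$n_cols, col = idx %% geom$n_cols)
}

#' Image key: tray, pot, date, time
#'
#' Identifies one cropped pot image. Rendered as
#' `"<tray>_<pot>_<date>_<time>"`, e.g. `"F11_Pot01_2017-06-01_0900"`;
#' images are stored under one folder per (tray, pot) so a pot's whole
#' history, germination to maturation, sits in a single directory.
#'
#' @param tray Tray label, e.g. `"F11"`.
#' @param pot Pot label, e.g. `"Pot01"` (index must be within the grid).
#' @param date Date (`Date` or `"YYYY-MM-DD"` string).
#' @param time Time as `"HHMM"` (or `"HH:MM"`) string.
#' @param geom A [tray_geometry()] used to validate the pot index.
#' @return An object of class `image_key`.
#' @export
image_key <- function(tray, pot, date, time, geom = tray_geometry()) {
  pot_position(pot, geom) # validates
  time <- gsub(":", "", time, fixed = TRUE)
  structure(
    list(tray = tray, pot = pot, date = as.character(as.Date(date)),
         time = time),
    class = "image_key"
  )
}

#' @export
format.image_key <- function(x, ...) {
  sprintf("%s_%s_%s_%s", x$tray, x$pot, x$date, x$time)
}

#' @export
print.image_key <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Folder for an image key
#'
#' @param key An [image_key()].
#' @return Relative folder name, e.g. `"F11_Pot01"`.
#' @export
key_folder <- function(key) {
  sprintf("%s_%s", key$tray, key$pot)
}

#' Arrange cropped pot images into the catalog directory layout
#'
#' Writes each image as a PNG named after its key inside one folder per
#' (tray, pot): `<root>/F11_Pot01/F11_Pot01_2017-06-01_0900.png`.
#' Re-running with the same records overwrites files in place
#' (idempotent); records with identical keys trigger a warning and the
#' later record wins.
#'
#' @param records List of `list(key = image_key, image = RGB array)`.
#' @param root Output root directory.
#' @return Invisibly, a data frame manifest with columns `tray`, `pot`,
#'   `date`, `time`, `path`.
#' @export
arrange <- function(records, root) {
  if (length(records) == 0) {
    return(invisible(data.frame(
      tray = character(0), pot = character(0), date = character(0),
      time = character(0), path = character(0)
    )))
  }
  keys <- vapply(records, function(r) format(r$key), character(1))
  if (anyDuplicated(keys)) {
    warning("duplicate image keys: later records overwrite earlier ones")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    folder <- file.path(root, key_folder(r$key))
    dir.create(folder, showWarnings = FALSE)
    path <- file.path(folder, paste0(format(r$key), ".png"))
    png::writePNG(r$image, path)
    data.frame(
      tray = r$key$tray, pot = r$key$pot, date = r$key$date,
      time = r$key$time, path = path, stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
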