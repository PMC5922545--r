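#' Batch-process a catalog tree into a plant-area time series
#'
#' Walks all `<tray>_<pot>` folders under `root` (the layout written by
#' [arrange()]), segments every PNG with the supplied model, and returns
#' one record per image: tray, pot, date, time, plant area in pixels.
#' Unreadable or failing images are logged as warnings and skipped, never
#' fatal. Records are sorted by (tray, pot, date, time).
#'
#' @param root Catalog root directory.
#' @param model A `seg_model`.
#' @param params A [segment_params()].
#' @param out_csv Optional path; when given the records are also written
#'   as CSV (schema `tray,pot,date,time,area_px`, one header row).
#' @return Data frame with columns `tray`, `pot`, `date`, `time`,
#'   `area_px`.
#' @export
batch_process <- function(root, model, params = segment_params(),
                          out_csv = NULL) {
  if (!dir.exists(root)) {
    stop("unreadable root folder: ", root)
  }
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[grepl("^[^_]+_Pot[0-9]+$", basename(dirs))]
  rows <- list()
  for (d in dirs) {
    files <- list.files(d, pattern = "\\.png$", full.names = TRUE)
    for (f in files) {
      parts <- strsplit(sub("\\.png$", "", basename(f)), "_")[[1]]
      if (length(parts) != 4) {
        warning("skipping unparseable filename: ", basename(f))
        next
      }
      rec <- tryCatch({
        img <- png::readPNG(f)
        if (length(dim(img)) == 2) {
          img <- array(rep(img, 3), dim = c(dim(img), 3))
        }
        if (dim(img)[3] > 3) {
          img <- img[, , 1:3, drop = FALSE]
        }
        seg <- segment_pot(img, model, params)
        data.frame(
          tray = parts[1], pot = parts[2], date = parts[3],
          time = parts[4], area_px = seg$area,
          stringsAsFactors = FALSE
        )
      }, error = function(e) {
        warning(sprintf("skipping %s: %s", basename(f),
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(rec)) {
        rows[[length(rows) + 1]] <- rec
      }
    }
  }
  records <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      tray = character(0), pot = character(0), date = character(0),
      time = character(0), area_px = numeric(0)
    )
  }
  records <- records[order(records$tray, records$pot, records$date,
                           records$time), , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(out_csv)) {
    utils::write.csv(records, out_csv, row.names = FALSE)
  }
  records
}

#' Extract one pot's growth series
#'
#' Time-sorted `(timestamp, area)` sequence for a (tray, pot) key; gaps
#' are preserved, nothing is interpolated or smoothed. An unknown key
#' yields an empty series.
#'
#' @param records Data frame from [batch_process()].
#' @param tray,pot Key to extract.
#' @return Data frame with `datetime` (POSIXct), `day` (days since the
#'   first record of this series), `area_px`, time-sorted.
#' @export
growth_series <- function(records, tray, pot) {
  s <- records[records$tray == tray & records$pot == pot, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(
      datetime = as.POSIXct(character(0), tz = "UTC"),
      day = numeric(0), area_px = numeric(0)
    ))
  }
  dt <- as.POSIXct(
    paste(s$date, sub("^(\\d{2})(\\d{2})$", "\\1:\\2", s$time)),
    tz = "UTC"
  )
  o <- order(dt)
  dt <- dt[o]
  data.frame(
    datetime = dt,
    day = as.numeric(difftime(dt, dt[1], units = "days")),
    area_px = s$area_px[o]
  )
}

#' Growth slope within a day window
#'
#' Least-squares slope of area versus time for records whose `day` falls
#' in `[window[1], window[2]]`, in pixels per day.
#'
#' @param series Data frame from [growth_series()].
#' @param window Length-2 numeric day interval.
#' @return Slope in px/day, or `NA` (with a warning) when fewer than two
#'   points fall in the window.
#' @export
growth_slope <- function(series, window = range(series$day)) {
  s <- series[series$day >= window[1] & series$day <= window[2], ,
              drop = FALSE]
  if (nrow(s) < 2) {
    warning("fewer than two points in the window; slope undefined")
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(area_px ~ day, data = s))[2])
}
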