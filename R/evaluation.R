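#' Radial landmark errors in millimetres
#'
#' Pairs predicted and ground-truth landmark sets by `image_id`, maps both
#' to the original (calibrated) frame, and computes Euclidean distances
#' scaled by the calibration's mm-per-pixel. Because the network-frame
#' resize is anisotropic, errors are always measured after mapping back to
#' the original frame, where the pixel pitch is isotropic.
#'
#' @param predicted,truth Lists of [landmark_set] objects.
#' @param calibration A [ceph_calibration()]. For phantom data pass a
#'   calibration whose `original_size` is the phantom frame and
#'   `mm_per_pixel_original` the phantom pixel pitch (use 1 to read errors
#'   in pixels).
#' @param strata Optional named character vector (`image_id` -> stratum
#'   tag) carried into the table for stratified reports.
#' @return A data frame (`error_table`) with columns `image_id`,
#'   `landmark`, `error_mm`, `stratum`.
#' @export
radial_errors <- function(predicted, truth, calibration = ceph_calibration(),
                          strata = NULL) {
  pid <- vapply(predicted, function(l) l$image_id, "")
  tid <- vapply(truth, function(l) l$image_id, "")
  missing <- setdiff(union(pid, tid), intersect(pid, tid))
  if (length(missing))
    stop(sprintf("unpaired image ids: %s", paste(missing, collapse = ", ")))
  ow <- calibration$original_size[1]; oh <- calibration$original_size[2]
  rows <- lapply(seq_along(predicted), function(i) {
    p <- map_coordinates(predicted[[i]], ow, oh, frame = "original")
    t <- map_coordinates(truth[[match(pid[i], tid)]], ow, oh,
                         frame = "original")
    d <- sqrt(rowSums((p$points - t$points)^2)) *
      calibration$mm_per_pixel_original
    data.frame(image_id = pid[i], landmark = ceph_landmark_names(),
               error_mm = unname(d),
               stratum = if (is.null(strata)) NA_character_
                         else unname(strata[pid[i]]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("error_table", "data.frame")
  out
}

#' Mean radial error
#'
#' Arithmetic mean and population standard deviation of the radial errors,
#' overall or per group.
#'
#' @param table An `error_table` from [radial_errors()].
#' @param group_by `"overall"`, `"landmark"`, `"image_id"`, or `"stratum"`.
#' @return Data frame with columns `group`, `n`, `mre`, `sd`.
#' @export
mre <- function(table, group_by = "overall") {
  stopifnot(nrow(table) > 0)
  g <- if (group_by == "overall") rep("overall", nrow(table))
       else table[[group_by]]
  keep <- !is.na(g)
  sp <- split(table$error_mm[keep], g[keep])
  out <- data.frame(group = names(sp),
                    n = vapply(sp, length, 0L),
                    mre = vapply(sp, mean, 0),
                    sd = vapply(sp, pop_sd, 0), row.names = NULL)
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Successful detection rate
#'
#' Percentage of radial errors strictly below each threshold (an error
#' exactly at a threshold counts as a miss), per landmark and overall.
#'
#' @param table An `error_table`.
#' @param thresholds Ascending thresholds in mm.
#' @param strict Use strict `<` (default) or `<=` at the threshold.
#' @return An object of class `sdr_report`: data frame with one row per
#'   landmark plus `"overall"`, SDR columns per threshold, and MRE/SD.
#' @export
sdr <- function(table, thresholds = c(1, 2, 3, 4, 5), strict = TRUE) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  cmp <- if (strict) `<` else `<=`
  one <- function(err) {
    c(vapply(thresholds, function(t) 100 * mean(cmp(err, t)), 0),
      mean(err), pop_sd(err))
  }
  groups <- c(split(table$error_mm, table$landmark),
              list(overall = table$error_mm))
  m <- t(vapply(groups, one, numeric(length(thresholds) + 2)))
  out <- data.frame(group = rownames(m), m, row.names = NULL)
  names(out) <- c("group", sprintf("sdr_%g", thresholds), "mre", "sd")
  attr(out, "thresholds") <- thresholds
  attr(out, "boundary") <- if (strict) "strict" else "inclusive"
  attr(out, "sd_type") <- "population"
  class(out) <- c("sdr_report", "data.frame")
  out
}

#' Cumulative radial-error curve
#'
#' Empirical CDF of the radial errors evaluated on a grid (fraction of
#' errors less than or equal to each grid value).
#'
#' @param table An `error_table`.
#' @param grid Millimetre values at which to evaluate the curve.
#' @return Data frame with columns `mm` and `fraction`.
#' @export
cumulative_curve <- function(table, grid = seq(0, 5, by = 0.1)) {
  err <- sort(table$error_mm)
  data.frame(mm = grid,
             fraction = vapply(grid, function(g) mean(err <= g), 0))
}

#' Stratified SDR/MRE report
#'
#' One [sdr()] report per stratum plus the overall report; strata without
#' rows are flagged as absent.
#'
#' @param table An `error_table` with a `stratum` column.
#' @param thresholds Passed to [sdr()].
#' @param strata Optional stratum levels to report (defaults to the levels
#'   present).
#' @return Named list of `sdr_report` objects (plus `overall`); absent
#'   strata are `NULL` entries.
#' @export
stratified_report <- function(table, thresholds = c(1, 2, 3, 4, 5),
                              strata = NULL) {
  if (all(is.na(table$stratum))) stop("no stratum tags in the error table")
  lv <- if (is.null(strata)) sort(unique(stats::na.omit(table$stratum)))
        else strata
  out <- lapply(lv, function(s) {
    sub <- table[!is.na(table$stratum) & table$stratum == s, ]
    if (!nrow(sub)) NULL else sdr(sub, thresholds)
  })
  names(out) <- as.character(lv)
  out$overall <- sdr(table, thresholds)
  out
}

#' Write an SDR report to CSV/JSON
#'
#' @param report An `sdr_report`.
#' @param path Output path (`.csv` or `.json` decides the format).
#' @export
write_sdr_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(boundary = attr(report, "boundary"),
                              sd_type = attr(report, "sd_type"),
                              rows = report),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
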