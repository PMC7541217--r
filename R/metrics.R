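#' Point-to-point landmark error
#'
#' Euclidean distance in mm between the manual (reference) and estimated
#' positions of one landmark over a series of images. The landmark error
#' (LE) reported in evaluation tables is the mean of these distances; the SD
#' alongside is the sample (n-1) standard deviation.
#'
#' @param manual_mm,estimated_mm Matrices (n x 2) of positions in mm (a
#'   single `c(x, y)` pair is accepted).
#' @return Numeric vector of per-image distances (mm).
#' @export
landmark_error <- function(manual_mm, estimated_mm) {
  m <- rbind(manual_mm)
  a <- rbind(estimated_mm)
  if (nrow(m) == 0) stop("no observations", call. = FALSE)
  stopifnot(nrow(m) == nrow(a))
  as.numeric(sqrt((m[, 1] - a[, 1])^2 + (m[, 2] - a[, 2])^2))
}

#' Successful detection rate
#'
#' Percentage of cases whose error is strictly below the precision radius z:
#' `SDR = #{i : ||m_i - a_i|| < z} / n * 100`. The inequality is strict, so
#' an error exactly equal to z does not count as a success.
#'
#' @param errors_mm Numeric vector of per-case errors (mm).
#' @param z Precision radius (mm), > 0.
#' @return Percentage in \[0, 100\].
#' @export
sdr <- function(errors_mm, z) {
  if (length(errors_mm) == 0) stop("no errors supplied", call. = FALSE)
  stopifnot(z > 0)
  100 * mean(errors_mm < z)
}

#' Per-landmark evaluation report
#'
#' Builds the standard evaluation table: one row per landmark with the mean
#' landmark error, its SD, and SDR at 2 / 2.5 / 3 / 4 mm, plus an aggregate
#' row of unweighted column means across landmarks (see [aggregate_report]).
#'
#' @param truths List of reference [landmark_set] (one per image).
#' @param predictions List of predicted [landmark_set], parallel.
#' @param zs SDR radii in mm.
#' @return An `evaluation_report`: data frame with columns `name`,
#'   `le_mean`, `le_sd`, `sdr2`, `sdr2.5`, `sdr3`, `sdr4` and attributes
#'   `aggregate` (named numeric) and `n_images`.
#' @export
evaluate_landmarks <- function(truths, predictions, zs = c(2, 2.5, 3, 4)) {
  stopifnot(length(truths) == length(predictions), length(truths) >= 1)
  nms <- truths[[1]]$name
  rows <- lapply(nms, function(nm) {
    m <- t(vapply(truths, landmark_xy, numeric(2), name = nm))
    a <- t(vapply(predictions, landmark_xy, numeric(2), name = nm))
    e <- landmark_error(m, a)
    stats <- c(mean(e), if (length(e) > 1) stats::sd(e) else 0,
               vapply(zs, sdr, numeric(1), errors_mm = e))
    stats
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("le_mean", "le_sd", paste0("sdr", sub("\\.0$", "", zs)))
  tab <- cbind(name = nms, tab, stringsAsFactors = FALSE)
  attr(tab, "aggregate") <- aggregate_report(tab)
  attr(tab, "n_images") <- length(truths)
  class(tab) <- c("evaluation_report", "data.frame")
  tab
}

#' Aggregate row of an evaluation table
#'
#' Unweighted arithmetic mean of each numeric column across the landmark
#' rows (rounding happens only at presentation).
#'
#' @param report Data frame with one row per landmark and numeric metric
#'   columns (e.g. an `evaluation_report`, or the published per-landmark
#'   table from [reported_performance]).
#' @return Named numeric vector of column means.
#' @export
aggregate_report <- function(report) {
  num <- vapply(report, is.numeric, TRUE)
  if (anyNA(report[num])) stop("incomplete report rows", call. = FALSE)
  colMeans(report[, num, drop = FALSE])
}

#' Correlation between landmark error and SDR
#'
#' Sample Pearson correlation between the per-landmark mean error column and
#' the SDR(2 mm) column; landmarks that are hard to trace have both a larger
#' error and a lower detection rate, so the coefficient is expected to be
#' clearly negative.
#'
#' @param report Data frame with columns `le_mean` and `sdr2`.
#' @return Pearson r.
#' @export
error_sdr_correlation <- function(report) {
  x <- report$le_mean
  y <- report$sdr2
  if (length(x) < 3) stop("need at least 3 landmark rows", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Published per-landmark benchmark table
#'
#' The per-landmark mean error, SD and SDR values published for this
#' detection protocol on the ISBI 2015 lateral-cephalogram test set
#' (150 training / 250 test images at 0.1 mm/px), shipped as package data.
#' Useful as reference input for [aggregate_report] and
#' [error_sdr_correlation].
#'
#' @return Data frame with columns `name`, `le_mean`, `le_sd`, `sdr2`,
#'   `sdr2.5`, `sdr3`, `sdr4` (19 rows).
#' @export
reported_performance <- function() {
  utils::read.csv(system.file("extdata", "reported_landmark_performance.csv",
                              package = "cephmark"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}
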