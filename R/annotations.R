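#' Read an ISBI-style landmark annotation file
#'
#' One line per landmark, `"x,y"` in pixel units, lines 1..n in registry
#' order. Distribution files may carry extra trailing rows (e.g. challenge
#' class labels); only the first `length(names)` coordinate lines are
#' landmarks and any extra lines trigger a warning naming their count.
#' Pixel coordinates are converted to millimetres via the pixel spacing.
#'
#' @param path Annotation text file.
#' @param spacing_mm Millimetres per pixel used to convert to mm.
#' @param names Landmark registry the file follows; default the canonical 19.
#' @param provenance Provenance tag for the resulting set.
#' @return A [landmark_set] in mm.
#' @export
read_annotation <- function(path, spacing_mm = 0.1,
                            names = ceph_landmark_names(),
                            provenance = "annotatorA") {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  n <- length(names)
  if (length(lines) < n) {
    stop(sprintf("annotation file %s has %d coordinate lines; %d required",
                 path, length(lines), n), call. = FALSE)
  }
  coords <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    parts <- strsplit(lines[[k]], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(vals) != 2 || anyNA(vals)) {
      stop(sprintf("malformed coordinate on line %d of %s: '%s'",
                   k, path, lines[[k]]), call. = FALSE)
    }
    coords[k, ] <- vals
  }
  if (length(lines) > n) {
    warning(sprintf("%s: %d extra trailing line(s) ignored",
                    path, length(lines) - n), call. = FALSE)
  }
  landmark_set(px_to_mm(coords[, 1], spacing_mm),
               px_to_mm(coords[, 2], spacing_mm),
               names = names, provenance = provenance)
}

#' Write a landmark set as an annotation file
#'
#' Inverse of [read_annotation]: coordinates are converted from mm to pixel
#' units (not rounded, so the round trip is exact to floating precision)
#' and written one `"x,y"` line per landmark in registry order.
#'
#' @param ls A [landmark_set].
#' @param path Output path.
#' @param spacing_mm Millimetres per pixel.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ls, path, spacing_mm = 0.1) {
  stopifnot(inherits(ls, "landmark_set"))
  lines <- sprintf("%.12g,%.12g", ls$x_mm / spacing_mm, ls$y_mm / spacing_mm)
  writeLines(lines, path)
  invisible(path)
}

#' Write a prediction report
#'
#' Flat CSV with one row per detected landmark: the estimated point, its
#' 95% confidence ellipse (centre, semi-axes in mm, major-axis angle in
#' degrees from +x), the maximal pixel score in the ROI, and the number of
#' grid points the coarse screening stage classified as true.
#'
#' @param predictions A list of `ceph_prediction` objects (see
#'   [detect_landmark]) or a data frame already in report layout.
#' @param path Output CSV path.
#' @return Invisibly, the report data frame.
#' @export
write_prediction_report <- function(predictions, path) {
  df <- if (is.data.frame(predictions)) predictions
    else if (length(predictions)) {
      do.call(rbind, c(lapply(predictions, as.data.frame.ceph_prediction),
                       list(make.row.names = FALSE)))
    }
  cols <- c("landmark", "x_mm", "y_mm", "ellipse_cx", "ellipse_cy",
            "semi_major_mm", "semi_minor_mm", "angle_deg", "max_score",
            "n_true_lrs")
  if (is.null(df) || nrow(df) == 0) {
    df <- as.data.frame(stats::setNames(
      c(list(character()), rep(list(numeric()), 8), list(integer())), cols))
  }
  stopifnot(all(cols %in% names(df)))
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(df)
}

#' Read back a prediction report
#' @param path CSV written by [write_prediction_report].
#' @return Data frame.
#' @export
read_prediction_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
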