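#' Cephalogram image container
#'
#' A grayscale raster with a physical pixel spacing. Pixel values are kept
#' on the 8-bit \[0, 255\] scale; pixel indices are 0-based with the origin at
#' the top-left pixel, x along the width (columns) and y along the height
#' (rows). The physical frame places the origin at the centre of pixel
#' (0, 0), so `mm = px * spacing_mm` in both axes. All thresholds in the
#' detection pipeline are metric; pixels appear only at I/O and sampling
#' boundaries.
#'
#' @param pixels Numeric matrix (rows = y / height, cols = x / width),
#'   intensities in \[0, 255\].
#' @param spacing_mm Millimetres per pixel (> 0); default 0.1, i.e. one
#'   pixel is a 0.1 mm square.
#' @return A `ceph_image` object.
#' @export
ceph_image <- function(pixels, spacing_mm = 0.1) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0) {
    stop("spacing_mm must be a positive scalar", call. = FALSE)
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie within [0, 255]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         width_px = ncol(pixels), height_px = nrow(pixels)),
    class = "ceph_image"
  )
}

#' @export
print.ceph_image <- function(x, ...) {
  cat(sprintf("<ceph_image %d x %d px, %.4g mm/px (%.1f x %.1f mm)>\n",
              x$width_px, x$height_px, x$spacing_mm,
              x$width_px * x$spacing_mm, x$height_px * x$spacing_mm))
  invisible(x)
}

#' Convert pixel indices to millimetres and back
#'
#' 0-based pixel index `p` maps to `p * spacing_mm`; the inverse rounds to
#' the nearest grid point, so the round trip is exact on pixel centres.
#'
#' @param px,mm Numeric vector of pixel indices / mm coordinates.
#' @param spacing_mm Millimetres per pixel.
#' @return Numeric vector.
#' @export
px_to_mm <- function(px, spacing_mm) px * spacing_mm

#' @rdname px_to_mm
#' @export
mm_to_px <- function(mm, spacing_mm) as.integer(round(mm / spacing_mm))

#' Read a grayscale cephalogram image
#'
#' PNG and TIFF rasters are supported (8-bit grayscale; RGB input is
#' converted by channel averaging). Values are rescaled to \[0, 255\].
#'
#' @param path File path, extension `.png`, `.tif` or `.tiff`.
#' @param spacing_mm Millimetres per pixel of the scan.
#' @return A [ceph_image].
#' @export
read_ceph_image <- function(path, spacing_mm = 0.1) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use png or tiff)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  ceph_image(arr * 255, spacing_mm = spacing_mm)
}

#' Write a cephalogram image
#'
#' @param img A [ceph_image].
#' @param path Output path; format chosen from the extension (png/tif/tiff).
#' @return Invisibly, `path`.
#' @export
write_ceph_image <- function(img, path) {
  stopifnot(inherits(img, "ceph_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / 255
  switch(ext,
    png = png::writePNG(norm, target = path),
    tif = ,
    tiff = tiff::writeTIFF(norm, where = path, bits.per.sample = 8),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Block-mean downsampling
#'
#' Reduces the raster by an integer factor, replacing each `factor x factor`
#' block with its mean; trailing rows/columns that do not fill a block are
#' dropped. The pixel spacing grows by the same factor. Used by the
#' low-resolution screening stage (factor 3 by default there).
#'
#' @param img A [ceph_image].
#' @param factor Positive integer.
#' @return A [ceph_image] at the coarser spacing.
#' @export
downsample_image <- function(img, factor) {
  stopifnot(inherits(img, "ceph_image"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1) return(img)
  h <- (img$height_px %/% factor) * factor
  w <- (img$width_px %/% factor) * factor
  if (h < factor || w < factor) {
    stop("image smaller than one block at this factor", call. = FALSE)
  }
  px <- img$pixels[seq_len(h), seq_len(w), drop = FALSE]
  # mean over factor x factor blocks via two strided reductions
  px <- matrix(colMeans(matrix(px, nrow = factor)), nrow = h %/% factor)
  px <- t(matrix(colMeans(matrix(t(px), nrow = factor)), nrow = w %/% factor))
  ceph_image(px, spacing_mm = img$spacing_mm * factor)
}
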