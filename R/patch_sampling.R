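#' Sampling configuration for the two screening stages
#'
#' All geometric knobs of the detector are metric. Defaults follow the
#' full-scale protocol: the coarse stage (LRS) samples the 3x-downsampled
#' image on a 3 mm lattice with 9.1 mm square patches and is trained with
#' true patches drawn within 18 mm of the landmark; the fine stage (HRS)
#' screens every pixel of a 40 mm square ROI at native resolution, trained
#' with true patches within 0.9 mm and false patches in the 2.1-40 mm
#' annulus; 200 true and 500 false patches are drawn per image
#' (700 per image, i.e. 105,000 patches from a 150-image training set).
#'
#' `hrs_pixel_stride_px` (default 1 = every ROI pixel) subsamples the ROI
#' lattice and is an extension for desk-scale runs.
#'
#' @param lrs_stride_mm Grid stride of the coarse stage, mm.
#' @param patch_side_mm Side of the square patch window, mm. The pixel side
#'   at the working scale is `round(patch_side_mm / spacing)` forced odd, so
#'   the centre pixel is well defined.
#' @param lrs_patch_side_mm Patch side used by the coarse stage; `NULL`
#'   (default) means `patch_side_mm`, i.e. the same metric field of view at
#'   both scales. An extension knob: desk-scale synthetic structures carry
#'   no surrounding anatomy, so the coarse stage needs a window wide enough
#'   to contain a whole structure to tell neighbours apart.
#' @param lrs_downsample_factor Integer block-mean downsampling factor for
#'   the coarse stage (fine stage always runs at native resolution).
#' @param roi_side_mm Side of the square ROI proposed by the coarse stage.
#' @param hrs_pixel_stride_px Integer stride over ROI pixels.
#' @param lrs_true_radius_mm Radius of the coarse-stage true region.
#' @param hrs_true_radius_mm,hrs_false_inner_mm,hrs_false_outer_mm Fine-stage
#'   true disc radius and false annulus bounds (mm); must satisfy
#'   `true < inner < outer`.
#' @param n_true,n_false Patches per image per class (NT, NF).
#' @param n_hard_false Additional false-labelled patches per image drawn
#'   from the *true* regions of the other landmarks of the ground-truth set
#'   (hard negatives). Default 0 = pure area-uniform false sampling. On
#'   real radiographs the false class is densely textured everywhere, so
#'   uniform sampling suffices; on sparse synthetic frames other structures
#'   occupy ~1% of the false region and would otherwise be almost absent
#'   from training.
#' @param rng_seed Optional integer seed for reproducible sampling.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(lrs_stride_mm = 3.0, patch_side_mm = 9.1,
                            lrs_patch_side_mm = NULL,
                            lrs_downsample_factor = 3, roi_side_mm = 40.0,
                            hrs_pixel_stride_px = 1L,
                            lrs_true_radius_mm = 18.0,
                            hrs_true_radius_mm = 0.9,
                            hrs_false_inner_mm = 2.1,
                            hrs_false_outer_mm = 40.0,
                            n_true = 200L, n_false = 500L,
                            n_hard_false = 0L, rng_seed = NULL) {
  cfg <- list(lrs_stride_mm = lrs_stride_mm, patch_side_mm = patch_side_mm,
              lrs_patch_side_mm = if (is.null(lrs_patch_side_mm))
                patch_side_mm else lrs_patch_side_mm,
              lrs_downsample_factor = as.integer(lrs_downsample_factor),
              roi_side_mm = roi_side_mm,
              hrs_pixel_stride_px = as.integer(hrs_pixel_stride_px),
              lrs_true_radius_mm = lrs_true_radius_mm,
              hrs_true_radius_mm = hrs_true_radius_mm,
              hrs_false_inner_mm = hrs_false_inner_mm,
              hrs_false_outer_mm = hrs_false_outer_mm,
              n_true = as.integer(n_true), n_false = as.integer(n_false),
              n_hard_false = as.integer(n_hard_false), rng_seed = rng_seed)
  with(cfg, {
    stopifnot(lrs_stride_mm > 0, patch_side_mm > 0, lrs_patch_side_mm > 0,
              roi_side_mm > 0,
              lrs_downsample_factor >= 1, hrs_pixel_stride_px >= 1,
              n_true >= 1, n_false >= 1, n_hard_false >= 0)
    if (!(hrs_true_radius_mm > 0 &&
          hrs_true_radius_mm < hrs_false_inner_mm &&
          hrs_false_inner_mm < hrs_false_outer_mm)) {
      stop("need 0 < hrs_true_radius < hrs_false_inner < hrs_false_outer",
           call. = FALSE)
    }
  })
  class(cfg) <- "sampling_config"
  cfg
}

#' Desk-scale sampling profile
#'
#' A scaled-down profile for synthetic data, where structures carry no
#' anatomical context: the coarse true radius shrinks to the patch's
#' visibility range, the ROI to 20 mm (a 40 mm ROI would span almost a whole
#' 50 mm synthetic frame), and the ROI lattice is strided by 2 px. The
#' coarse stage runs at native resolution here: the synthetic structures are
#' only ~1 mm across, so they must be told apart by sub-millimetre shape
#' detail that block-mean downsampling would erase.
#'
#' @param ... Overrides passed on to [sampling_config].
#' @return A `sampling_config`.
#' @export
desk_sampling_config <- function(...) {
  defaults <- list(lrs_stride_mm = 1.0, patch_side_mm = 1.5,
                   lrs_patch_side_mm = 3.1,
                   lrs_downsample_factor = 1L, roi_side_mm = 20.0,
                   hrs_pixel_stride_px = 2L, lrs_true_radius_mm = 0.9,
                   hrs_true_radius_mm = 0.9, hrs_false_inner_mm = 2.1,
                   hrs_false_outer_mm = 20.0, n_true = 60L, n_false = 300L,
                   n_hard_false = 60L)
  over <- list(...)
  do.call(sampling_config, utils::modifyList(defaults, over))
}

# odd patch side in pixels at a working spacing
patch_side_px <- function(patch_side_mm, spacing_mm) {
  s <- as.integer(round(patch_side_mm / spacing_mm))
  if (s %% 2L == 0L) s <- s + 1L
  max(s, 1L)
}

# run expr under a temporary RNG state seeded with `seed` (NULL = leave RNG)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

new_patch_batch <- function(centers_mm, image, side_px, scale,
                            oob = NULL, windows = NULL, labels = NULL) {
  structure(list(centers_mm = centers_mm, image = image,
                 side_px = side_px, spacing_mm = image$spacing_mm,
                 scale = scale, oob = oob, windows = windows,
                 labels = labels, n = nrow(centers_mm)),
            class = "patch_batch")
}

#' @export
print.patch_batch <- function(x, ...) {
  cat(sprintf(
    "<patch_batch: %d patches, %d px side, %.4g mm/px, scale = %s%s>\n",
    x$n, x$side_px, x$spacing_mm, x$scale,
    if (is.null(x$windows)) " (lazy)" else ""))
  invisible(x)
}

#' Number of patches in a batch
#' @param batch A `patch_batch`.
#' @return Integer count.
#' @export
n_patches <- function(batch) batch$n

#' Extract pixel windows for (a subset of) a patch batch
#'
#' Windows are square intensity arrays of odd side centred on the patch
#' pixel; windows that overrun the image border are replicate-padded.
#' Batches are lazy by default, so ROI-scale screening can stream windows
#' in chunks instead of materialising the whole ROI.
#'
#' @param batch A `patch_batch`.
#' @param idx Indices of patches to extract (default all).
#' @return Numeric array `side x side x length(idx)`.
#' @export
patch_windows <- function(batch, idx = seq_len(batch$n)) {
  if (!is.null(batch$windows)) return(batch$windows[, , idx, drop = FALSE])
  cpx <- mm_to_px(batch$centers_mm[idx, 1], batch$spacing_mm)
  cpy <- mm_to_px(batch$centers_mm[idx, 2], batch$spacing_mm)
  cpp_extract_patches(batch$image$pixels, cpx, cpy, batch$side_px)
}

materialize_patches <- function(batch) {
  if (is.null(batch$windows)) batch$windows <- patch_windows(batch)
  batch
}

#' Coarse-stage sampling grid
#'
#' Downsamples the image by `lrs_downsample_factor` (block mean) and lays a
#' regular lattice of patch centres with stride `lrs_stride_mm` covering the
#' whole image, starting at the origin pixel. Patches are extracted at the
#' downsampled scale; windows that overrun the border are replicate-padded
#' and flagged in `$oob`.
#'
#' @param image A [ceph_image].
#' @param cfg A [sampling_config].
#' @return A `patch_batch` with materialised windows (centres in mm of the
#'   native frame).
#' @export
lrs_grid <- function(image, cfg) {
  work <- downsample_image(image, cfg$lrs_downsample_factor)
  side <- patch_side_px(cfg$lrs_patch_side_mm, work$spacing_mm)
  if (side > work$width_px || side > work$height_px) {
    stop("patch larger than image at the working scale", call. = FALSE)
  }
  xs <- seq(0, (image$width_px - 1) * image$spacing_mm, by = cfg$lrs_stride_mm)
  ys <- seq(0, (image$height_px - 1) * image$spacing_mm, by = cfg$lrs_stride_mm)
  centers <- cbind(x_mm = rep(xs, times = length(ys)),
                   y_mm = rep(ys, each = length(xs)))
  cpx <- mm_to_px(centers[, 1], work$spacing_mm)
  cpy <- mm_to_px(centers[, 2], work$spacing_mm)
  # clamp centres that fall off the cropped working raster
  cpx <- pmin(pmax(cpx, 0L), work$width_px - 1L)
  cpy <- pmin(pmax(cpy, 0L), work$height_px - 1L)
  half <- side %/% 2L
  oob <- (cpx - half < 0L) | (cpy - half < 0L) |
    (cpx + half > work$width_px - 1L) | (cpy + half > work$height_px - 1L)
  batch <- new_patch_batch(centers, work, side, "downsampled", oob = oob)
  materialize_patches(batch)
}

#' Fine-stage ROI candidate pixels
#'
#' Enumerates every pixel of the `roi_side_mm` square centred on
#' `center_mm` (half-open in mm, so an unclipped 40 mm ROI at 0.1 mm/px has
#' exactly 400 x 400 pixels), clipped to the image bounds and subsampled by
#' `hrs_pixel_stride_px`. Each candidate pixel yields one full-resolution
#' patch of side `patch_side_mm`. The returned batch is lazy: call
#' [patch_windows] to extract windows.
#'
#' @param center_mm Numeric `c(x, y)` ROI centre in mm; must be inside the
#'   image.
#' @param image A [ceph_image].
#' @param cfg A [sampling_config].
#' @return A lazy `patch_batch` at native resolution.
#' @export
hrs_roi_pixels <- function(center_mm, image, cfg) {
  s <- image$spacing_mm
  half <- cfg$roi_side_mm / 2
  wmax <- (image$width_px - 1) * s
  hmax <- (image$height_px - 1) * s
  if (center_mm[1] < 0 || center_mm[1] > wmax ||
      center_mm[2] < 0 || center_mm[2] > hmax) {
    stop("ROI centre outside image", call. = FALSE)
  }
  lo <- function(c) ceiling((c - half) / s - 1e-9)
  hi <- function(c) ceiling((c + half) / s - 1e-9) - 1
  px <- seq(max(lo(center_mm[1]), 0), min(hi(center_mm[1]), image$width_px - 1))
  py <- seq(max(lo(center_mm[2]), 0), min(hi(center_mm[2]), image$height_px - 1))
  if (length(px) == 0 || length(py) == 0) {
    stop("ROI entirely outside image", call. = FALSE)
  }
  k <- cfg$hrs_pixel_stride_px
  px <- px[seq(1, length(px), by = k)]
  py <- py[seq(1, length(py), by = k)]
  centers <- cbind(x_mm = rep(px, times = length(py)) * s,
                   y_mm = rep(py, each = length(px)) * s)
  side <- patch_side_px(cfg$patch_side_mm, s)
  new_patch_batch(centers, image, side, "full_resolution")
}

# area-uniform sample of n pixel positions (working scale) whose mm distance
# to `lm` lies in [rmin, rmax]; rejection sampling from the bounding box
sample_region_px <- function(n, lm_mm, work, rmin_mm, rmax_mm) {
  s <- work$spacing_mm
  xmax <- work$width_px - 1L
  ymax <- work$height_px - 1L
  # bounding box of the outer disc, clipped to the image
  bx <- c(max(0L, floor((lm_mm[1] - rmax_mm) / s)),
          min(xmax, ceiling((lm_mm[1] + rmax_mm) / s)))
  by <- c(max(0L, floor((lm_mm[2] - rmax_mm) / s)),
          min(ymax, ceiling((lm_mm[2] + rmax_mm) / s)))
  if (is.infinite(rmax_mm)) { bx <- c(0L, xmax); by <- c(0L, ymax) }
  out <- matrix(NA_integer_, 0, 2)
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(4L * (n - nrow(out)), 64L)
    cx <- sample.int(bx[2] - bx[1] + 1L, m, replace = TRUE) + bx[1] - 1L
    cy <- sample.int(by[2] - by[1] + 1L, m, replace = TRUE) + by[1] - 1L
    d <- sqrt((cx * s - lm_mm[1])^2 + (cy * s - lm_mm[2])^2)
    keep <- d >= rmin_mm & d <= rmax_mm
    out <- rbind(out, cbind(cx[keep], cy[keep]))
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("sampling region is empty at the image scale ",
           sprintf("(radii %.3g-%.3g mm)", rmin_mm, rmax_mm), call. = FALSE)
    }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Build a labelled training patch set for one landmark and stage
#'
#' Training data are generated by cropping: per image, `n_true` patch
#' centres are drawn area-uniformly from the stage's true region around the
#' ground-truth landmark and `n_false` from its false region, and a patch
#' window is cropped around each centre. Regions: coarse stage (LRS) true =
#' disc of `lrs_true_radius_mm`, false = its complement within the image
#' (both at the downsampled scale); fine stage (HRS) true = disc of
#' `hrs_true_radius_mm`, false = the `[hrs_false_inner_mm,
#' hrs_false_outer_mm]` annulus, at native resolution. When
#' `cfg$n_hard_false > 0`, that many additional false-labelled patches per
#' image are drawn from the true regions of the other landmarks (hard
#' negatives), cycled evenly. Total patch count is
#' `n_images * (n_true + n_false + n_hard_false)`; sampling is reproducible
#' under `cfg$rng_seed`.
#'
#' @param images List of [ceph_image].
#' @param truths List of ground-truth [landmark_set], parallel to `images`.
#' @param landmark_name Which landmark to build the set for.
#' @param stage `"LRS"` or `"HRS"`.
#' @param cfg A [sampling_config].
#' @return A `patch_batch` with materialised `windows` and integer `labels`
#'   (1 = true class, 0 = false class).
#' @export
build_training_set <- function(images, truths, landmark_name,
                               stage = c("LRS", "HRS"), cfg) {
  stage <- match.arg(stage)
  stopifnot(length(images) == length(truths), length(images) >= 1)
  with_seed(cfg$rng_seed, {
    per <- lapply(seq_along(images), function(i) {
      img <- images[[i]]
      lm <- landmark_xy(truths[[i]], landmark_name)
      if (stage == "LRS") {
        work <- downsample_image(img, cfg$lrs_downsample_factor)
        tr <- sample_region_px(cfg$n_true, lm, work, 0, cfg$lrs_true_radius_mm)
        fa <- sample_region_px(cfg$n_false, lm, work,
                               cfg$lrs_true_radius_mm, Inf)
      } else {
        work <- img
        tr <- sample_region_px(cfg$n_true, lm, work, 0, cfg$hrs_true_radius_mm)
        fa <- sample_region_px(cfg$n_false, lm, work,
                               cfg$hrs_false_inner_mm, cfg$hrs_false_outer_mm)
      }
      if (cfg$n_hard_false > 0L) {
        others <- setdiff(truths[[i]]$name, landmark_name)
        if (length(others)) {
          rtrue <- if (stage == "LRS") cfg$lrs_true_radius_mm else
            cfg$hrs_true_radius_mm
          pick <- rep_len(others, cfg$n_hard_false)
          hard <- do.call(rbind, lapply(others, function(o) {
            k <- sum(pick == o)
            if (k == 0) return(NULL)
            sample_region_px(k, landmark_xy(truths[[i]], o), work, 0, rtrue)
          }))
          fa <- rbind(fa, hard)
        }
      }
      side <- patch_side_px(
        if (stage == "LRS") cfg$lrs_patch_side_mm else cfg$patch_side_mm,
        work$spacing_mm)
      cen <- rbind(tr, fa)
      list(w = cpp_extract_patches(work$pixels, cen[, 1], cen[, 2], side),
           centers = cen * work$spacing_mm,
           labels = rep(c(1L, 0L), c(cfg$n_true, nrow(fa))),
           spacing = work$spacing_mm, side = side)
    })
    side <- per[[1]]$side
    n_tot <- sum(vapply(per, function(p) length(p$labels), 1L))
    windows <- array(0, c(side, side, n_tot))
    at <- 0L
    for (p in per) {
      k <- length(p$labels)
      windows[, , at + seq_len(k)] <- p$w
      at <- at + k
    }
    centers <- do.call(rbind, lapply(per, `[[`, "centers"))
    colnames(centers) <- c("x_mm", "y_mm")
    ref_img <- if (stage == "LRS") {
      downsample_image(images[[1]], cfg$lrs_downsample_factor)
    } else {
      images[[1]]
    }
    batch <- new_patch_batch(
      centers, ref_img, side,
      if (stage == "LRS") "downsampled" else "full_resolution",
      windows = windows,
      labels = unlist(lapply(per, `[[`, "labels")))
    batch$landmark <- landmark_name
    batch$stage <- stage
    batch
  })
}
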