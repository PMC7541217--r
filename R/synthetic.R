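#' Configuration of the synthetic cephalogram generator
#'
#' Generates grayscale frames with locally distinctive analytic structures
#' (smooth radial bumps, rings, anisotropic blobs and four-lobe crosses at
#' distinct amplitudes) whose true centres are known exactly, plus two
#' simulated annotators that jitter the truth with independent isotropic
#' Gaussian noise. The default jitter SDs (0.70 and 1.43 mm per axis,
#' emulating a careful and a less consistent observer) give an expected
#' inter-annotator distance of
#' `sqrt(pi/2) * sqrt(sdA^2 + sdB^2) = 2.0 mm`, matching the scale of
#' inter-observer variability on manually traced cephalograms.
#'
#' @param image_width_px,image_height_px Frame size in pixels.
#' @param spacing_mm Millimetres per pixel.
#' @param n_landmarks Number of landmarks (first n canonical names).
#' @param background,noise_sd Background intensity and Gaussian pixel noise
#'   SD on the 0-255 scale.
#' @param annotator_sd_mm Length-2 per-axis jitter SD (mm) of the two
#'   annotators.
#' @param layout_jitter_mm Per-case uniform displacement of each structure
#'   around its base layout position (mm).
#' @param min_separation_mm Minimal allowed distance between structure
#'   centres; layouts violating it are re-drawn (bounded retries).
#' @param margin_mm Keep structures at least this far from the frame edge.
#' @param rng_seed Master seed; each case derives its own stream from
#'   `(rng_seed, case_index)`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(image_width_px = 500L, image_height_px = 500L,
                             spacing_mm = 0.1, n_landmarks = 19L,
                             background = 20, noise_sd = 5,
                             annotator_sd_mm = c(0.70, 1.43),
                             layout_jitter_mm = 3, min_separation_mm = 9,
                             margin_mm = 5, rng_seed = 1L) {
  stopifnot(image_width_px > 0, image_height_px > 0, spacing_mm > 0,
            n_landmarks >= 1, n_landmarks <= 19, noise_sd >= 0,
            all(annotator_sd_mm >= 0), length(annotator_sd_mm) == 2)
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 spacing_mm = spacing_mm,
                 n_landmarks = as.integer(n_landmarks),
                 landmark_names = ceph_landmark_names()[seq_len(n_landmarks)],
                 background = background, noise_sd = noise_sd,
                 annotator_sd_mm = annotator_sd_mm,
                 layout_jitter_mm = layout_jitter_mm,
                 min_separation_mm = min_separation_mm,
                 margin_mm = margin_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param ... Overrides; desk default is 5 landmarks.
#' @export
desk_synthetic_config <- function(...) {
  do.call(synthetic_config,
          utils::modifyList(list(n_landmarks = 5L), list(...)))
}

# structure library: one entry per landmark index; shapes cycle and
# amplitudes descend so every landmark is photometrically distinct
structure_library <- function(n) {
  shapes <- rep(c("bump", "ring", "blob_x", "cross", "blob_y"), length.out = n)
  amps <- round(seq(235, 60, length.out = max(n, 2)))[seq_len(n)]
  # scales resolve sub-mm shape detail yet fit a ~3 mm field of view
  sigmas <- seq(0.45, 0.85, length.out = max(n, 2))[seq_len(n)]
  data.frame(shape = shapes, amplitude = amps, sigma_mm = sigmas,
             stringsAsFactors = FALSE)
}

# render one analytic structure onto intensity matrix `img` (in place value),
# centre (cx, cy) in mm; returns updated matrix
render_structure <- function(img, spacing, cx, cy, shape, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  ext <- 4 * sigma + 1  # render window half-width, mm
  xs <- max(0, floor((cx - ext) / spacing)):min(w - 1, ceiling((cx + ext) / spacing))
  ys <- max(0, floor((cy - ext) / spacing)):min(h - 1, ceiling((cy + ext) / spacing))
  if (length(xs) == 0 || length(ys) == 0) return(img)
  dx <- outer(rep(1, length(ys)), xs * spacing - cx)
  dy <- outer(ys * spacing - cy, rep(1, length(xs)))
  r2 <- (dx^2 + dy^2) / sigma^2
  f <- switch(shape,
    bump = exp(-r2 / 2),
    ring = exp(-(sqrt(r2) - 2)^2) + 0.6 * exp(-r2 / 0.5),
    blob_x = exp(-(dx^2 / (2 * (1.4 * sigma)^2) + dy^2 / (2 * (0.65 * sigma)^2))),
    blob_y = exp(-(dx^2 / (2 * (0.65 * sigma)^2) + dy^2 / (2 * (1.4 * sigma)^2))),
    cross = pmin(1, exp(-(dx^2 / (2 * (0.45 * sigma)^2))) +
                    exp(-(dy^2 / (2 * (0.45 * sigma)^2)))) *
      exp(-r2 / (2 * 1.2^2)),
    stop("unknown shape: ", shape)
  )
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * f
  img
}

# deterministic per-case seed below 2^31
case_seed <- function(master, case_index, salt = 0L) {
  as.integer((as.double(master) * 48271 + case_index * 30269 +
                salt * 7907) %% 2147483563) + 1L
}

base_layout <- function(cfg) {
  w <- (cfg$image_width_px - 1) * cfg$spacing_mm
  h <- (cfg$image_height_px - 1) * cfg$spacing_mm
  m <- cfg$margin_mm
  n <- cfg$n_landmarks
  k <- ceiling(sqrt(n))
  gx <- seq(m, w - m, length.out = k)
  gy <- seq(m, h - m, length.out = ceiling(n / k))
  cbind(x = rep(gx, times = ceiling(n / k))[seq_len(n)],
        y = rep(gy, each = k)[seq_len(n)])
}

#' Generate one synthetic case
#'
#' Deterministic under `(cfg$rng_seed, case_index)`: a frame with one
#' structure per landmark (each landmark sits at the analytic centre of its
#' structure), the exact truth, and two annotator jitters of the truth.
#'
#' @param cfg A [synthetic_config].
#' @param case_index Positive integer case number.
#' @return List with `image` ([ceph_image]), `truth`, `annotatorA`,
#'   `annotatorB` ([landmark_set]s) and `case_index`.
#' @export
generate_case <- function(cfg, case_index = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lib <- structure_library(cfg$n_landmarks)
  base <- base_layout(cfg)
  w <- (cfg$image_width_px - 1) * cfg$spacing_mm
  h <- (cfg$image_height_px - 1) * cfg$spacing_mm
  with_seed(case_seed(cfg$rng_seed, case_index), {
    pos <- NULL
    for (try in seq_len(50)) {
      jit <- matrix(stats::runif(2 * cfg$n_landmarks, -cfg$layout_jitter_mm,
                                 cfg$layout_jitter_mm), ncol = 2)
      cand <- base + jit
      cand[, 1] <- pmin(pmax(cand[, 1], cfg$margin_mm), w - cfg$margin_mm)
      cand[, 2] <- pmin(pmax(cand[, 2], cfg$margin_mm), h - cfg$margin_mm)
      dmin <- if (cfg$n_landmarks > 1) min(stats::dist(cand)) else Inf
      if (dmin >= cfg$min_separation_mm) {
        pos <- cand
        break
      }
    }
    if (is.null(pos)) {
      stop("could not place structures with the required separation",
           call. = FALSE)
    }
    img <- matrix(cfg$background, cfg$image_height_px, cfg$image_width_px)
    for (i in seq_len(cfg$n_landmarks)) {
      img <- render_structure(img, cfg$spacing_mm, pos[i, 1], pos[i, 2],
                              lib$shape[i], lib$amplitude[i], lib$sigma_mm[i])
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                          nrow(img), ncol(img))
    }
    img <- pmin(pmax(img, 0), 255)
    truth <- landmark_set(pos[, 1], pos[, 2], names = cfg$landmark_names,
                          provenance = "truth")
    jitter_ls <- function(sd, prov) {
      landmark_set(
        pmin(pmax(pos[, 1] + stats::rnorm(cfg$n_landmarks, 0, sd), 0), w),
        pmin(pmax(pos[, 2] + stats::rnorm(cfg$n_landmarks, 0, sd), 0), h),
        names = cfg$landmark_names, provenance = prov)
    }
    list(image = ceph_image(img, cfg$spacing_mm), truth = truth,
         annotatorA = jitter_ls(cfg$annotator_sd_mm[1], "annotatorA"),
         annotatorB = jitter_ls(cfg$annotator_sd_mm[2], "annotatorB"),
         case_index = case_index)
  })
}

#' Generate a synthetic train/test dataset on disk
#'
#' Writes `images/case_NNN.png`, annotation files under
#' `annotations/senior/` and `annotations/junior/` (ISBI dialect, pixel
#' units), exact truths under `annotations/truth/`, and a `manifest.json`
#' recording the split, seed and a config checksum. Case streams are
#' independent of the split sizes, so regeneration with the same seed is
#' identical.
#'
#' @param cfg A [synthetic_config].
#' @param n_train,n_test Number of cases per split.
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory?
#' @return The manifest (invisibly also written as JSON).
#' @export
generate_dataset <- function(cfg, n_train, n_test, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir, call. = FALSE)
  }
  for (d in c("images", "annotations/senior", "annotations/junior",
              "annotations/truth")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  n <- n_train + n_test
  cases <- data.frame(case = seq_len(n),
                      split = rep(c("train", "test"), c(n_train, n_test)),
                      image = sprintf("images/case_%03d.png", seq_len(n)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cs <- generate_case(cfg, i)
    write_ceph_image(cs$image, file.path(out_dir, cases$image[i]))
    for (sp in list(c("senior", "annotatorA"), c("junior", "annotatorB"),
                    c("truth", "truth"))) {
      write_annotation(cs[[if (sp[1] == "truth") "truth" else
        paste0("annotator", if (sp[1] == "senior") "A" else "B")]],
        file.path(out_dir, "annotations", sp[1],
                  sprintf("case_%03d.txt", i)),
        spacing_mm = cfg$spacing_mm)
    }
  }
  manifest <- list(seed = cfg$rng_seed, n_train = n_train, n_test = n_test,
                   spacing_mm = cfg$spacing_mm,
                   landmarks = cfg$landmark_names,
                   config_checksum = config_checksum(cfg),
                   cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# FNV-1a checksum of the serialized config (hex string); avoids an external
# digest dependency
config_checksum <- function(cfg) {
  bytes <- as.integer(charToRaw(paste(
    names(unlist(cfg)), unlist(cfg), collapse = "|")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
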