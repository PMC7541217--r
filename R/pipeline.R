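#' Model registry
#'
#' Detection needs one coarse-stage (LRS) and one fine-stage (HRS) model per
#' landmark — 38 models for the canonical 19-landmark registry. Models are
#' independent and trainable in any order; the registry keys them by
#' `(stage, landmark)`.
#'
#' @param landmark_names Landmark registry the models cover.
#' @return A `model_registry` environment-backed object.
#' @export
model_registry <- function(landmark_names = ceph_landmark_names()) {
  structure(list(store = new.env(parent = emptyenv()),
                 landmarks = landmark_names),
            class = "model_registry")
}

reg_key <- function(stage, landmark) paste(stage, landmark, sep = ":")

#' @rdname model_registry
#' @param registry A `model_registry`.
#' @param stage `"LRS"` or `"HRS"`.
#' @param landmark Landmark name.
#' @param model A `bcnn_model`.
#' @export
registry_add <- function(registry, stage, landmark, model) {
  stopifnot(inherits(registry, "model_registry"),
            stage %in% c("LRS", "HRS"), inherits(model, "bcnn_model"))
  if (!landmark %in% registry$landmarks) {
    stop("landmark not in registry: ", landmark, call. = FALSE)
  }
  assign(reg_key(stage, landmark), model, envir = registry$store)
  invisible(registry)
}

#' @rdname model_registry
#' @export
registry_get <- function(registry, stage, landmark) {
  key <- reg_key(stage, landmark)
  if (!exists(key, envir = registry$store, inherits = FALSE)) {
    stop(sprintf("no %s model for landmark '%s' in registry", stage, landmark),
         call. = FALSE)
  }
  get(key, envir = registry$store, inherits = FALSE)
}

#' @rdname model_registry
#' @export
registry_size <- function(registry) length(ls(registry$store))

#' @rdname model_registry
#' @export
registry_entries <- function(registry) {
  keys <- expand.grid(stage = c("LRS", "HRS"), landmark = registry$landmarks,
                      stringsAsFactors = FALSE)
  keys$present <- mapply(function(s, l) {
    exists(reg_key(s, l), envir = registry$store, inherits = FALSE)
  }, keys$stage, keys$landmark)
  keys
}

#' @export
print.model_registry <- function(x, ...) {
  cat(sprintf("<model_registry: %d/%d models over %d landmarks>\n",
              registry_size(x), 2 * length(x$landmarks), length(x$landmarks)))
  invisible(x)
}

# deterministic fan-out of a master seed to (stage, landmark, purpose) streams
derive_seed <- function(master, stage, landmark_index, salt = 0L) {
  stage_id <- match(stage, c("LRS", "HRS"))
  as.integer((as.double(master) * 7919 + stage_id * 104729 +
                landmark_index * 1009 + salt * 101) %% 2147483629) + 1L
}

#' Train detection models for a set of landmarks
#'
#' Convenience wrapper: builds the training patch set and fits one LRS and
#' one HRS classifier per landmark, returning a filled registry.
#'
#' @param images List of training [ceph_image].
#' @param truths Parallel list of ground-truth [landmark_set].
#' @param landmark_names Landmarks to train (default: registry of
#'   `truths[[1]]`).
#' @param sampling_cfg A [sampling_config].
#' @param arch A [cnn_architecture].
#' @param train_cfg A [training_config].
#' @param master_seed Integer; fans out deterministically per
#'   (stage, landmark).
#' @param verbose Print one line per trained model?
#' @return A `model_registry` holding `2 * length(landmark_names)` models.
#' @export
train_detector <- function(images, truths,
                           landmark_names = truths[[1]]$name,
                           sampling_cfg = desk_sampling_config(),
                           arch = desk_architecture(),
                           train_cfg = desk_training_config(),
                           master_seed = 1L, verbose = FALSE) {
  reg <- model_registry(landmark_names)
  for (k in seq_along(landmark_names)) {
    lm <- landmark_names[k]
    for (stage in c("LRS", "HRS")) {
      seed <- derive_seed(master_seed, stage, k)
      cfg_s <- sampling_cfg
      cfg_s$rng_seed <- seed
      ts <- build_training_set(images, truths, lm, stage, cfg_s)
      model <- build_model(arch, ts$side_px, seed = seed)
      cfg_t <- train_cfg
      cfg_t$rng_seed <- seed
      model <- train_model(model, ts, cfg_t)
      registry_add(reg, stage, lm, model)
      if (verbose) {
        message(sprintf("trained %s/%s: %d patches, final loss %.4f",
                        stage, lm, ts$n, utils::tail(model$loss_trace, 1)))
      }
    }
  }
  reg
}

#' Detect one landmark
#'
#' Runs the full two-stage screening for a single landmark: the coarse grid
#' is classified deterministically and the mean of the true positions
#' proposes the ROI centre (falling back to the maximum-probability grid
#' point when nothing is classified true); every ROI pixel is then screened
#' with `T` Monte-Carlo-dropout passes, scores are computed by
#' [score_weighting], and the landmark estimate is the [score_center] with
#' its 95% [confidence_ellipse]. If every score is zero (e.g. the dropout
#' passes all agree), the estimate falls back to the maximum-`mu` pixel with
#' a degenerate ellipse.
#'
#' @param image A [ceph_image].
#' @param landmark Landmark name.
#' @param registry A `model_registry` holding LRS and HRS models for the
#'   landmark.
#' @param sampling_cfg A [sampling_config].
#' @param score_cfg A [score_config].
#' @param T Monte-Carlo passes (default 17).
#' @param seed Master seed fanned out over the stages.
#' @return A `ceph_prediction` with the point, ellipse, the LRS centre and
#'   true count, the maximal score, and fallback flags.
#' @export
detect_landmark <- function(image, landmark, registry,
                            sampling_cfg = desk_sampling_config(),
                            score_cfg = score_config(), T = 17L, seed = 1L) {
  k <- match(landmark, registry$landmarks)
  if (is.na(k)) stop("landmark not in registry: ", landmark, call. = FALSE)
  lrs_model <- registry_get(registry, "LRS", landmark)
  hrs_model <- registry_get(registry, "HRS", landmark)

  grid <- lrs_grid(image, sampling_cfg)
  det <- predict_deterministic(lrs_model, grid)
  n_true <- sum(det$label)
  fallback_lrs <- n_true == 0L
  center <- if (fallback_lrs) {
    grid$centers_mm[which.max(det$prob_true), ]
  } else {
    lrs_center(grid$centers_mm[det$label, , drop = FALSE])
  }
  # keep the ROI centre inside the frame
  center <- pmin(pmax(center, 0),
                 c((image$width_px - 1), (image$height_px - 1)) *
                   image$spacing_mm)

  roi <- hrs_roi_pixels(center, image, sampling_cfg)
  bp <- predict_bayesian(hrs_model, roi, T = T,
                         seed = derive_seed(seed, "HRS", k, salt = 1L))
  scores <- score_weighting(bp, score_cfg)
  fallback_hrs <- !any(scores > 0)
  if (fallback_hrs) {
    point <- roi$centers_mm[which.max(bp$mu), ]
    ellipse <- structure(list(center_mm = point, semi_major_mm = 0,
                              semi_minor_mm = 0, angle_deg = 0,
                              coverage = 0.95, degenerate = TRUE),
                         class = "confidence_ellipse")
  } else {
    point <- score_center(roi$centers_mm, scores)
    ellipse <- confidence_ellipse(roi$centers_mm, scores)
  }

  structure(list(landmark = landmark,
                 point_mm = as.numeric(point),
                 ellipse = ellipse,
                 lrs_center_mm = as.numeric(center),
                 n_true_lrs = n_true,
                 max_score = if (fallback_hrs) 0 else max(scores),
                 fallback_used = fallback_lrs || fallback_hrs,
                 roi_n = roi$n, T = T),
            class = "ceph_prediction")
}

#' @export
print.ceph_prediction <- function(x, ...) {
  cat(sprintf(
    "<ceph_prediction %s: (%.2f, %.2f) mm, n_true_lrs = %d%s>\n",
    x$landmark, x$point_mm[1], x$point_mm[2], x$n_true_lrs,
    if (x$fallback_used) ", fallback" else ""))
  invisible(x)
}

#' @export
as.data.frame.ceph_prediction <- function(x, ...) {
  data.frame(landmark = x$landmark, x_mm = x$point_mm[1], y_mm = x$point_mm[2],
             ellipse_cx = x$ellipse$center_mm[1],
             ellipse_cy = x$ellipse$center_mm[2],
             semi_major_mm = x$ellipse$semi_major_mm,
             semi_minor_mm = x$ellipse$semi_minor_mm,
             angle_deg = x$ellipse$angle_deg,
             max_score = x$max_score, n_true_lrs = x$n_true_lrs,
             stringsAsFactors = FALSE)
}

#' Detect every landmark of the registry
#'
#' Landmarks are detected independently, in registry order; a failure on any
#' landmark aborts with an error naming it (no silent omissions).
#'
#' @inheritParams detect_landmark
#' @return List with `predictions` (list of `ceph_prediction`) and
#'   `landmarks` (a [landmark_set] with provenance `"prediction"`).
#' @export
detect_all <- function(image, registry,
                       sampling_cfg = desk_sampling_config(),
                       score_cfg = score_config(), T = 17L, seed = 1L) {
  preds <- vector("list", length(registry$landmarks))
  names(preds) <- registry$landmarks
  for (lm in registry$landmarks) {
    preds[[lm]] <- tryCatch(
      detect_landmark(image, lm, registry, sampling_cfg, score_cfg, T, seed),
      error = function(e) {
        stop(sprintf("detection failed for landmark '%s': %s",
                     lm, conditionMessage(e)), call. = FALSE)
      })
  }
  pts <- vapply(preds, function(p) p$point_mm, numeric(2))
  list(predictions = preds,
       landmarks = landmark_set(pts[1, ], pts[2, ],
                                names = registry$landmarks,
                                provenance = "prediction"))
}

#' Plot a detection on its image
#'
#' Draws the grayscale image with the estimated point and its 95% confidence
#' ellipse; optionally overlays the truth.
#'
#' @param x A `ceph_prediction`.
#' @param image The [ceph_image] it was computed on.
#' @param truth_mm Optional `c(x, y)` reference point in mm.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.ceph_prediction <- function(x, image, truth_mm = NULL, ...) {
  s <- image$spacing_mm
  w <- (image$width_px - 1) * s
  h <- (image$height_px - 1) * s
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", main = x$landmark)
  graphics::rasterImage(image$pixels / 255, 0, h, w, 0)
  if (!x$ellipse$degenerate) {
    graphics::lines(ellipse_points(x$ellipse), col = "dodgerblue", lwd = 2)
  }
  graphics::points(x$point_mm[1], x$point_mm[2], col = "dodgerblue", pch = 3)
  if (!is.null(truth_mm)) {
    graphics::points(truth_mm[1], truth_mm[2], col = "green3", pch = 4)
  }
  invisible(x)
}
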