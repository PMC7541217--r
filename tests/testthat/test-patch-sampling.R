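test_that("the coarse grid lattice covers the image at the metric stride", {
  img <- flat_image(300, 300)
  cfg <- sampling_config(lrs_stride_mm = 3, patch_side_mm = 9.1,
                         lrs_downsample_factor = 3)
  grid <- lrs_grid(img, cfg)
  # 300 px at 0.1 mm/px with a 3 mm (30 px) stride -> 10 x 10 lattice
  expect_equal(n_patches(grid), 100)
  expect_equal(grid$side_px, 31)        # 9.1 mm at 0.3 mm/px, forced odd
  expect_equal(grid$spacing_mm, 0.3, tolerance = 1e-12)
  # centres unique, in bounds, at exact stride multiples
  expect_equal(anyDuplicated(grid$centers_mm), 0)
  expect_true(all(grid$centers_mm >= 0 & grid$centers_mm <= 29.9))
  offs <- grid$centers_mm / 3
  expect_close(offs, round(offs), 1e-9)
})

test_that("grid patches are extracted with replicate padding at borders", {
  img <- flat_image(90, 90, value = 77)
  cfg <- sampling_config(lrs_stride_mm = 3, patch_side_mm = 4.5,
                         lrs_downsample_factor = 3)
  grid <- lrs_grid(img, cfg)
  expect_true(any(grid$oob))            # corner windows overrun
  w <- patch_windows(grid)
  expect_equal(dim(w)[1], grid$side_px)
  expect_true(all(w == 77))             # replicate padding of a flat image
})

test_that("patch extraction errors when the patch exceeds the image", {
  img <- flat_image(30, 30)
  cfg <- sampling_config(patch_side_mm = 12, lrs_downsample_factor = 3)
  expect_error(lrs_grid(img, cfg), "larger than image")
})

test_that("ROI pixel enumeration matches the clipped-rectangle count", {
  img <- flat_image(600, 600)
  cfg <- sampling_config(roi_side_mm = 40, hrs_pixel_stride_px = 1)
  roi <- hrs_roi_pixels(c(30, 30), img, cfg)
  expect_equal(n_patches(roi), 400 * 400)   # unclipped 40 mm ROI at 0.1 mm/px
  cfg4 <- sampling_config(roi_side_mm = 40, hrs_pixel_stride_px = 4)
  expect_equal(n_patches(hrs_roi_pixels(c(30, 30), img, cfg4)), 100 * 100)

  # near a border the count equals the brute-force clipped count
  cfgb <- sampling_config(roi_side_mm = 10, hrs_pixel_stride_px = 3)
  roib <- hrs_roi_pixels(c(1.2, 58), img, cfgb)
  s <- img$spacing_mm
  px <- seq(0, img$width_px - 1)
  py <- seq(0, img$height_px - 1)
  inx <- px[px * s >= 1.2 - 5 - 1e-9 & px * s < 1.2 + 5 - 1e-9]
  iny <- py[py * s >= 58 - 5 - 1e-9 & py * s < 58 + 5 - 1e-9]
  brute <- length(inx[seq(1, length(inx), 3)]) *
    length(iny[seq(1, length(iny), 3)])
  expect_equal(n_patches(roib), brute)
  expect_error(hrs_roi_pixels(c(70, 30), img, cfg), "outside")
})

test_that("training sets honour counts, labels and region geometry", {
  cases <- synth_cases(2)
  images <- lapply(cases, `[[`, "image")
  truths <- lapply(cases, `[[`, "truth")
  cfg <- desk_sampling_config(n_true = 20L, n_false = 50L,
                              n_hard_false = 0L, rng_seed = 9)

  for (stage in c("LRS", "HRS")) {
    ts <- build_training_set(images, truths, "Sella", stage, cfg)
    expect_equal(ts$n, 2 * 70)
    expect_equal(mean(ts$labels == 1), 20 / 70)
    lm <- landmark_xy(truths[[1]], "Sella")
    d1 <- sqrt((ts$centers_mm[1:70, 1] - lm[1])^2 +
                 (ts$centers_mm[1:70, 2] - lm[2])^2)
    rtrue <- if (stage == "LRS") cfg$lrs_true_radius_mm else
      cfg$hrs_true_radius_mm
    expect_true(all(d1[ts$labels[1:70] == 1] <= rtrue + 1e-9))
    if (stage == "LRS") {
      expect_true(all(d1[ts$labels[1:70] == 0] > rtrue))
    } else {
      dfalse <- d1[ts$labels[1:70] == 0]
      expect_true(all(dfalse >= cfg$hrs_false_inner_mm - 1e-9 &
                        dfalse <= cfg$hrs_false_outer_mm + 1e-9))
      # nothing in the excluded (true, inner) gap by construction
      expect_false(any(d1 > rtrue & d1 < cfg$hrs_false_inner_mm))
    }
  }
})

test_that("hard negatives come from the other landmarks' true regions", {
  cases <- synth_cases(2)
  images <- lapply(cases, `[[`, "image")
  truths <- lapply(cases, `[[`, "truth")
  cfg <- desk_sampling_config(n_true = 10L, n_false = 20L,
                              n_hard_false = 12L, rng_seed = 4)
  ts <- build_training_set(images, truths, "Sella", "HRS", cfg)
  expect_equal(ts$n, 2L * (10L + 20L + 12L))
  # per image, the last 12 false patches sit within the true radius of some
  # other landmark
  per <- 42L
  for (i in 1:2) {
    hard <- ts$centers_mm[(i - 1) * per + 31:42, , drop = FALSE]
    others <- as.matrix(truths[[i]][truths[[i]]$name != "Sella",
                                    c("x_mm", "y_mm")])
    dmin <- apply(hard, 1, function(p) {
      min(sqrt(rowSums(sweep(others, 2, p)^2)))
    })
    expect_true(all(dmin <= cfg$hrs_true_radius_mm + 1e-9))
  }
  expect_true(all(ts$labels[(0:1) * per + rep(31:42, each = 2)] == 0L))
})

test_that("training-set sampling is reproducible under a fixed seed", {
  cases <- synth_cases(2)
  images <- lapply(cases, `[[`, "image")
  truths <- lapply(cases, `[[`, "truth")
  cfg <- desk_sampling_config(n_true = 10L, n_false = 20L, rng_seed = 77)
  a <- build_training_set(images, truths, "Nasion", "HRS", cfg)
  b <- build_training_set(images, truths, "Nasion", "HRS", cfg)
  expect_identical(a$centers_mm, b$centers_mm)
  expect_identical(a$windows, b$windows)
})

test_that("degenerate sampling regions are reported", {
  img <- flat_image(40, 40)  # 4 mm frame: no pixel is 18 mm from a landmark
  truth <- landmark_set(2, 2, names = "Sella")
  cfg <- sampling_config(n_true = 5L, n_false = 5L, rng_seed = 1,
                         patch_side_mm = 0.5, lrs_downsample_factor = 1)
  expect_error(
    build_training_set(list(img), list(truth), "Sella", "LRS", cfg),
    "empty")
})

test_that("config invariants are enforced", {
  expect_error(sampling_config(hrs_true_radius_mm = 3, hrs_false_inner_mm = 2),
               "hrs_true_radius")
  expect_error(sampling_config(lrs_stride_mm = -1))
})
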