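test_that("mm/pixel conversions are exact inverses on grid points", {
  for (spacing in c(0.1, 0.25, 1)) {
    px <- 0:50
    expect_identical(mm_to_px(px_to_mm(px, spacing), spacing), px)
  }
  expect_equal(px_to_mm(c(100, 200), 0.1), c(10, 20))
})

test_that("ceph_image validates its invariants", {
  img <- ceph_image(matrix(0:254, 15, 17)[1:15, 1:17], spacing_mm = 0.1)
  expect_equal(img$width_px, 17)
  expect_equal(img$height_px, 15)
  expect_error(ceph_image(matrix(-1, 3, 3)), "within")
  expect_error(ceph_image(matrix(300, 3, 3)), "within")
  expect_error(ceph_image(matrix(1, 3, 3), spacing_mm = 0), "positive")
})

test_that("annotation files read/convert and tolerate extra lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(sprintf("%d,%d", 1:19 * 10, 1:19 * 20), "2", "3"), path)
  expect_warning(ls19 <- read_annotation(path, spacing_mm = 0.1),
                 "2 extra")
  expect_equal(nrow(ls19), 19)
  expect_equal(ls19$x_mm[1], 1)   # "10,20" at 0.1 mm/px
  expect_equal(ls19$y_mm[19], 38)
})

test_that("malformed and short annotation files fail with line context", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1,2", "oops", rep("3,4", 17)), path)
  expect_error(read_annotation(path), "line 2")
  writeLines(rep("1,1", 7), path)
  expect_error(read_annotation(path), "19 required")
})

test_that("annotation write/read round trip is exact to 1e-9 mm", {
  set.seed(5)
  ls <- landmark_set(runif(19, 0, 190), runif(19, 0, 230),
                     provenance = "annotatorB")
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotation(ls, path, spacing_mm = 0.1)
  back <- read_annotation(path, spacing_mm = 0.1, provenance = "annotatorB")
  expect_close(back$x_mm, ls$x_mm, 1e-9)
  expect_close(back$y_mm, ls$y_mm, 1e-9)
})

test_that("ground truth is the annotator mean, symmetric and idempotent", {
  a <- landmark_set(rep(0, 19), rep(0, 19), provenance = "annotatorA")
  b <- landmark_set(rep(2, 19), rep(4, 19), provenance = "annotatorB")
  gt <- ground_truth(a, b)
  expect_equal(gt$x_mm, rep(1, 19))
  expect_equal(gt$y_mm, rep(2, 19))
  expect_equal(landmark_provenance(gt), "ground_truth")
  # symmetry
  gt2 <- ground_truth(b, a)
  expect_equal(gt2$x_mm, gt$x_mm)
  # idempotent on equal inputs
  expect_equal(ground_truth(a, a)$x_mm, a$x_mm)
  # jittered annotators: mean within max(|a-b|)/2 of each
  set.seed(1)
  a2 <- landmark_set(runif(19, 10, 20), runif(19, 10, 20))
  b2 <- landmark_set(a2$x_mm + rnorm(19, 0, 1), a2$y_mm + rnorm(19, 0, 1))
  g2 <- ground_truth(a2, b2)
  half <- sqrt((a2$x_mm - b2$x_mm)^2 + (a2$y_mm - b2$y_mm)^2) / 2
  expect_true(all(sqrt((g2$x_mm - a2$x_mm)^2 + (g2$y_mm - a2$y_mm)^2) <=
                    half + 1e-12))
  # mismatched registries refuse
  short <- landmark_set(1:5, 1:5)
  expect_error(ground_truth(a, short), "registries")
})

test_that("prediction reports round trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  # empty prediction list -> header-only file
  write_prediction_report(list(), path)
  empty <- read_prediction_report(path)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("landmark", "x_mm", "semi_major_mm") %in% names(empty)))

  df <- data.frame(landmark = c("Sella", "Nasion"),
                   x_mm = c(12.345678, 1), y_mm = c(9.87, 2),
                   ellipse_cx = c(12.3, 1), ellipse_cy = c(9.9, 2),
                   semi_major_mm = c(1.5, 0.5), semi_minor_mm = c(0.7, 0.2),
                   angle_deg = c(30, 170), max_score = c(22025.4, 3.2),
                   n_true_lrs = c(4L, 2L))
  write_prediction_report(df, path)
  back <- read_prediction_report(path)
  expect_equal(nrow(back), 2)
  expect_close(back$x_mm, df$x_mm, 1e-6)
  expect_close(back$max_score, df$max_score, 1e-6)
})

test_that("images survive a PNG write/read round trip", {
  img <- ceph_image(matrix(round(seq(0, 255, length.out = 30 * 20)), 30, 20),
                    spacing_mm = 0.1)
  path <- withr::local_tempfile(fileext = ".png")
  write_ceph_image(img, path)
  back <- read_ceph_image(path, spacing_mm = 0.1)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_true(max(abs(back$pixels - img$pixels)) <= 0.5)  # 8-bit quantization
})

test_that("block-mean downsampling averages blocks and scales spacing", {
  img <- ceph_image(matrix(as.numeric(1:36), 6, 6), spacing_mm = 0.1)
  dn <- downsample_image(img, 3)
  expect_equal(dn$spacing_mm, 0.3, tolerance = 1e-12)
  expect_equal(dim(dn$pixels), c(2, 2))
  expect_equal(dn$pixels[1, 1], mean(img$pixels[1:3, 1:3]))
  expect_equal(dn$pixels[2, 2], mean(img$pixels[4:6, 4:6]))
})
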