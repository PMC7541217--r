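test_that("the coarse-centre estimate is the mean of true positions", {
  expect_equal(lrs_center(rbind(c(0, 0), c(2, 2))), c(x_mm = 1, y_mm = 1),
               ignore_attr = TRUE)
  expect_equal(lrs_center(rbind(c(4.2, -1))), c(4.2, -1), ignore_attr = TRUE)
  set.seed(3)
  pts <- matrix(rnorm(200), 100, 2)
  expect_close(lrs_center(pts), c(mean(pts[, 1]), mean(pts[, 2])), 1e-12)
  expect_error(lrs_center(pts[0, , drop = FALSE]), class = "cephmark_no_true")
})

test_that("score weighting matches an independent transcription", {
  mu <- c(0, 0.3, 0.75, 1, 0.5)
  sg <- c(0.05, 0.2, 0.01, 0, 0.1)
  cfg <- score_config(s_sigma = 1.3)
  got <- score_weighting(data.frame(mu = mu, sigma = sg), cfg)
  # independent elementwise transcription of the formula
  tot <- sqrt(sum(sg^2))
  want <- vapply(seq_along(mu), function(i) {
    (exp(10 * mu[i]) - 1) *
      tanh(tot / (1.3 * max(sg[i], cfg$sigma_floor)))
  }, numeric(1))
  expect_close(got, want, 1e-9)
  # mu = 0 annihilates the score regardless of sigma
  expect_identical(got[1] == 0, TRUE)
  # mu = 1 with floored sigma saturates tanh at 1: (e^10 - 1)
  expect_equal(got[4], exp(10) - 1, tolerance = 1e-9)
  expect_true(all(got >= 0))
  expect_error(score_weighting(data.frame(mu = numeric(0),
                                          sigma = numeric(0))), "empty")
})

test_that("score weighting is monotone in mu (up) and sigma (down)", {
  cfg <- score_config()
  base_sigma <- rep(0.1, 41)
  mus <- seq(0, 1, length.out = 41)
  s_mu <- score_weighting(data.frame(mu = mus, sigma = base_sigma), cfg)
  expect_true(all(diff(s_mu) > 0))
  # keep the tanh argument out of its saturation plateau so differences
  # stay resolvable in double precision
  sigmas <- seq(0.1, 0.6, length.out = 41)
  s_sg <- score_weighting(data.frame(mu = rep(0.7, 41), sigma = sigmas),
                          score_config(s_sigma = 4))
  expect_true(all(diff(s_sg) < 0))
})

test_that("the score centre is the brute-force weighted centroid", {
  expect_equal(score_center(rbind(c(0, 0), c(2, 0)), c(1, 1)), c(1, 0))
  expect_equal(score_center(rbind(c(5, 7), c(1, 1)), c(3, 0)), c(5, 7))
  set.seed(8)
  pos <- matrix(runif(160, 0, 40), 80, 2)
  w <- rexp(80)
  brute <- c(sum(w * pos[, 1]) / sum(w), sum(w * pos[, 2]) / sum(w))
  expect_close(score_center(pos, w), brute, 1e-12)
  expect_error(score_center(pos, rep(0, 80)), class = "cephmark_zero_scores")
  # centre lies inside the convex hull bounding box of supported positions
  sc <- score_center(pos, w)
  expect_true(all(sc >= apply(pos, 2, min) & sc <= apply(pos, 2, max)))
})

test_that("ellipse semi-axes recover the spread of an isotropic field", {
  # score weights proportional to a bivariate normal density on a fine grid
  s <- 1.7
  g <- expand.grid(x = seq(-9, 9, by = 0.05), y = seq(-9, 9, by = 0.05))
  w <- exp(-(g$x^2 + g$y^2) / (2 * s^2))
  e <- confidence_ellipse(as.matrix(g), w)
  expect_equal(e$semi_major_mm, s * sqrt(qchisq(0.95, 2)), tolerance = 0.01)
  expect_equal(e$semi_minor_mm, s * sqrt(qchisq(0.95, 2)), tolerance = 0.01)
  expect_close(e$center_mm, c(0, 0), 1e-9)
  expect_false(e$degenerate)
  # ~95% of the score mass falls inside the ellipse
  inside <- (g$x^2 + g$y^2) <= qchisq(0.95, 2) * s^2
  expect_equal(sum(w[inside]) / sum(w), 0.95, tolerance = 0.01)
})

test_that("all score mass on one pixel degenerates the ellipse", {
  pos <- rbind(c(1, 2), c(3, 4), c(5, 6))
  e <- confidence_ellipse(pos, c(0, 7, 0))
  expect_true(e$degenerate)
  expect_equal(e$semi_major_mm, 0)
  expect_equal(e$semi_minor_mm, 0)
  # collinear support: minor axis 0, flagged
  pos2 <- cbind(seq(0, 1, length.out = 9), seq(0, 2, length.out = 9))
  e2 <- confidence_ellipse(pos2, rep(1, 9))
  expect_true(e2$degenerate)
  expect_gt(e2$semi_major_mm, 0)
  expect_equal(e2$semi_minor_mm, 0, tolerance = 1e-9)
})

test_that("the ellipse is equivariant under translation and rotation", {
  set.seed(12)
  pos <- matrix(rnorm(120, sd = 2), 60, 2)
  w <- rexp(60)
  e0 <- confidence_ellipse(pos, w)
  # translation moves the centre, not the shape
  t <- c(13, -4)
  e1 <- confidence_ellipse(sweep(pos, 2, t, "+"), w)
  expect_close(e1$center_mm, e0$center_mm + t, 1e-9)
  expect_equal(e1$semi_major_mm, e0$semi_major_mm, tolerance = 1e-9)
  expect_equal(e1$semi_minor_mm, e0$semi_minor_mm, tolerance = 1e-9)
  expect_equal(e1$angle_deg, e0$angle_deg, tolerance = 1e-6)
  # rotation turns the major axis by the same angle (mod 180)
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  e2 <- confidence_ellipse(pos %*% t(R), w)
  expect_equal(e2$semi_major_mm, e0$semi_major_mm, tolerance = 1e-9)
  dd <- (e2$angle_deg - e0$angle_deg - 35) %% 180
  expect_true(min(dd, 180 - dd) < 1e-6)
})
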