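#' Score configuration
#'
#' `s_sigma` is the positive scale inside the tanh of the score weighting;
#' it is not pinned by the reference protocol, so it defaults to 1 and is
#' exposed here. `sigma_floor` replaces a zero per-pixel uncertainty in the
#' denominator, so the tanh term attains its supremum 1 — the continuous
#' limit of the formula.
#'
#' @param s_sigma Positive scale.
#' @param sigma_floor Small positive floor for zero uncertainties.
#' @return A `score_config` list.
#' @export
score_config <- function(s_sigma = 1.0, sigma_floor = 1e-12) {
  stopifnot(s_sigma > 0, sigma_floor > 0)
  structure(list(s_sigma = s_sigma, sigma_floor = sigma_floor),
            class = "score_config")
}

#' Coarse-stage centre estimate
#'
#' The ROI centre proposed by low-resolution screening is the coordinate-wise
#' arithmetic mean of the grid positions classified as true.
#'
#' @param true_positions_mm Matrix (n x 2) of positions classified true.
#' @return Numeric `c(x_mm, y_mm)`.
#' @export
lrs_center <- function(true_positions_mm) {
  true_positions_mm <- rbind(true_positions_mm)
  if (nrow(true_positions_mm) == 0) {
    stop(structure(class = c("cephmark_no_true", "error", "condition"),
                   list(message = "no grid position classified true",
                        call = NULL)))
  }
  colMeans(true_positions_mm[, 1:2, drop = FALSE])
}

#' Score weighting of Bayesian pixel predictions
#'
#' Pixels likely to be the landmark have a high posterior mean and a low
#' uncertainty; both are combined into
#' `score_i = (exp(10 mu_i) - 1) * tanh( sqrt(sum_j sigma_j^2) /
#' (s_sigma * sigma_i) )`, where the sum runs over all N candidate pixels of
#' the ROI and a zero `sigma_i` is floored (see [score_config]). Scores are
#' nonnegative, increase with `mu` and decrease with `sigma`.
#'
#' @param result Data frame (or list) with numeric `mu` and `sigma` of equal
#'   length (as returned by [predict_bayesian]).
#' @param cfg A [score_config].
#' @return Numeric score vector.
#' @export
score_weighting <- function(result, cfg = score_config()) {
  mu <- result$mu
  sigma <- result$sigma
  if (is.null(mu) || length(mu) == 0) {
    stop("empty screening result", call. = FALSE)
  }
  stopifnot(length(mu) == length(sigma), all(mu >= 0 & mu <= 1),
            all(sigma >= 0))
  total <- sqrt(sum(sigma^2))
  (exp(10 * mu) - 1) * tanh(total / (cfg$s_sigma * pmax(sigma, cfg$sigma_floor)))
}

#' Score centre (final landmark estimate)
#'
#' The score-weighted centroid of the candidate pixel positions, in analogy
#' to a centre of mass.
#'
#' @param positions_mm Matrix (n x 2) of candidate positions.
#' @param scores Nonnegative scores, one per position.
#' @return Numeric `c(x_mm, y_mm)`.
#' @export
score_center <- function(positions_mm, scores) {
  stopifnot(nrow(positions_mm) == length(scores))
  s <- sum(scores)
  if (!(s > 0)) {
    stop(structure(class = c("cephmark_zero_scores", "error", "condition"),
                   list(message = "all scores are zero (degenerate ROI)",
                        call = NULL)))
  }
  c(sum(scores * positions_mm[, 1]), sum(scores * positions_mm[, 2])) / s
}

#' Confidence ellipse of a score field
#'
#' Normalised scores are treated as a spatial probability surface (the same
#' reading that makes the score centre a mass centre): the ellipse is centred
#' on the score centre, shaped by the score-weighted covariance of the
#' candidate positions, and scaled by the chi-square(2 df) quantile of the
#' coverage level (5.991 at 95%), so the boundary is
#' `(x - c)' Sigma^{-1} (x - c) = q`. Axes and orientation come from the
#' eigendecomposition; a singular covariance (all mass on a point or a line)
#' yields a degenerate ellipse with the corresponding semi-axis 0 and
#' `degenerate = TRUE`.
#'
#' @param positions_mm Matrix (n x 2) of candidate positions.
#' @param scores Nonnegative scores with positive sum.
#' @param coverage Coverage level in (0, 1); default 0.95.
#' @return A `confidence_ellipse`: list with `center_mm`, `semi_major_mm`,
#'   `semi_minor_mm`, `angle_deg` (major axis vs +x, in [0, 180)),
#'   `coverage`, `degenerate`.
#' @export
confidence_ellipse <- function(positions_mm, scores, coverage = 0.95) {
  stopifnot(coverage > 0, coverage < 1)
  ctr <- score_center(positions_mm, scores)
  w <- scores / sum(scores)
  dx <- positions_mm[, 1] - ctr[1]
  dy <- positions_mm[, 2] - ctr[2]
  cov <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                  sum(w * dx * dy), sum(w * dy * dy)), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  q <- stats::qchisq(coverage, df = 2)
  lam <- pmax(eg$values, 0)
  semi <- sqrt(lam * q)
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ang %% 180
  structure(list(center_mm = ctr, semi_major_mm = semi[1],
                 semi_minor_mm = semi[2], angle_deg = ang,
                 coverage = coverage,
                 degenerate = semi[2] <= sqrt(.Machine$double.eps)),
            class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf(
    "<%.0f%% confidence ellipse @ (%.2f, %.2f) mm, semi-axes %.2f x %.2f mm, %.1f deg%s>\n",
    100 * x$coverage, x$center_mm[1], x$center_mm[2], x$semi_major_mm,
    x$semi_minor_mm, x$angle_deg, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Points of an ellipse boundary (for plotting)
#' @param e A `confidence_ellipse`.
#' @param n Number of boundary points.
#' @return Matrix (n x 2) of xy coordinates in mm.
#' @export
ellipse_points <- function(e, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- e$angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- cbind(e$semi_major_mm * cos(t), e$semi_minor_mm * sin(t)) %*% t(R)
  sweep(xy, 2, e$center_mm, "+")
}
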