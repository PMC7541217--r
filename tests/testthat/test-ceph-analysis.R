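test_that("vertex angles follow the arccos oracle", {
  expect_equal(vertex_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(vertex_angle(c(2, 0), c(0, 0), c(5, 0)), 0)   # same side
  expect_equal(vertex_angle(c(-1, 0), c(0, 0), c(3, 0)), 180)
  set.seed(14)
  for (i in 1:25) {
    P <- rnorm(2); V <- rnorm(2); Q <- rnorm(2)
    u <- P - V; v <- Q - V
    want <- acos(pmin(1, pmax(-1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_close(vertex_angle(P, V, Q), want, 1e-9)
  }
  expect_error(vertex_angle(c(0, 0), c(0, 0), c(1, 1)), "coincides")
})

test_that("line angles respect unsigned and signed conventions", {
  expect_equal(line_angle(c(0, 0), c(1, 0), c(3, 3), c(4, 3)), 0)  # parallel
  expect_equal(line_angle(c(0, 0), c(1, 0), c(0, 0), c(0, 2)), 90)
  expect_true(line_angle(c(0, 0), c(1, 0), c(0, 0), c(-1, 0.1)) <= 90)
  # signed mode antisymmetric under argument swap
  set.seed(15)
  for (i in 1:20) {
    A1 <- rnorm(2); A2 <- rnorm(2); B1 <- rnorm(2); B2 <- rnorm(2)
    f <- line_angle(A1, A2, B1, B2, signed = TRUE)
    b <- line_angle(B1, B2, A1, A2, signed = TRUE)
    if (abs(abs(f) - 180) > 1e-9) expect_close(f, -b, 1e-9)
  }
  expect_error(line_angle(c(0, 0), c(0, 0), c(0, 0), c(1, 1)), "zero-length")
})

# a hand-constructed landmark geometry with known parameter values
analytic_landmarks <- function() {
  pts <- list(
    "Sella" = c(8, 4), "Nasion" = c(16, 4),
    "Orbitale" = c(14, 6), "Porion" = c(6, 6),
    "A-point" = c(16, 10), "B-point" = c(15, 14),
    "Pogonion" = c(15, 16), "Menton" = c(14, 17), "Gnathion" = c(14.6, 16.6),
    "Gonion" = c(7, 15),
    "Lower incisal incision" = c(14.5, 12.5),
    "Upper incisal incision" = c(15.5, 11.5),
    "Upper lip" = c(17, 11), "Lower lip" = c(17, 13),
    "Subnasale" = c(16.5, 9), "Soft tissue pogonion" = c(16, 16),
    "Posterior Nasal Spine" = c(10, 9), "Anterior Nasal Spine" = c(15.5, 9),
    "Articulare" = c(6.5, 8)
  )
  landmark_set(vapply(pts, `[`, 1, 1), vapply(pts, `[`, 2, 2),
               names = names(pts))
}

test_that("the eight parameters match manual trigonometry", {
  ls <- analytic_landmarks()
  v <- compute_parameters(ls)
  g <- function(nm) landmark_xy(ls, nm)
  expect_close(v[["ANB"]], vertex_angle(g("A-point"), g("Nasion"),
                                        g("B-point")), 1e-12)
  expect_close(v[["SNA"]], vertex_angle(g("Sella"), g("Nasion"),
                                        g("A-point")), 1e-12)
  # FHI = S-Go / N-Me by hand
  expect_close(v[["FHI"]],
               sqrt(sum((g("Sella") - g("Gonion"))^2)) /
                 sqrt(sum((g("Nasion") - g("Menton"))^2)), 1e-12)
  # MW distance, and zero when the incisal points coincide
  expect_close(v[["MW"]], sqrt(2), 1e-12)
  ls0 <- ls
  ls0$x_mm[ls0$name == "Lower incisal incision"] <- 15.5
  ls0$y_mm[ls0$name == "Lower incisal incision"] <- 11.5
  expect_equal(compute_parameters(ls0)[["MW"]], 0)
  # ODI/APDI sums of unsigned line angles, recomputed by hand
  odi <- line_angle(g("A-point"), g("B-point"), g("Menton"), g("Gonion")) +
    line_angle(g("Orbitale"), g("Porion"),
               g("Posterior Nasal Spine"), g("Anterior Nasal Spine"))
  expect_close(v[["ODI"]], odi, 1e-9)
  apdi <- line_angle(g("Orbitale"), g("Porion"), g("Nasion"), g("Pogonion")) +
    line_angle(g("Nasion"), g("Pogonion"), g("A-point"), g("B-point")) +
    line_angle(g("Orbitale"), g("Porion"),
               g("Posterior Nasal Spine"), g("Anterior Nasal Spine"))
  expect_close(v[["APDI"]], apdi, 1e-9)
  expect_close(v[["FMA"]], line_angle(g("Sella"), g("Nasion"),
                                      g("Gonion"), g("Gnathion")), 1e-9)
  # missing operands are named
  expect_error(compute_parameters(landmark_set(1:5, 1:5)),
               "missing landmark.*B-point")
})

test_that("angle and ratio parameters are rigid-motion invariant", {
  ls <- analytic_landmarks()
  v0 <- compute_parameters(ls)
  th <- 23 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- as.matrix(ls[, c("x_mm", "y_mm")]) %*% t(R)
  ls1 <- landmark_set(xy[, 1] + 5, xy[, 2] + 11, names = ls$name)
  v1 <- compute_parameters(ls1)
  expect_close(unclass(v1), unclass(v0), 1e-9)
  # ANB ~ |SNA - SNB| when N-A and N-B lie on the same side of S-N
  expect_close(v0[["ANB"]], abs(v0[["SNA"]] - v0[["SNB"]]), 1e-9)
})

test_that("threshold classification is half-open and deterministic", {
  tab <- load_classification_table()
  vals <- c(ANB = 4.0, SNB = 74.6, SNA = 90, MW = 0)
  cls <- classify_parameters(vals, tab)
  expect_equal(unname(cls["ANB"]), "1")
  expect_equal(unname(cls["SNB"]), "1")   # boundary joins the upper interval
  expect_equal(unname(cls["SNA"]), "2")
  expect_equal(unname(cls["MW"]), "3")    # [0, 2) band
  expect_error(classify_parameters(c(XYZ = 1), tab), "absent")
  # classify o compute on a constructed set lands in a known class
  ls <- analytic_landmarks()
  v <- compute_parameters(ls)
  cls2 <- classify_parameters(v[c("ANB", "SNA", "SNB")], tab)
  expect_true(all(cls2 %in% c("1", "2", "3")))
})

test_that("confusion matrices tally counts, percentages and the diagonal", {
  t1 <- c("a", "a", "b", "b")
  expect_equal(confusion_and_diagonal(t1, t1)$diagonal_accuracy, 100)
  expect_equal(confusion_and_diagonal(c("a", "b"),
                                      c("b", "a"))$diagonal_accuracy, 0)
  set.seed(3)
  tl <- sample(letters[1:3], 120, replace = TRUE)
  pl <- sample(letters[1:3], 120, replace = TRUE)
  cm <- confusion_and_diagonal(tl, pl)
  brute <- sum(tl == pl) / 120 * 100
  expect_equal(cm$diagonal_accuracy, brute)
  expect_equal(sum(cm$counts), 120)
  expect_true(all(abs(rowSums(cm$row_pct) - 100) <= 0.02))
  expect_error(confusion_and_diagonal(character(0), character(0)), "empty")
})

test_that("count recovery inverts printed percentages", {
  # trivial 50/50 row
  r <- recover_counts_from_percentages(matrix(c(50, 50), 1), max_total = 10)
  expect_equal(r$row_totals, 2)
  expect_equal(r$counts[1, ], c(1L, 1L))
  # round trip: random counts -> percentages -> recovery reproduces them
  set.seed(21)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    cts <- as.vector(stats::rmultinom(1, n, c(0.5, 0.3, 0.2)))
    pct <- floor(100 * cts / n * 100 + 0.5) / 100
    rec <- recover_counts_from_percentages(matrix(pct, 1), max_total = 150)
    got <- rec$counts[1, ]
    expect_equal(floor(100 * got / sum(got) * 100 + 0.5) / 100, pct)
  }
  expect_error(recover_counts_from_percentages(matrix(c(60, 60), 1), 100),
               "sum to 100")
})

test_that("joint recovery reproduces the published diagonal accuracies", {
  rows <- reported_confusion_rows()
  joint <- recover_confusion_joint(rows[c("ANB", "SNA", "SNB")],
                                   max_total = 250)
  expect_equal(attr(joint, "grand_total"), 249)
  expect_equal(joint$SNB$row_totals, c(71, 39, 139))
  expect_equal(round(joint$SNB$diagonal_accuracy, 2), 83.13)
  expect_equal(joint$SNA$row_totals, c(105, 90, 54))
  expect_equal(round(joint$SNA$diagonal_accuracy, 2), 72.69)
  expect_equal(round(joint$ANB$diagonal_accuracy, 2), 80.72)
  # MW carries one typographic slip (89.76 vs consistent 89.80); a small
  # tolerance recovers it and matches the published diagonal
  mw <- recover_counts_from_percentages(rows$MW, max_total = 250,
                                        grand_total = 249, pct_tol = 0.05)
  expect_equal(round(mw$diagonal_accuracy, 2), 80.32)
})
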