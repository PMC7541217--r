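#' Interior angle at a vertex
#'
#' The angle at `V` between the rays `V -> P` and `V -> Q`, in degrees in
#' \[0, 180\]. This is the construction behind SNA, SNB and ANB (e.g. ANB is
#' the angle at Nasion between A-point and B-point).
#'
#' @param P,V,Q Numeric `c(x, y)` points; `V` must differ from both.
#' @return Angle in degrees.
#' @export
vertex_angle <- function(P, V, Q) {
  u <- P - V
  v <- Q - V
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("vertex coincides with an endpoint", call. = FALSE)
  }
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Angle between two lines
#'
#' Unsigned mode (default) returns the minimal angle between the undirected
#' lines through `A1 -> A2` and `B1 -> B2`, in \[0, 90\] degrees — the
#' convention used for the composite indices (ODI, APDI, FMA). Signed mode
#' returns the rotation from direction `A1 -> A2` to `B1 -> B2` in
#' (-180, 180], antisymmetric under swapping the arguments.
#'
#' @param A1,A2,B1,B2 Numeric `c(x, y)` endpoints; both segments must have
#'   positive length.
#' @param signed Use the signed convention?
#' @return Angle in degrees.
#' @export
line_angle <- function(A1, A2, B1, B2, signed = FALSE) {
  u <- A2 - A1
  v <- B2 - B1
  if (all(u == 0) || all(v == 0)) {
    stop("zero-length segment", call. = FALSE)
  }
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  ang <- atan2(cross, dot) * 180 / pi   # (-180, 180]
  if (ang <= -180) ang <- 180
  if (signed) return(ang)
  a <- abs(ang)
  if (a > 90) a <- 180 - a
  a
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

#' Compute the eight orthodontic skeletal parameters
#'
#' From a complete landmark set:
#' \itemize{
#' \item ANB, SNA, SNB: vertex angles at Nasion (A-point/B-point) and the
#'   angles at Nasion between Sella and A-point / B-point;
#' \item ODI (overbite depth indicator): angle(A-B, Menton-Gonion) +
#'   angle(Orbitale-Porion, PNS-ANS);
#' \item APDI (anteroposterior dysplasia indicator): angle(Orbitale-Porion,
#'   Nasion-Pogonion) + angle(Nasion-Pogonion, A-B) + angle(Orbitale-Porion,
#'   PNS-ANS);
#' \item FHI (facial height index): posterior face height (Sella-Gonion) /
#'   anterior face height (Nasion-Menton);
#' \item FMA: angle(Sella-Nasion, Gonion-Gnathion);
#' \item MW (modified Wits): distance between the lower and upper incisal
#'   incisions — Euclidean by default, or the signed horizontal offset
#'   `x(LII) - x(UII)` with `mw_mode = "signed_horizontal"` for threshold
#'   tables with negative classes.
#' }
#' Composite angles use the unsigned line-angle convention unless
#' `angle_mode = "signed"`; the mode is recorded as an attribute.
#'
#' @param ls A [landmark_set] containing the required landmarks.
#' @param angle_mode `"unsigned"` (default) or `"signed"` for the line-angle
#'   components.
#' @param mw_mode `"euclidean"` (default) or `"signed_horizontal"`.
#' @return Named numeric vector (ANB, SNB, SNA, ODI, APDI, FHI, FMA, MW)
#'   with attributes `angle_mode`, `mw_mode`.
#' @export
compute_parameters <- function(ls, angle_mode = c("unsigned", "signed"),
                               mw_mode = c("euclidean", "signed_horizontal")) {
  angle_mode <- match.arg(angle_mode)
  mw_mode <- match.arg(mw_mode)
  need <- c("Sella", "Nasion", "Orbitale", "Porion", "A-point", "B-point",
            "Pogonion", "Menton", "Gnathion", "Gonion",
            "Lower incisal incision", "Upper incisal incision",
            "Posterior Nasal Spine", "Anterior Nasal Spine")
  missing <- setdiff(need, ls$name)
  if (length(missing)) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- function(nm) landmark_xy(ls, nm)
  S <- g("Sella"); N <- g("Nasion"); Or <- g("Orbitale"); Po <- g("Porion")
  A <- g("A-point"); B <- g("B-point"); Pog <- g("Pogonion")
  Me <- g("Menton"); Gn <- g("Gnathion"); Go <- g("Gonion")
  LII <- g("Lower incisal incision"); UII <- g("Upper incisal incision")
  PNS <- g("Posterior Nasal Spine"); ANS <- g("Anterior Nasal Spine")
  sgn <- angle_mode == "signed"
  la <- function(p1, p2, q1, q2) line_angle(p1, p2, q1, q2, signed = sgn)
  out <- c(
    ANB = vertex_angle(A, N, B),
    SNB = vertex_angle(S, N, B),
    SNA = vertex_angle(S, N, A),
    ODI = la(A, B, Me, Go) + la(Or, Po, PNS, ANS),
    APDI = la(Or, Po, N, Pog) + la(N, Pog, A, B) + la(Or, Po, PNS, ANS),
    FHI = dist2(S, Go) / dist2(N, Me),
    FMA = la(S, N, Go, Gn),
    MW = if (mw_mode == "euclidean") dist2(LII, UII) else LII[1] - UII[1]
  )
  attr(out, "angle_mode") <- angle_mode
  attr(out, "mw_mode") <- mw_mode
  out
}

#' Load a classification threshold table
#'
#' CSV with columns `parameter`, `label`, `lower`, `upper` defining, per
#' parameter, ordered class labels over half-open intervals `[lower, upper)`
#' (use `-Inf`/`Inf` for the open ends). Intervals must be disjoint and
#' cover the real line. A template with conventional clinical ranges ships
#' in `system.file("extdata", "classification_thresholds.csv", package =
#' "cephmark")`; numeric cutoffs for clinical use must come from a validated
#' source, the template only documents the expected layout.
#'
#' @param path CSV path; default the packaged template.
#' @return A `classification_table` data frame.
#' @export
load_classification_table <- function(path = system.file(
    "extdata", "classification_thresholds.csv", package = "cephmark")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("parameter", "label", "lower", "upper") %in% names(tab)))
  tab$lower <- as.numeric(tab$lower)
  tab$upper <- as.numeric(tab$upper)
  for (p in unique(tab$parameter)) {
    sub <- tab[tab$parameter == p, ]
    sub <- sub[order(sub$lower), ]
    if (sub$lower[1] != -Inf || sub$upper[nrow(sub)] != Inf ||
        (nrow(sub) > 1 && any(sub$upper[-nrow(sub)] != sub$lower[-1]))) {
      stop("intervals for ", p, " must be disjoint and cover the real line",
           call. = FALSE)
    }
  }
  class(tab) <- c("classification_table", "data.frame")
  tab
}

#' Classify parameter values against a threshold table
#'
#' Each value receives the label of the half-open interval `[lower, upper)`
#' containing it, so a boundary value belongs to the upper interval's closed
#' lower end — deterministic by construction.
#'
#' @param values Named numeric vector from [compute_parameters] (any subset).
#' @param table A `classification_table`.
#' @return Named character vector of class labels.
#' @export
classify_parameters <- function(values, table) {
  vapply(names(values), function(p) {
    sub <- table[table$parameter == p, ]
    if (nrow(sub) == 0) {
      stop("parameter absent from classification table: ", p, call. = FALSE)
    }
    hit <- which(values[[p]] >= sub$lower & values[[p]] < sub$upper)
    as.character(sub$label[hit[1]])
  }, character(1))
}

#' Confusion matrix with row percentages and diagonal accuracy
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param labels Class label ordering (default: sorted union).
#' @return A `confusion_matrix`: list with integer `counts`, `row_pct`
#'   (rows summing to 100 up to 2-d.p. rounding) and `diagonal_accuracy`
#'   (= 100 * trace / total).
#' @export
confusion_and_diagonal <- function(true_labels, pred_labels, labels = NULL) {
  if (length(true_labels) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(true_labels) == length(pred_labels))
  if (is.null(labels)) {
    labels <- sort(unique(c(as.character(true_labels),
                            as.character(pred_labels))))
  }
  counts <- table(factor(true_labels, levels = labels),
                  factor(pred_labels, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(true = labels, pred = labels))
  row_pct <- round(100 * counts / pmax(rowSums(counts), 1), 2)
  structure(list(counts = counts, row_pct = row_pct,
                 diagonal_accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: diagonal accuracy %.2f%%>\n",
              x$diagonal_accuracy))
  print(x$counts)
  invisible(x)
}

# half-up rounding to `digits` decimals (the convention of printed tables)
round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

# all integer count vectors of total n whose half-up 2-d.p. percentages
# equal `pct` (within pct_tol, for tables with typographic slips); each
# count is floor or ceiling of its ideal value
row_count_solutions <- function(pct, n, pct_tol = 0) {
  ideal <- pct * n / 100
  lo <- floor(ideal)
  hi <- ceiling(ideal)
  k <- length(pct)
  combos <- expand.grid(rep(list(c(0L, 1L)), k))
  sols <- list()
  for (i in seq_len(nrow(combos))) {
    cand <- lo + as.integer(combos[i, ]) * (hi - lo)
    if (sum(cand) == n && all(cand >= 0) &&
        all(abs(round_half_up(100 * cand / n) - round_half_up(pct)) <=
              pct_tol + 1e-9)) {
      sols[[length(sols) + 1L]] <- as.integer(cand)
    }
  }
  unique(sols)
}

feasible_row_totals <- function(pct, max_total, pct_tol = 0) {
  k <- length(pct)
  out <- integer(0)
  for (n in seq(k, max_total)) {
    if (length(row_count_solutions(pct, n, pct_tol))) out <- c(out, n)
  }
  out
}

#' Recover integer confusion counts from printed row percentages
#'
#' Published confusion matrices often print only row percentages (2 d.p.,
#' half-up). For each row this searches the smallest integer total
#' `n <= max_total` admitting nonnegative integer counts that reproduce the
#' printed percentages, and reports the counts, the count-weighted diagonal
#' accuracy, and whether several count vectors fit at that total. When
#' `grand_total` is given, row totals are instead chosen (each from its
#' feasible set, preferring the smallest) so that they sum to `grand_total`
#' — see [recover_confusion_joint] for inferring a common grand total across
#' several parameter tables that share one test set.
#'
#' @param row_percentages Numeric matrix, one row per true class, entries in
#'   percent (rows sum to 100 up to rounding).
#' @param max_total Largest row total to try (>= number of classes).
#' @param grand_total Optional required sum of row totals.
#' @param pct_tol Tolerated absolute deviation (percentage points) between a
#'   candidate's rounded percentages and the printed ones; default 0
#'   (exact). A small tolerance recovers rows whose printed value carries a
#'   typographic slip.
#' @return List with `counts` (integer matrix), `row_totals`,
#'   `diagonal_accuracy`, `non_unique` (logical per row).
#' @export
recover_counts_from_percentages <- function(row_percentages, max_total = 250L,
                                            grand_total = NULL, pct_tol = 0) {
  pm <- rbind(row_percentages)
  k <- ncol(pm)
  if (max_total < k) stop("max_total smaller than class count", call. = FALSE)
  bad <- abs(rowSums(pm) - 100) > 0.02 + ncol(pm) * pct_tol + 1e-9
  if (any(bad)) {
    stop("row percentages must sum to 100 (+/- 0.02): row ",
         which(bad)[1], call. = FALSE)
  }
  feas <- apply(pm, 1, feasible_row_totals, max_total = max_total,
                pct_tol = pct_tol, simplify = FALSE)
  if (any(lengths(feas) == 0)) {
    stop("no feasible total <= ", max_total, " for row ",
         which(lengths(feas) == 0)[1], call. = FALSE)
  }
  totals <- if (is.null(grand_total)) {
    vapply(feas, min, integer(1))
  } else {
    pick <- pick_totals_summing(feas, grand_total)
    if (is.null(pick)) {
      stop("no combination of feasible row totals sums to ", grand_total,
           call. = FALSE)
    }
    pick
  }
  counts <- matrix(0L, nrow(pm), k)
  non_unique <- logical(nrow(pm))
  for (i in seq_len(nrow(pm))) {
    sols <- row_count_solutions(pm[i, ], totals[i], pct_tol)
    counts[i, ] <- sols[[1]]
    non_unique[i] <- length(sols) > 1
  }
  list(counts = counts, row_totals = totals,
       diagonal_accuracy = 100 * sum(diag(counts)) / sum(counts),
       non_unique = non_unique)
}

# depth-first pick of one total per row so they sum to target (smallest first)
pick_totals_summing <- function(feas, target) {
  n <- length(feas)
  rec <- function(i, remaining) {
    if (i > n) return(if (remaining == 0) integer(0) else NULL)
    lower <- sum(vapply(feas[seq(i, n)], min, integer(1)))
    upper <- sum(vapply(feas[seq(i, n)], max, integer(1)))
    if (remaining < lower || remaining > upper) return(NULL)
    for (t in feas[[i]]) {
      rest <- rec(i + 1, remaining - t)
      if (!is.null(rest)) return(c(t, rest))
    }
    NULL
  }
  rec(1, target)
}

#' Joint count recovery across parameter tables sharing one test set
#'
#' All parameters of a published confusion table are evaluated on the same
#' cases, so their grand totals (sums of row totals) coincide. This computes,
#' per table, the set of achievable grand totals (all combinations of
#' feasible row totals up to `max_total`) and picks the smallest grand total
#' achievable by every table, then recovers each table's counts under that
#' constraint. This disambiguates rows whose percentages are also consistent
#' with a smaller total (e.g. a row printed as 25.93/3.70/70.37 fits 27 cases
#' as well as the true 54).
#'
#' @param tables Named list of row-percentage matrices.
#' @param max_total Largest row total to try.
#' @param pct_tol Percentage tolerance, see
#'   [recover_counts_from_percentages].
#' @return Named list of [recover_counts_from_percentages] results, with
#'   attribute `grand_total`.
#' @export
recover_confusion_joint <- function(tables, max_total = 250L, pct_tol = 0) {
  feas_sets <- lapply(tables, function(pm) {
    pm <- rbind(pm)
    feas <- apply(pm, 1, feasible_row_totals, max_total = max_total,
                  pct_tol = pct_tol, simplify = FALSE)
    if (any(lengths(feas) == 0)) {
      stop("no feasible totals for a row (max_total too small?)",
           call. = FALSE)
    }
    sums <- unique(unlist(lapply(
      seq_len(prod(lengths(feas))) - 1L,
      function(ix) {
        pick <- integer(length(feas))
        for (j in seq_along(feas)) {
          pick[j] <- feas[[j]][ix %% lengths(feas)[j] + 1L]
          ix <- ix %/% lengths(feas)[j]
        }
        sum(pick)
      })))
    sums[sums <= max_total]
  })
  common <- Reduce(intersect, feas_sets)
  if (length(common) == 0) {
    stop("tables admit no common grand total <= ", max_total, call. = FALSE)
  }
  g <- min(common)
  out <- lapply(tables, recover_counts_from_percentages,
                max_total = max_total, grand_total = g, pct_tol = pct_tol)
  attr(out, "grand_total") <- g
  out
}

#' Published confusion-matrix row percentages
#'
#' Row percentages (2 d.p.) of the confusion matrices published for
#' threshold classification of ANB, SNB, SNA and MW on the ISBI 2015 test
#' set, shipped as package data for use with
#' [recover_counts_from_percentages] and [recover_confusion_joint].
#'
#' @return Named list of numeric matrices (true classes in rows).
#' @export
reported_confusion_rows <- function() {
  tab <- utils::read.csv(system.file("extdata", "reported_confusion_rows.csv",
                                     package = "cephmark"),
                         stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$parameter), function(d) {
    d <- d[order(d$row), ]
    labels <- strsplit(d$class_labels[1], ";", fixed = TRUE)[[1]]
    m <- as.matrix(d[, paste0("p", seq_along(labels)), drop = FALSE])
    dimnames(m) <- list(true = labels, pred = labels)
    m
  })
  out[unique(tab$parameter)]
}
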