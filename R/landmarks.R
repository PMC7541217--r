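#' Canonical cephalometric landmark names
#'
#' The 19 landmarks in conventional reporting order (Sella through
#' Articulare). All landmark sets produced or consumed by cephmark are
#' validated against a registry of names; this is the default registry.
#'
#' @return Character vector of 19 landmark names.
#' @export
ceph_landmark_names <- function() {
  c(
    "Sella", "Nasion", "Orbitale", "Porion", "A-point", "B-point",
    "Pogonion", "Menton", "Gnathion", "Gonion",
    "Lower incisal incision", "Upper incisal incision",
    "Upper lip", "Lower lip", "Subnasale", "Soft tissue pogonion",
    "Posterior Nasal Spine", "Anterior Nasal Spine", "Articulare"
  )
}

#' Construct a landmark set
#'
#' A landmark set is a data frame of named 2-D points in millimetres, in the
#' image frame (origin at the centre of the top-left pixel, x rightward,
#' y downward), together with a provenance tag recording where the
#' coordinates came from.
#'
#' @param x_mm,y_mm Numeric coordinates in mm, one per landmark.
#' @param names Landmark names; default the canonical 19
#'   (truncated to `length(x_mm)` when fewer points are supplied, e.g. for
#'   reduced synthetic registries).
#' @param provenance One of `"annotatorA"`, `"annotatorB"`, `"ground_truth"`,
#'   `"prediction"`, `"truth"`.
#' @return A `landmark_set`: data frame with columns `name`, `x_mm`, `y_mm`.
#' @export
landmark_set <- function(x_mm, y_mm,
                         names = ceph_landmark_names()[seq_along(x_mm)],
                         provenance = c("ground_truth", "annotatorA",
                                        "annotatorB", "prediction", "truth")) {
  provenance <- match.arg(provenance)
  if (length(x_mm) != length(y_mm)) {
    stop("x_mm and y_mm must have the same length", call. = FALSE)
  }
  if (length(names) != length(x_mm)) {
    stop("need one name per landmark", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("duplicated landmark names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(x_mm)) || !all(is.finite(y_mm))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  out <- data.frame(name = as.character(names), x_mm = as.numeric(x_mm),
                    y_mm = as.numeric(y_mm), stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("landmark_set", "data.frame")
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d landmarks, provenance = %s>\n",
              nrow(x), attr(x, "provenance")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Provenance of a landmark set
#' @param ls A `landmark_set`.
#' @return Character scalar.
#' @export
landmark_provenance <- function(ls) attr(ls, "provenance")

assert_same_registry <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$name, b$name)) {
    stop("landmark sets use different landmark registries", call. = FALSE)
  }
  invisible(TRUE)
}

#' Ground truth as the mean of two annotators
#'
#' Manual annotations carry inter-observer variability; the reference
#' position for training and evaluation is the coordinate-wise arithmetic
#' mean of the two annotators' points, which compensates that variability.
#'
#' @param a,b Two complete `landmark_set`s over the same registry and frame.
#' @return A `landmark_set` with provenance `"ground_truth"`.
#' @export
ground_truth <- function(a, b) {
  assert_same_registry(a, b)
  landmark_set((a$x_mm + b$x_mm) / 2, (a$y_mm + b$y_mm) / 2,
               names = a$name, provenance = "ground_truth")
}

#' Look up one landmark's coordinates
#' @param ls A `landmark_set`.
#' @param name Landmark name.
#' @return Numeric length-2 vector `c(x_mm, y_mm)`.
#' @export
landmark_xy <- function(ls, name) {
  i <- match(name, ls$name)
  if (is.na(i)) stop("landmark not present: ", name, call. = FALSE)
  c(ls$x_mm[i], ls$y_mm[i])
}
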