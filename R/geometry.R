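#' Tubular-model geometry
#'
#' The bundle scaffold is a tube built on the bundle centroid: at five
#' centroid points (indexes 0, 3, 10, 17, 20) a circular cross-section is
#' erected in the plane normal to the local centroid tangent. Each circle
#' carries eight peripheral points at 45 degree spacing, delimiting eight
#' circular sectors that guide spline control-point placement.
#'
#' @name tubular-model
NULL

vnorm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic unit vector perpendicular to u: cross u with the coordinate
# axis along which u has its smallest absolute component (internal).
perpendicular_vector <- function(u) {
  e <- c(0, 0, 0)
  e[which.min(abs(u))] <- 1
  unit_vector(cross3(u, e))
}

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#'
#' Builds the proper 3 x 3 rotation matrix for a right-handed rotation by
#' `theta` degrees about the unit vector `axis`, written entrywise in the
#' axis-angle (Rodrigues) closed form.
#'
#' @param axis Length-3 unit vector (checked to within 1e-6; zero axis is an
#'   error).
#' @param theta Rotation angle in degrees.
#' @return A 3 x 3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, theta) {
  if (length(axis) != 3L || !all(is.finite(axis)))
    stop("'axis' must be a finite length-3 vector")
  n <- vnorm(axis)
  if (n < 1e-12) stop("rotation axis must be non-zero")
  if (abs(n - 1) > 1e-6) stop("rotation axis must be a unit vector")
  u <- axis / n
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th); vt <- 1 - ct
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ux * ux * vt + ct,      ux * uy * vt - uz * st, ux * uz * vt + uy * st,
    uy * ux * vt + uz * st, uy * uy * vt + ct,      uy * uz * vt - ux * st,
    uz * ux * vt - uy * st, uz * uy * vt + ux * st, uz * uz * vt + ct
  ), nrow = 3L, byrow = TRUE)
}

#' Unit tangents of a centroid at the cross-section points
#'
#' Fits one interpolating cubic spline per coordinate over a chord-length
#' parametrization of the centroid points and evaluates the analytic first
#' derivative at the requested points.
#'
#' @param centroid An n x 3 coordinate matrix (typically 21 points).
#' @param section_indexes 0-based point indexes at which tangents are
#'   evaluated (default [section_point_indexes()]).
#' @return A `length(section_indexes)` x 3 matrix of unit tangent vectors.
#' @export
centroid_tangents <- function(centroid, section_indexes = section_point_indexes()) {
  centroid <- as_fiber(centroid)
  if (any(section_indexes < 0L | section_indexes > nrow(centroid) - 1L))
    stop("section indexes out of range")
  seg <- sqrt(rowSums(diff(centroid)^2))
  if (sum(seg) < 1e-9)
    stop("degenerate centroid: zero spatial extent")
  if (any(seg < 1e-12))
    stop("degenerate centroid: coincident consecutive points")
  s <- c(0, cumsum(seg))
  at <- s[section_indexes + 1L]
  d <- vapply(1:3, function(k) {
    f <- stats::splinefun(s, centroid[, k], method = "fmm")
    f(at, deriv = 1L)
  }, numeric(length(at)))
  d <- matrix(d, ncol = 3L)
  t(apply(d, 1L, unit_vector))
}

#' Initial peripheral point of a cross-sectional circle
#'
#' Selects the point at distance `radius` from `center` in the plane through
#' `center` normal to `tangent`. When `reference_dir` is given, the radial
#' direction is its normalized projection onto that plane, which is how
#' successive circles stay aligned relative to the first circle point. A
#' reference parallel to the tangent falls back to a deterministic
#' perpendicular (with a message).
#'
#' @param center Circle center (length-3, mm).
#' @param tangent Unit tangent (plane normal).
#' @param radius Circle radius (mm, > 0).
#' @param reference_dir Optional radial reference direction.
#' @return A length-3 point.
#' @export
initial_peripheral_point <- function(center, tangent, radius, reference_dir = NULL) {
  if (radius <= 0) stop("radius must be positive")
  tangent <- unit_vector(tangent)
  dir <- NULL
  if (!is.null(reference_dir)) {
    proj <- reference_dir - sum(reference_dir * tangent) * tangent
    if (vnorm(proj) > 1e-9) {
      dir <- proj / vnorm(proj)
    } else {
      message("reference direction parallel to tangent; using deterministic perpendicular")
    }
  }
  if (is.null(dir)) dir <- perpendicular_vector(tangent)
  center + radius * dir
}

#' Build one cross-sectional circle of the tubular model
#'
#' The initial peripheral point is rotated seven times about the tangent axis
#' through the center, with angles 45, 90, ..., 315 degrees, yielding eight
#' peripheral points that delimit eight 45 degree circular sectors.
#'
#' @inheritParams initial_peripheral_point
#' @return An object of class `fibersim_cross_section` with fields `center`,
#'   `radius`, `tangent`, `peripheral` (8 x 3 matrix), and the in-plane
#'   orthonormal frame `e1`, `e2` (sector 0 starts at `e1`; `e2` is 90
#'   degrees along the rotation direction).
#' @export
build_cross_section <- function(center, tangent, radius, reference_dir = NULL) {
  tangent <- unit_vector(tangent)
  p0 <- initial_peripheral_point(center, tangent, radius, reference_dir)
  e1 <- (p0 - center) / radius
  e2 <- cross3(tangent, e1)
  peripheral <- matrix(NA_real_, 8L, 3L)
  peripheral[1L, ] <- p0
  for (k in 1:7) {
    R <- rotation_matrix(tangent, 45 * k)
    peripheral[k + 1L, ] <- center + as.vector(R %*% (p0 - center))
  }
  structure(
    list(center = as.numeric(center), radius = radius, tangent = tangent,
         peripheral = peripheral, e1 = e1, e2 = e2),
    class = "fibersim_cross_section"
  )
}

#' Build the tubular scaffold of a bundle
#'
#' Erects the five cross-sectional circles at the centroid points with the
#' given radii. The radial direction of the first circle is a deterministic
#' perpendicular of its tangent; each subsequent circle takes the previous
#' circle's radial direction as reference and projects it onto its own plane
#' (parallel-transport style), so that sector k of every section corresponds
#' to sector k of the next and the spline control nets do not twist.
#'
#' @param centroid A 21 x 3 centroid matrix.
#' @param radii Numeric vector of 5 positive radii (mm), ordered end,
#'   intermediate, central, intermediate, end.
#' @param section_indexes 0-based centroid point indexes of the sections.
#' @return An object of class `fibersim_tubular_model` with fields
#'   `sections` (list of 5 `fibersim_cross_section`), `section_indexes`,
#'   and `centroid`.
#' @export
build_tubular_model <- function(centroid, radii,
                                section_indexes = section_point_indexes()) {
  centroid <- as_fiber(centroid)
  if (length(radii) != length(section_indexes))
    stop("need one radius per cross-section")
  if (any(radii <= 0)) stop("all radii must be positive")
  tangents <- centroid_tangents(centroid, section_indexes)
  sections <- vector("list", length(section_indexes))
  ref <- NULL
  for (i in seq_along(section_indexes)) {
    ci <- centroid[section_indexes[i] + 1L, ]
    sections[[i]] <- build_cross_section(ci, tangents[i, ], radii[i],
                                         reference_dir = ref)
    ref <- sections[[i]]$e1
  }
  structure(
    list(sections = sections, section_indexes = as.integer(section_indexes),
         centroid = centroid),
    class = "fibersim_tubular_model"
  )
}

#' @export
print.fibersim_tubular_model <- function(x, ...) {
  cat(sprintf("<fibersim_tubular_model: %d sections at centroid indexes %s, radii %s mm>\n",
              length(x$sections),
              paste(x$section_indexes, collapse = ","),
              paste(format(vapply(x$sections, `[[`, 0, "radius"), digits = 3),
                    collapse = ",")))
  invisible(x)
}
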