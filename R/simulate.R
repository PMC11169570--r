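#' Bundle simulation
#'
#' Fibers are generated inside the tubular scaffold: for each fiber one of
#' the eight circular sectors is drawn, a control point is sampled uniformly
#' over that sector's disc wedge in each of the five cross-sections, and a
#' fourth-order spline through the five control points is resampled to 21
#' equidistant points. Gaussian dispersion can be added at the bundle ends.
#'
#' @name bundle-simulation
NULL

#' Simulation parameters for one bundle
#'
#' @param centroid A 21 x 3 centroid matrix describing the bundle trajectory.
#' @param radii 5 positive cross-section radii (mm).
#' @param n_fibers Number of fibers to generate (>= 1).
#' @param noise_mean Per-coordinate mean of the Gaussian end noise (mm).
#' @param noise_sigma Per-coordinate standard deviation of the end noise
#'   (mm, >= 0; 0 disables noise).
#' @param noise_point_indexes List with `head`/`tail` 0-based point index
#'   sets receiving noise (default points 0-4 and 16-20).
#' @param seed Optional integer seed making the bundle reproducible.
#' @return An object of class `fibersim_sim_params`.
#' @export
bundle_sim_params <- function(centroid, radii, n_fibers,
                              noise_mean = 0, noise_sigma = 0,
                              noise_point_indexes = default_noise_indexes(),
                              seed = NULL) {
  centroid <- as_fiber(centroid)
  if (length(radii) != 5L || any(radii <= 0))
    stop("'radii' must be 5 positive lengths (mm)")
  if (n_fibers < 1L) stop("'n_fibers' must be >= 1")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(
    list(centroid = centroid, radii = as.numeric(radii),
         n_fibers = as.integer(n_fibers),
         noise_mean = noise_mean, noise_sigma = noise_sigma,
         noise_point_indexes = noise_point_indexes,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "fibersim_sim_params"
  )
}

#' Sample a point uniformly over one circular sector of a cross-section
#'
#' Area-uniform sampling over the 45 degree disc wedge of the given sector:
#' the radial coordinate is `r * sqrt(u)` and the angle is uniform within
#' the sector, measured from the section's initial peripheral direction.
#'
#' @param section A `fibersim_cross_section`.
#' @param sector_index Sector number 0..7.
#' @return A length-3 point in the section plane.
#' @export
sample_sector_point <- function(section, sector_index) {
  if (sector_index < 0L || sector_index > 7L)
    stop("'sector_index' must be in 0..7")
  rr <- section$radius * sqrt(stats::runif(1L))
  ang <- (sector_index + stats::runif(1L)) * pi / 4
  section$center + rr * (cos(ang) * section$e1 + sin(ang) * section$e2)
}

#' Fit a fourth-order spline fiber over five control points
#'
#' Five control points define a fourth-order spline curve with clamped
#' ends — a degree-4 Bezier curve in Bernstein form. The curve starts and
#' ends exactly at the first and last control points, approximates the
#' curve between the inner control points, and never leaves their convex
#' hull, so fibers built from control points inside the tubular scaffold
#' stay inside the tube. The curve is resampled to `n_points` approximately
#' equidistant points along its arc length.
#'
#' @param control_points A 5 x 3 matrix, one control point per cross-section.
#' @param n_points Number of output points (default 21).
#' @param dense Number of dense samples used for arc-length resampling.
#' @return An `n_points` x 3 fiber matrix.
#' @export
fit_fiber_spline <- function(control_points, n_points = fiber_npoints_default(),
                             dense = 200L) {
  control_points <- as.matrix(control_points)
  if (nrow(control_points) != 5L || ncol(control_points) != 3L)
    stop("'control_points' must be a 5 x 3 matrix")
  seg <- sqrt(rowSums(diff(control_points)^2))
  if (any(seg < 1e-9)) stop("coincident control points")
  td <- seq(0, 1, length.out = dense)
  B <- vapply(0:4, function(k) choose(4, k) * td^k * (1 - td)^(4 - k),
              numeric(dense))                     # Bernstein basis
  curve <- B %*% control_points
  curve[1L, ] <- control_points[1L, ]
  curve[dense, ] <- control_points[5L, ]
  resample_fiber(curve, n_points)
}

#' Add Gaussian dispersion to the end points of a fiber
#'
#' Each named point is perturbed by an independent 3D Gaussian displacement
#' with the given per-coordinate mean and standard deviation; all other
#' points are returned unchanged.
#'
#' @param fiber An n x 3 fiber matrix.
#' @param mean Per-coordinate noise mean (mm).
#' @param sigma Per-coordinate noise standard deviation (mm, >= 0).
#' @param point_indexes List of 0-based index vectors (default
#'   [default_noise_indexes()]).
#' @return The perturbed fiber.
#' @export
add_end_noise <- function(fiber, mean = 0, sigma,
                          point_indexes = default_noise_indexes()) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0 && mean == 0) return(fiber)
  idx <- sort(unique(unlist(point_indexes))) + 1L
  if (any(idx < 1L | idx > nrow(fiber))) stop("noise point index out of range")
  noise <- matrix(stats::rnorm(length(idx) * 3L, mean = mean, sd = sigma),
                  ncol = 3L)
  fiber[idx, ] <- fiber[idx, ] + noise
  fiber
}

#' Simulate a fiber bundle
#'
#' Builds the tubular scaffold from the centroid and radii, then generates
#' `n_fibers` spline fibers. For each fiber a sector 0..7 is drawn uniformly
#' and one control point is sampled in that sector of every cross-section,
#' so the spline stays within one angular lane of the tube. Optional
#' Gaussian end noise is applied last. Given `params$seed`, the output is
#' fully reproducible; the caller's RNG state is left untouched.
#'
#' @param params A [bundle_sim_params()] object.
#' @param label Bundle label.
#' @return A [bundle()] whose `centroid` and `params` fields record the
#'   generating inputs.
#' @export
simulate_bundle <- function(params, label = "simulated") {
  stopifnot(inherits(params, "fibersim_sim_params"))
  model <- build_tubular_model(params$centroid, params$radii)
  with_seed(params$seed, {
    fibers <- vector("list", params$n_fibers)
    use_noise <- params$noise_sigma > 0 || params$noise_mean != 0
    for (j in seq_len(params$n_fibers)) {
      sector <- sample.int(8L, 1L) - 1L
      cps <- t(vapply(model$sections, sample_sector_point, numeric(3L),
                      sector_index = sector))
      f <- fit_fiber_spline(cps)
      if (use_noise)
        f <- add_end_noise(f, params$noise_mean, params$noise_sigma,
                           params$noise_point_indexes)
      fibers[[j]] <- f
    }
    bundle(fibers, label = label, centroid = params$centroid, params = params)
  })
}
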