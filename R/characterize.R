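#' Bundle characterization
#'
#' Extracts the simulation parameters of an existing bundle — centroid,
#' per-section radii, fiber count — so that a bundle from an atlas or a
#' previous simulation can be re-simulated. Fibers are first orientation-
#' aligned to a reference fiber, since streamlines can be stored in either
#' point order.
#'
#' @name bundle-characterization
NULL

#' Align the orientation of a fiber to a reference fiber
#'
#' Compares the summed Euclidean distances between corresponding endpoints
#' (`|f_first - ref_first| + |f_last - ref_last|`) against the crossed
#' pairing; when the crossed pairing is strictly smaller the fiber's point
#' order is reversed. Ties keep the fiber unchanged.
#'
#' @param fiber,reference Fibers with equal point counts.
#' @return The fiber, possibly reversed.
#' @export
align_fiber <- function(fiber, reference) {
  n <- nrow(fiber)
  direct <- vnorm(fiber[1L, ] - reference[1L, ]) +
            vnorm(fiber[n, ] - reference[nrow(reference), ])
  crossed <- vnorm(fiber[1L, ] - reference[nrow(reference), ]) +
             vnorm(fiber[n, ] - reference[1L, ])
  if (direct > crossed) reverse_fiber(fiber) else fiber
}

#' Select the reference fiber of a bundle
#'
#' Among fibers with polyline length greater than `min_length` (short fibers
#' tend to be noisier), returns the fiber minimizing the mean dME distance
#' to all other fibers of the bundle; ties are broken by lowest index. If no
#' fiber passes the length filter, all fibers are considered (with a
#' warning).
#'
#' @param x A bundle or list of fibers.
#' @param min_length Length filter in mm (default 50).
#' @return The reference fiber, with its index in the bundle attached as
#'   attribute `"index"`.
#' @export
select_reference_fiber <- function(x, min_length = 50) {
  fibers <- if (inherits(x, "fibersim_bundle")) x$fibers else x
  if (length(fibers) == 0L) stop("empty bundle")
  if (length(fibers) == 1L)
    return(structure(fibers[[1L]], index = 1L))
  lens <- vapply(fibers, fiber_length, numeric(1L))
  cand <- which(lens > min_length)
  if (length(cand) == 0L) {
    warning("no fiber longer than ", min_length,
            " mm; considering all fibers for the reference")
    cand <- seq_along(fibers)
  }
  D <- dme_matrix(fibers, fibers)
  mean_to_others <- (rowSums(D) - diag(D)) / (length(fibers) - 1L)
  best <- cand[which.min(mean_to_others[cand])]
  structure(fibers[[best]], index = best)
}

#' Orientation-align all fibers of a bundle to a reference
#'
#' @param x A bundle or list of fibers.
#' @param reference Reference fiber; defaults to [select_reference_fiber()].
#' @return A list of aligned fibers.
#' @export
align_bundle <- function(x, reference = NULL) {
  fibers <- if (inherits(x, "fibersim_bundle")) x$fibers else x
  if (is.null(reference)) reference <- select_reference_fiber(fibers)
  lapply(fibers, align_fiber, reference = reference)
}

#' Point-wise mean centroid of a bundle
#'
#' Point k of the centroid is the mean of point k over all fibers. Fibers
#' must be orientation-aligned first; when `align = TRUE` (default) the
#' alignment to the bundle's reference fiber is performed internally.
#'
#' @param x A bundle or list of fibers.
#' @param align Align fibers to the reference fiber before averaging.
#' @return A centroid fiber (n x 3 matrix).
#' @export
compute_centroid <- function(x, align = TRUE) {
  fibers <- if (inherits(x, "fibersim_bundle")) x$fibers else x
  if (length(fibers) == 0L) stop("empty bundle")
  if (align) fibers <- align_bundle(fibers)
  Reduce(`+`, fibers) / length(fibers)
}

#' Estimate the five cross-section radii of a bundle
#'
#' The radius of each cross-sectional circle is the mean Euclidean distance
#' between the circle's central point (the centroid point at that index)
#' and the corresponding point of every fiber. Fibers must be aligned to
#' the centroid orientation.
#'
#' @param x A bundle or list of aligned fibers.
#' @param centroid The bundle centroid.
#' @param section_indexes 0-based centroid point indexes of the sections.
#' @return Numeric vector of radii (mm), one per section.
#' @export
estimate_radii <- function(x, centroid,
                           section_indexes = section_point_indexes()) {
  fibers <- if (inherits(x, "fibersim_bundle")) x$fibers else x
  if (length(fibers) == 0L) stop("empty bundle")
  idx <- section_indexes + 1L
  arr <- fiber_array(fibers)
  vapply(idx, function(i) {
    d <- sweep(matrix(arr[, i, ], ncol = 3L), 2L, centroid[i, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1L))
}

#' Profile a bundle for re-simulation
#'
#' Chains reference-fiber selection, orientation alignment, centroid
#' computation, and radius estimation, returning the parameter set needed
#' to simulate a bundle resembling the input. Radii below `min_radius` are
#' clamped (with a warning) since a zero radius cannot seed the tubular
#' model.
#'
#' @param x A non-empty bundle or list of fibers.
#' @param min_length Reference-fiber length filter (mm).
#' @param min_radius Lower clamp for recovered radii (mm).
#' @return An object of class `fibersim_bundle_profile` with fields
#'   `centroid`, `radii`, `n_fibers`, `source_label`.
#' @export
profile_bundle <- function(x, min_length = 50, min_radius = 0.1) {
  fibers <- if (inherits(x, "fibersim_bundle")) x$fibers else x
  if (length(fibers) == 0L) stop("empty bundle")
  label <- if (inherits(x, "fibersim_bundle")) x$label else "bundle"
  ref <- select_reference_fiber(fibers, min_length)
  aligned <- align_bundle(fibers, ref)
  centroid <- compute_centroid(aligned, align = FALSE)
  radii <- estimate_radii(aligned, centroid)
  if (any(radii < min_radius)) {
    warning("recovered radii below ", min_radius, " mm clamped")
    radii <- pmax(radii, min_radius)
  }
  structure(
    list(centroid = centroid, radii = radii, n_fibers = length(fibers),
         source_label = label),
    class = "fibersim_bundle_profile"
  )
}

#' @export
print.fibersim_bundle_profile <- function(x, ...) {
  cat(sprintf("<fibersim_bundle_profile '%s': %d fibers, radii %s mm>\n",
              x$source_label, x$n_fibers,
              paste(format(x$radii, digits = 3), collapse = ",")))
  invisible(x)
}
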