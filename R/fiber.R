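#' Fiber and bundle containers
#'
#' A fiber (streamline) is an ordered polyline in 3D, stored as an n x 3
#' numeric matrix of RAS millimetre coordinates. The package convention,
#' following common deep-white-matter processing pipelines, is 21 equidistant
#' points per fiber; [resample_fiber()] enforces this. A bundle is a labelled
#' set of fibers sharing one centroid.
#'
#' @name fiber
NULL

#' Number of points per fiber under the package convention
#' @return The integer 21.
#' @export
fiber_npoints_default <- function() 21L

#' Centroid point indexes of the five cross-sectional regions
#'
#' The tubular model places its five cross-sections (two ends, two
#' intermediate, one central) at these centroid point indexes. Indexes are
#' 0-based, matching the streamline-processing convention for 21-point
#' fibers.
#'
#' @return Integer vector `c(0, 3, 10, 17, 20)`.
#' @export
section_point_indexes <- function() c(0L, 3L, 10L, 17L, 20L)

#' Default end-noise point index sets
#'
#' Gaussian dispersion at the bundle ends is applied to the first and last
#' five points of each fiber (0-based indexes 0-4 and 16-20 for 21-point
#' fibers).
#'
#' @return A list with components `head` and `tail` of 0-based point indexes.
#' @export
default_noise_indexes <- function() list(head = 0:4, tail = 16:20)

#' Construct and validate a fiber
#'
#' @param points An n x 3 numeric matrix (mm), or something coercible to one.
#' @param n_points Required number of points, or `NULL` to accept any n >= 2.
#' @return The validated points matrix.
#' @export
as_fiber <- function(points, n_points = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("a fiber must be an n x 3 matrix of 3D coordinates")
  if (!is.null(n_points) && nrow(points) != n_points)
    stop(sprintf("fiber has %d points, expected %d", nrow(points), n_points))
  if (nrow(points) < 2L)
    stop("a fiber needs at least 2 points")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("fiber contains non-finite coordinates")
  if (all(abs(sweep(points, 2L, points[1L, ])) < 1e-12))
    stop("degenerate fiber: all points identical")
  dimnames(points) <- NULL
  points
}

#' Polyline length of a fiber
#'
#' @param fiber An n x 3 coordinate matrix.
#' @return Sum of consecutive point distances (mm).
#' @export
fiber_length <- function(fiber) {
  d <- diff(fiber)
  sum(sqrt(rowSums(d^2)))
}

#' Reverse the point order of a fiber
#' @param fiber An n x 3 coordinate matrix.
#' @return The fiber with rows in reverse order.
#' @export
reverse_fiber <- function(fiber) fiber[rev(seq_len(nrow(fiber))), , drop = FALSE]

#' Resample a fiber to equidistant points along its polyline
#'
#' Linear interpolation at equal arc-length steps along the polyline. The
#' first and last points are preserved exactly.
#'
#' @param fiber An n x 3 coordinate matrix.
#' @param n Number of output points (default 21).
#' @return An n x 3 matrix.
#' @export
resample_fiber <- function(fiber, n = fiber_npoints_default()) {
  seg <- sqrt(rowSums(diff(fiber)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("cannot resample a zero-length fiber")
  target <- seq(0, total, length.out = n)
  out <- vapply(1:3, function(k) {
    stats::approx(s, fiber[, k], xout = target, ties = "ordered")$y
  }, numeric(n))
  out[1L, ] <- fiber[1L, ]
  out[n, ] <- fiber[nrow(fiber), ]
  out
}

#' Construct a bundle
#'
#' @param fibers List of fibers (n x 3 matrices), all with the same number of
#'   points.
#' @param label Bundle label (character or integer-like).
#' @param centroid Optional centroid fiber.
#' @param params Optional simulation parameters ([bundle_sim_params()]) when
#'   the bundle was simulated.
#' @return An object of class `fibersim_bundle`.
#' @export
bundle <- function(fibers, label = "bundle", centroid = NULL, params = NULL) {
  if (!is.list(fibers) || length(fibers) == 0L)
    stop("'fibers' must be a non-empty list of coordinate matrices")
  np <- nrow(fibers[[1L]])
  fibers <- lapply(fibers, as_fiber, n_points = np)
  structure(
    list(label = as.character(label), fibers = fibers,
         centroid = centroid, params = params),
    class = "fibersim_bundle"
  )
}

#' Number of fibers in a bundle
#' @param x A `fibersim_bundle`.
#' @return Integer count.
#' @export
n_fibers <- function(x) length(x$fibers)

#' @export
print.fibersim_bundle <- function(x, ...) {
  cat(sprintf("<fibersim_bundle '%s': %d fibers x %d points>\n",
              x$label, n_fibers(x), nrow(x$fibers[[1L]])))
  invisible(x)
}

# Stack a list of fibers into an n x p x 3 array (internal).
fiber_array <- function(fibers) {
  if (is.array(fibers) && length(dim(fibers)) == 3L) return(fibers)
  if (inherits(fibers, "fibersim_bundle")) fibers <- fibers$fibers
  p <- nrow(fibers[[1L]])
  arr <- array(NA_real_, dim = c(length(fibers), p, 3L))
  for (i in seq_along(fibers)) arr[i, , ] <- fibers[[i]]
  arr
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards (internal).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible sub-seed from a base seed and fiber content, so that
# per-bundle streams depend on the centroid geometry, not its position in the
# input list (internal).
derive_seed <- function(seed, fiber, salt = 0L) {
  h <- sum(floor(abs(fiber) * 64)) %% 1048573
  as.integer((as.numeric(seed) * 7919 + h * 31 + salt) %% 2147483629)
}
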