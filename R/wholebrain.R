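#' Whole-brain ground-truth datasets
#'
#' A ground-truth dataset is a set of simulated bundles with known per-fiber
#' labels, built from a set of centroids (sampled from a tractography or
#' generated synthetically inside a brain-shaped volume) and per-bundle
#' parameters drawn from calibrated ranges: end radii 8-10 mm, intermediate
#' radii 6-8 mm (each below its neighbouring end radius), central radius
#' 5-7 mm (below both intermediate radii), 50-300 fibers per bundle, and
#' end-noise sigma 2.5-3.5 mm. Bundles whose fibers come closer than 10 mm
#' to another bundle's fibers are registered as crossing pairs.
#'
#' @name wholebrain
NULL

#' Specification of a ground-truth dataset
#'
#' @param n_bundles Number of bundles to simulate.
#' @param r_end Range (mm) of the end-circle radii r1, r5.
#' @param r_mid Range (mm) of the intermediate radii r2, r4.
#' @param r_central Range (mm) of the central radius r3.
#' @param fiber_range Range of per-bundle fiber counts.
#' @param sigma_range Range (mm) of the Gaussian end-noise sigma.
#' @param noise_mean Per-coordinate noise mean (mm).
#' @param min_length Centroid length filter (mm).
#' @param min_distance Minimum pairwise centroid dME distance (mm).
#' @param crossing_threshold Fiber distance (mm) below which two bundles
#'   count as crossing.
#' @param distribution Sampling law over each range: `"truncnorm"` (normal
#'   centred at the range midpoint with sd = range/4, truncated to the
#'   range) or `"uniform"`.
#' @param seed Optional dataset seed.
#' @return An object of class `fibersim_dataset_spec`.
#' @export
dataset_spec <- function(n_bundles,
                         r_end = c(8, 10), r_mid = c(6, 8), r_central = c(5, 7),
                         fiber_range = c(50L, 300L), sigma_range = c(2.5, 3.5),
                         noise_mean = 0,
                         min_length = 50, min_distance = 10,
                         crossing_threshold = 10,
                         distribution = c("truncnorm", "uniform"),
                         seed = NULL) {
  distribution <- match.arg(distribution)
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!all(vapply(list(r_end, r_mid, r_central, fiber_range, sigma_range),
                  rng_ok, logical(1L))))
    stop("all ranges must be length-2 vectors with min <= max")
  if (n_bundles < 1L) stop("'n_bundles' must be >= 1")
  structure(
    list(n_bundles = as.integer(n_bundles),
         r_end = r_end, r_mid = r_mid, r_central = r_central,
         fiber_range = as.integer(fiber_range), sigma_range = sigma_range,
         noise_mean = noise_mean,
         min_length = min_length, min_distance = min_distance,
         crossing_threshold = crossing_threshold,
         distribution = distribution,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "fibersim_dataset_spec"
  )
}

# One draw from the spec's sampling law over [lo, hi] (internal).
draw_in_range <- function(range, distribution, upper = Inf, cap = 1000L) {
  lo <- range[1]; hi <- min(range[2], Inf)
  for (i in seq_len(cap)) {
    x <- if (distribution == "uniform") stats::runif(1L, lo, hi)
         else stats::rnorm(1L, mean = (lo + hi) / 2, sd = max((hi - lo) / 4, 1e-12))
    if (x >= lo && x <= hi && x < upper) return(x)
    if (lo == hi && lo < upper) return(lo)
  }
  stop("could not draw a value in [", lo, ", ", hi, "] below ", upper,
       " after ", cap, " attempts")
}

#' Draw the simulation parameters of one bundle
#'
#' End radii are drawn first within their range; each intermediate radius is
#' drawn within its range but below its end radius; the central radius is
#' drawn within its range but below both intermediate radii (redraw until
#' valid, capped). Fiber count and noise sigma are drawn from their ranges.
#' Uses the current RNG stream.
#'
#' @param spec A [dataset_spec()].
#' @return A list with `radii` (length 5), `n_fibers`, `noise_sigma`.
#' @export
sample_bundle_params <- function(spec) {
  d <- spec$distribution
  r1 <- draw_in_range(spec$r_end, d)
  r5 <- draw_in_range(spec$r_end, d)
  r2 <- draw_in_range(spec$r_mid, d, upper = r1)
  r4 <- draw_in_range(spec$r_mid, d, upper = r5)
  r3 <- draw_in_range(spec$r_central, d, upper = min(r2, r4))
  nf <- as.integer(round(draw_in_range(spec$fiber_range + c(-0.49, 0.49), d)))
  nf <- max(spec$fiber_range[1], min(spec$fiber_range[2], nf))
  sg <- draw_in_range(spec$sigma_range, d)
  list(radii = c(r1, r2, r3, r4, r5), n_fibers = nf, noise_sigma = sg)
}

#' Select bundle centroids from a tractography
#'
#' Filters fibers by polyline length (`> min_length`), then randomly picks
#' fibers whose pairwise dME distance to all previously accepted centroids
#' is at least `min_distance`.
#'
#' @param tractography List of fibers (equal point counts).
#' @param n Number of centroids wanted.
#' @param min_length Length filter (mm).
#' @param min_distance Minimum pairwise dME distance (mm).
#' @return A list of `n` centroid fibers. Errors (reporting the achievable
#'   count) if fewer than `n` qualify.
#' @export
select_centroids <- function(tractography, n, min_length = 50,
                             min_distance = 10) {
  if (length(tractography) == 0L) stop("empty tractography")
  lens <- vapply(tractography, fiber_length, numeric(1L))
  pool <- tractography[lens > min_length]
  if (length(pool) == 0L)
    stop("no fiber longer than ", min_length, " mm")
  order <- sample.int(length(pool))
  accepted <- list()
  for (i in order) {
    f <- pool[[i]]
    ok <- all(vapply(accepted, function(a) dme(f, a) >= min_distance,
                     logical(1L)))
    if (ok) accepted[[length(accepted) + 1L]] <- f
    if (length(accepted) == n) return(accepted)
  }
  stop("only ", length(accepted), " centroids satisfy the filters; ",
       n, " requested")
}

#' Generate synthetic bundle centroids inside a brain-shaped volume
#'
#' Self-contained stand-in for centroids sampled from a real whole-brain
#' tractography: smooth random quadratic arcs (Bezier curves) whose
#' endpoints lie inside an ellipsoidal volume of roughly adult-brain
#' dimensions, resampled to 21 points, filtered by length (`> min_length`)
#' and pairwise dME distance (`>= min_distance`). Rejection sampling; errors
#' when the iteration cap is exceeded.
#'
#' @param n Number of centroids.
#' @param semi_axes Ellipsoid semi-axes (mm), default `c(70, 85, 60)`
#'   (left-right, anterior-posterior, inferior-superior).
#' @param center Ellipsoid center (mm).
#' @param min_length Length filter (mm).
#' @param min_distance Minimum pairwise dME distance (mm).
#' @param span Range (mm) of endpoint separations drawn for each arc.
#' @param bow Maximum perpendicular offset (mm) of the arc midpoint.
#' @param max_iter Rejection-sampling iteration cap.
#' @param seed Optional seed.
#' @return A list of `n` centroid fibers (21 x 3 matrices).
#' @export
generate_synthetic_centroids <- function(n, semi_axes = c(70, 85, 60),
                                         center = c(0, 0, 0),
                                         min_length = 50, min_distance = 10,
                                         span = c(60, 150), bow = 30,
                                         max_iter = 500L * n, seed = NULL) {
  if (n < 1L) stop("'n' must be >= 1")
  inside <- function(p) {
    q <- sweep(p, 2L, center)
    all(rowSums(sweep(q, 2L, semi_axes, `/`)^2) <= 1)
  }
  sample_point <- function(shrink = 0.92) {
    repeat {
      p <- stats::runif(3L, -1, 1)
      if (sum(p^2) <= 1) return(center + shrink * semi_axes * p)
    }
  }
  with_seed(seed, {
    accepted <- list()
    for (it in seq_len(max_iter)) {
      a <- sample_point()
      b <- sample_point()
      d <- vnorm(b - a)
      if (d < span[1] || d > span[2]) next
      mid <- (a + b) / 2
      u <- unit_vector(b - a)
      perp <- perpendicular_vector(u)
      # random rotation of the bow direction about the chord
      ang <- stats::runif(1L, 0, 360)
      perp <- as.vector(rotation_matrix(u, ang) %*% perp)
      m <- mid + stats::runif(1L, 0.2, 1) * bow * perp
      tt <- seq(0, 1, length.out = 60L)
      curve <- outer((1 - tt)^2, a) + outer(2 * tt * (1 - tt), m) +
               outer(tt^2, b)
      f <- resample_fiber(curve, fiber_npoints_default())
      if (!inside(f)) next
      if (fiber_length(f) <= min_length) next
      ok <- all(vapply(accepted, function(g) dme(f, g) >= min_distance,
                       logical(1L)))
      if (!ok) next
      accepted[[length(accepted) + 1L]] <- f
      if (length(accepted) == n) return(accepted)
    }
    stop("synthetic centroid generation exceeded ", max_iter,
         " iterations with ", length(accepted), "/", n, " accepted")
  })
}

#' Build a whole-brain ground-truth dataset
#'
#' Draws per-bundle parameters and simulates one bundle per centroid,
#' assigning integer labels 0..n-1 and registering crossing bundle pairs.
#' Each bundle's RNG stream is seeded from the dataset seed and the
#' centroid's own geometry, so permuting the centroid list permutes the
#' labels but leaves each bundle's geometry unchanged.
#'
#' @param spec A [dataset_spec()] with `n_bundles == length(centroids)`.
#' @param centroids List of centroid fibers.
#' @return An object of class `fibersim_dataset`: `bundles` (list), `labels`
#'   (integer per fiber, in bundle order), `crossing_pairs` (2-column matrix
#'   of bundle labels), `params` (per-bundle parameter list), `spec`.
#' @export
build_dataset <- function(spec, centroids) {
  stopifnot(inherits(spec, "fibersim_dataset_spec"))
  if (length(centroids) != spec$n_bundles)
    stop("need exactly ", spec$n_bundles, " centroids, got ", length(centroids))
  base_seed <- if (is.null(spec$seed)) 0L else spec$seed
  bundles <- vector("list", spec$n_bundles)
  params <- vector("list", spec$n_bundles)
  for (i in seq_len(spec$n_bundles)) {
    cen <- as_fiber(centroids[[i]], fiber_npoints_default())
    bseed <- derive_seed(base_seed, cen)
    par <- with_seed(bseed, sample_bundle_params(spec))
    sp <- bundle_sim_params(cen, par$radii, par$n_fibers,
                            noise_mean = spec$noise_mean,
                            noise_sigma = par$noise_sigma,
                            seed = derive_seed(base_seed, cen, salt = 1L))
    bundles[[i]] <- simulate_bundle(sp, label = as.character(i - 1L))
    params[[i]] <- par
  }
  labels <- rep.int(0:(spec$n_bundles - 1L),
                    vapply(bundles, n_fibers, integer(1L)))
  ds <- structure(
    list(bundles = bundles, labels = labels,
         crossing_pairs = NULL, params = params, spec = spec),
    class = "fibersim_dataset"
  )
  ds$crossing_pairs <- detect_crossings(ds, threshold = spec$crossing_threshold)
  ds
}

#' All fibers of a dataset, in bundle order
#' @param dataset A `fibersim_dataset`.
#' @return A list of fibers matching `dataset$labels`.
#' @export
dataset_fibers <- function(dataset) {
  do.call(c, lapply(dataset$bundles, `[[`, "fibers"))
}

#' @export
print.fibersim_dataset <- function(x, ...) {
  cat(sprintf("<fibersim_dataset: %d bundles, %d fibers, %d crossing pairs>\n",
              length(x$bundles), length(x$labels), nrow(x$crossing_pairs)))
  invisible(x)
}

#' Detect crossing bundle pairs
#'
#' Two bundles cross when they contain fibers at a dME distance below
#' `threshold` (default 10 mm). Pairs are prefiltered with the metric lower
#' bound `min fiber distance >= dme(centroidA, centroidB) - RA - RB`, where
#' R is each bundle's maximal fiber-to-centroid dME; surviving pairs are
#' checked exactly against the full cross-distance matrix.
#'
#' @param x A `fibersim_dataset` or list of bundles.
#' @param threshold Crossing distance in mm.
#' @return A 2-column integer matrix of unordered crossing label pairs
#'   (labels as in the dataset, sorted, a < b). Zero rows when none cross.
#' @export
detect_crossings <- function(x, threshold = 10) {
  bundles <- if (inherits(x, "fibersim_dataset")) x$bundles else x
  nb <- length(bundles)
  labels <- vapply(seq_len(nb), function(i) {
    lb <- suppressWarnings(as.integer(bundles[[i]]$label))
    if (is.na(lb)) i - 1L else lb
  }, integer(1L))
  if (nb < 2L)
    return(matrix(integer(0L), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  reps <- lapply(bundles, function(b) {
    if (!is.null(b$centroid)) b$centroid else compute_centroid(b, align = FALSE)
  })
  radius <- vapply(seq_len(nb), function(i) {
    max(dme_matrix(bundles[[i]], list(reps[[i]])))
  }, numeric(1L))
  pairs <- list()
  for (i in 1:(nb - 1L)) {
    for (j in (i + 1L):nb) {
      lower <- dme(reps[[i]], reps[[j]]) - radius[i] - radius[j]
      if (lower >= threshold) next
      if (min(dme_matrix(bundles[[i]], bundles[[j]])) < threshold)
        pairs[[length(pairs) + 1L]] <- sort(c(labels[i], labels[j]))
    }
  }
  if (length(pairs) == 0L)
    return(matrix(integer(0L), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("a", "b"))
  m
}
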