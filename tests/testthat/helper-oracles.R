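# Fixtures and independent oracles used across the test files.

# straight fiber along +x starting at `origin`, length `len`
straight_fiber <- function(len = 80, n = 21, origin = c(0, 0, 0)) {
  cbind(seq(0, len, length.out = n) + origin[1], origin[2], origin[3])
}

# planar circular arc of radius R spanning `span` radians in the xy-plane
arc_fiber <- function(R = 50, span = pi / 2, n = 21) {
  th <- seq(0, span, length.out = n)
  cbind(R * cos(th), R * sin(th), 0)
}

# rotation matrix from the unit quaternion built from (axis, angle in deg):
# an independent construction of the same rotation
quaternion_rotation <- function(axis, theta_deg) {
  th <- theta_deg * pi / 180
  q <- c(cos(th / 2), sin(th / 2) * axis / sqrt(sum(axis^2)))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random smooth-ish fiber: jittered straight line (for metric oracles)
random_fiber <- function(n = 21, scale = 5) {
  straight_fiber(stats::runif(1, 60, 100), n,
                 origin = stats::runif(3, -40, 40)) +
    matrix(stats::rnorm(n * 3, sd = scale), ncol = 3)
}

# scalar per-pair dME, written the naive way (oracle for dme/dme_matrix)
dme_brute <- function(a, b) {
  n <- nrow(a)
  direct <- 0; flip <- 0
  for (i in 1:n) {
    direct <- max(direct, sqrt(sum((a[i, ] - b[i, ])^2)))
    flip <- max(flip, sqrt(sum((a[i, ] - b[n + 1 - i, ])^2)))
  }
  min(direct, flip)
}

# brute-force nearest-neighbour inter-bundle distance oracle
inter_bundle_brute <- function(A, B) {
  fa <- A$fibers; fb <- B$fibers
  da <- sapply(fa, function(f) min(sapply(fb, function(g) dme_brute(f, g))))
  db <- sapply(fb, function(f) min(sapply(fa, function(g) dme_brute(f, g))))
  c(mean = mean(c(da, db)), sd = stats::sd(c(da, db)))
}

# brute-force crossing scan over all bundle pairs (labels as in bundles)
crossings_brute <- function(bundles, threshold = 10) {
  nb <- length(bundles)
  out <- NULL
  if (nb < 2) return(matrix(integer(0), ncol = 2))
  for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
    dmin <- Inf
    for (f in bundles[[i]]$fibers) for (g in bundles[[j]]$fibers)
      dmin <- min(dmin, dme_brute(f, g))
    if (dmin < threshold)
      out <- rbind(out, sort(as.integer(c(bundles[[i]]$label,
                                          bundles[[j]]$label))))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# direct-summation Sn/PPV/Acc oracle
sn_ppv_brute <- function(t, N = rowSums(t)) {
  sn_num <- 0
  for (i in seq_len(nrow(t))) sn_num <- sn_num + max(t[i, ])
  ppv_num <- 0; ppv_den <- 0
  for (j in seq_len(ncol(t))) {
    ppv_num <- ppv_num + max(t[, j])
    ppv_den <- ppv_den + sum(t[, j])
  }
  sn <- sn_num / sum(N); ppv <- ppv_num / ppv_den
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# plain per-pair reference QuickBundles (independent of the vectorized
# implementation): same greedy algorithm, naive distance loops
qb_reference <- function(fibers, threshold, n_points = 12) {
  rs <- lapply(fibers, fibersim::resample_fiber, n = n_points)
  mdf_pair <- function(a, b) {
    d1 <- mean(sqrt(rowSums((a - b)^2)))
    d2 <- mean(sqrt(rowSums((a - b[nrow(b):1, ])^2)))
    min(d1, d2)
  }
  cents <- list(); counts <- c(); labels <- integer(length(fibers))
  for (f in seq_along(rs)) {
    v <- rs[[f]]
    best <- Inf; bj <- 0
    for (j in seq_along(cents)) {
      d <- mdf_pair(v, cents[[j]])
      if (d < best) { best <- d; bj <- j }
    }
    if (bj > 0 && best < threshold) {
      d1 <- mean(sqrt(rowSums((v - cents[[bj]])^2)))
      d2 <- mean(sqrt(rowSums((v[nrow(v):1, ] - cents[[bj]])^2)))
      add <- if (d1 <= d2) v else v[nrow(v):1, ]
      cents[[bj]] <- cents[[bj]] + (add - cents[[bj]]) / (counts[bj] + 1)
      counts[bj] <- counts[bj] + 1
      labels[f] <- bj
    } else {
      cents[[length(cents) + 1]] <- v
      counts <- c(counts, 1)
      labels[f] <- length(cents)
    }
  }
  labels
}

# a small simulated bundle reused across tests
test_bundle <- function(n = 60, radii = rep(5, 5), sigma = 0, seed = 1,
                        origin = c(0, 0, 0), len = 80) {
  cen <- straight_fiber(len, origin = origin)
  simulate_bundle(bundle_sim_params(cen, radii, n, noise_sigma = sigma,
                                    seed = seed))
}
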