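# Whole-brain ground truth: parameter sampling, centroids, crossings.

test_that("per-bundle parameter draws satisfy the range and ordering rules", {
  spec <- dataset_spec(1)
  set.seed(81)
  draws <- replicate(2000, sample_bundle_params(spec), simplify = FALSE)
  for (d in draws) {
    r <- d$radii
    expect_true(r[1] >= 8 && r[1] <= 10)
    expect_true(r[5] >= 8 && r[5] <= 10)
    expect_true(r[2] >= 6 && r[2] <= 8 && r[2] < r[1])
    expect_true(r[4] >= 6 && r[4] <= 8 && r[4] < r[5])
    expect_true(r[3] >= 5 && r[3] <= 7 && r[3] < min(r[2], r[4]))
    expect_true(d$n_fibers >= 50 && d$n_fibers <= 300)
    expect_true(d$noise_sigma >= 2.5 && d$noise_sigma <= 3.5)
  }
  # collapsed ranges become deterministic
  spec0 <- dataset_spec(1, r_end = c(9, 9), r_mid = c(7, 7),
                        r_central = c(6, 6), fiber_range = c(100L, 100L),
                        sigma_range = c(3, 3))
  d0 <- sample_bundle_params(spec0)
  expect_equal(d0$radii, c(9, 7, 6, 7, 9))
  expect_identical(d0$n_fibers, 100L)
})

test_that("unconstrained radius marginals follow the truncated normal law", {
  spec <- dataset_spec(1)
  set.seed(82)
  r1 <- vapply(1:2000, function(i) sample_bundle_params(spec)$radii[1], 0)
  ptrunc <- function(q) {
    (stats::pnorm(q, 9, 0.5) - stats::pnorm(8, 9, 0.5)) /
      (stats::pnorm(10, 9, 0.5) - stats::pnorm(8, 9, 0.5))
  }
  ks <- suppressWarnings(stats::ks.test(r1, ptrunc))
  expect_gt(ks$p.value, 0.01)
  # uniform alternative stays in range too
  specu <- dataset_spec(1, distribution = "uniform")
  set.seed(83)
  ru <- replicate(200, sample_bundle_params(specu)$radii[1])
  expect_true(all(ru >= 8 & ru <= 10))
})

test_that("centroid selection filters by length and pairwise distance", {
  f <- straight_fiber(80)
  pool <- list(
    straight_fiber(30),                                  # too short
    f,
    f + rep(c(0, 3, 0), each = 21),                      # too close to f
    f + rep(c(0, 25, 0), each = 21),
    f + rep(c(0, 50, 0), each = 21)
  )
  set.seed(84)
  sel <- select_centroids(pool, 3)
  expect_length(sel, 3)
  expect_true(all(vapply(sel, fiber_length, 0) > 50))
  D <- dme_matrix(sel, sel)
  expect_true(all(D[upper.tri(D)] >= 10))
  expect_error(select_centroids(pool, 4), "3 centroids satisfy")
  set.seed(85)
  one <- select_centroids(pool, 1)
  expect_gt(fiber_length(one[[1]]), 50)
})

test_that("synthetic centroids satisfy their own filters and reproduce", {
  cents <- generate_synthetic_centroids(30, seed = 86)
  expect_length(cents, 30)
  expect_true(all(vapply(cents, nrow, 0L) == 21L))
  expect_true(all(vapply(cents, fiber_length, 0) > 50))
  D <- dme_matrix(cents, cents)
  expect_true(all(D[upper.tri(D)] >= 10))
  # contained in the brain-shaped ellipsoid
  for (f in cents)
    expect_true(all(rowSums(sweep(f, 2, c(70, 85, 60), `/`)^2) <= 1 + 1e-9))
  # pairwise distances on the order of the volume scale
  expect_gt(mean(D[upper.tri(D)]), 30)
  expect_lt(mean(D[upper.tri(D)]), 200)
  expect_identical(generate_synthetic_centroids(5, seed = 87),
                   generate_synthetic_centroids(5, seed = 87))
  expect_error(generate_synthetic_centroids(500, semi_axes = c(20, 20, 20),
                                            max_iter = 300L),
               "exceeded")
})

test_that("dataset assembly: bookkeeping, ranges, determinism, permutation", {
  cents <- generate_synthetic_centroids(6, seed = 88)
  spec <- dataset_spec(6, seed = 89)
  ds <- build_dataset(spec, cents)
  counts <- vapply(ds$bundles, n_fibers, 0L)
  expect_identical(length(ds$labels), sum(counts))
  expect_identical(as.integer(table(ds$labels)), counts)
  expect_identical(vapply(ds$bundles, `[[`, "", "label"), as.character(0:5))
  for (p in ds$params) {
    expect_true(all(p$radii > 0))
    expect_true(p$n_fibers >= 50 && p$n_fibers <= 300)
  }
  # reproducible by seed
  ds2 <- build_dataset(spec, cents)
  expect_identical(ds$bundles[[3]]$fibers, ds2$bundles[[3]]$fibers)
  # permuting centroids permutes labels but not geometry
  perm <- c(4, 1, 6, 2, 5, 3)
  dsp <- build_dataset(spec, cents[perm])
  for (i in seq_along(perm))
    expect_identical(dsp$bundles[[i]]$fibers, ds$bundles[[perm[i]]]$fibers)
})

test_that("crossing detection matches the brute-force scan", {
  # widely separated straight bundles never cross
  far <- list(test_bundle(n = 8, seed = 91, origin = c(0, 0, 0)),
              test_bundle(n = 8, seed = 92, origin = c(0, 100, 0)),
              test_bundle(n = 8, seed = 93, origin = c(0, 200, 0)))
  far[[1]]$label <- "0"; far[[2]]$label <- "1"; far[[3]]$label <- "2"
  expect_identical(nrow(detect_crossings(far)), 0L)
  # two centroids 5 mm apart cross
  near <- list(test_bundle(n = 10, seed = 94),
               test_bundle(n = 10, seed = 95, origin = c(0, 5, 0)))
  near[[1]]$label <- "0"; near[[2]]$label <- "1"
  cp <- detect_crossings(near)
  expect_equal(unname(cp), matrix(c(0L, 1L), ncol = 2))
  # random synthetic dataset equals the O(n^2) oracle
  cents <- generate_synthetic_centroids(8, seed = 96, min_distance = 12)
  ds <- build_dataset(dataset_spec(8, seed = 97), cents)
  small <- lapply(ds$bundles, function(b) {
    bundle(b$fibers[seq_len(min(25, n_fibers(b)))], label = b$label,
           centroid = b$centroid)
  })
  expect_equal(unname(detect_crossings(small)),
               unname(crossings_brute(small)))
})
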