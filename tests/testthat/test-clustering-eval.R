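# Cluster-evaluation metrics, QuickBundles baseline, permutation harness.

test_that("overlap score evaluates its closed form and is symmetric", {
  expect_equal(overlap_score(1:8, 1:8), 1)
  expect_equal(overlap_score(1:4, 5:8), 0)
  expect_equal(overlap_score(1:4, 1:8), 16 / 32)
  expect_equal(overlap_score(1:8, 1:4), overlap_score(1:4, 1:8))
  expect_error(overlap_score(integer(0), 1:3), "empty")
  # OS = 1 iff the clusters are equal as sets
  set.seed(111)
  for (k in 1:20) {
    cp <- sample(100, sample(3:20, 1))
    cg <- sample(100, sample(3:20, 1))
    os <- overlap_score(cp, cg)
    expect_true(os >= 0 && os <= 1)
    expect_identical(os == 1, setequal(cp, cg))
  }
})

test_that("cluster matching: identity, lumping, splitting", {
  truth <- rep(0:3, each = 10)
  m <- match_clusters(truth, truth + 100L)
  expect_identical(c(m$tp, m$fp, m$fn), c(4L, 0L, 0L))
  expect_equal(m$matches$os, rep(1, 4))
  # everything in one predicted cluster: OS = |Cg|/|Call| = 1/4 < 0.8
  lump <- match_clusters(truth, rep(1L, 40))
  expect_identical(c(lump$tp, lump$fp, lump$fn), c(0L, 1L, 4L))
  # a truth cluster split in equal halves has OS 0.5 on each half
  split_pred <- c(rep(1L, 5), rep(2L, 5), rep(3L, 10), rep(4L, 10), rep(5L, 10))
  sp <- match_clusters(truth, split_pred)
  expect_identical(sp$fn, 1L)
  expect_identical(sp$tp, 3L)
  # unassigned fibers count toward no predicted cluster
  pred_noise <- truth + 100L
  pred_noise[1:3] <- NA
  mn <- match_clusters(truth, pred_noise)
  expect_identical(mn$n_pred, 4L)
})

test_that("precision/recall/F and Sn/PPV/Acc follow their definitions", {
  expect_equal(precision_recall_f(3, 2, 1),
               c(precision = 0.6, recall = 0.75,
                 f_measure = 2 * 0.6 * 0.75 / 1.35))
  expect_equal(unname(precision_recall_f(2, 2, 0)[c("precision", "recall")]),
               c(0.5, 1))
  expect_equal(unname(precision_recall_f(2, 2, 0)["f_measure"]), 2 / 3)
  expect_warning(expect_warning(z <- precision_recall_f(0, 0, 0),
                                "precision undefined"),
                 "recall undefined")
  expect_equal(unname(z), c(0, 0, 0))
  # Sn/PPV/Acc: perfect diagonal
  expect_equal(unname(sn_ppv_acc(diag(c(5, 7, 9)))), c(1, 1, 1))
  expect_equal(unname(sn_ppv_acc(matrix(c(8, 2, 3, 7), 2))["acc"]),
               sqrt((8 + 7) / 20 * (8 + 7) / 20))
  expect_error(sn_ppv_acc(matrix(0, 2, 2)), "all-zero")
  # random tables equal the direct-summation oracle
  set.seed(112)
  for (k in 1:20) {
    t <- matrix(stats::rpois(12, 4), 3, 4)
    if (sum(t) == 0) t[1, 1] <- 1
    expect_equal(sn_ppv_acc(t), sn_ppv_brute(t))
    N <- rowSums(t) + stats::rpois(3, 2)   # some unassigned fibers
    expect_equal(sn_ppv_acc(t, N), sn_ppv_brute(t, N))
  }
})

test_that("MMR sums TP overlap scores over the ground-truth count", {
  m <- data.frame(truth = c(0L, 1L), pred = c(10L, 11L), os = c(0.9, 0.8))
  expect_equal(mmr(m, n_truth = 4), 0.425)
  expect_equal(mmr(data.frame(truth = integer(0), pred = integer(0),
                              os = numeric(0)), n_truth = 3), 0)
  truth <- rep(0:3, each = 10)
  expect_equal(mmr(match_clusters(truth, truth + 1L)), 1)
  # MMR never exceeds Recall (each TP contributes OS <= 1)
  set.seed(113)
  for (k in 1:20) {
    truth_r <- sample(0:4, 60, replace = TRUE)
    pred_r <- sample(1:7, 60, replace = TRUE)
    mc <- match_clusters(truth_r, pred_r, os_threshold = 0.2)
    rec <- suppressWarnings(precision_recall_f(mc$tp, mc$fp, mc$fn)["recall"])
    expect_lte(mmr(mc), unname(rec) + 1e-12)
  }
})

test_that("exact bipartite MMR agrees with the greedy TP sum when unambiguous", {
  skip_if_not_installed("igraph")
  truth <- rep(0:3, each = 10)
  expect_equal(mmr_exact(truth, truth + 1L), 1)
  set.seed(114)
  for (k in 1:10) {
    truth_r <- rep(0:2, each = 12)
    pred_r <- truth_r + 1L
    flip <- sample(36, 4)
    pred_r[flip] <- sample(1:3, 4, replace = TRUE)
    greedy <- mmr(match_clusters(truth_r, pred_r))
    exact <- mmr_exact(truth_r, pred_r)
    expect_gte(exact + 1e-9, greedy)  # matching can only improve the sum
  }
})

test_that("crossing recovery counts TP crossing bundles", {
  ds <- list(crossing_pairs = matrix(c(0L, 1L, 2L, 3L, 0L, 2L), ncol = 2,
                                     byrow = TRUE))
  # crossing bundles: 0, 1, 2, 3 -> 4 of them; matches recover 3
  m <- data.frame(truth = c(0L, 1L, 2L, 7L), pred = 1:4, os = rep(0.9, 4))
  expect_equal(crossing_recovery(ds, m), 75)
  m_all <- data.frame(truth = 0:3, pred = 1:4, os = rep(1, 4))
  expect_equal(crossing_recovery(ds, m_all), 100)
  none <- list(crossing_pairs = matrix(integer(0), ncol = 2))
  expect_warning(v <- crossing_recovery(none, m), "no crossing")
  expect_true(is.na(v))
})

test_that("Fisher-Yates shuffles are uniform bijections", {
  expect_identical(fisher_yates(5L), 5L)
  set.seed(115)
  x <- 1:50
  y <- fisher_yates(x)
  expect_identical(sort(y), x)
  # all 6 permutations of a length-3 sequence occur uniformly
  draws <- replicate(6000, paste(fisher_yates(1:3), collapse = ""))
  tab <- table(draws)
  expect_identical(length(tab), 6L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("QuickBundles baseline separates bundles and matches the reference", {
  A <- test_bundle(n = 25, radii = rep(3, 5), seed = 121)
  B <- test_bundle(n = 25, radii = rep(3, 5), seed = 122,
                   origin = c(0, 60, 0))
  fibers <- c(A$fibers, B$fibers)
  labels <- quickbundles(fibers, threshold = 20)
  expect_identical(length(unique(labels)), 2L)
  expect_identical(length(unique(labels[1:25])), 1L)
  expect_identical(length(unique(labels[26:50])), 1L)
  # threshold -> Inf gives a single cluster
  expect_identical(length(unique(quickbundles(fibers, 1e9))), 1L)
  expect_error(quickbundles(fibers, 0), "> 0")
  # identical to the independent per-pair reference implementation
  set.seed(123)
  for (k in 1:5) {
    fs <- replicate(30, random_fiber(), simplify = FALSE)
    th <- stats::runif(1, 8, 25)
    expect_identical(quickbundles(fs, th), qb_reference(fs, th))
  }
})

test_that("evaluation harness: perfect clusterer, order invariance", {
  cents <- generate_synthetic_centroids(4, seed = 131)
  spec <- dataset_spec(4, fiber_range = c(20L, 30L), seed = 132)
  ds <- build_dataset(spec, cents)
  # mock clusterer that returns the ground truth regardless of input order
  perfect <- local({
    key <- vapply(dataset_fibers(ds), function(f) paste(f[1, ], collapse = ","),
                  "")
    truth <- ds$labels
    function(fibers, threshold) {
      k <- vapply(fibers, function(f) paste(f[1, ], collapse = ","), "")
      truth[match(k, key)] + 1L
    }
  })
  ev <- evaluate_clustering(ds, perfect, thresholds = c(10, 15),
                            n_permutations = 3, seed = 133)
  s <- ev$summary
  expect_equal(s$accuracy, c(1, 1))
  expect_equal(s$precision, c(1, 1))
  expect_equal(s$recall, c(1, 1))
  expect_equal(s$f_measure, c(1, 1))
  expect_equal(s$mmr, c(1, 1))
  # order-invariant clusterer: zero spread over permutations
  expect_equal(s$accuracy_perm_sd, c(0, 0))
  expect_equal(s$mmr_perm_mean, c(1, 1))
  expect_identical(s$n_clusters, c(4L, 4L))
})
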