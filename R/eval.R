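#' Cluster evaluation against ground truth
#'
#' Clusterings are compared to the known bundle labels through the Overlap
#' Score OS(Cp, Cg) = |Cp n Cg|^2 / (|Cp||Cg|). A predicted cluster is a
#' true positive when it matches a ground-truth cluster with OS at or above
#' a threshold (default 0.8); matching is one-to-one, greedy in descending
#' OS. From the TP/FP/FN counts come Precision, Recall and F-measure; from
#' the full contingency table come the clustering-wise Sensitivity (Sn),
#' Positive Predictive Value (PPV) and their geometric mean, the Accuracy;
#' the Maximum Matching Ratio (MMR) sums the OS of the TP matches and
#' divides by the number of ground-truth clusters.
#'
#' Cluster assignments are integer vectors, one label per fiber; `NA` or a
#' negative label marks an unassigned (noise) fiber.
#'
#' @name clustering-evaluation
NULL

# Normalize an assignment vector: negative labels -> NA (internal).
norm_assignment <- function(x) {
  x <- as.integer(x)
  x[!is.na(x) & x < 0L] <- NA_integer_
  x
}

#' Overlap Score between two clusters
#'
#' @param cp,cg Non-empty vectors of fiber identifiers (predicted and
#'   ground-truth cluster membership).
#' @return `|cp n cg|^2 / (|cp| |cg|)`, in `[0, 1]`.
#' @export
overlap_score <- function(cp, cg) {
  if (length(cp) == 0L || length(cg) == 0L)
    stop("overlap score of an empty cluster is undefined")
  length(intersect(cp, cg))^2 / (length(cp) * length(cg))
}

#' Contingency table between a ground truth and a prediction
#'
#' @param truth,pred Per-fiber integer label vectors of equal length;
#'   `NA`/negative predicted labels are unassigned fibers.
#' @return A list: `t` (matrix of shared fiber counts, rows = ground-truth
#'   clusters, cols = predicted clusters), `N` (ground-truth cluster sizes,
#'   including fibers left unassigned by the prediction), `truth_ids`,
#'   `pred_ids`.
#' @export
contingency_table <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("'truth' and 'pred' must cover the same fibers")
  pred <- norm_assignment(pred)
  truth_ids <- sort(unique(truth))
  pred_ids <- sort(unique(pred[!is.na(pred)]))
  N <- as.integer(table(factor(truth, levels = truth_ids)))
  keep <- !is.na(pred)
  t <- table(factor(truth[keep], levels = truth_ids),
             factor(pred[keep], levels = pred_ids))
  t <- matrix(as.integer(t), nrow = length(truth_ids),
              dimnames = list(truth_ids, pred_ids))
  list(t = t, N = N, truth_ids = truth_ids, pred_ids = pred_ids)
}

#' Match predicted clusters to ground-truth clusters by Overlap Score
#'
#' Candidate (ground truth, predicted) pairs with OS at or above
#' `os_threshold` are matched one-to-one, greedily in descending OS. TP is
#' the number of matched predicted clusters, FP the remaining predicted
#' clusters, FN the ground-truth clusters left unmatched.
#'
#' @param truth,pred Per-fiber label vectors (see [contingency_table()]).
#' @param os_threshold Overlap Score threshold (default 0.8).
#' @return A list: `tp`, `fp`, `fn`, `n_truth`, `n_pred`, and `matches`, a
#'   data frame with columns `truth`, `pred`, `os` (one row per TP).
#' @export
match_clusters <- function(truth, pred, os_threshold = 0.8) {
  ct <- contingency_table(truth, pred)
  n <- length(ct$truth_ids); m <- length(ct$pred_ids)
  empty <- data.frame(truth = integer(0L), pred = integer(0L),
                      os = numeric(0L))
  if (m == 0L)
    return(list(tp = 0L, fp = 0L, fn = n, n_truth = n, n_pred = 0L,
                matches = empty))
  Np <- colSums(ct$t)  # predicted cluster sizes (assigned fibers)
  os <- ct$t^2 / outer(ct$N, pmax(Np, 1L))
  cand <- which(os >= os_threshold & ct$t > 0L, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(tp = 0L, fp = m, fn = n, n_truth = n, n_pred = m,
                matches = empty))
  ord <- order(os[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  used_truth <- logical(n); used_pred <- logical(m)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used_truth[i] || used_pred[j]) next
    used_truth[i] <- TRUE; used_pred[j] <- TRUE
    rows[[length(rows) + 1L]] <-
      data.frame(truth = ct$truth_ids[i], pred = ct$pred_ids[j],
                 os = os[i, j])
  }
  matches <- do.call(rbind, rows)
  tp <- nrow(matches)
  list(tp = tp, fp = m - tp, fn = n - tp, n_truth = n, n_pred = m,
       matches = matches)
}

#' Precision, Recall and F-measure from TP/FP/FN counts
#'
#' Zero denominators return 0 with a warning.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f_measure)`.
#' @export
precision_recall_f <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); returning 0")
      return(0)
    }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f_measure = f)
}

#' Clustering-wise Sensitivity, Positive Predictive Value and Accuracy
#'
#' `Sn = sum_i max_j t_ij / sum_i N_i`, `PPV = sum_j max_i t_ij /
#' sum_j T_j` (T_j the column sums), `Acc = sqrt(Sn * PPV)`.
#'
#' @param t Contingency matrix (rows = ground-truth clusters, cols =
#'   predicted clusters), or the list returned by [contingency_table()].
#' @param truth_sizes Ground-truth cluster sizes N_i; defaults to the row
#'   sums of `t` (supply the true sizes when fibers were left unassigned).
#' @return Named numeric vector `c(sn, ppv, acc)`.
#' @export
sn_ppv_acc <- function(t, truth_sizes = NULL) {
  if (is.list(t) && !is.null(t$t)) {
    if (is.null(truth_sizes)) truth_sizes <- t$N
    t <- t$t
  }
  if (is.null(truth_sizes)) truth_sizes <- rowSums(t)
  if (sum(t) == 0) stop("all-zero contingency table")
  sn <- sum(apply(t, 1L, max)) / sum(truth_sizes)
  ppv <- sum(apply(t, 2L, max)) / sum(colSums(t))
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum Matching Ratio
#'
#' Sum of the Overlap Scores of the TP matches divided by the number of
#' ground-truth clusters. With `exact = TRUE` the TP sum is replaced by a
#' maximum-weight bipartite matching over all cluster pairs with OS at or
#' above the threshold (requires the igraph package); the two variants
#' differ only when one ground-truth cluster is the best match of several
#' predicted clusters.
#'
#' @param matches Data frame of matches (from [match_clusters()]), or a
#'   list as returned by that function.
#' @param n_truth Number of ground-truth clusters (taken from the list when
#'   available).
#' @return MMR in `[0, 1]`.
#' @export
mmr <- function(matches, n_truth = NULL) {
  if (is.list(matches) && !is.null(matches$matches)) {
    if (is.null(n_truth)) n_truth <- matches$n_truth
    matches <- matches$matches
  }
  if (is.null(n_truth) || n_truth < 1L)
    stop("'n_truth' must be >= 1")
  if (nrow(matches) == 0L) return(0)
  sum(matches$os) / n_truth
}

#' @rdname mmr
#' @param truth,pred Per-fiber label vectors.
#' @param os_threshold Overlap Score threshold for candidate edges.
#' @export
mmr_exact <- function(truth, pred, os_threshold = 0.8) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the exact MMR variant requires the 'igraph' package")
  ct <- contingency_table(truth, pred)
  n <- length(ct$truth_ids); m <- length(ct$pred_ids)
  if (m == 0L) return(0)
  Np <- colSums(ct$t)
  os <- ct$t^2 / outer(ct$N, pmax(Np, 1L))
  cand <- which(os >= os_threshold & ct$t > 0L, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, m)),
    edges = as.vector(t(cbind(cand[, 1L], n + cand[, 2L])))
  )
  mwm <- igraph::max_bipartite_match(g, weights = os[cand])
  mwm$matching_weight / n
}

#' Crossing-bundle recovery percentage
#'
#' Percentage of crossing ground-truth bundles recovered as TP clusters.
#' Returns `NA` (with a warning) when the dataset has no crossing pairs.
#'
#' @param dataset A `fibersim_dataset` with a crossing registry.
#' @param matches Match result from [match_clusters()] (list or its
#'   `matches` data frame).
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
crossing_recovery <- function(dataset, matches) {
  if (is.list(matches) && !is.null(matches$matches)) matches <- matches$matches
  crossing <- unique(as.vector(dataset$crossing_pairs))
  if (length(crossing) == 0L) {
    warning("dataset has no crossing bundles; recovery undefined")
    return(NA_real_)
  }
  100 * sum(crossing %in% matches$truth) / length(crossing)
}

#' QuickBundles baseline clusterer
#'
#' Greedy single-pass clustering with the Minimum Average Direct-Flip (MDF)
#' distance on fibers resampled to `n_points` (default 12) points: each
#' fiber joins the nearest existing cluster centroid if the MDF distance is
#' below `threshold`, otherwise it starts a new cluster. The cluster
#' centroid is the running mean of its member fibers, each flip-aligned to
#' the centroid before being added.
#'
#' @param fibers List of fibers (equal point counts).
#' @param threshold MDF distance threshold in mm (> 0).
#' @param n_points Resampling point count for the MDF computation.
#' @return Integer cluster labels (1-based), one per fiber, in input order.
#' @export
quickbundles <- function(fibers, threshold, n_points = 12L) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  nf <- length(fibers)
  if (nf == 0L) return(integer(0L))
  p <- n_points
  # row-major flattening: (x1, y1, z1, x2, ...)
  X <- t(vapply(fibers, function(f) as.vector(t(resample_fiber(f, p))),
                numeric(3L * p)))
  flip_cols <- as.vector(t(matrix(seq_len(3L * p), ncol = 3L,
                                  byrow = TRUE)[p:1, ]))
  G <- matrix(0, 3L * p, p)
  G[cbind(seq_len(3L * p), rep(seq_len(p), each = 3L))] <- 1
  centroids <- matrix(NA_real_, nf, 3L * p)  # grown lazily
  counts <- integer(nf)
  k <- 0L
  labels <- integer(nf)
  for (f in seq_len(nf)) {
    v <- X[f, ]
    vf <- v[flip_cols]
    if (k > 0L) {
      C <- centroids[seq_len(k), , drop = FALSE]
      dd <- rowMeans(sqrt((C - rep(v, each = k))^2 %*% G))
      df <- rowMeans(sqrt((C - rep(vf, each = k))^2 %*% G))
      d <- pmin(dd, df)
      j <- which.min(d)
    }
    if (k > 0L && d[j] < threshold) {
      add <- if (dd[j] <= df[j]) v else vf
      centroids[j, ] <- centroids[j, ] + (add - centroids[j, ]) / (counts[j] + 1L)
      counts[j] <- counts[j] + 1L
      labels[f] <- j
    } else {
      k <- k + 1L
      centroids[k, ] <- v
      counts[k] <- 1L
      labels[f] <- k
    }
  }
  labels
}

#' Fisher-Yates shuffle
#'
#' Uniformly random permutation: walking backwards from the last element,
#' swap the current element with one at a randomly chosen index up to and
#' including itself.
#'
#' @param x A vector (or list) to permute.
#' @return The permuted sequence; deterministic given the RNG state.
#' @export
fisher_yates <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  for (i in seq.int(n, 2L)) {
    j <- sample.int(i, 1L)
    tmp <- x[[i]]; x[[i]] <- x[[j]]; x[[j]] <- tmp
  }
  x
}

# Metrics of one clustering run against ground truth (internal).
eval_one <- function(truth, pred, os_threshold) {
  mc <- match_clusters(truth, pred, os_threshold)
  prf <- suppressWarnings(precision_recall_f(mc$tp, mc$fp, mc$fn))
  spa <- sn_ppv_acc(contingency_table(truth, pred))
  data.frame(
    n_clusters = mc$n_pred, tp = mc$tp, fp = mc$fp, fn = mc$fn,
    accuracy = unname(spa["acc"]), precision = unname(prf["precision"]),
    recall = unname(prf["recall"]), f_measure = unname(prf["f_measure"]),
    mmr = mmr(mc)
  )
}

#' Evaluate a clusterer against a ground-truth dataset
#'
#' Runs the clusterer at each distance threshold on the original fiber
#' order and on `n_permutations` Fisher-Yates shuffles of the input (the
#' permutation only reorders the input; metrics are always computed against
#' the same ground truth, with predictions mapped back to the original
#' fiber order).
#'
#' @param dataset A `fibersim_dataset`.
#' @param clusterer Function `(fibers, threshold) -> integer labels` (one
#'   label per fiber, `NA`/negative = unassigned). Default
#'   [quickbundles()].
#' @param thresholds Distance thresholds in mm.
#' @param os_threshold Overlap Score threshold for TP matching.
#' @param n_permutations Number of input permutations (0 to skip).
#' @param seed Seed for the permutation draws.
#' @return A list: `summary`, a data frame with one row per threshold
#'   (original-order metrics plus permutation means and standard
#'   deviations), and `matches`, the per-threshold [match_clusters()]
#'   results on the original order.
#' @export
evaluate_clustering <- function(dataset, clusterer = quickbundles,
                                thresholds = c(10, 12, 15, 20),
                                os_threshold = 0.8, n_permutations = 5L,
                                seed = NULL) {
  fibers <- dataset_fibers(dataset)
  truth <- dataset$labels
  stopifnot(length(fibers) == length(truth))
  rows <- list()
  matches <- list()
  for (th in thresholds) {
    pred <- clusterer(fibers, th)
    if (length(pred) != length(fibers))
      stop("clusterer returned ", length(pred), " labels for ",
           length(fibers), " fibers (threshold ", th, ")")
    base <- eval_one(truth, pred, os_threshold)
    matches[[as.character(th)]] <- match_clusters(truth, pred, os_threshold)
    if (n_permutations > 0L) {
      perm_rows <- with_seed(seed, {
        lapply(seq_len(n_permutations), function(k) {
          perm <- fisher_yates(seq_along(fibers))
          pred_p <- clusterer(fibers[perm], th)
          back <- rep(NA_integer_, length(fibers))
          back[perm] <- pred_p
          eval_one(truth, back, os_threshold)
        })
      })
      pm <- do.call(rbind, perm_rows)
      stat_cols <- c("n_clusters", "accuracy", "precision", "recall",
                     "f_measure", "mmr")
      for (cn in stat_cols) {
        base[[paste0(cn, "_perm_mean")]] <- mean(pm[[cn]])
        base[[paste0(cn, "_perm_sd")]] <- stats::sd(pm[[cn]])
      }
    }
    rows[[as.character(th)]] <- cbind(data.frame(threshold = th), base)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, matches = matches)
}
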