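#' Streamline and bundle similarity metrics
#'
#' The core fiber distance is the maximum-Euclidean flip distance dME: the
#' maximum over corresponding points of the Euclidean point distance,
#' minimized over the two possible fiber orientations. On top of it the
#' package provides the inter-bundle distance (average nearest-fiber
#' distance) and the intersection percentage (fraction of fibers of one
#' bundle having a fiber of the other within a threshold, default 10 mm).
#'
#' @name similarity-metrics
NULL

#' Maximum-Euclidean flip distance between two fibers
#'
#' `dme(A, B) = min( max_i |a_i - b_i| , max_i |a_i - b_(N-1-i)| )`, where
#' the second term reverses the point order of B. Both fibers must have the
#' same number of points.
#'
#' @param a,b Fibers (n x 3 matrices) with equal point counts.
#' @return Distance in mm (>= 0, symmetric, 0 for identical fibers or a
#'   fiber and its own reversal).
#' @export
dme <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop("fibers must have the same number of points")
  direct <- sqrt(max(rowSums((a - b)^2)))
  flipped <- sqrt(max(rowSums((a - b[rev(seq_len(nrow(b))), , drop = FALSE])^2)))
  min(direct, flipped)
}

#' Pairwise dME distance matrix between two fiber sets
#'
#' Computed per point index with vectorized cross-distances, in column
#' blocks to bound memory; entries are identical to the naive per-pair
#' computation.
#'
#' @param A,B Bundles, lists of fibers, or n x p x 3 arrays.
#' @param block Number of columns (fibers of B) processed per block.
#' @return An `nA` x `nB` matrix of dME distances (mm).
#' @export
dme_matrix <- function(A, B, block = 4096L) {
  A <- fiber_array(A); B <- fiber_array(B)
  if (dim(A)[2L] != dim(B)[2L])
    stop("fibers must have the same number of points")
  p <- dim(A)[2L]
  na <- dim(A)[1L]; nb <- dim(B)[1L]
  out <- matrix(NA_real_, na, nb)
  starts <- seq.int(1L, nb, by = block)
  for (s in starts) {
    cols <- s:min(s + block - 1L, nb)
    direct <- matrix(0, na, length(cols))
    flip <- matrix(0, na, length(cols))
    for (i in seq_len(p)) {
      d2 <- outer(A[, i, 1L], B[cols, i, 1L], `-`)^2 +
            outer(A[, i, 2L], B[cols, i, 2L], `-`)^2 +
            outer(A[, i, 3L], B[cols, i, 3L], `-`)^2
      direct <- pmax(direct, d2)
      ii <- p + 1L - i
      f2 <- outer(A[, i, 1L], B[cols, ii, 1L], `-`)^2 +
            outer(A[, i, 2L], B[cols, ii, 2L], `-`)^2 +
            outer(A[, i, 3L], B[cols, ii, 3L], `-`)^2
      flip <- pmax(flip, f2)
    }
    out[, cols] <- sqrt(pmin(direct, flip))
  }
  out
}

#' Inter-bundle distance
#'
#' For every fiber of A the dME distance to its closest fiber of B, and
#' vice versa; the mean and standard deviation are taken over the pooled
#' closest-distance list, making the measure symmetric in A and B.
#'
#' @param A,B Non-empty bundles or fiber lists.
#' @return Named numeric vector `c(mean = , sd = )` in mm (`sd` is 0 for a
#'   single pooled distance).
#' @export
inter_bundle_distance <- function(A, B) {
  D <- dme_matrix(A, B)
  pooled <- c(apply(D, 1L, min), apply(D, 2L, min))
  s <- if (length(pooled) > 1L) stats::sd(pooled) else 0
  c(mean = mean(pooled), sd = s)
}

#' Intersection percentage between two bundles
#'
#' Two fibers are considered similar if their dME distance is below
#' `threshold` (default 10 mm). The default convention takes B as the
#' reference bundle and reports the percentage of B's fibers having at
#' least one similar fiber in A, i.e. how much of the reference bundle is
#' reproduced; `symmetric = TRUE` averages both directions.
#'
#' @param A Comparison bundle (e.g. a simulated bundle).
#' @param B Reference bundle (e.g. the original atlas bundle).
#' @param threshold Similarity threshold in mm.
#' @param symmetric Average the two directional percentages.
#' @return Percentage in `[0, 100]`.
#' @export
intersection_percentage <- function(A, B, threshold = 10, symmetric = FALSE) {
  D <- dme_matrix(A, B)
  ip_b <- 100 * mean(apply(D, 2L, min) < threshold)
  if (!symmetric) return(ip_b)
  ip_a <- 100 * mean(apply(D, 1L, min) < threshold)
  (ip_a + ip_b) / 2
}
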