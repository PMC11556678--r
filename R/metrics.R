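#' Correlation distance between two voxel patterns
#'
#' The representational dissimilarity `d = 1 - Pearson's r`, ranging from 0
#' (identical up to a positive affine transform) through 1 (uncorrelated) to
#' 2 (perfectly anticorrelated). Because Pearson's r normalizes for both the
#' mean and the standard deviation of each pattern, this metric captures
#' pattern shape only and discards overall amplitude.
#'
#' @param a,b Voxel patterns ([voxel_pattern()] or bare numeric vectors) of
#'   equal length; both must have nonzero variance.
#' @return Dissimilarity in `[0, 2]` (unitless).
#' @examples
#' correlation_distance(c(1, 2, 3, 4), c(1, 2, 3, 4))    # 0
#' correlation_distance(c(1, 2, 3, 4), -c(1, 2, 3, 4))   # 2
#' correlation_distance(c(1, -1, 1, -1), c(1, 1, -1, -1)) # 1
#' @export
correlation_distance <- function(a, b) {
  va <- pattern_values(a, "a")
  vb <- pattern_values(b, "b")
  if (length(va) != length(vb)) {
    stop("voxel counts differ: ", length(va), " vs ", length(vb))
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation distance is undefined for a zero-variance pattern")
  }
  1 - stats::cor(va, vb)
}

#' Euclidean distance between two voxel patterns
#'
#' Order-2 Minkowski distance. Unlike the correlation metric it retains
#' amplitude information. With `normalized = TRUE` the distance is divided
#' by `sqrt(voxel_count)` (a root-mean-square difference) so that values are
#' comparable across regions of interest with different voxel counts.
#'
#' @inheritParams correlation_distance
#' @param normalized Divide by `sqrt(voxel_count)`? Default `FALSE`.
#' @return Nonnegative dissimilarity.
#' @export
euclidean_distance <- function(a, b, normalized = FALSE) {
  va <- pattern_values(a, "a")
  vb <- pattern_values(b, "b")
  if (length(va) != length(vb)) {
    stop("voxel counts differ: ", length(va), " vs ", length(vb))
  }
  d <- sqrt(sum((va - vb)^2))
  if (isTRUE(normalized)) d / sqrt(length(va)) else d
}

#' Mahalanobis distance between two voxel patterns
#'
#' `sqrt((a - b)' S^{-1} (a - b))` for a voxelwise noise covariance summary
#' `S`, which down-weights voxels (or voxel combinations) with high noise.
#' `S` may be a full positive-definite matrix or a vector of per-voxel
#' variances (diagonal covariance); see [estimate_noise_cov()] for a
#' shrinkage estimator from residual patterns.
#'
#' @inheritParams correlation_distance
#' @param noise_cov Positive-definite covariance matrix
#'   (`voxel_count x voxel_count`) or a length-`voxel_count` vector of
#'   positive per-voxel variances.
#' @return Nonnegative dissimilarity.
#' @export
mahalanobis_distance <- function(a, b, noise_cov) {
  va <- pattern_values(a, "a")
  vb <- pattern_values(b, "b")
  if (length(va) != length(vb)) {
    stop("voxel counts differ: ", length(va), " vs ", length(vb))
  }
  dv <- va - vb
  if (is.matrix(noise_cov)) {
    if (!all(dim(noise_cov) == length(dv))) {
      stop("noise covariance dimension does not match voxel count")
    }
    ch <- tryCatch(chol(noise_cov), error = function(e) {
      stop("noise covariance is not positive definite")
    })
    z <- backsolve(ch, dv, transpose = TRUE)
    sqrt(sum(z^2))
  } else {
    s2 <- as.numeric(noise_cov)
    if (length(s2) != length(dv)) {
      stop("noise variance vector length does not match voxel count")
    }
    if (any(s2 <= 0)) stop("noise covariance is not positive definite")
    sqrt(sum(dv^2 / s2))
  }
}

#' Shrinkage estimate of voxelwise noise covariance
#'
#' Estimates the noise covariance from residual (noise) patterns and shrinks
#' it toward the scaled identity, `(1 - shrinkage) * S + shrinkage *
#' mean(diag(S)) * I`. With far fewer residual patterns than voxels the raw
#' sample covariance is singular; the diagonal default plus shrinkage keeps
#' the Mahalanobis metric well defined.
#'
#' @param residuals Numeric matrix of residual patterns, one per row.
#' @param shrinkage Shrinkage weight in `[0, 1]`, default `0.1`.
#' @param diagonal Keep only per-voxel variances (default `TRUE`)?
#' @return A variance vector (if `diagonal`) or covariance matrix, suitable
#'   for [mahalanobis_distance()].
#' @export
estimate_noise_cov <- function(residuals, shrinkage = 0.1, diagonal = TRUE) {
  x <- as.matrix(residuals)
  if (nrow(x) < 2L) stop("need at least 2 residual patterns")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  if (diagonal) {
    v <- apply(x, 2L, stats::var)
    (1 - shrinkage) * v + shrinkage * mean(v)
  } else {
    s <- stats::cov(x)
    (1 - shrinkage) * s + shrinkage * mean(diag(s)) * diag(ncol(x))
  }
}

# Dispatch a named metric; `options` collects metric-specific settings
# (euclidean: normalized; mahalanobis: noise_cov).
pattern_dissimilarity <- function(a, b, metric, options = list()) {
  switch(metric,
    correlation = correlation_distance(a, b),
    euclidean = euclidean_distance(a, b,
                                   normalized = isTRUE(options$normalized)),
    mahalanobis = {
      if (is.null(options$noise_cov)) {
        stop("mahalanobis metric requires metric_options$noise_cov")
      }
      mahalanobis_distance(a, b, options$noise_cov)
    },
    stop("unknown metric '", metric, "'")
  )
}

#' Build a representational dissimilarity matrix (RDM)
#'
#' Applies the chosen dissimilarity metric to every pair of anchor patterns
#' and places the values in a symmetric, zero-diagonal matrix — the RDM that
#' the semantic map is built from.
#'
#' @param anchors An [anchor_set()].
#' @param metric One of `"correlation"`, `"euclidean"`, `"mahalanobis"`.
#' @param metric_options List of metric settings: `normalized` (euclidean),
#'   `noise_cov` (mahalanobis).
#' @return An object of class `rdm`: list with `labels`, `matrix`
#'   (`n_cond x n_cond`, unitless), `metric`, `metric_options`.
#' @examples
#' a <- make_anchors(4, 60, seed = 1)$anchors
#' r <- build_rdm(a, metric = "correlation")
#' round(r$matrix, 2)
#' @export
build_rdm <- function(anchors,
                      metric = c("correlation", "euclidean", "mahalanobis"),
                      metric_options = list()) {
  stopifnot(inherits(anchors, "anchor_set"))
  metric <- match.arg(metric)
  n <- anchors$n_cond
  m <- matrix(0, n, n, dimnames = list(anchors$labels, anchors$labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- tryCatch(
        pattern_dissimilarity(anchors$patterns[i, ], anchors$patterns[j, ],
                              metric, metric_options),
        error = function(e) {
          stop("dissimilarity failed for pair (", anchors$labels[i], ", ",
               anchors$labels[j], "): ", conditionMessage(e))
        }
      )
      m[i, j] <- m[j, i] <- d
    }
  }
  new_rdm(m, anchors$labels, metric, metric_options)
}

# Low-level rdm constructor + invariant checks; also used by the readers
# and by tests that plant an explicit distance matrix.
new_rdm <- function(matrix, labels = rownames(matrix),
                    metric = "euclidean", metric_options = list()) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (is.null(labels)) labels <- paste0("state", seq_len(n))
  labels <- as.character(labels)
  if (ncol(matrix) != n) stop("RDM must be square")
  if (length(labels) != n) stop("RDM needs one label per row")
  asym <- abs(matrix - t(matrix))
  if (max(asym) > 1e-8) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("RDM is asymmetric; worst cell (%s, %s): |d_ij - d_ji| = %g",
                 labels[w[1L]], labels[w[2L]], max(asym)))
  }
  if (any(diag(matrix) != 0)) stop("RDM diagonal must be exactly 0")
  if (any(matrix < 0)) stop("RDM entries must be nonnegative")
  if (metric == "correlation" && any(matrix > 2 + 1e-12)) {
    stop("correlation-distance RDM entries must be <= 2")
  }
  dimnames(matrix) <- list(labels, labels)
  structure(
    list(labels = labels, matrix = matrix, metric = metric,
         metric_options = metric_options),
    class = "rdm"
  )
}

#' Construct an RDM from a precomputed dissimilarity matrix
#'
#' @param matrix Symmetric, zero-diagonal, nonnegative dissimilarity matrix.
#' @param labels Condition labels (default: rownames, else `state1..n`).
#' @param metric Metric tag recorded on the object.
#' @param metric_options Metric settings recorded on the object.
#' @return An object of class `rdm`.
#' @export
as_rdm <- function(matrix, labels = rownames(matrix),
                   metric = "euclidean", metric_options = list()) {
  new_rdm(matrix, labels, metric, metric_options)
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm> ", length(x$labels), " x ", length(x$labels),
      " (", x$metric, " distance)\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}
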