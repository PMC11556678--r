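#' Embed an RDM into a low-dimensional semantic map
#'
#' Classical (Torgerson) multidimensional scaling: the squared
#' dissimilarity matrix is double-centered, eigendecomposed, and the top
#' `dims` strictly positive eigenpairs give the anchor coordinates
#' (eigenvector columns scaled by the square root of the eigenvalue). The
#' quantities needed to project a new pattern into the map without
#' recomputing the embedding — the retained eigenbasis and the column means
#' of the squared anchor distance matrix — are stored on the object, and
#' the configuration is brought into the canonical orientation of
#' [canonical_orientation()] so repeated runs are bit-stable.
#'
#' Correlation-distance RDMs are generally non-Euclidean, so trailing
#' eigenvalues can be negative; those axes are truncated. The retained
#' fraction of positive-eigenvalue variance is stored as
#' `retained_variance`.
#'
#' @param rdm An [rdm] (see [build_rdm()], [as_rdm()]).
#' @param dims Map dimensionality, 2 or 3.
#' @return An object of class `semantic_map`: `labels`, `coords`
#'   (`n_cond x dims`, centered, map units), `dims`, `eigenvalues`
#'   (retained, descending), `basis` (eigenvectors, eigenvalues and squared
#'   distance column means for landmark projection), `rotation` (the
#'   canonical orientation transform), `orientation` tag, `metric`,
#'   `metric_options` and `retained_variance`.
#' @examples
#' a <- make_anchors(4, 80, seed = 2)$anchors
#' m <- embed_rdm(build_rdm(a, "correlation"), dims = 2)
#' round(m$coords, 3)
#' @export
embed_rdm <- function(rdm, dims = 2) {
  stopifnot(inherits(rdm, "rdm"))
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  dims <- as.integer(dims)
  n <- length(rdm$labels)
  if (n < dims + 1L) {
    warning("embedding ", n, " anchors in ", dims,
            " dimensions; at least dims + 1 anchors are recommended")
  }
  d2 <- rdm$matrix^2
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% d2 %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-12
  n_pos <- sum(e$values > tol)
  if (n_pos < 1L) {
    stop("no strictly positive eigenvalue; cannot embed (spectrum: ",
         paste(signif(e$values, 4), collapse = ", "), ")")
  }
  if (n_pos < dims) {
    warning("only ", n_pos, " strictly positive eigenvalue(s) for a ", dims,
            "-D map (spectrum: ", paste(signif(e$values, 4), collapse = ", "),
            "); remaining axes are zero")
  }
  n_real <- min(dims, n_pos)
  lam <- e$values[seq_len(n_real)]
  vec <- e$vectors[, seq_len(n_real), drop = FALSE]
  coords <- cbind(vec %*% diag(sqrt(lam), n_real),
                  matrix(0, n, dims - n_real))
  dimnames(coords) <- list(rdm$labels, paste0("dim", seq_len(dims)))
  map <- structure(
    list(
      labels = rdm$labels,
      coords = coords,
      dims = dims,
      eigenvalues = lam,
      basis = list(vectors = vec, values = lam, mu = colMeans(d2)),
      rotation = diag(dims),
      orientation = "raw",
      metric = rdm$metric,
      metric_options = rdm$metric_options,
      retained_variance = sum(lam) / sum(e$values[e$values > tol])
    ),
    class = "semantic_map"
  )
  canonical_orientation(map)
}

#' @export
print.semantic_map <- function(x, ...) {
  cat("<semantic_map> ", length(x$labels), " anchors in ", x$dims, "-D (",
      x$metric, " distance; ",
      sprintf("%.1f%%", 100 * x$retained_variance),
      " of positive-eigenvalue variance)\n", sep = "")
  print(round(x$coords, 3))
  invisible(x)
}

#' Canonical orientation of a semantic map
#'
#' Classical MDS determines the configuration only up to rotation and
#' reflection. To make maps reproducible across runs and serializations,
#' the configuration is rigidly transformed so that anchor 1 lies on the
#' nonnegative first axis, anchor 2 has nonnegative second coordinate (and,
#' in 3-D, lies in the plane of the first two axes while anchor 3 has
#' nonnegative third coordinate). Pairwise distances are unchanged. The
#' same transform is stored on the map and applied to every projected
#' pattern. Degenerate configurations (anchor 1 at the origin, or anchor 2
#' collinear with anchor 1 in 3-D) pass through unchanged with
#' `orientation = "degenerate"`.
#'
#' @param map A [semantic_map][embed_rdm()].
#' @return The map with canonicalized `coords`, updated `rotation` and an
#'   `orientation` tag. Idempotent.
#' @export
canonical_orientation <- function(map) {
  stopifnot(inherits(map, "semantic_map"))
  c0 <- map$coords
  dims <- map$dims
  n <- nrow(c0)
  eps <- 1e-12
  c1 <- c0[1L, ]
  if (sqrt(sum(c1^2)) < eps) {
    map$orientation <- "degenerate"
    return(map)
  }
  u1 <- c1 / sqrt(sum(c1^2))
  if (dims == 2L) {
    q <- rbind(u1, c(-u1[2L], u1[1L]))
    new <- c0 %*% t(q)
    if (n >= 2L && new[2L, 2L] < 0) q[2L, ] <- -q[2L, ]
    tag <- "anchor-aligned"
  } else {
    u2 <- NULL
    if (n >= 2L) {
      w <- c0[2L, ] - sum(c0[2L, ] * u1) * u1
      if (sqrt(sum(w^2)) >= eps) u2 <- w / sqrt(sum(w^2))
    }
    if (is.null(u2)) {
      map$orientation <- "degenerate"
      return(map)
    }
    u3 <- c(u1[2L] * u2[3L] - u1[3L] * u2[2L],
            u1[3L] * u2[1L] - u1[1L] * u2[3L],
            u1[1L] * u2[2L] - u1[2L] * u2[1L])
    q <- rbind(u1, u2, u3)
    new <- c0 %*% t(q)
    if (n >= 3L && new[3L, 3L] < 0) q[3L, ] <- -q[3L, ]
    tag <- "anchor-aligned"
  }
  dimnames(q) <- NULL
  map$coords <- c0 %*% t(q)
  dimnames(map$coords) <- list(map$labels, paste0("dim", seq_len(dims)))
  map$rotation <- q %*% map$rotation
  map$orientation <- tag
  map
}

#' Project a dissimilarity vector into an existing semantic map
#'
#' The landmark-MDS out-of-sample step: given the dissimilarities from a
#' new point to every anchor, square them, center against the stored column
#' means of the squared anchor distance matrix, and map through the
#' pseudo-inverse transpose of the anchor coordinate matrix,
#' `x = -1/2 * diag(1/sqrt(lambda)) V' (delta^2 - mu)`, followed by the
#' map's canonical orientation transform.
#'
#' @param map A [semantic_map][embed_rdm()].
#' @param d Numeric vector of dissimilarities to each anchor, in anchor
#'   order.
#' @return Numeric `dims`-vector of map coordinates.
#' @export
project_distances <- function(map, d) {
  stopifnot(inherits(map, "semantic_map"))
  d <- as.numeric(d)
  if (length(d) != length(map$labels)) {
    stop("need one dissimilarity per anchor (", length(map$labels), ")")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("dissimilarities must be finite and nonnegative")
  }
  centered <- d^2 - map$basis$mu
  x_real <- -0.5 * drop(crossprod(map$basis$vectors, centered)) /
    sqrt(map$basis$values)
  x_raw <- c(x_real, rep(0, map$dims - length(x_real)))
  unname(drop(map$rotation %*% x_raw))
}

#' Project a voxel pattern into the semantic map
#'
#' Computes the dissimilarity of the current mental-state pattern (CMS) to
#' every anchor under the map's metric and places it in the map by landmark
#' MDS ([project_distances()]). Deterministic: the same pattern always maps
#' to the same point.
#'
#' @param map A [semantic_map][embed_rdm()].
#' @param anchors The [anchor_set()] the map was built from.
#' @param cms Current mental-state pattern ([voxel_pattern()] or numeric
#'   vector) with the anchors' voxel count.
#' @param metric,metric_options Must match the map's; defaults to them.
#' @return Numeric `dims`-vector of map coordinates.
#' @export
project_pattern <- function(map, anchors, cms, metric = map$metric,
                            metric_options = map$metric_options) {
  stopifnot(inherits(map, "semantic_map"), inherits(anchors, "anchor_set"))
  if (!identical(metric, map$metric)) {
    stop("metric '", metric, "' does not match the map's metric '",
         map$metric, "'")
  }
  if (!identical(anchors$labels, map$labels)) {
    stop("anchor labels do not match the map's anchors")
  }
  v <- pattern_values(cms, "cms")
  if (length(v) != anchors$voxel_count) {
    stop("cms voxel count (", length(v), ") does not match anchors (",
         anchors$voxel_count, ")")
  }
  d <- vapply(seq_len(anchors$n_cond), function(i) {
    pattern_dissimilarity(v, anchors$patterns[i, ], metric, metric_options)
  }, numeric(1L))
  project_distances(map, d)
}

#' Goodness of fit of a semantic map (Kruskal stress-1)
#'
#' `stress = sqrt( sum_{i<j} (delta_ij - dhat_ij)^2 / sum_{i<j} delta_ij^2 )`
#' where `delta` are the RDM dissimilarities and `dhat` the embedded
#' Euclidean distances. 0 means the map reproduces the RDM exactly; values
#' grow as the low-dimensional projection distorts the dissimilarity
#' structure.
#'
#' @param map A [semantic_map][embed_rdm()].
#' @param rdm The [rdm] the map should reproduce (labels must match).
#' @return An object of class `stress_report`: `stress` (nonnegative
#'   scalar), `formula = "kruskal_stress1"`, `dims`.
#' @export
map_stress <- function(map, rdm) {
  stopifnot(inherits(map, "semantic_map"), inherits(rdm, "rdm"))
  if (!identical(map$labels, rdm$labels)) {
    stop("map and RDM labels do not match")
  }
  delta <- rdm$matrix[lower.tri(rdm$matrix)]
  if (all(delta == 0)) {
    stop("stress is undefined for an all-zero RDM")
  }
  dhat <- as.numeric(stats::dist(map$coords))
  structure(
    list(stress = sqrt(sum((delta - dhat)^2) / sum(delta^2)),
         formula = "kruskal_stress1", dims = map$dims),
    class = "stress_report"
  )
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf("<stress_report> Kruskal stress-1 = %.4g (%d-D)\n",
              x$stress, x$dims))
  invisible(x)
}
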