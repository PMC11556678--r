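# Shared fixtures: planted low-dimensional configurations and alignment
# helpers used by the MDS / landmark tests.

# n points planted in `dims` dimensions; returned with their exact
# Euclidean distance matrix wrapped as an rdm.
planted_config <- function(n, dims = 2, seed = 1) {
  x <- withr::with_seed(seed, matrix(stats::rnorm(n * dims), n, dims))
  labels <- paste0("s", seq_len(n))
  rownames(x) <- labels
  list(coords = x,
       rdm = as_rdm(as.matrix(stats::dist(x)), labels, metric = "euclidean"))
}

# Pad planted dims-D coordinates with zero columns so they can act as
# voxel patterns (Euclidean distances unchanged).
pad_to_voxels <- function(x, voxels = 10) {
  cbind(x, matrix(0, nrow(x), voxels - ncol(x)))
}

# Max absolute residual after optimal rigid alignment (rotation,
# reflection, translation; no scaling) of x onto y.
procrustes_residual <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  max(abs(xc %*% (s$v %*% t(s$u)) - yc))
}

# A random rotation (optionally a reflection) in `dims` dimensions.
random_rotation <- function(dims, seed, reflect = FALSE) {
  q <- withr::with_seed(seed,
    qr.Q(qr(matrix(stats::rnorm(dims * dims), dims, dims))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  if (reflect) q[, dims] <- -q[, dims]
  q
}

# Independent dissimilarity oracle from definitional sums (never calls the
# package's metric functions).
pattern_dissimilarity_oracle <- function(a, b, metric) {
  if (metric == "correlation") {
    am <- a - mean(a); bm <- b - mean(b)
    1 - sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  } else {
    sqrt(sum((a - b)^2))
  }
}

# Small anchor set + correlation map, reused across feedback/loop tests.
fixture_anchor_map <- function(n_cond = 4, voxels = 120, seed = 7) {
  made <- make_anchors(n_cond, voxels, seed = seed)
  rdm <- build_rdm(made$anchors, "correlation")
  list(anchors = made$anchors, rdm = rdm, map = embed_rdm(rdm, 2))
}
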