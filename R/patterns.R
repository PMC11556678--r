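#' Construct a multi-voxel activity pattern
#'
#' A voxel pattern is one multi-voxel activity vector: either an anchor
#' (a base mental-state pattern measured in a localizer run) or the online
#' estimate of the current mental state (CMS). Values are in arbitrary BOLD
#' units or percent signal change; what matters downstream is the pattern's
#' shape (correlation metric) or shape plus amplitude (Euclidean/Mahalanobis,
#' pattern strength).
#'
#' @param values Numeric vector of voxel activations (length >= 3, all
#'   finite).
#' @param label Optional mental-state name (e.g. `"happy"`).
#' @return An object of class `voxel_pattern` with fields `values`, `label`
#'   and `voxel_count`.
#' @examples
#' p <- voxel_pattern(c(1.2, -0.4, 0.8, 0.1), label = "happy")
#' p$voxel_count
#' @export
voxel_pattern <- function(values, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 3L) {
    stop("a voxel pattern needs at least 3 voxels, got ", length(values))
  }
  if (!all(is.finite(values))) {
    stop("voxel pattern contains non-finite values")
  }
  structure(
    list(values = values, label = label, voxel_count = length(values)),
    class = "voxel_pattern"
  )
}

#' @export
print.voxel_pattern <- function(x, ...) {
  cat("<voxel_pattern>",
      if (!is.null(x$label)) paste0("'", x$label, "'") else "(unlabelled)",
      "-", x$voxel_count, "voxels\n")
  invisible(x)
}

# Extract a numeric value vector from a voxel_pattern or a bare numeric
# vector. Metric functions accept bare vectors (length >= 2) so that short
# worked examples remain expressible; the voxel_pattern constructor itself
# is stricter.
pattern_values <- function(x, arg = "pattern") {
  v <- if (inherits(x, "voxel_pattern")) x$values else as.numeric(x)
  if (length(v) < 2L) stop(arg, " must have at least 2 voxels")
  if (!all(is.finite(v))) stop(arg, " contains non-finite values")
  v
}

pattern_label <- function(x, default = NULL) {
  if (inherits(x, "voxel_pattern") && !is.null(x$label)) x$label else default
}

#' Construct a labelled set of anchor patterns
#'
#' Anchors are the base mental-state patterns measured during preparatory
#' (localizer) runs; they become the landmark points of the semantic map.
#'
#' @param patterns Numeric matrix, one row per condition (mental state), one
#'   column per voxel. All rows must have nonzero variance (required for the
#'   correlation metric).
#' @param labels Character vector of unique mental-state names, one per row.
#'   Defaults to the matrix rownames.
#' @param source Free-text provenance tag (e.g. `"localizer run 1"`).
#' @return An object of class `anchor_set` with fields `labels`, `patterns`,
#'   `source`, `n_cond` and `voxel_count`.
#' @examples
#' m <- rbind(happy = c(1, 0, 2, 1), sad = c(-1, 1, 0, 2))
#' a <- anchor_set(m)
#' a$labels
#' @export
anchor_set <- function(patterns, labels = rownames(patterns),
                       source = "unspecified") {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "double"
  if (is.null(labels)) {
    stop("anchor labels are required (pass `labels` or set rownames)")
  }
  labels <- as.character(labels)
  if (nrow(patterns) < 2L) stop("an anchor set needs at least 2 conditions")
  if (length(labels) != nrow(patterns)) {
    stop("got ", length(labels), " labels for ", nrow(patterns), " patterns")
  }
  if (anyDuplicated(labels)) {
    stop("anchor labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(is.finite(patterns))) stop("anchor patterns contain non-finite values")
  if (ncol(patterns) < 2L) stop("anchor patterns need at least 2 voxels")
  row_var <- apply(patterns, 1L, stats::var)
  if (any(row_var == 0)) {
    stop("anchor pattern(s) with zero variance: ",
         paste(labels[row_var == 0], collapse = ", "))
  }
  rownames(patterns) <- labels
  structure(
    list(labels = labels, patterns = patterns, source = source,
         n_cond = nrow(patterns), voxel_count = ncol(patterns)),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("<anchor_set> ", x$n_cond, " states x ", x$voxel_count, " voxels (",
      paste(x$labels, collapse = ", "), ") [", x$source, "]\n", sep = "")
  invisible(x)
}

# Pull the pattern for one labelled anchor as a voxel_pattern.
anchor_pattern <- function(anchors, label) {
  i <- match(label, anchors$labels)
  if (is.na(i)) stop("unknown anchor label '", label, "'")
  voxel_pattern(anchors$patterns[i, ], label = label)
}

#' Normalize a voxel pattern
#'
#' @param p A [voxel_pattern()] (or bare numeric vector).
#' @param method One of `"none"` (identity), `"zscore"` (mean 0, SD 1) or
#'   `"psc"` (percent signal change against a baseline pattern,
#'   `100 * (p - baseline) / baseline` per voxel).
#' @param baseline Baseline pattern, required for `method = "psc"`; must have
#'   the same voxel count and no zero values.
#' @return A `voxel_pattern` with the same label.
#' @export
normalize_pattern <- function(p, method = c("none", "zscore", "psc"),
                              baseline = NULL) {
  method <- match.arg(method)
  v <- pattern_values(p)
  out <- switch(method,
    none = v,
    zscore = {
      s <- stats::sd(v)
      if (s == 0) stop("cannot z-score a zero-variance pattern")
      (v - mean(v)) / s
    },
    psc = {
      if (is.null(baseline)) stop("psc normalization requires a baseline pattern")
      b <- pattern_values(baseline, arg = "baseline")
      if (length(b) != length(v)) {
        stop("baseline voxel count (", length(b), ") does not match pattern (",
             length(v), ")")
      }
      if (any(b == 0)) {
        stop("psc normalization undefined: baseline has zero at voxel(s) ",
             paste(utils::head(which(b == 0), 5L), collapse = ", "))
      }
      100 * (v - b) / b
    }
  )
  if (length(out) >= 3L) voxel_pattern(out, label = pattern_label(p)) else out
}

#' Rank voxels by between-condition discriminability
#'
#' Scores every voxel with a one-way F statistic across condition labels and
#' returns the indices of the `k` most discriminative voxels. Intended as a
#' voxel-selection pre-processing step before representational similarity
#' analysis, standing in for classifier-weight-based selection.
#'
#' @param training_patterns Numeric matrix, trials in rows, voxels in
#'   columns.
#' @param labels Condition label per trial (>= 2 conditions, >= 2 trials
#'   each).
#' @param k Number of voxels to keep, `1 <= k <= ncol(training_patterns)`.
#' @return Integer vector of `k` voxel indices ordered by descending F score
#'   (ties broken by ascending index), with the scores attached as the
#'   `"score"` attribute.
#' @export
select_voxels <- function(training_patterns, labels, k) {
  x <- as.matrix(training_patterns)
  labels <- as.factor(labels)
  n <- nrow(x)
  V <- ncol(x)
  if (length(labels) != n) stop("one label per trial required")
  if (nlevels(labels) < 2L) stop("voxel selection needs at least 2 conditions")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("condition(s) with fewer than 2 trials: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  if (length(k) != 1L || is.na(k) || k < 1L || k > V) {
    stop("k must be in 1..", V)
  }
  k <- as.integer(k)
  g <- nlevels(labels)
  grand <- colMeans(x)
  ssb <- numeric(V)
  ssw <- numeric(V)
  for (lev in levels(labels)) {
    xi <- x[labels == lev, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + nrow(xi) * (mi - grand)^2
    ssw <- ssw + colSums(sweep(xi, 2L, mi)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))  # Inf where within-variance is 0
  ord <- order(-f, seq_len(V))
  idx <- ord[seq_len(k)]
  attr(idx, "score") <- f[idx]
  idx
}
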