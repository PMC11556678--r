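#' Select the feedback target anchor for a CMS pattern
#'
#' The target mental state (TMS) at any feedback moment is the anchor whose
#' pattern has the highest Pearson correlation with the current
#' mental-state pattern. Ties are broken by anchor order (stable).
#'
#' @param cms Current mental-state pattern (nonconstant).
#' @param anchors An [anchor_set()].
#' @return The target anchor label (character scalar), with the per-anchor
#'   correlations attached as the `"similarity"` attribute.
#' @export
select_target <- function(cms, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  r <- anchor_similarities(cms, anchors)
  out <- anchors$labels[which.max(r)]
  attr(out, "similarity") <- r
  out
}

# Pearson correlation of a cms with every anchor, as a named vector.
anchor_similarities <- function(cms, anchors) {
  v <- pattern_values(cms, "cms")
  if (length(v) != anchors$voxel_count) {
    stop("cms voxel count (", length(v), ") does not match anchors (",
         anchors$voxel_count, ")")
  }
  if (stats::sd(v) == 0) {
    stop("target selection is undefined for a zero-variance cms")
  }
  r <- drop(stats::cor(v, t(anchors$patterns)))
  names(r) <- anchors$labels
  r
}

#' Target-related pattern strength by vector projection
#'
#' Quantifies how strongly the current mental-state pattern (CMS) expresses
#' the target mental-state pattern (TMS): both vectors are mean-centered,
#' the CMS is projected onto the TMS, and the strength is the length of the
#' projection relative to the TMS length — the scalar projection
#' coefficient `(CMS . TMS) / (TMS . TMS)`. The similarity is Pearson's r
#' (the cosine of the angle theta between the centered vectors), so
#' rescaling the CMS by `k > 0` leaves similarity and theta unchanged while
#' multiplying the strength by exactly `k`: similarity carries the content,
#' strength the engagement intensity.
#'
#' @param cms,tms Voxel patterns of equal length; the centered TMS must
#'   have nonzero norm.
#' @param center Mean-center both vectors first (default `TRUE`, so that
#'   similarity coincides with Pearson's r). `FALSE` projects the raw
#'   vectors and reports the raw cosine.
#' @return An object of class `intensity_result`: `target_label`,
#'   `similarity` in `[-1, 1]`, `angle_theta` in `[0, pi]` radians, and the
#'   signed `strength`. The identity
#'   `strength = similarity * ||cms_c|| / ||tms_c||` holds to numerical
#'   precision.
#' @examples
#' tms <- voxel_pattern(c(1, 0, 2, -1), "happy")
#' pattern_strength(voxel_pattern(2 * c(1, 0, 2, -1)), tms)$strength  # 2
#' @export
pattern_strength <- function(cms, tms, center = TRUE) {
  vc <- pattern_values(cms, "cms")
  vt <- pattern_values(tms, "tms")
  if (length(vc) != length(vt)) {
    stop("voxel counts differ: ", length(vc), " vs ", length(vt))
  }
  if (center) {
    vc <- vc - mean(vc)
    vt <- vt - mean(vt)
  }
  tt <- sum(vt^2)
  if (tt == 0) {
    stop("pattern strength is undefined: centered tms has zero norm")
  }
  ct <- sum(vc * vt)
  strength <- ct / tt
  cn <- sqrt(sum(vc^2))
  similarity <- if (cn == 0) 0 else ct / (cn * sqrt(tt))
  structure(
    list(target_label = pattern_label(tms),
         similarity = similarity,
         angle_theta = acos(min(1, max(-1, similarity))),
         strength = strength),
    class = "intensity_result"
  )
}

#' @export
print.intensity_result <- function(x, ...) {
  cat(sprintf("<intensity_result> target=%s r=%.3f theta=%.3f rad strength=%.3f\n",
              if (is.null(x$target_label)) "?" else x$target_label,
              x$similarity, x$angle_theta, x$strength))
  invisible(x)
}

#' Display style settings for feedback frames
#'
#' @param s_min,s_max Minimum/maximum CMS marker size on the semantic map,
#'   in display units (points).
#' @param strength_cap Pattern strength mapped to the maximum marker size;
#'   strengths above it are clipped. Default 1.5 so above-localizer
#'   engagement is visible but bounded.
#' @param fill_cap Pattern strength at which a thermometer is full; same
#'   default and rationale.
#' @return A list of class `feedback_style`.
#' @export
feedback_style <- function(s_min = 4, s_max = 20, strength_cap = 1.5,
                           fill_cap = 1.5) {
  stopifnot(s_min >= 0, s_max >= s_min, strength_cap > 0, fill_cap > 0)
  structure(list(s_min = s_min, s_max = s_max, strength_cap = strength_cap,
                 fill_cap = fill_cap),
            class = "feedback_style")
}

# One time point of display state. Not exported as a constructor; built by
# map_frame(), circular_frame() and the session driver.
new_feedback_frame <- function(t_index = NA_integer_, cms_coords = NULL,
                               target_label = NA_character_,
                               strength = NA_real_, marker_size = NA_real_,
                               thermometer_fills = numeric(0),
                               arrow_angle = NA_real_, dist = NA_real_,
                               similarity = NA_real_, degenerate = FALSE) {
  structure(
    list(t_index = t_index, cms_coords = cms_coords,
         target_label = target_label, strength = strength,
         marker_size = marker_size, thermometer_fills = thermometer_fills,
         arrow_angle = arrow_angle, dist = dist, similarity = similarity,
         degenerate = degenerate),
    class = "feedback_frame"
  )
}

#' @export
print.feedback_frame <- function(x, ...) {
  cat(sprintf("<feedback_frame> t=%s target=%s strength=%.3f",
              x$t_index, x$target_label, x$strength))
  if (!is.null(x$cms_coords)) {
    cat(" at (", paste(sprintf("%.3f", x$cms_coords), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# Shared affine size/fill map: clip strength to [0, cap], scale to [0, 1].
clipped_fraction <- function(strength, cap) {
  min(max(strength, 0), cap) / cap
}

#' Semantic-map feedback frame with a strength-sized marker
#'
#' The map display variant: the CMS is drawn as a point at its projected
#' map coordinates, and the target-related pattern strength is conveyed by
#' the marker size, `s_min + (s_max - s_min) * clip(strength, 0,
#' strength_cap) / strength_cap` — monotone nondecreasing in strength.
#' Negative strength (CMS anticorrelated with the target) renders at the
#' minimum size rather than inverting the display.
#'
#' @param map A [semantic_map][embed_rdm()].
#' @param coords Projected CMS coordinates (`dims`-vector).
#' @param intensity An [intensity_result][pattern_strength()].
#' @param style A [feedback_style()].
#' @param t_index Feedback time step recorded on the frame.
#' @return A `feedback_frame` with `marker_size` set and no thermometer
#'   fields.
#' @export
map_frame <- function(map, coords, intensity, style = feedback_style(),
                      t_index = NA_integer_) {
  stopifnot(inherits(map, "semantic_map"),
            inherits(intensity, "intensity_result"),
            inherits(style, "feedback_style"))
  coords <- as.numeric(coords)
  if (length(coords) != map$dims) {
    stop("coords length (", length(coords), ") does not match map dims (",
         map$dims, ")")
  }
  size <- style$s_min + (style$s_max - style$s_min) *
    clipped_fraction(intensity$strength, style$strength_cap)
  new_feedback_frame(t_index = t_index, cms_coords = coords,
                     target_label = intensity$target_label,
                     strength = intensity$strength, marker_size = size,
                     similarity = intensity$similarity)
}

#' Angular placement of anchors on the circular thermometer display
#'
#' `mode = "generic"` spaces the anchors equally (gap `2*pi/n`),
#' counterclockwise from `pi/2` (top of the display) in declared label
#' order — the caller can pass labels pre-ordered along a generic semantic
#' arrangement such as the valence–arousal circumplex. `mode =
#' "dissimilarity"` searches all distinct circular orderings (necklaces,
#' brute force, so at most 8 anchors) for the one whose adjacent
#' dissimilarity shares best match equal spacing, i.e. minimizing
#' `sum |1/n - d_ij / sum(adjacent d)|`, then makes each angular gap
#' proportional to the adjacent dissimilarity — so the most dissimilar
#' states end up far apart on the circle.
#'
#' @param anchors An [anchor_set()] or a character vector of labels.
#' @param rdm Required for `mode = "dissimilarity"`.
#' @param mode `"generic"` or `"dissimilarity"`.
#' @return Named numeric vector of angles in radians, `[0, 2*pi)`, in the
#'   original label order; the chosen circular ordering is attached as the
#'   `"ordering"` attribute.
#' @export
circular_layout <- function(anchors, rdm = NULL,
                            mode = c("generic", "dissimilarity")) {
  mode <- match.arg(mode)
  labels <- if (inherits(anchors, "anchor_set")) anchors$labels
            else as.character(anchors)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 anchors")
  if (mode == "generic") {
    ang <- (pi / 2 + 2 * pi * (seq_len(n) - 1L) / n) %% (2 * pi)
    names(ang) <- labels
    attr(ang, "ordering") <- labels
    return(ang)
  }
  if (is.null(rdm)) stop("dissimilarity mode requires an RDM")
  stopifnot(inherits(rdm, "rdm"))
  if (!identical(rdm$labels, labels)) stop("RDM labels do not match anchors")
  if (n > 8L) {
    stop("dissimilarity mode searches all circular orderings and is limited ",
         "to 8 anchors; use mode = 'generic' for larger sets")
  }
  orderings <- if (n == 2L) {
    list(c(1L, 2L))
  } else {
    perms <- all_permutations(seq.int(2L, n))
    keep <- vapply(perms, function(p) p[1L] < p[length(p)], logical(1L))
    lapply(perms[keep], function(p) c(1L, p))
  }
  best <- NULL
  best_cost <- Inf
  for (ord in orderings) {
    d_adj <- vapply(seq_len(n), function(i) {
      rdm$matrix[ord[i], ord[i %% n + 1L]]
    }, numeric(1L))
    s <- sum(d_adj)
    cost <- if (s == 0) 0 else sum(abs(1 / n - d_adj / s))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- list(ord = ord, d_adj = d_adj, s = s)
    }
  }
  gaps <- if (best$s == 0) rep(2 * pi / n, n) else 2 * pi * best$d_adj / best$s
  ang_on_circle <- (pi / 2 + cumsum(c(0, gaps[-n]))) %% (2 * pi)
  ang <- numeric(n)
  ang[best$ord] <- ang_on_circle
  names(ang) <- labels
  attr(ang, "ordering") <- labels[best$ord]
  ang
}

# All permutations of a vector (n <= 7 here).
all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- all_permutations(x[-i])
    out <- c(out, lapply(rest, function(p) c(x[i], p)))
  }
  out
}

#' Similarity arrow position on the circular display
#'
#' The arrow points between the target thermometer (highest CMS
#' correlation) and whichever of its two layout-adjacent neighbours has
#' the larger correlation. With similarities clamped at 0 (negative
#' correlations carry no positional evidence), the interpolation scalar is
#' `dist = 1 - target / (target + neighbour)`, which lies in `[0, 0.5]`
#' (0: arrow exactly at the target; 0.5: halfway, at equal similarity).
#' The arrow angle is the target angle displaced by `dist` times the
#' angular gap toward the neighbour. If no similarity is positive the
#' arrow is pinned at the target with `dist = 0` and flagged degenerate.
#'
#' @param similarities Named per-anchor Pearson correlation vector.
#' @param layout Named per-anchor angle vector from [circular_layout()].
#' @return List with `arrow_angle` (radians, `[0, 2*pi)`), `dist`,
#'   `target_label`, `neighbour_label`, `degenerate` flag.
#' @export
arrow_angle <- function(similarities, layout) {
  n <- length(layout)
  if (n < 2L) stop("need at least 2 anchors")
  if (length(similarities) != n) {
    stop("need one similarity per anchor")
  }
  if (!is.null(names(similarities)) &&
      !identical(names(similarities), names(layout))) {
    similarities <- similarities[names(layout)]
    if (any(is.na(similarities))) stop("similarity names do not match layout")
  }
  ti <- which.max(similarities)
  ord <- order(layout, seq_len(n))           # counterclockwise positions
  pos <- match(ti, ord)
  nb_ccw <- ord[pos %% n + 1L]
  nb_cw <- ord[(pos - 2L) %% n + 1L]
  t_sim <- max(similarities[ti], 0)
  s_ccw <- max(similarities[nb_ccw], 0)
  s_cw <- max(similarities[nb_cw], 0)
  gap_ccw <- (layout[nb_ccw] - layout[ti]) %% (2 * pi)
  gap_cw <- (layout[ti] - layout[nb_cw]) %% (2 * pi)
  if (n == 2L) {
    # the single other anchor serves as both neighbours; approach it
    # through the smaller gap (ties: counterclockwise)
    use_ccw <- gap_ccw <= gap_cw
  } else if (s_ccw != s_cw) {
    use_ccw <- s_ccw > s_cw
  } else {
    use_ccw <- TRUE
  }
  nb <- if (use_ccw) nb_ccw else nb_cw
  nb_sim <- if (use_ccw) s_ccw else s_cw
  degenerate <- (t_sim + nb_sim) <= 0
  dist <- if (degenerate) 0 else 1 - t_sim / (t_sim + nb_sim)
  signed_gap <- if (use_ccw) gap_ccw else -gap_cw
  angle <- (layout[ti] + dist * signed_gap) %% (2 * pi)
  list(arrow_angle = unname(angle), dist = unname(dist),
       target_label = names(layout)[ti], neighbour_label = names(layout)[nb],
       degenerate = degenerate)
}

#' Circular-thermometer feedback frame
#'
#' The circular display variant: one thermometer per anchor, arranged by
#' [circular_layout()]. Only the target thermometer is filled at any
#' moment (fill = `clip(strength, 0, fill_cap) / fill_cap`), keeping the
#' display uncluttered, and the central arrow conveys similarity via
#' [arrow_angle()]. Nonpositive strength leaves every thermometer empty.
#'
#' @param similarities Named per-anchor Pearson correlation vector.
#' @param intensity An [intensity_result][pattern_strength()] whose
#'   `target_label` is present in the layout.
#' @param layout Named angles from [circular_layout()].
#' @param style A [feedback_style()].
#' @param t_index Feedback time step recorded on the frame.
#' @return A `feedback_frame` with `thermometer_fills`, `arrow_angle` and
#'   `dist` set.
#' @export
circular_frame <- function(similarities, intensity, layout,
                           style = feedback_style(),
                           t_index = NA_integer_) {
  stopifnot(inherits(intensity, "intensity_result"),
            inherits(style, "feedback_style"))
  if (!intensity$target_label %in% names(layout)) {
    stop("target label '", intensity$target_label, "' is not in the layout")
  }
  arrow <- arrow_angle(similarities, layout)
  fills <- stats::setNames(numeric(length(layout)), names(layout))
  if (intensity$strength > 0) {
    fills[intensity$target_label] <-
      clipped_fraction(intensity$strength, style$fill_cap)
  }
  new_feedback_frame(t_index = t_index,
                     target_label = intensity$target_label,
                     strength = intensity$strength,
                     thermometer_fills = fills,
                     arrow_angle = arrow$arrow_angle, dist = arrow$dist,
                     similarity = intensity$similarity,
                     degenerate = arrow$degenerate)
}
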