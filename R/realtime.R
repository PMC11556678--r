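#' Closed-loop session configuration
#'
#' Parameters of the online current-mental-state (CMS) estimator and
#' feedback cadence. Defaults follow common real-time fMRI practice: a
#' 4-volume sliding window shifted by a 2-volume haemodynamic delay
#' (about 4 s at TR 2 s) and mild exponential smoothing.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param window_volumes Sliding-window length `W` (volumes, >= 1).
#' @param hemodynamic_delay_volumes Delay shift `D` (volumes, >= 0) applied
#'   before averaging, compensating the lag of the BOLD response.
#' @param baseline_volumes Volume indices used to compute the per-voxel
#'   baseline (volume mode only).
#' @param smoothing_alpha Exponential smoothing weight in `[0, 1]`; 1 means
#'   no smoothing (each estimate independent of the previous one).
#' @param metric,metric_options Dissimilarity metric for map projection and
#'   distance-to-target.
#' @param feedback_every Steps between feedback frames; 1 = continuous
#'   feedback, larger values give intermittent feedback.
#' @param seed Seed recorded on the session (the loop itself is
#'   deterministic; the seed documents the provenance of its inputs).
#' @return A list of class `session_config`.
#' @export
session_config <- function(tr_seconds = 2, window_volumes = 4L,
                           hemodynamic_delay_volumes = 2L,
                           baseline_volumes = NULL, smoothing_alpha = 0.5,
                           metric = "correlation", metric_options = list(),
                           feedback_every = 1L, seed = 1L) {
  stopifnot(tr_seconds > 0, window_volumes >= 1L,
            hemodynamic_delay_volumes >= 0L,
            smoothing_alpha >= 0, smoothing_alpha <= 1,
            feedback_every >= 1L)
  structure(
    list(tr_seconds = tr_seconds,
         window_volumes = as.integer(window_volumes),
         hemodynamic_delay_volumes = as.integer(hemodynamic_delay_volumes),
         baseline_volumes = baseline_volumes,
         smoothing_alpha = smoothing_alpha, metric = metric,
         metric_options = metric_options,
         feedback_every = as.integer(feedback_every), seed = seed),
    class = "session_config"
  )
}

#' Estimate the current mental-state pattern from a volume window
#'
#' Averages a (delay-shifted) window of volumes over time, converts the
#' average to percent signal change against the per-voxel baseline, and
#' exponentially smooths it against the previous estimate:
#' `alpha * psc + (1 - alpha) * previous`.
#'
#' @param volume_window Numeric `W x V` matrix, exactly
#'   `config$window_volumes` rows.
#' @param baseline_mean Per-voxel baseline (finite, nonzero).
#' @param config A [session_config()].
#' @param previous Previous CMS estimate (or `NULL` at the first step).
#' @return A [voxel_pattern()] labelled `"cms"`.
#' @export
estimate_cms <- function(volume_window, baseline_mean, config,
                         previous = NULL) {
  stopifnot(inherits(config, "session_config"))
  x <- as.matrix(volume_window)
  if (nrow(x) != config$window_volumes) {
    stop("underfull window: got ", nrow(x), " volumes, need ",
         config$window_volumes)
  }
  b <- as.numeric(baseline_mean)
  if (length(b) != ncol(x)) stop("baseline length does not match voxel count")
  if (any(!is.finite(b)) || any(b == 0)) {
    stop("baseline must be finite and nonzero in every voxel")
  }
  psc <- 100 * (colMeans(x) - b) / b
  a <- config$smoothing_alpha
  est <- if (is.null(previous) || a == 1) psc else {
    a * psc + (1 - a) * pattern_values(previous)
  }
  voxel_pattern(est, label = "cms")
}

#' Run a closed-loop semantic neurofeedback session
#'
#' Drives the full loop over a pattern or volume stream: per feedback step
#' the CMS is estimated ([estimate_cms()] in volume mode; pass-through in
#' trial mode), the target is selected as the most similar anchor
#' ([select_target()]), the target-related pattern strength is computed
#' ([pattern_strength()]), the CMS is placed in the semantic map
#' ([project_pattern()]), and a feedback frame combining the map display
#' and the circular-thermometer display is emitted. The correlation
#' distance between the CMS and the *instructed* target anchor is recorded
#' per frame as the navigation error. The loop is fully deterministic
#' given its inputs.
#'
#' @param source Either a `steps x voxels` matrix of trial patterns
#'   ("trial mode") or a `volume_stream` from [make_timeseries()] / a list
#'   with `volumes` and optionally `baseline_mean` ("volume mode"; if
#'   `baseline_mean` is absent it is computed over
#'   `config$baseline_volumes`).
#' @param anchors The [anchor_set()] the map was built from.
#' @param map A [semantic_map][embed_rdm()] built from `anchors` with
#'   `config$metric`.
#' @param config A [session_config()].
#' @param instructed_targets Instructed anchor label per source step
#'   (trial mode) or per volume (volume mode).
#' @param run_id Integer run identifier per source step/volume (default:
#'   all 1).
#' @param layout Circular layout for the thermometer display; default
#'   generic.
#' @param style A [feedback_style()].
#' @return An object of class `trajectory`: `frames` (list of
#'   `feedback_frame`), `t_index` (source step of each frame),
#'   `instructed_targets` and `run_id` per frame, `distance_to_target`
#'   (correlation distance CMS vs instructed anchor, in `[0, 2]`),
#'   `cms_coords` (frames x dims) and `run_boundaries` (first frame index
#'   of each run).
#' @export
run_session <- function(source, anchors, map, config, instructed_targets,
                        run_id = NULL, layout = circular_layout(anchors),
                        style = feedback_style()) {
  stopifnot(inherits(anchors, "anchor_set"), inherits(map, "semantic_map"),
            inherits(config, "session_config"))
  if (!identical(config$metric, map$metric)) {
    stop("config metric '", config$metric, "' does not match the map's '",
         map$metric, "'")
  }
  volume_mode <- is.list(source) && !is.null(source$volumes)
  xs <- if (volume_mode) as.matrix(source$volumes) else as.matrix(source)
  if (ncol(xs) != anchors$voxel_count) {
    stop("source voxel count (", ncol(xs), ") does not match anchors (",
         anchors$voxel_count, ")")
  }
  n_steps <- nrow(xs)
  instructed_targets <- as.character(instructed_targets)
  if (length(instructed_targets) != n_steps) {
    stop("need one instructed target per source step (", n_steps, ")")
  }
  unknown <- setdiff(instructed_targets, anchors$labels)
  if (length(unknown)) {
    stop("unknown instructed target(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  if (is.null(run_id)) run_id <- rep(1L, n_steps)
  run_id <- as.integer(run_id)
  if (length(run_id) != n_steps) stop("need one run id per source step")

  if (volume_mode) {
    bmean <- source$baseline_mean
    if (is.null(bmean)) {
      if (is.null(config$baseline_volumes)) {
        stop("volume mode needs baseline_mean or config$baseline_volumes")
      }
      bmean <- colMeans(xs[config$baseline_volumes, , drop = FALSE])
    }
    first <- config$window_volumes + config$hemodynamic_delay_volumes
    if (first > n_steps) stop("stream shorter than window + delay")
    steps <- seq.int(first, n_steps, by = config$feedback_every)
  } else {
    steps <- seq.int(1L, n_steps, by = config$feedback_every)
  }

  frames <- vector("list", length(steps))
  dist_to_target <- numeric(length(steps))
  coords_mat <- matrix(NA_real_, length(steps), map$dims)
  previous <- NULL
  for (k in seq_along(steps)) {
    t <- steps[k]
    if (volume_mode) {
      w0 <- t - config$hemodynamic_delay_volumes - config$window_volumes + 1L
      window <- xs[seq.int(w0, length.out = config$window_volumes), ,
                   drop = FALSE]
      cms <- estimate_cms(window, bmean, config, previous)
      previous <- cms
    } else {
      cms <- voxel_pattern(xs[t, ], label = "cms")
    }
    sims <- anchor_similarities(cms, anchors)
    target <- anchors$labels[which.max(sims)]
    intensity <- pattern_strength(cms, anchor_pattern(anchors, target))
    coords <- project_pattern(map, anchors, cms)
    fr <- map_frame(map, coords, intensity, style, t_index = t)
    circ <- circular_frame(sims, intensity, layout, style, t_index = t)
    fr$thermometer_fills <- circ$thermometer_fills
    fr$arrow_angle <- circ$arrow_angle
    fr$dist <- circ$dist
    fr$degenerate <- circ$degenerate
    frames[[k]] <- fr
    coords_mat[k, ] <- coords
    dist_to_target[k] <- correlation_distance(
      cms, anchors$patterns[match(instructed_targets[t], anchors$labels), ])
  }
  fr_run <- run_id[steps]
  structure(
    list(frames = frames, t_index = steps,
         instructed_targets = instructed_targets[steps], run_id = fr_run,
         distance_to_target = dist_to_target, cms_coords = coords_mat,
         run_boundaries = which(c(TRUE, diff(fr_run) != 0)),
         config = config),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames, ",
      length(unique(x$run_id)), " run(s); mean distance-to-target ",
      sprintf("%.3f", mean(x$distance_to_target)), "\n", sep = "")
  invisible(x)
}

#' Navigation performance metrics for a trajectory
#'
#' Summarizes how well the participant (or agent) replicated the
#' instructed target mental states: per-block mean distance-to-target,
#' the within-run least-squares slope of distance-to-target against frame
#' index (negative slope = improvement within the run), and the
#' between-run improvement, `mean(run 1 distances) - mean(run 2
#' distances)` (positive = run 2 closer to target).
#'
#' @param traj A [trajectory][run_session()].
#' @return List with `block_means` (data frame: run, target, n_frames,
#'   mean_distance), `run_slopes` (named per run) and
#'   `between_run_improvement` (`NA` with fewer than 2 runs).
#' @export
navigation_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  d <- traj$distance_to_target
  runs <- traj$run_id
  block <- cumsum(c(TRUE, diff(runs) != 0 |
                      traj$instructed_targets[-1L] !=
                        traj$instructed_targets[-length(d)]))
  block_means <- do.call(rbind, lapply(split(seq_along(d), block), function(i) {
    data.frame(run = runs[i[1L]], target = traj$instructed_targets[i[1L]],
               n_frames = length(i), mean_distance = mean(d[i]))
  }))
  rownames(block_means) <- NULL
  run_levels <- unique(runs)
  slopes <- vapply(run_levels, function(r) {
    i <- which(runs == r)
    if (length(i) < 2L) {
      stop("run ", r, " has fewer than 2 frames; slope undefined")
    }
    x <- seq_along(i)
    sum((x - mean(x)) * (d[i] - mean(d[i]))) / sum((x - mean(x))^2)
  }, numeric(1L))
  names(slopes) <- paste0("run", run_levels)
  improvement <- if (length(run_levels) >= 2L) {
    mean(d[runs == run_levels[1L]]) - mean(d[runs == run_levels[2L]])
  } else {
    NA_real_
  }
  list(block_means = block_means, run_slopes = slopes,
       between_run_improvement = improvement)
}
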