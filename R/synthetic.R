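#' Default prescribed anchor correlation structure
#'
#' A plausible similarity structure among emotional mental states: for four
#' states (happy, content, sad, angry) same-valence pairs correlate
#' positively, opposite-valence pairs weakly negatively — the kind of
#' structure localizer patterns show when emotions order along valence and
#' arousal. For other sizes, a mildly exchangeable structure (off-diagonal
#' 0.2) is used.
#'
#' @param n_cond Number of mental states.
#' @return `n_cond x n_cond` symmetric positive-definite correlation
#'   matrix.
#' @export
default_target_corr <- function(n_cond) {
  if (n_cond == 4L) {
    c4 <- matrix(c(
       1.0,  0.5, -0.3, -0.1,
       0.5,  1.0, -0.1, -0.3,
      -0.3, -0.1,  1.0,  0.4,
      -0.1, -0.3,  0.4,  1.0), 4L, 4L)
    return(c4)
  }
  m <- matrix(0.2, n_cond, n_cond)
  diag(m) <- 1
  m
}

default_state_labels <- function(n_cond) {
  base <- c("happy", "content", "sad", "angry",
            "neutral", "afraid", "surprised", "calm")
  if (n_cond <= length(base)) base[seq_len(n_cond)]
  else sprintf("state%02d", seq_len(n_cond))
}

#' Generate anchor patterns with a prescribed correlation structure
#'
#' Draws `n_cond` i.i.d. standard-normal voxel vectors and mixes them by a
#' symmetric matrix square root of the target correlation matrix `C`, so
#' the sample correlations among the returned patterns approach `C` as the
#' voxel count grows. The achieved sample correlation matrix is returned
#' alongside, and downstream tests should compare against the achieved —
#' not the prescribed — values.
#'
#' @param n_cond Number of mental states (>= 1).
#' @param voxel_count Number of voxels `V` (>= 10 * n_cond recommended).
#' @param target_corr Prescribed correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite). Default [default_target_corr()].
#' @param labels State labels; default [default_state_labels()].
#' @param seed RNG seed; generation is a pure function of the arguments.
#' @return List with `anchors` (an [anchor_set()]; for `n_cond = 1` a bare
#'   1-row matrix, since an anchor set needs two states) and
#'   `achieved_corr`.
#' @export
make_anchors <- function(n_cond, voxel_count,
                         target_corr = default_target_corr(n_cond),
                         labels = default_state_labels(n_cond), seed = 1L) {
  stopifnot(n_cond >= 1L, voxel_count >= 2L)
  target_corr <- as.matrix(target_corr)
  if (!all(dim(target_corr) == n_cond)) {
    stop("target_corr must be ", n_cond, " x ", n_cond)
  }
  if (max(abs(target_corr - t(target_corr))) > 1e-10 ||
      max(abs(diag(target_corr) - 1)) > 1e-10) {
    stop("target_corr must be symmetric with unit diagonal")
  }
  e <- eigen((target_corr + t(target_corr)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10) {
    stop("target_corr is not positive semi-definite (min eigenvalue ",
         signif(min(e$values), 3), ")")
  }
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n_cond) %*% t(e$vectors)
  z <- withr::with_seed(seed,
    matrix(stats::rnorm(n_cond * voxel_count), n_cond, voxel_count))
  pat <- root %*% z
  rownames(pat) <- labels
  achieved <- if (n_cond == 1L) matrix(1, 1, 1) else stats::cor(t(pat))
  dimnames(achieved) <- list(labels, labels)
  anchors <- if (n_cond >= 2L) {
    anchor_set(pat, labels, source = paste0("synthetic (seed ", seed, ")"))
  } else {
    pat
  }
  list(anchors = anchors, achieved_corr = achieved)
}

#' Generate noisy localizer trials from anchor patterns
#'
#' Each trial is `intensity * anchor + noise_sigma * sd(anchor) * N(0, 1)`
#' per voxel: amplitude scaling emulates varying emotional engagement, and
#' the noise level is expressed relative to the anchor's own spatial SD so
#' `noise_sigma = 1` means noise as strong as the signal.
#'
#' @param anchors An [anchor_set()].
#' @param condition_sequence Character vector of anchor labels, one per
#'   trial.
#' @param intensity_schedule Per-trial amplitude multiplier (scalar
#'   recycled, default 1).
#' @param noise_sigma Trial noise SD relative to the anchor SD.
#' @param seed RNG seed.
#' @return List with `patterns` (trials x voxels), `labels`
#'   (condition per trial) and `intensity` (per trial).
#' @export
make_trials <- function(anchors, condition_sequence, intensity_schedule = 1,
                        noise_sigma = 0.5, seed = 1L) {
  stopifnot(inherits(anchors, "anchor_set"), noise_sigma >= 0)
  condition_sequence <- as.character(condition_sequence)
  n_trials <- length(condition_sequence)
  unknown <- setdiff(condition_sequence, anchors$labels)
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unique(unknown), collapse = ", "))
  }
  intensity <- rep_len(intensity_schedule, n_trials)
  v <- anchors$voxel_count
  anchor_sd <- apply(anchors$patterns, 1L, stats::sd)
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(n_trials * v), n_trials, v))
  idx <- match(condition_sequence, anchors$labels)
  patterns <- anchors$patterns[idx, , drop = FALSE] * intensity +
    noise * (noise_sigma * anchor_sd[idx])
  rownames(patterns) <- sprintf("trial%03d_%s", seq_len(n_trials),
                                condition_sequence)
  list(patterns = patterns, labels = condition_sequence,
       intensity = intensity)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma BOLD impulse response: a positive gamma peaking
#' at `peak` seconds minus a later undershoot gamma peaking around
#' `undershoot` seconds, scaled by `undershoot_ratio`; normalized to a
#' maximum of 1.
#'
#' @param t Time in seconds (vector).
#' @param peak Time-to-peak of the positive lobe (default 6 s).
#' @param undershoot Time-to-peak of the undershoot lobe (default 16 s).
#' @param undershoot_ratio Undershoot amplitude ratio (default 1/6).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16,
                             undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  grid <- seq(0, 32, by = 0.1)
  hmax <- max(stats::dgamma(grid, shape = peak, rate = 1) -
                undershoot_ratio * stats::dgamma(grid, shape = undershoot,
                                                 rate = 1))
  h / hmax
}

#' Simulate an HRF-convolved block-design volume stream
#'
#' Builds voxel time series as `baseline + sum over conditions of
#' anchor pattern x (HRF-convolved boxcar) x amplitude + white noise`,
#' emulating a localizer or neurofeedback run. Blocks of different
#' conditions must not overlap in time.
#'
#' @param anchors An [anchor_set()].
#' @param block_design Data frame with columns `condition`, `onset_s`,
#'   `duration_s`.
#' @param n_volumes Number of volumes to simulate.
#' @param tr_seconds Repetition time (default 2 s).
#' @param baseline Baseline signal level added to every voxel (default
#'   100, so percent signal change is on the anchor scale).
#' @param amplitude Peak signal scale applied to the anchor patterns
#'   (default 1).
#' @param noise_sigma SD of additive white voxel noise in raw signal units
#'   (default 0.1).
#' @param seed RNG seed.
#' @return List of class `volume_stream`: `volumes` (volumes x voxels),
#'   `baseline_mean` (per-voxel baseline), `tr_seconds`, `design`,
#'   `neural` (the convolved regressor per condition).
#' @export
make_timeseries <- function(anchors, block_design, n_volumes,
                            tr_seconds = 2, baseline = 100, amplitude = 1,
                            noise_sigma = 0.1, seed = 1L) {
  stopifnot(inherits(anchors, "anchor_set"), n_volumes >= 1L,
            tr_seconds > 0, noise_sigma >= 0)
  bd <- as.data.frame(block_design)
  if (!all(c("condition", "onset_s", "duration_s") %in% names(bd))) {
    stop("block_design needs columns condition, onset_s, duration_s")
  }
  bd$condition <- as.character(bd$condition)
  unknown <- setdiff(bd$condition, anchors$labels)
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unique(unknown), collapse = ", "))
  }
  if (nrow(bd) >= 2L) {
    o <- order(bd$onset_s)
    for (i in seq_len(nrow(bd) - 1L)) {
      a <- o[i]; b <- o[i + 1L]
      if (bd$onset_s[a] + bd$duration_s[a] > bd$onset_s[b] &&
          bd$condition[a] != bd$condition[b]) {
        stop("overlapping blocks of different conditions ('",
             bd$condition[a], "' and '", bd$condition[b], "')")
      }
    }
  }
  t_vol <- (seq_len(n_volumes) - 1L) * tr_seconds
  hrf_t <- seq(0, 32, by = tr_seconds)
  hrf <- hrf_double_gamma(hrf_t)
  neural <- matrix(0, n_volumes, anchors$n_cond,
                   dimnames = list(NULL, anchors$labels))
  for (lab in unique(bd$condition)) {
    box <- rep(0, n_volumes)
    for (k in which(bd$condition == lab)) {
      box <- box | (t_vol >= bd$onset_s[k] &
                      t_vol < bd$onset_s[k] + bd$duration_s[k])
    }
    conv <- stats::convolve(as.numeric(box), rev(hrf), type = "open")
    neural[, lab] <- conv[seq_len(n_volumes)]
  }
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(n_volumes * anchors$voxel_count), n_volumes))
  volumes <- baseline + amplitude * neural %*% anchors$patterns +
    noise_sigma * noise
  structure(
    list(volumes = volumes,
         baseline_mean = rep(baseline, anchors$voxel_count),
         tr_seconds = tr_seconds, design = bd, neural = neural),
    class = "volume_stream"
  )
}

#' Configuration of the synthetic navigating participant agent
#'
#' The agent abstracts "engaging in an emotion" as movement of a convex
#' mixture over anchor states: each step it moves its mixture weights a
#' fraction `learning_rate` toward the instructed target's vertex, with
#' optional jitter on the weights and voxel noise on the emitted pattern.
#' This is a deliberate stand-in for real emotion induction (pictures,
#' autobiographical recall), which is outside what a simulator can model.
#'
#' @param start_state Mixture weights over anchors (nonnegative, sum 1) or
#'   `NULL` for the uniform mixture — the 'neutral' starting point.
#' @param learning_rate Per-step step size toward the target vertex, in
#'   `[0, 1]`.
#' @param state_noise_sigma SD of per-step jitter on the mixture weights
#'   (re-projected to the simplex).
#' @param emission_sigma SD of voxel noise on the emitted pattern, relative
#'   to the mean anchor SD.
#' @param seed RNG seed.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(start_state = NULL, learning_rate = 0.2,
                         state_noise_sigma = 0.02, emission_sigma = 0.1,
                         seed = 1L) {
  stopifnot(learning_rate >= 0, learning_rate <= 1,
            state_noise_sigma >= 0, emission_sigma >= 0)
  if (!is.null(start_state)) {
    if (any(start_state < 0) || abs(sum(start_state) - 1) > 1e-8) {
      stop("start_state must be nonnegative mixture weights summing to 1")
    }
  }
  structure(list(start_state = start_state, learning_rate = learning_rate,
                 state_noise_sigma = state_noise_sigma,
                 emission_sigma = emission_sigma, seed = seed),
            class = "agent_config")
}

# Euclidean projection of a vector onto the probability simplex
# (sort-and-threshold algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Simulate a navigating participant
#'
#' Runs the agent of [agent_config()] over a sequence of instruction
#' blocks: within each block the mixture moves geometrically toward the
#' instructed anchor's vertex (`w <- (1 - eta) w + eta e_target`), is
#' jittered and re-projected to the simplex, and the emitted pattern is
#' the anchor mixture plus emission noise. The agent's state persists
#' across blocks, emulating within-session practice.
#'
#' @param anchors An [anchor_set()].
#' @param instruction_blocks Data frame with columns `target` (anchor
#'   label) and `n_steps`; optional `run` (integer run id, default 1).
#' @param agent An [agent_config()].
#' @return List with `patterns` (steps x voxels), `mixtures` (ground-truth
#'   mixture trace, steps x n_cond), `instructed` (target label per step)
#'   and `run_id` (per step).
#' @export
simulate_agent <- function(anchors, instruction_blocks,
                           agent = agent_config()) {
  stopifnot(inherits(anchors, "anchor_set"), inherits(agent, "agent_config"))
  ib <- as.data.frame(instruction_blocks)
  if (!all(c("target", "n_steps") %in% names(ib))) {
    stop("instruction_blocks needs columns target, n_steps")
  }
  ib$target <- as.character(ib$target)
  unknown <- setdiff(ib$target, anchors$labels)
  if (length(unknown)) {
    stop("unknown instruction target(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  if (is.null(ib$run)) ib$run <- 1L
  n <- anchors$n_cond
  v <- anchors$voxel_count
  w <- if (is.null(agent$start_state)) rep(1 / n, n) else {
    if (length(agent$start_state) != n) {
      stop("start_state length must equal the number of anchors")
    }
    as.numeric(agent$start_state)
  }
  steps <- sum(ib$n_steps)
  instructed <- rep(ib$target, ib$n_steps)
  run_id <- rep(as.integer(ib$run), ib$n_steps)
  mean_sd <- mean(apply(anchors$patterns, 1L, stats::sd))
  withr::with_seed(agent$seed, {
    mixtures <- matrix(NA_real_, steps, n,
                       dimnames = list(NULL, anchors$labels))
    patterns <- matrix(NA_real_, steps, v)
    for (s in seq_len(steps)) {
      tgt <- match(instructed[s], anchors$labels)
      e_t <- as.numeric(seq_len(n) == tgt)
      w <- (1 - agent$learning_rate) * w + agent$learning_rate * e_t
      if (agent$state_noise_sigma > 0) {
        w <- project_simplex(w + stats::rnorm(n, 0, agent$state_noise_sigma))
      }
      mixtures[s, ] <- w
      emit <- drop(w %*% anchors$patterns)
      if (agent$emission_sigma > 0) {
        emit <- emit + stats::rnorm(v, 0, agent$emission_sigma * mean_sd)
      }
      patterns[s, ] <- emit
    }
  })
  list(patterns = patterns, mixtures = mixtures, instructed = instructed,
       run_id = run_id)
}
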