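# Synthetic three-ball cascade kinematics with full ground truth.
#
# The generator is ball-centric: each ball is thrown every `cycle_period`
# seconds, one third of a cycle after the previous ball, alternating hands.
# Flight is ballistic under `gravity`; between a catch and the next throw the
# ball rides the hand through a smooth "scoop" dip, which is what real
# in-hand carries look like and keeps the vertical trace close to a smooth
# periodic oscillation.

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' (config, seed) without disturbing the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Configuration for the synthetic three-ball cascade
#'
#' @param n_balls number of balls; only the standard three-ball cascade is
#'   supported.
#' @param gravity gravitational acceleration, m/s^2. Fractions of 9.81
#'   emulate reduced-gravity training schedules.
#' @param cycle_period full cycle period of one ball, seconds (throws occur
#'   every `cycle_period / 3`, alternating hands).
#' @param phase_jitter_sd per-throw timing noise, radians of cycle phase.
#'   Throw times are jittered by Gaussian noise with standard deviation
#'   `phase_jitter_sd * cycle_period / (2*pi)` seconds.
#' @param dwell_fraction fraction of a cycle the ball spends in the hand,
#'   in (0, 1).
#' @param drop_hazard probability that any given catch fails and ends the
#'   trial.
#' @param frame_rate sampling rate of the emulated camera, Hz.
#' @param trial_count number of trials to simulate.
#' @param max_cycles hard cap on cycles per trial (a trial with
#'   `drop_hazard = 0` would otherwise never end).
#' @param release_height height of the release/catch point, m.
#' @param scoop_depth depth of the in-hand carry below the release point, m.
#' @param hand_sep lateral distance between the two hands, m.
#' @param throw_inset lateral distance of the release point inward of the
#'   hand, m (cascade throws release near the midline and are caught
#'   outside, so opposite flights cross at different points).
#' @param seed integer seed; the simulation is a pure function of
#'   (config, seed).
#' @return an object of class `cascade_config`.
#' @export
cascade_config <- function(n_balls = 3L, gravity = 9.81, cycle_period = 1.2,
                           phase_jitter_sd = 0.15, dwell_fraction = 1 / 3,
                           drop_hazard = 0.05, frame_rate = 60,
                           trial_count = 1L, max_cycles = 25L,
                           release_height = 1.0, scoop_depth = 0.08,
                           hand_sep = 0.4, throw_inset = 0.08, seed = 1L) {
  if (n_balls != 3L)
    stop("only the three-ball cascade is supported (n_balls = 3)", call. = FALSE)
  stopifnot_scalar(gravity, "gravity", positive = TRUE)
  stopifnot_scalar(cycle_period, "cycle_period", positive = TRUE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar(phase_jitter_sd, "phase_jitter_sd")
  if (phase_jitter_sd < 0) stop("phase_jitter_sd must be >= 0", call. = FALSE)
  if (dwell_fraction <= 0 || dwell_fraction >= 1)
    stop("dwell_fraction must lie in (0, 1)", call. = FALSE)
  if (drop_hazard < 0 || drop_hazard > 1)
    stop("drop_hazard must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_balls = 3L, gravity = gravity, cycle_period = cycle_period,
    phase_jitter_sd = phase_jitter_sd, dwell_fraction = dwell_fraction,
    drop_hazard = drop_hazard, frame_rate = frame_rate,
    trial_count = as.integer(trial_count), max_cycles = as.integer(max_cycles),
    release_height = release_height, scoop_depth = scoop_depth,
    hand_sep = hand_sep, throw_inset = throw_inset, seed = seed
  ), class = "cascade_config")
}

# Piecewise trajectory of one ball given its throw times and throwing hands.
# Returns position at the sample times plus the true (cycle-linear) phase.
# `pre_offset` shifts the pre-first-throw hold laterally (a hand holding two
# balls keeps them apart), tapering to zero by the first throw.
ball_trajectory <- function(tt, throw_t, throw_hand, cfg, pre_offset = 0) {
  g <- cfg$gravity
  Tf <- (1 - cfg$dwell_fraction) * cfg$cycle_period
  v0 <- g * Tf / 2
  y0 <- cfg$release_height
  xh <- c(L = -cfg$hand_sep / 2, R = cfg$hand_sep / 2)
  # release point sits inward of the hand; catches happen at the hand
  xr <- xh - sign(xh) * cfg$throw_inset
  catch_t <- throw_t + Tf
  K <- length(throw_t)

  y <- rep(y0, length(tt))
  x <- rep(xh[[throw_hand[1]]], length(tt))
  # pre-first-throw dwell in the first throwing hand
  pre <- tt < throw_t[1]
  if (any(pre) && throw_t[1] > 0) {
    u <- tt[pre] / throw_t[1]
    y[pre] <- y0 - cfg$scoop_depth * sin(pi * u)
    from1 <- throw_hand[1]
    x[pre] <- xh[[from1]] + (xr[[from1]] - xh[[from1]]) * u + pre_offset * (1 - u)
  }
  for (k in seq_len(K)) {
    from <- throw_hand[k]
    to <- if (from == "L") "R" else "L"
    fl <- tt >= throw_t[k] & tt < catch_t[k]
    if (any(fl)) {
      u <- tt[fl] - throw_t[k]
      y[fl] <- y0 + v0 * u - 0.5 * g * u^2
      x[fl] <- xr[[from]] + (xh[[to]] - xr[[from]]) * u / Tf
    }
    dw_end <- if (k < K) throw_t[k + 1] else max(tt) + 1
    dw <- tt >= catch_t[k] & tt < dw_end
    if (any(dw)) {
      span <- max(dw_end - catch_t[k], 1e-9)
      u <- pmin((tt[dw] - catch_t[k]) / span, 1)
      y[dw] <- y0 - cfg$scoop_depth * sin(pi * u)
      x[dw] <- xh[[to]] + (xr[[to]] - xh[[to]]) * u
    }
  }
  # true phase: 360 degrees per cycle, linear between successive throw times
  cyc <- c(throw_t, throw_t[K] + cfg$cycle_period)
  phase <- stats::approx(cyc, 360 * (seq_along(cyc) - 1), xout = tt,
                         rule = 2)$y
  list(x = x, y = y, phase = phase)
}

#' Simulate three-ball cascade trials
#'
#' Generates ballistic ball trajectories, static hand positions, throw/catch
#' events, per-ball ground-truth phases, and trial-ending drops. A drop
#' truncates the trial at the failed catch; completed catches before the
#' drop define the trial's catch count.
#'
#' @param cfg a [cascade_config()].
#' @return an object of class `cascade_session`: a list of trials, each with
#'   elements `tracks` (list of `ball_track`: `ball_id`, `t`, `x`, `y`,
#'   `events` data frame), `hands` (data frame `t`, `x_L`, `y_L`, `x_R`,
#'   `y_R`), `truth` (true events, phases, drop time) and `n_catches`.
#' @examples
#' sess <- simulate_cascade(cascade_config(trial_count = 2, seed = 7))
#' sess[[1]]$n_catches
#' @export
simulate_cascade <- function(cfg) {
  stopifnot(inherits(cfg, "cascade_config"))
  with_seed(cfg$seed, {
    trials <- lapply(seq_len(cfg$trial_count), function(i) simulate_one_trial(cfg))
  })
  structure(trials, class = "cascade_session", config = cfg)
}

simulate_one_trial <- function(cfg) {
  T. <- cfg$cycle_period
  Tf <- (1 - cfg$dwell_fraction) * T.
  fs <- cfg$frame_rate
  jit_sd <- cfg$phase_jitter_sd * T. / (2 * pi)

  # chronological throw schedule over all balls
  sched <- do.call(rbind, lapply(1:3, function(b) {
    k <- 0:(cfg$max_cycles - 1)
    nom <- k * T. + (b - 1) * T. / 3
    jit <- if (jit_sd > 0) stats::rnorm(length(k), 0, jit_sd) else 0
    # global throw index 3k + (b-1): even -> left hand
    hand <- ifelse((3 * k + b - 1) %% 2 == 0, "L", "R")
    data.frame(ball = b, k = k, t = nom + jit, hand = hand,
               stringsAsFactors = FALSE)
  }))
  sched <- sched[order(sched$t), ]
  # keep throws causally ordered per ball (jitter must not reorder cycles)
  for (b in 1:3) {
    ix <- which(sched$ball == b)
    tb <- sched$t[ix]
    tb <- cummax(tb + seq_along(tb) * 1e-9)
    tb <- pmax(tb, c(0, tb[-length(tb)] + Tf + 0.02))
    sched$t[ix] <- tb
  }
  sched <- sched[order(sched$t), ]

  # drops: each catch fails independently with drop_hazard
  fails <- stats::runif(nrow(sched)) < cfg$drop_hazard
  drop_ix <- which(fails)[1]
  if (!is.na(drop_ix)) {
    t_end <- sched$t[drop_ix] + Tf       # time of the failed catch
    keep <- sched$t + Tf <= t_end + 1e-9 # throws whose catch completes
    n_catches <- sum(keep) - 1L          # failed catch itself not completed
  } else {
    t_end <- max(sched$t) + Tf
    keep <- rep(TRUE, nrow(sched))
    n_catches <- sum(keep)
  }
  sched <- sched[sched$t < t_end, ]
  tt <- seq(0, t_end, by = 1 / fs)

  tracks <- lapply(1:3, function(b) {
    sb <- sched[sched$ball == b, ]
    if (nrow(sb) == 0) {
      return(structure(list(ball_id = b, t = tt, x = rep(0, length(tt)),
                            y = rep(cfg$release_height, length(tt)),
                            events = empty_events(),
                            true_phase = rep(NA_real_, length(tt))),
                       class = "ball_track"))
    }
    # ball 3 shares the starting hand with ball 1: hold it toward the centre
    pre_offset <- if (b == 3L) ifelse(sb$hand[1] == "L", 0.06, -0.06) else 0
    traj <- ball_trajectory(tt, sb$t, sb$hand, cfg, pre_offset = pre_offset)
    catch_hand <- ifelse(sb$hand == "L", "R", "L")
    ev <- rbind(
      data.frame(kind = "throw", time = sb$t, hand = sb$hand,
                 stringsAsFactors = FALSE),
      data.frame(kind = "catch", time = sb$t + Tf, hand = catch_hand,
                 stringsAsFactors = FALSE)
    )
    ev <- ev[ev$time <= t_end + 1e-9, ]
    ev <- ev[order(ev$time), ]
    structure(list(ball_id = b, t = tt, x = traj$x, y = traj$y,
                   events = ev, true_phase = traj$phase),
              class = "ball_track")
  })

  xh <- cfg$hand_sep / 2
  hands <- data.frame(t = tt,
                      x_L = -xh, y_L = cfg$release_height - 0.02,
                      x_R = xh, y_R = cfg$release_height - 0.02)

  truth <- list(
    events = do.call(rbind, lapply(tracks, function(tr) {
      if (nrow(tr$events) == 0) return(NULL)
      cbind(ball = tr$ball_id, tr$events)
    })),
    phases = vapply(tracks, function(tr) tr$true_phase, numeric(length(tt))),
    t = tt,
    drop_time = if (!is.na(drop_ix)) t_end else NA_real_,
    n_catches = n_catches
  )
  list(tracks = tracks, hands = hands, truth = truth, n_catches = n_catches)
}

empty_events <- function() {
  data.frame(kind = character(), time = numeric(), hand = character(),
             stringsAsFactors = FALSE)
}

#' Corrupt ideal ball tracks into frame-wise detection tables
#'
#' Emulates the output of a frame-wise ball/hand detector: per frame an
#' unordered list of candidate ball positions with dropout, isotropic
#' Gaussian position noise and Poisson-distributed uniform false positives,
#' plus (noisy) hand positions. An optional pixel projection (scale plus
#' flipped vertical axis) emulates image coordinates; the projection
#' parameters travel with the table so ingestion can restore physical units.
#'
#' @param trial one trial from [simulate_cascade()] (elements `tracks`,
#'   `hands`).
#' @param dropout_rate probability that a true ball is missing from a frame.
#' @param false_positive_rate expected number of spurious candidates per
#'   frame (Poisson).
#' @param noise_sd isotropic detection noise standard deviation, in the
#'   output units (m, or px if projected).
#' @param pixels_per_m if non-`NULL`, project to pixel coordinates with this
#'   scale and a flipped y axis.
#' @param seed optional seed for the corruption noise.
#' @return a `detection_table`: data frame with columns `frame`, `t`,
#'   `type` (`"ball"`, `"hand_L"`, `"hand_R"`), `x`, `y`, and (for ground
#'   truth scoring only) `true_ball` (`NA` for false positives).
#' @export
corrupt_detections <- function(trial, dropout_rate = 0,
                               false_positive_rate = 0, noise_sd = 0,
                               pixels_per_m = NULL, seed = NULL) {
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]", call. = FALSE)
  if (false_positive_rate < 0) stop("false_positive_rate must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  tracks <- trial$tracks
  hands <- trial$hands
  tt <- tracks[[1]]$t
  nf <- length(tt)

  with_seed(seed, {
    ball_rows <- do.call(rbind, lapply(tracks, function(tr) {
      keep <- if (dropout_rate > 0) stats::runif(nf) >= dropout_rate else rep(TRUE, nf)
      data.frame(frame = which(keep) - 1L, t = tt[keep],
                 type = "ball", x = tr$x[keep], y = tr$y[keep],
                 true_ball = tr$ball_id, stringsAsFactors = FALSE)
    }))
    if (noise_sd > 0) {
      ball_rows$x <- ball_rows$x + stats::rnorm(nrow(ball_rows), 0, noise_sd)
      ball_rows$y <- ball_rows$y + stats::rnorm(nrow(ball_rows), 0, noise_sd)
    }
    if (false_positive_rate > 0) {
      xr <- range(c(ball_rows$x, hands$x_L, hands$x_R))
      yr <- range(c(ball_rows$y, hands$y_L, hands$y_R))
      nfp <- stats::rpois(nf, false_positive_rate)
      fp_frames <- rep(seq_len(nf) - 1L, nfp)
      if (length(fp_frames)) {
        fp <- data.frame(frame = fp_frames, t = tt[fp_frames + 1L],
                         type = "ball",
                         x = stats::runif(length(fp_frames), xr[1] - 0.2, xr[2] + 0.2),
                         y = stats::runif(length(fp_frames), yr[1] - 0.2, yr[2] + 0.2),
                         true_ball = NA_integer_, stringsAsFactors = FALSE)
        ball_rows <- rbind(ball_rows, fp)
      }
    }
    # shuffle candidates so within-frame order carries no identity
    ball_rows <- ball_rows[sample.int(nrow(ball_rows)), ]
  })
  ball_rows <- ball_rows[order(ball_rows$frame), ]

  hand_rows <- rbind(
    data.frame(frame = seq_len(nf) - 1L, t = tt, type = "hand_L",
               x = hands$x_L, y = hands$y_L, true_ball = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(frame = seq_len(nf) - 1L, t = tt, type = "hand_R",
               x = hands$x_R, y = hands$y_R, true_ball = NA_integer_,
               stringsAsFactors = FALSE)
  )
  det <- rbind(ball_rows, hand_rows)
  det <- det[order(det$frame, det$type), ]
  rownames(det) <- NULL
  if (!is.null(pixels_per_m)) {
    y_max <- max(det$y) + 0.2
    det$x <- det$x * pixels_per_m
    det$y <- (y_max - det$y) * pixels_per_m
    attr(det, "projection") <- list(pixels_per_m = pixels_per_m, y_max = y_max)
  }
  class(det) <- c("detection_table", "data.frame")
  det
}

#' Restore physical units on a pixel-projected detection table
#'
#' Detection tables carry their projection parameters; ingestion flips the
#' vertical axis back to up-positive metres. Tables without a projection are
#' returned unchanged.
#' @param det a `detection_table`.
#' @export
ingest_detections <- function(det, pixels_per_m = NULL, y_max = NULL) {
  proj <- attr(det, "projection")
  if (is.null(proj) && is.null(pixels_per_m)) return(det)
  ppm <- pixels_per_m %||% proj$pixels_per_m
  ym <- y_max %||% proj$y_max
  det$x <- det$x / ppm
  det$y <- ym - det$y / ppm
  attr(det, "projection") <- NULL
  det
}
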