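# Synthetic two-ball visual-occlusion sessions.

#' Configuration for the synthetic occlusion session
#'
#' @param n_trials number of throw-catch attempts (60 on ordinary days,
#'   300 on test days).
#' @param success_prob probability that a trial's second catch succeeds with
#'   both hands. On a failed trial the failing hand(s) are drawn at random.
#' @param catch_cov 3x3 symmetric positive-definite covariance (m^2) of the
#'   catch-position scatter in the hand-centred frame.
#' @param blocks number of blocks the trials are split into.
#' @param shutter_duration shutter-closure duration, s.
#' @param condition_mix named proportions over conditions
#'   `apex_locked`, `none`, `random`; must sum to 1.
#' @param flight_time flight duration of the occluded ball, s.
#' @param invalid_rate fraction of trials marked invalid (shutter
#'   malfunction / marker loss emulation).
#' @param seed integer seed.
#' @export
occlusion_config <- function(n_trials = 300L, success_prob = 0.8,
                             catch_cov = diag(0.02^2, 3), blocks = 4L,
                             shutter_duration = 0.5,
                             condition_mix = c(apex_locked = 1 / 3,
                                               none = 1 / 3, random = 1 / 3),
                             flight_time = 0.7, invalid_rate = 0.02,
                             seed = 1L) {
  if (success_prob < 0 || success_prob > 1)
    stop("success_prob must lie in [0, 1]", call. = FALSE)
  catch_cov <- as.matrix(catch_cov)
  if (!isTRUE(all.equal(catch_cov, t(catch_cov))) ||
      any(eigen(catch_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("catch_cov must be symmetric positive-definite", call. = FALSE)
  if (abs(sum(condition_mix) - 1) > 1e-8)
    stop("condition_mix proportions must sum to 1", call. = FALSE)
  if (invalid_rate < 0 || invalid_rate > 1)
    stop("invalid_rate must lie in [0, 1]", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), success_prob = success_prob,
                 catch_cov = catch_cov, blocks = as.integer(blocks),
                 shutter_duration = shutter_duration,
                 condition_mix = condition_mix, flight_time = flight_time,
                 invalid_rate = invalid_rate, seed = seed),
            class = "occlusion_config")
}

# one synthetic ballistic flight of the occluded ball, sampled at 60 Hz
occluded_ball_track <- function(flight_time, gravity = 9.81, fs = 60) {
  v0 <- gravity * flight_time / 2
  tt <- seq(0, flight_time, by = 1 / fs)
  structure(list(ball_id = 2L, t = tt, x = rep(0, length(tt)),
                 y = 1 + v0 * tt - 0.5 * gravity * tt^2,
                 events = empty_events()), class = "ball_track")
}

#' Simulate a two-ball visual-occlusion session
#'
#' Each trial alternately throws and catches two balls with opposite hands;
#' the trial outcome is a both-hands second-catch success drawn
#' Bernoulli(`success_prob`), and successful catches scatter around the
#' wrist with covariance `catch_cov`. Shutter intervals follow the trial's
#' condition: locked to the occluded ball's apex, absent, or uniformly
#' random over the flight.
#'
#' @param cfg an [occlusion_config()].
#' @return data frame of class `occlusion_trials` with one row per trial:
#'   block, condition, validity, per-hand success flags, both-hands
#'   `success`, wrist and catch positions (columns `wrist_*_L/R`,
#'   `catch_*_L/R`, `NA` where the catch failed), and shutter interval
#'   (`t_close`, `t_open`, `NA` for condition `none`).
#' @export
simulate_occlusion_session <- function(cfg) {
  stopifnot(inherits(cfg, "occlusion_config"))
  n <- cfg$n_trials
  with_seed(cfg$seed, {
    condition <- sample(names(cfg$condition_mix), n, replace = TRUE,
                        prob = cfg$condition_mix)
    block <- rep(seq_len(cfg$blocks), length.out = n)[order(seq_len(n))]
    block <- sort(block)
    valid <- stats::runif(n) >= cfg$invalid_rate
    success <- stats::runif(n) < cfg$success_prob
    # on failure at least one hand fails: 1 = L only, 2 = R only, 3 = both
    fail_mode <- sample(1:3, n, replace = TRUE)
    success_L <- success | fail_mode == 2
    success_R <- success | fail_mode == 1

    track <- occluded_ball_track(cfg$flight_time)
    shut <- t(vapply(condition, function(cond) {
      iv <- schedule_shutter(track, cond, cfg$shutter_duration)
      if (nrow(iv) == 0) c(NA_real_, NA_real_) else c(iv$t_close[1], iv$t_open[1])
    }, numeric(2)))

    wrist <- cbind(x = rep(c(-0.2, 0.2), length.out = 2 * n),
                   y = 0.1, z = 0.9)
    scatter <- MASS::mvrnorm(2 * n, mu = c(0, 0, 0), Sigma = cfg$catch_cov)
    catch <- wrist + scatter
    iL <- seq(1, 2 * n, by = 2); iR <- iL + 1
    out <- data.frame(
      trial = seq_len(n), block = block, condition = condition,
      valid = valid, success_L = success_L, success_R = success_R,
      success = success_L & success_R,
      t_close = shut[, 1], t_open = shut[, 2],
      wrist_x_L = wrist[iL, 1], wrist_y_L = wrist[iL, 2], wrist_z_L = wrist[iL, 3],
      wrist_x_R = wrist[iR, 1], wrist_y_R = wrist[iR, 2], wrist_z_R = wrist[iR, 3],
      catch_x_L = ifelse(success_L, catch[iL, 1], NA_real_),
      catch_y_L = ifelse(success_L, catch[iL, 2], NA_real_),
      catch_z_L = ifelse(success_L, catch[iL, 3], NA_real_),
      catch_x_R = ifelse(success_R, catch[iR, 1], NA_real_),
      catch_y_R = ifelse(success_R, catch[iR, 2], NA_real_),
      catch_z_R = ifelse(success_R, catch[iR, 3], NA_real_),
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("occlusion_trials", "data.frame")
  attr(out, "config") <- cfg
  out
}
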