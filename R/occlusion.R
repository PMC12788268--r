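# Prediction and Accuracy indices from the two-ball visual-occlusion task:
# apex-locked shutter scheduling, hand-centred catch clouds, 95%
# probability ellipsoids, and the day-level indices.

#' Schedule shutter-glass closure for an occlusion trial
#'
#' Condition `apex_locked` closes the shutter for `shutter_duration`
#' seconds starting at the occluded ball's flight apex; `none` leaves the
#' shutter open; `random` draws the onset uniformly over the ball's flight
#' so that the closure ends by the end of the flight where possible.
#'
#' @param ball_track a `ball_track` of the occluded ball.
#' @param condition one of `"apex_locked"`, `"none"`, `"random"`.
#' @param shutter_duration closure duration, s.
#' @return data frame with columns `t_close`, `t_open` (zero rows for
#'   condition `none`).
#' @export
schedule_shutter <- function(ball_track, condition, shutter_duration = 0.5) {
  condition <- match.arg(condition, c("apex_locked", "none", "random"))
  if (condition == "none")
    return(data.frame(t_close = numeric(), t_open = numeric()))
  apexes <- detect_apexes(ball_track$t, ball_track$y)
  if (!length(apexes))
    stop("no apex found on the occluded ball's track", call. = FALSE)
  t_close <- if (condition == "apex_locked") {
    apexes[1]
  } else {
    hi <- max(min(ball_track$t), max(ball_track$t) - shutter_duration)
    stats::runif(1, min(ball_track$t), hi)
  }
  data.frame(t_close = t_close, t_open = t_close + shutter_duration)
}

#' Prediction index from occlusion trials
#'
#' Fraction of valid trials in which both hands successfully completed the
#' second catch; invalid trials are excluded from numerator and
#' denominator.
#'
#' @param trials data frame with logical columns `valid` and `success`
#'   (both-hands success), e.g. from [simulate_occlusion_session()].
#' @return `P` in `[0, 1]`, with counts in attributes `n_succ`, `n_valid`;
#'   `NA` when no valid trial exists.
#' @export
prediction_index <- function(trials) {
  v <- trials[trials$valid, , drop = FALSE]
  if (nrow(v) == 0) {
    out <- NA_real_
    attr(out, "n_succ") <- 0L; attr(out, "n_valid") <- 0L
    return(out)
  }
  out <- mean(v$success)
  attr(out, "n_succ") <- sum(v$success)
  attr(out, "n_valid") <- nrow(v)
  out
}

#' Express catch positions in the hand-centred frame
#'
#' Pure translation: the wrist-marker position at the catch is subtracted,
#' axes unchanged.
#'
#' @param catch_pos,wrist_pos numeric matrices (n x 3) or length-3 vectors.
#' @return relative positions; rows with any missing coordinate are
#'   dropped.
#' @export
hand_centered <- function(catch_pos, wrist_pos) {
  catch_pos <- rbind(catch_pos); wrist_pos <- rbind(wrist_pos)
  rel <- catch_pos - wrist_pos
  ok <- stats::complete.cases(rel)
  rel[ok, , drop = FALSE]
}

#' Fit a 95% probability ellipsoid to a 3D point cloud
#'
#' Gaussian model: with sample covariance `Sigma` (n-1 normalization) and
#' `c` the chi-square(3 df) quantile at the coverage level
#' (7.8147 at 0.95), the ellipsoid volume is
#' `V = (4/3) * pi * c^(3/2) * sqrt(det(Sigma))`. Fits are flagged
#' unstable when fewer than four points are available or the covariance is
#' near-singular (condition number above `cond_max`).
#'
#' @param points n x 3 matrix of hand-centred catch positions, m.
#' @param coverage probability mass enclosed by the ellipsoid.
#' @param cond_max covariance condition-number ceiling for a stable fit.
#' @return list of class `ellipsoid_fit`: `center`, `cov`, `volume`,
#'   `n_points`, `stable`.
#' @export
fit_ellipsoid <- function(points, coverage = 0.95, cond_max = 1e6) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  n <- nrow(points)
  if (n < 4) {
    return(structure(list(center = colMeans(points), cov = NULL,
                          volume = NA_real_, n_points = n, stable = FALSE),
                     class = "ellipsoid_fit"))
  }
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  stable <- min(ev) > 0 && max(ev) / min(ev) <= cond_max
  vol <- if (stable) {
    cc <- stats::qchisq(coverage, df = 3)
    (4 / 3) * pi * cc^(3 / 2) * sqrt(det(S))
  } else NA_real_
  structure(list(center = colMeans(points), cov = S, volume = vol,
                 n_points = n, stable = stable),
            class = "ellipsoid_fit")
}

#' Accuracy index from per-hand, per-block ellipsoid volumes
#'
#' Geometric mean of the stable ellipsoid volumes over both hands and all
#' blocks (`A = (prod V)^(1/(2|B|))` when both hands contribute every
#' block). Smaller values indicate tighter catch clustering, i.e. higher
#' spatial accuracy. `A` is missing when either hand has no stable block.
#'
#' @param volumes data frame with columns `hand`, `block`, `volume`, and
#'   optionally `stable` (unstable rows are dropped).
#' @return the index `A`, or `NA`.
#' @export
accuracy_index <- function(volumes) {
  if ("stable" %in% names(volumes))
    volumes <- volumes[volumes$stable, , drop = FALSE]
  volumes <- volumes[is.finite(volumes$volume), , drop = FALSE]
  if (!all(c("L", "R") %in% volumes$hand)) return(NA_real_)
  if (any(volumes$volume <= 0)) stop("volumes must be positive", call. = FALSE)
  exp(mean(log(volumes$volume)))
}

#' Day-level occlusion indices from a trial table
#'
#' Computes the Prediction index over valid trials and the Accuracy index
#' from hand-centred second-catch clouds pooled per (hand, block), fitting
#' a 95% probability ellipsoid to each.
#'
#' @param trials an `occlusion_trials` data frame.
#' @param coverage ellipsoid coverage level.
#' @return list with `P`, `A`, `volumes` (per hand x block fits), and
#'   counts.
#' @export
day_occlusion_indices <- function(trials, coverage = 0.95) {
  P <- prediction_index(trials)
  v <- trials[trials$valid, , drop = FALSE]
  vols <- do.call(rbind, lapply(c("L", "R"), function(h) {
    do.call(rbind, lapply(sort(unique(v$block)), function(b) {
      rows <- v[v$block == b, , drop = FALSE]
      catch <- as.matrix(rows[, paste0("catch_", c("x", "y", "z"), "_", h)])
      wrist <- as.matrix(rows[, paste0("wrist_", c("x", "y", "z"), "_", h)])
      rel <- hand_centered(catch, wrist)
      fit <- fit_ellipsoid(rel, coverage = coverage)
      data.frame(hand = h, block = b, volume = fit$volume,
                 n_points = fit$n_points, stable = fit$stable,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(P = as.numeric(P), A = accuracy_index(vols), volumes = vols,
       n_succ = attr(P, "n_succ"), n_valid = attr(P, "n_valid"))
}
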