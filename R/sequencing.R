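# Sequencing: instantaneous ball phases from the analytic signal, window
# scores against the ideal 120-degree cascade offsets, day-level pooling,
# and the valid-window-count exclusion rule.

#' Smooth and mean-subtract a vertical position series
#'
#' Zero-phase (forward-backward) low-pass Butterworth filter followed by
#' mean subtraction. Instantaneous phase is only meaningful for a
#' narrow-band signal, so the cascade pipeline calls this with a cutoff
#' near the cycle fundamental; the default 5 Hz is a generic kinematic
#' smoothing cutoff.
#'
#' @param y vertical position series.
#' @param fs sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @return zero-mean filtered series of the same length.
#' @export
smooth_center <- function(y, fs, cutoff = 5) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(cutoff, "cutoff", positive = TRUE)
  if (length(y) < fs)
    stop("series too short: need at least 1 s of samples", call. = FALSE)
  if (cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  y <- y - mean(y)
  if (stats::sd(y) == 0) return(y)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  yt <- signal::filtfilt(bf, y)
  yt - mean(yt)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real zero-mean series.
#' @return complex vector `x + i H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a smoothed vertical series
#'
#' Argument of the analytic signal, in degrees wrapped to (-180, 180].
#'
#' @param y_tilde zero-mean band-limited series (see [smooth_center()]).
#' @return phase in degrees; all-zero input is rejected.
#' @export
instantaneous_phase <- function(y_tilde) {
  if (all(y_tilde == 0))
    stop("phase undefined for an all-zero series", call. = FALSE)
  wrap_deg(Arg(analytic_signal(y_tilde)) * 180 / pi)
}

#' Detect flight apexes on a vertical series
#'
#' Apexes are downward zero-crossings of the vertical velocity with
#' negative acceleration, with a refractory period between successive
#' apexes (a quarter cycle by default).
#'
#' @param t sample times, s.
#' @param y (smoothed) vertical positions.
#' @param refractory minimum spacing between apexes, s. If `NULL`, a
#'   quarter of the dominant period estimated from the zero-crossing rate.
#' @return apex times, s.
#' @export
detect_apexes <- function(t, y, refractory = NULL) {
  v <- diff(y) / diff(t)
  acc <- c(diff(v), 0) / diff(t)
  cross <- which(v[-length(v)] > 0 & v[-1] <= 0 & acc[-length(acc)] < 0)
  if (!length(cross)) return(numeric())
  # refine: apex time between the two samples bracketing the crossing
  tap <- (t[cross + 1] + t[cross + 2]) / 2
  if (is.null(refractory)) {
    refractory <- if (length(tap) > 1) stats::median(diff(tap)) / 4 else 0
  }
  keep <- c(TRUE, diff(tap) > refractory)
  out <- tap[1]
  for (i in seq_along(tap)[-1])
    if (tap[i] - out[length(out)] > refractory) out <- c(out, tap[i])
  out
}

#' Build scoring windows from a merged apex stream
#'
#' Each run of three consecutive apexes from three distinct balls yields
#' one window spanning the first to the third apex; windows overlap,
#' sliding one apex at a time.
#'
#' @param apexes data frame with columns `ball` and `time`.
#' @return data frame of windows: `w_start`, `w_end`, `balls` (the ordered
#'   ball labels, comma-separated).
#' @export
make_windows <- function(apexes) {
  if (nrow(apexes) < 3) return(data.frame(w_start = numeric(),
                                          w_end = numeric(),
                                          balls = character()))
  apexes <- apexes[order(apexes$time), ]
  n <- nrow(apexes)
  i <- seq_len(n - 2)
  distinct <- apexes$ball[i] != apexes$ball[i + 1] &
    apexes$ball[i] != apexes$ball[i + 2] &
    apexes$ball[i + 1] != apexes$ball[i + 2]
  data.frame(
    w_start = apexes$time[i][distinct],
    w_end = apexes$time[i + 2][distinct],
    balls = paste(apexes$ball[i], apexes$ball[i + 1],
                  apexes$ball[i + 2], sep = ",")[distinct],
    stringsAsFactors = FALSE
  )
}

#' Window-wise Sequencing score
#'
#' Over the usable samples of a window, the three pairwise instantaneous
#' phase differences are compared with the ideal 120-degree cascade
#' spacing; the deviation `delta_ij` is the circular distance from the raw
#' difference to the nearest of +120 or -120 degrees (which makes the score
#' invariant to ball relabelling and to a common phase rotation). The score
#' is
#' `S_w = mean_k [ 1 - (delta_12 + delta_13 + delta_23) / (3 * 180) ]`,
#' in `[0, 1]`, with 1 for perfectly maintained offsets.
#'
#' @param t sample times, s.
#' @param phi numeric matrix with three columns: per-ball phase in degrees.
#' @param w_start,w_end window bounds, s.
#' @param usable optional logical mask of usable samples (e.g. excluding
#'   filter/Hilbert edge effects).
#' @return the score, or `NA` when no usable sample falls in the window.
#' @export
window_score <- function(t, phi, w_start, w_end, usable = NULL) {
  stopifnot(ncol(phi) == 3)
  in_w <- t >= w_start & t <= w_end
  if (!is.null(usable)) in_w <- in_w & usable
  if (!any(in_w)) return(NA_real_)
  d12 <- dist_to_ideal120(phi[in_w, 2] - phi[in_w, 1])
  d13 <- dist_to_ideal120(phi[in_w, 3] - phi[in_w, 1])
  d23 <- dist_to_ideal120(phi[in_w, 3] - phi[in_w, 2])
  mean(1 - (d12 + d13 + d23) / (3 * 180))
}

#' Per-trial Sequencing windows from three ball tracks
#'
#' Runs the full phase stage on one trial: resamples the three tracks onto
#' a common grid, band-limits each vertical series near the cascade
#' fundamental, computes instantaneous phases, detects apexes, builds
#' windows and scores them. The first and last half cycle are excluded
#' from the usable samples to avoid Hilbert edge effects.
#'
#' @param tracks list of three `ball_track`s.
#' @param fs sampling rate, Hz.
#' @param cutoff_scale low-pass cutoff as a multiple of the apex-estimated
#'   cycle frequency.
#' @return data frame of windows with their scores (`S_w`), `K` usable
#'   samples, and bounds; zero rows when fewer than three apexes exist.
#' @export
sequencing_windows <- function(tracks, fs = 60, cutoff_scale = 1.5) {
  if (length(tracks) != 3)
    stop("Sequencing is defined for exactly three balls", call. = FALSE)
  t0 <- max(vapply(tracks, function(tr) min(tr$t), 0))
  t1 <- min(vapply(tracks, function(tr) max(tr$t), 0))
  if (t1 - t0 < 2) return(empty_window_frame())
  tt <- seq(t0, t1, by = 1 / fs)
  ys <- lapply(tracks, function(tr) stats::approx(tr$t, tr$y, tt, rule = 2)$y)

  # estimate the cycle period from raw apex spacing, then band-limit
  ap0 <- lapply(ys, function(y) detect_apexes(tt, smooth_center(y, fs, 5)))
  spacing <- unlist(lapply(ap0, function(a) if (length(a) > 1) diff(a) else NULL))
  period <- if (length(spacing)) stats::median(spacing) else 1
  cutoff <- min(cutoff_scale / period, fs / 2 - 1e-6)

  yts <- lapply(ys, function(y) smooth_center(y, fs, cutoff))
  phi <- vapply(yts, instantaneous_phase, numeric(length(tt)))
  apexes <- do.call(rbind, lapply(1:3, function(b) {
    a <- detect_apexes(tt, yts[[b]], refractory = period / 4)
    if (!length(a)) return(NULL)
    data.frame(ball = b, time = a)
  }))
  if (is.null(apexes) || nrow(apexes) < 3) return(empty_window_frame())
  w <- make_windows(apexes)
  if (nrow(w) == 0) return(empty_window_frame())
  usable <- tt >= t0 + period / 2 & tt <= t1 - period / 2
  w$K <- vapply(seq_len(nrow(w)), function(i)
    sum(tt >= w$w_start[i] & tt <= w$w_end[i] & usable), 0L)
  w$S_w <- vapply(seq_len(nrow(w)), function(i)
    window_score(tt, phi, w$w_start[i], w$w_end[i], usable), 0)
  w <- w[w$K >= 1 & !is.na(w$S_w), ]
  rownames(w) <- NULL
  w
}

empty_window_frame <- function() {
  data.frame(w_start = numeric(), w_end = numeric(), balls = character(),
             K = integer(), S_w = numeric())
}

#' Day-level Sequencing index
#'
#' Arithmetic mean of all valid window scores pooled over a day's real-world
#' sessions.
#'
#' @param window_scores numeric vector of pooled `S_w` values.
#' @return list with `S` (mean, `NA` when no windows) and `n_windows`.
#' @export
day_sequencing <- function(window_scores) {
  window_scores <- window_scores[is.finite(window_scores)]
  list(S = if (length(window_scores)) mean(window_scores) else NA_real_,
       n_windows = length(window_scores))
}

#' Window-count outlier exclusion rule
#'
#' Participant-days with too few valid Sequencing windows yield unstable
#' mean scores. The counts are log-transformed (over positive counts) and a
#' conservative lower bound of three standard deviations below the mean is
#' applied: `threshold = exp(mean(log N) - 3 sd(log N))`. Days with counts
#' below the threshold, and all zero-count days, are excluded.
#'
#' @param counts non-negative integer vector of valid-window counts.
#' @return logical exclusion mask (`TRUE` = excluded), with the numeric
#'   threshold in attribute `threshold`.
#' @export
exclude_low_window_days <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  pos <- counts[counts >= 1]
  if (length(pos) < 2) {
    mask <- counts == 0
    attr(mask, "threshold") <- 0
    return(mask)
  }
  lg <- log(pos)
  s <- stats::sd(lg)
  threshold <- if (s == 0) 0 else exp(mean(lg) - 3 * s)
  mask <- counts == 0 | counts < threshold
  attr(mask, "threshold") <- threshold
  mask
}
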