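# Shared fixtures and independent oracles.

# Independent brute-force evaluation of the window Sequencing score:
# explicit loops and naive circular arithmetic, no shared code with the
# package implementation.
brute_force_window_score <- function(phi) {
  total <- 0
  for (k in seq_len(nrow(phi))) {
    dev_sum <- 0
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      d <- phi[k, pair[2]] - phi[k, pair[1]]
      best <- Inf
      for (target in c(120, -120)) {
        a <- (d - target) %% 360
        best <- min(best, a, 360 - a)
      }
      dev_sum <- dev_sum + best
    }
    total <- total + 1 - dev_sum / (3 * 180)
  }
  total / nrow(phi)
}

# Three sinusoidal "ball" tracks offset by a third of a period.
sinusoid_tracks <- function(freq = 1, fs = 60, duration = 20, amp = 0.5) {
  tt <- seq(0, duration, by = 1 / fs)
  lapply(1:3, function(b) {
    structure(list(ball_id = b, t = tt,
                   x = rep(0, length(tt)),
                   y = 1 + amp * cos(2 * pi * freq * (tt - (b - 1) / (3 * freq))),
                   events = data.frame()),
              class = "ball_track")
  })
}

# A clean default cascade trial (no jitter, no drops).
clean_trial <- function(max_cycles = 10, seed = 3, ...) {
  simulate_cascade(cascade_config(phase_jitter_sd = 0, drop_hazard = 0,
                                  max_cycles = max_cycles, seed = seed,
                                  ...))[[1]]
}

# Majority-label identity accuracy of reconstructed tracks against the
# ground-truth ball labels carried by the detection table.
identity_accuracy <- function(tracks) {
  labs <- unlist(lapply(tracks, function(tr) {
    tb <- tr$true_ball[!is.na(tr$true_ball)]
    if (!length(tb)) return(NULL)
    tb == as.integer(names(which.max(table(tb))))
  }))
  mean(labs)
}

# Deterministic window-count fixture: log-normal counts plus known low
# outliers; its exp(meanlog - 3 sdlog) threshold falls between 4 and 5.
window_count_fixture <- function() {
  set.seed(1)
  base <- round(rlnorm(55, meanlog = 3.6, sdlog = 0.45))
  c(0L, 1L, 4L, base[base >= 6])
}
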