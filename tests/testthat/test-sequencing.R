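test_that("smoothing is zero-mean, passband-flat, and noise-suppressing", {
  fs <- 60
  tt <- seq(0, 10, by = 1 / fs)
  expect_equal(smooth_center(rep(5, length(tt)), fs), rep(0, length(tt)))

  y <- sin(2 * pi * 1.5 * tt)
  yt <- smooth_center(y, fs, cutoff = 5)
  interior <- seq(fs, length(tt) - fs)
  expect_lt(max(abs(yt[interior] - y[interior])) / 1, 0.01)

  noisy <- y + 0.5 * sin(2 * pi * 20 * tt)
  yt2 <- smooth_center(noisy, fs, cutoff = 5)
  noise_before <- mean((noisy - y)^2)
  noise_after <- mean((yt2[interior] - y[interior])^2)
  expect_lt(noise_after / noise_before, 0.1)

  expect_error(smooth_center(1:10, fs), "too short")
  expect_error(smooth_center(y, fs, cutoff = 40), "Nyquist")
})

test_that("instantaneous phase matches the analytic signal of sinusoids", {
  fs <- 60
  tt <- seq(0, 20, by = 1 / fs)
  f <- 0.8
  interior <- tt > 2 & tt < 18
  phi_cos <- instantaneous_phase(cos(2 * pi * f * tt))
  expected <- ((360 * f * tt + 180) %% 360) - 180
  err <- abs(((phi_cos - expected + 180) %% 360) - 180)
  expect_lt(max(err[interior]), 1)

  phi_sin <- instantaneous_phase(sin(2 * pi * f * tt))
  expected_sin <- ((360 * f * tt - 90 + 180) %% 360) - 180
  err_sin <- abs(((phi_sin - expected_sin + 180) %% 360) - 180)
  expect_lt(max(err_sin[interior]), 1)

  expect_error(instantaneous_phase(rep(0, 100)), "all-zero")
})

test_that("three sinusoids offset by T/3 show 120-degree phase differences", {
  fs <- 60
  tt <- seq(0, 20, by = 1 / fs)
  f <- 0.8
  phi <- vapply(0:2, function(b)
    instantaneous_phase(cos(2 * pi * f * (tt - b / (3 * f)))),
    numeric(length(tt)))
  interior <- tt > 2 & tt < 18
  for (pair in list(c(1, 2), c(2, 3))) {
    d <- phi[interior, pair[1]] - phi[interior, pair[2]]
    dev <- abs(((d - 120 + 180) %% 360) - 180)
    expect_lt(max(dev), 1)
  }
})

test_that("apex detection matches closed forms and ground truth", {
  fs <- 60
  g <- 9.81; v0 <- 3
  tt <- seq(0, 2 * v0 / g, by = 1 / fs)
  apexes <- detect_apexes(tt, v0 * tt - g * tt^2 / 2)
  expect_length(apexes, 1)
  expect_lt(abs(apexes - v0 / g), 1 / fs)

  tt2 <- seq(0, 10, by = 1 / fs)
  ap2 <- detect_apexes(tt2, sin(2 * pi * tt2 / 1.25))
  expect_true(all(abs(diff(ap2) - 1.25) < 1 / fs))

  # jittered cascade: apex count equals ground-truth throw count
  trial <- simulate_cascade(cascade_config(phase_jitter_sd = 0.3,
                                           drop_hazard = 0, max_cycles = 8,
                                           seed = 5))[[1]]
  for (tr in trial$tracks) {
    yt <- smooth_center(tr$y, fs, cutoff = 2)
    ap <- detect_apexes(tr$t, yt, refractory = 0.3)
    n_throws <- sum(tr$events$kind == "throw")
    expect_lte(abs(length(ap) - n_throws), 1)
  }
})

test_that("window construction enumerates distinct-ball apex triples", {
  mk <- function(balls) data.frame(ball = balls, time = seq_along(balls))
  expect_equal(nrow(make_windows(mk(c(1, 2, 3, 1, 2, 3)))), 4)
  w <- make_windows(mk(c(1, 1, 2, 3)))
  expect_equal(nrow(w), 1)
  expect_equal(w$w_start, 2)
  expect_equal(w$w_end, 4)
  expect_equal(nrow(make_windows(mk(c(1, 2, 1, 2)))), 0)
  expect_equal(nrow(make_windows(mk(c(1, 2)))), 0)
})

test_that("window score equals hand-derived values on canonical phase sets", {
  tt <- seq(0, 1, by = 0.01)
  n <- length(tt)
  # exact 120-degree spacing -> perfect score
  phi_exact <- cbind(rep(0, n), rep(120, n), rep(240, n))
  expect_equal(window_score(tt, phi_exact, 0, 1), 1)
  # all balls in phase: every pair 120 degrees off -> 1/3
  phi_same <- cbind(rep(10, n), rep(10, n), rep(10, n))
  expect_equal(window_score(tt, phi_same, 0, 1), 1 / 3)
  # one gap perturbed by eps: two pairs off by eps -> 1 - eps/270
  eps <- 6
  phi_eps <- cbind(rep(0, n), rep(120 + eps, n), rep(240, n))
  expect_equal(window_score(tt, phi_eps, 0, 1), 1 - eps / 270)
})

test_that("window score agrees with the brute-force oracle on random phases", {
  set.seed(99)
  for (i in 1:100) {
    K <- sample(5:40, 1)
    phi <- matrix(runif(3 * K, -180, 180), ncol = 3)
    tt <- seq_len(K)
    expect_equal(window_score(tt, phi, 1, K), brute_force_window_score(phi),
                 tolerance = 1e-12)
  }
})

test_that("window score is invariant to rotation and relabelling, bounded in [0,1]", {
  set.seed(7)
  for (i in 1:50) {
    K <- 20
    phi <- matrix(runif(3 * K, -180, 180), ncol = 3)
    tt <- seq_len(K)
    s <- window_score(tt, phi, 1, K)
    expect_gte(s, 0); expect_lte(s, 1)
    rot <- ((phi + runif(1, -360, 360) + 180) %% 360) - 180
    expect_equal(window_score(tt, rot, 1, K), s, tolerance = 1e-10)
    perm <- phi[, sample(3)]
    expect_equal(window_score(tt, perm, 1, K), s, tolerance = 1e-10)
  }
})

test_that("day-level Sequencing pools window scores", {
  expect_equal(day_sequencing(c(1, 0.5))$S, 0.75)
  expect_equal(day_sequencing(0.8)$S, 0.8)
  empty <- day_sequencing(numeric())
  expect_true(is.na(empty$S))
  expect_equal(empty$n_windows, 0)
})

test_that("zero-jitter cascades score near-perfect Sequencing", {
  trial <- clean_trial(max_cycles = 10)
  w <- sequencing_windows(trial$tracks)
  expect_gt(nrow(w), 5)
  expect_gte(day_sequencing(w$S_w)$S, 0.98)
  expect_true(all(w$S_w >= 0 & w$S_w <= 1))
})

test_that("mean Sequencing decreases with phase jitter", {
  mean_S <- vapply(c(0, 0.5, 1.0), function(j) {
    sess <- simulate_cascade(cascade_config(phase_jitter_sd = j,
                                            drop_hazard = 0, max_cycles = 10,
                                            trial_count = 3, seed = 31))
    mean(unlist(lapply(sess, function(tr) sequencing_windows(tr$tracks)$S_w)))
  }, 0)
  expect_true(all(diff(mean_S) < 0))
})

test_that("window-count exclusion implements the 3-sigma log rule", {
  counts <- window_count_fixture()
  mask <- exclude_low_window_days(counts)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 4); expect_lt(thr, 5)
  expect_setequal(counts[mask], c(0L, 1L, 4L))

  # all-equal counts: only zero-count days go
  m2 <- exclude_low_window_days(c(50, 50, 50, 0))
  expect_equal(which(m2), 4L)
  expect_true(all(exclude_low_window_days(c(0, 0))))
  expect_error(exclude_low_window_days(c(-1, 3)), "non-negative")
})
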