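test_that("cascade flights follow the projectile closed form", {
  cfg <- cascade_config(phase_jitter_sd = 0, drop_hazard = 0,
                        max_cycles = 6, seed = 1)
  trial <- simulate_cascade(cfg)[[1]]
  Tf <- (1 - cfg$dwell_fraction) * cfg$cycle_period
  v0 <- cfg$gravity * Tf / 2
  tr <- trial$tracks[[1]]
  # first flight of ball 1: throw at t = 0
  fl <- tr$t > 0 & tr$t < Tf
  expect_equal(max(tr$y[fl]), cfg$release_height + v0^2 / (2 * cfg$gravity),
               tolerance = 1e-3)
  t_apex <- tr$t[fl][which.max(tr$y[fl])]
  expect_lt(abs(t_apex - v0 / cfg$gravity), 1 / cfg$frame_rate)
  # reduced gravity lowers the throw (same flight time by construction)
  lo <- simulate_cascade(cascade_config(gravity = 0.4 * 9.81,
                                        phase_jitter_sd = 0, drop_hazard = 0,
                                        max_cycles = 6, seed = 1))[[1]]
  expect_lt(max(lo$tracks[[1]]$y), max(tr$y))
})

test_that("cascade simulation is a pure function of (config, seed)", {
  cfg <- cascade_config(trial_count = 3, seed = 11)
  a <- simulate_cascade(cfg)
  b <- simulate_cascade(cfg)
  expect_identical(a, b)
  c2 <- simulate_cascade(cascade_config(trial_count = 3, seed = 12))
  expect_false(identical(a, c2))
})

test_that("drops truncate trials and set the completed-catch count", {
  none <- simulate_cascade(cascade_config(drop_hazard = 0, max_cycles = 8,
                                          phase_jitter_sd = 0, seed = 2))[[1]]
  expect_equal(none$n_catches, 3 * 8)
  expect_true(is.na(none$truth$drop_time))
  all_drop <- simulate_cascade(cascade_config(drop_hazard = 1, max_cycles = 8,
                                              seed = 2))[[1]]
  expect_equal(all_drop$n_catches, 0)
  expect_false(is.na(all_drop$truth$drop_time))
  # ground-truth event times strictly increase per ball
  for (tr in none$tracks) {
    for (k in c("throw", "catch"))
      expect_true(all(diff(tr$events$time[tr$events$kind == k]) > 0))
  }
})

test_that("cascade config rejects invalid parameters", {
  expect_error(cascade_config(n_balls = 4), "three-ball")
  expect_error(cascade_config(gravity = -1), "gravity")
  expect_error(cascade_config(cycle_period = Inf), "cycle_period")
  expect_error(cascade_config(dwell_fraction = 1), "dwell_fraction")
  expect_error(cascade_config(phase_jitter_sd = -0.1), "phase_jitter_sd")
})

test_that("occlusion sessions hit the configured success probability", {
  all_succ <- simulate_occlusion_session(
    occlusion_config(n_trials = 50, success_prob = 1, invalid_rate = 0, seed = 1))
  expect_equal(prediction_index(all_succ), 1, ignore_attr = TRUE)
  half <- simulate_occlusion_session(
    occlusion_config(n_trials = 1e4, success_prob = 0.5, invalid_rate = 0,
                     seed = 7))
  p <- as.numeric(prediction_index(half))
  expect_gt(p, 0.49)
  expect_lt(p, 0.51)
  expect_error(occlusion_config(catch_cov = diag(c(1, 1, 0))),
               "positive-definite")
  expect_error(occlusion_config(condition_mix = c(apex_locked = 0.5, none = 0.2,
                                                  random = 0.2)),
               "sum to 1")
})

test_that("detection corruption is lossless when noiseless", {
  trial <- clean_trial(max_cycles = 6)
  det <- corrupt_detections(trial)
  tracks <- track_balls(det, max_jump = 0.12, max_gap = 6)
  expect_length(tracks, 3)
  # exact round trip: each reconstructed track equals one simulated ball
  for (tr in tracks) {
    b <- tr$true_ball[1]
    expect_true(all(tr$true_ball == b))
    src <- trial$tracks[[b]]
    expect_equal(tr$y, src$y)
    expect_equal(tr$x, src$x)
  }
})

test_that("pixel projection on detection tables round-trips through ingest", {
  trial <- clean_trial(max_cycles = 4)
  det_px <- corrupt_detections(trial, pixels_per_m = 500, seed = 1)
  expect_false(is.null(attr(det_px, "projection")))
  back <- ingest_detections(det_px)
  det_m <- corrupt_detections(trial, seed = 1)
  expect_equal(back$y, det_m$y, tolerance = 1e-12)
  expect_equal(back$x, det_m$x, tolerance = 1e-12)
})

test_that("performance generator inverts the log link and respects dispersion", {
  z0 <- data.frame(Z_P = 0, Z_A = 0, Z_S = 0)
  cfg <- perf_gen_config(seed = 3)
  out <- generate_performance(z0, cfg)
  expect_equal(out$mu, exp(cfg$beta[[1]]))
  # phi -> 0: sample variance collapses around mu
  zz <- z0[rep(1, 2000), , drop = FALSE]
  tight <- generate_performance(zz, perf_gen_config(dispersion = 1e-6, seed = 4))
  expect_lt(stats::sd(tight$Perf) / mean(tight$Perf), 0.01)
  expect_true(all(tight$Perf > 0))
  expect_error(perf_gen_config(dispersion = 0), "dispersion")
  expect_error(generate_performance(data.frame(Z_P = NA, Z_A = 0, Z_S = 0), cfg),
               "finite")
})

test_that("a fit on generated performance recovers the generating coefficients", {
  z <- simulate_indices(2000, seed = 21)
  d <- generate_performance(z, perf_gen_config(dispersion = 0.5, seed = 22))
  fit <- fit_glm(Perf ~ Z_P + Z_A + Z_S, d, family = "gamma_log")
  truth <- perf_gen_config()$beta
  expect_true(all(abs(fit$beta - truth) < 0.05))
})

test_that("the full synthetic study is deterministic and well-formed", {
  cfg <- study_config(n_participants = 4, trials_per_day = 2, occl_trials = 20,
                      max_cycles = 10, seed = 9)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$index), 4 * 3)
  expect_setequal(unique(a$index$group), c("Low-g", "Normal-g"))
  expect_length(a$data, 12)
  expect_named(a$data[[1]], c("cascade", "detections", "occlusion"))
})
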