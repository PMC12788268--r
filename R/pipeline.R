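# End-to-end orchestration: synthetic study generation, per-day index
# computation through the tracking/sequencing/occlusion stages, index
# standardization, and the performance GLMs.

#' Study-level configuration
#'
#' Bundles the simulation and pipeline parameters for a full synthetic
#' study: 20 beginners split into Low-g and Normal-g groups, measured on
#' Days 1, 5 and 10. Skill schedules (throw-timing jitter, drop hazard,
#' occlusion catch success, catch scatter) improve with training day and
#' vary between participants; `noise_scale = 0` produces an idealized
#' noiseless study (no jitter, no drops, perfect occlusion catches).
#'
#' @param n_participants number of participants (half per group).
#' @param days training days carrying the full measurement battery.
#' @param trials_per_day real-world cascade trials per participant-day.
#' @param max_cycles cycle cap per cascade trial.
#' @param cycle_period,dwell_fraction,gravity,frame_rate cascade kinematics
#'   (see [cascade_config()]).
#' @param noise_scale multiplies every noise source; 0 gives the noiseless
#'   study.
#' @param dropout_rate,false_positive_rate,detection_noise_sd detector
#'   corruption (see [corrupt_detections()]).
#' @param occl_trials,occl_blocks,occl_invalid_rate occlusion-session shape
#'   (see [occlusion_config()]).
#' @param run_sensitivity whether [run_pipeline()] fits the sensitivity
#'   models.
#' @param seed master seed; every stage derives its own stream from it.
#' @export
study_config <- function(n_participants = 20L, days = c(1L, 5L, 10L),
                         trials_per_day = 8L, max_cycles = 25L,
                         cycle_period = 1.2, dwell_fraction = 1 / 3,
                         gravity = 9.81, frame_rate = 60,
                         noise_scale = 1,
                         dropout_rate = 0.02, false_positive_rate = 0.5,
                         detection_noise_sd = 0.004,
                         occl_trials = 60L, occl_blocks = 4L,
                         occl_invalid_rate = 0.02,
                         run_sensitivity = FALSE, seed = 1L) {
  structure(list(
    n_participants = as.integer(n_participants), days = as.integer(days),
    trials_per_day = as.integer(trials_per_day),
    max_cycles = as.integer(max_cycles), cycle_period = cycle_period,
    dwell_fraction = dwell_fraction, gravity = gravity,
    frame_rate = frame_rate, noise_scale = noise_scale,
    dropout_rate = dropout_rate, false_positive_rate = false_positive_rate,
    detection_noise_sd = detection_noise_sd,
    occl_trials = as.integer(occl_trials),
    occl_blocks = as.integer(occl_blocks),
    occl_invalid_rate = occl_invalid_rate,
    run_sensitivity = isTRUE(run_sensitivity), seed = as.integer(seed)
  ), class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' Round-trips losslessly, so a stored config reproduces a run exactly.
#' @param cfg a [study_config()].
#' @param path file path.
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

# Participant-day skill schedule: parameters improve with training day and
# vary with participant-level component traits (a_S, a_P, a_A, modestly
# correlated) plus day-level wobble, so the three indices are related but
# not collinear -- real sub-skills develop at different rates.
skill_schedule <- function(day, ability, noise_scale, lowg = FALSE) {
  u <- (day - 1) / 9
  # the slow-tempo low-gravity training condition mainly promotes early
  # rhythm (Sequencing) gains; emulated as an extra ramp on the
  # sequencing trait
  a_S <- ability[1] + 0.3 * u * lowg
  a_P <- ability[2]
  a_A <- ability[3]
  # overall performance draws on all three components, sequencing most
  a_perf <- 0.6 * a_S + 0.25 * a_P + 0.15 * a_A
  list(
    phase_jitter_sd = noise_scale *
      pmin(exp(log(0.9) + (log(0.35) - log(0.9)) * u - 0.4 * a_S), 1.5),
    drop_hazard = if (noise_scale == 0) 0 else
      stats::plogis(-1.1 - 1.6 * u - 0.6 * a_perf),
    success_prob = if (noise_scale == 0) 1 else
      stats::plogis(0.2 + 1.8 * u + 0.7 * a_P),
    catch_sigma = noise_scale * 0.06 * exp(-0.8 * u - 0.35 * a_A)
  )
}

# participant traits: three correlated component abilities
draw_abilities <- function(n, seed, sd = 0.6, rho = 0.3) {
  Sigma <- sd^2 * (diag(3) * (1 - rho) + rho)
  with_seed(seed, MASS::mvrnorm(n, mu = rep(0, 3), Sigma = Sigma))
}

#' Generate a full synthetic study
#'
#' Emits, for every participant-day, raw cascade trials, corrupted
#' detection tables, and an occlusion-trial table, together with the
#' generating ground truth. Deterministic given the config seed.
#'
#' @param cfg a [study_config()].
#' @return list of class `study_data` with `config`, `index` (per
#'   participant-day generating parameters and ground-truth catch counts)
#'   and `data` (named list `p<participant>_d<day>` of `cascade`,
#'   `detections`, `occlusion`).
#' @export
generate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  n <- cfg$n_participants
  group <- rep(c("Low-g", "Normal-g"), each = ceiling(n / 2))[seq_len(n)]
  ability <- draw_abilities(n, cfg$seed)
  index <- list(); data <- list()
  for (p in seq_len(n)) {
    for (d in cfg$days) {
      sub_seed <- (cfg$seed + 7919L * p + 104729L * d) %% .Machine$integer.max
      # day-level wobble: skills fluctuate across days (fatigue, attention)
      wobble <- with_seed(sub_seed + 900L, stats::rnorm(3, 0, 0.3))
      sk <- skill_schedule(d, ability[p, ] + wobble, cfg$noise_scale,
                           lowg = group[p] == "Low-g")
      casc_cfg <- cascade_config(
        gravity = cfg$gravity, cycle_period = cfg$cycle_period,
        phase_jitter_sd = sk$phase_jitter_sd,
        dwell_fraction = cfg$dwell_fraction, drop_hazard = sk$drop_hazard,
        frame_rate = cfg$frame_rate, trial_count = cfg$trials_per_day,
        max_cycles = cfg$max_cycles, seed = sub_seed
      )
      cascade <- simulate_cascade(casc_cfg)
      detections <- lapply(seq_along(cascade), function(i)
        corrupt_detections(
          cascade[[i]],
          dropout_rate = cfg$noise_scale * cfg$dropout_rate,
          false_positive_rate = cfg$noise_scale * cfg$false_positive_rate,
          noise_sd = cfg$noise_scale * cfg$detection_noise_sd,
          seed = sub_seed + i
        ))
      occ_cfg <- occlusion_config(
        n_trials = cfg$occl_trials, success_prob = sk$success_prob,
        catch_cov = diag(max(sk$catch_sigma, 1e-4)^2 * c(1, 0.8, 1.2)),
        blocks = cfg$occl_blocks,
        invalid_rate = if (cfg$noise_scale == 0) 0 else cfg$occl_invalid_rate,
        seed = sub_seed + 500L
      )
      occlusion <- simulate_occlusion_session(occ_cfg)
      if (cfg$noise_scale == 0) {
        # perfect catches: exactly at the wrist, a degenerate scatter
        for (h in c("L", "R")) for (ax in c("x", "y", "z"))
          occlusion[[paste0("catch_", ax, "_", h)]] <-
            occlusion[[paste0("wrist_", ax, "_", h)]]
      }
      key <- sprintf("p%02d_d%02d", p, d)
      data[[key]] <- list(cascade = cascade, detections = detections,
                          occlusion = occlusion)
      index[[key]] <- data.frame(
        participant = p, day = d, group = group[p],
        ability_S = ability[p, 1], ability_P = ability[p, 2],
        ability_A = ability[p, 3], phase_jitter_sd = sk$phase_jitter_sd,
        drop_hazard = sk$drop_hazard, success_prob_true = sk$success_prob,
        catch_sigma_true = sk$catch_sigma,
        true_catches = paste(vapply(cascade, `[[`, 0L, "n_catches"),
                             collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(config = cfg, index = do.call(rbind, index), data = data),
            class = "study_data")
}

# Per participant-day index computation on raw streams: tracking,
# event labelling, Sequencing windows, Perf, occlusion indices.
compute_day_indices <- function(day_data, cfg) {
  catch_counts <- integer(); pooled_Sw <- numeric()
  for (i in seq_along(day_data$detections)) {
    det <- day_data$detections[[i]]
    tracks <- suppressWarnings(
      track_balls(det, max_jump = 0.12, max_gap = 6L))
    hands <- day_data$cascade[[i]]$hands
    tracks <- label_events(tracks, hands)
    catch_counts <- c(catch_counts, sum(vapply(tracks, function(tr)
      sum(tr$events$kind == "catch"), 0L)))
    w <- tryCatch(sequencing_windows(tracks, fs = cfg$frame_rate),
                  error = function(e) empty_window_frame())
    pooled_Sw <- c(pooled_Sw, w$S_w)
  }
  seqs <- day_sequencing(pooled_Sw)
  occ <- day_occlusion_indices(day_data$occlusion)
  data.frame(Perf = perf_metric(catch_counts), S = seqs$S,
             n_windows = seqs$n_windows, P = occ$P, A = occ$A,
             n_valid_occl = occ$n_valid)
}

#' Day-level indices for every participant-day of a study
#'
#' Runs the measurement stages on the raw streams: ball tracking and event
#' labelling on the detection tables, Sequencing windows and pooled day
#' scores, the performance metric over trial catch counts, and the
#' occlusion-based Prediction/Accuracy indices; then applies the
#' window-count exclusion rule to the Sequencing column.
#'
#' @param study a `study_data` from [generate_study()].
#' @return data frame with one row per participant-day (`Perf`, `S`,
#'   `n_windows`, `P`, `A`, `S_excluded`); the exclusion log is in
#'   attribute `exclusions`.
#' @export
study_day_indices <- function(study) {
  stopifnot(inherits(study, "study_data"))
  cfg <- study$config
  idx <- study$index
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    key <- sprintf("p%02d_d%02d", idx$participant[i], idx$day[i])
    cbind(idx[i, c("participant", "day", "group")],
          compute_day_indices(study$data[[key]], cfg))
  })
  day_indices <- do.call(rbind, rows)
  rownames(day_indices) <- NULL
  excl_mask <- exclude_low_window_days(day_indices$n_windows)
  exclusions <- day_indices[excl_mask, c("participant", "day", "n_windows")]
  if (nrow(exclusions))
    exclusions$reason <- sprintf("n_windows below threshold %.2f",
                                 attr(excl_mask, "threshold"))
  day_indices$S_excluded <- as.logical(excl_mask)
  day_indices$S[excl_mask] <- NA_real_
  attr(day_indices, "exclusions") <- exclusions
  day_indices
}

#' Run the full analysis pipeline on a (synthetic) study
#'
#' Generates (or accepts) a study, reconstructs ball tracks from the
#' detection tables, computes the day-level Sequencing, Prediction and
#' Accuracy indices and the performance metric, applies the window-count
#' exclusion rule and the monotone + robust-z transforms, and fits the
#' Gamma-Log and Normal-Identity performance models with their evaluation
#' metrics. Degenerate index distributions (e.g. a noiseless study where
#' the Accuracy ellipsoids are singular) skip the modelling stage with an
#' explanatory message instead of failing.
#'
#' @param cfg a [study_config()].
#' @param study optionally a pre-generated `study_data` (must match `cfg`).
#' @param out_dir if non-`NULL`, per-stage CSV tables and a JSON report are
#'   written here.
#' @return list of class `pipeline_report`: `day_indices`, `exclusions`,
#'   `diagnostics`, `models` (or `skipped_reason`), `summary_by_group`.
#' @export
run_pipeline <- function(cfg = study_config(), study = NULL, out_dir = NULL) {
  if (is.null(study)) study <- generate_study(cfg)
  day_indices <- study_day_indices(study)
  exclusions <- attr(day_indices, "exclusions")
  attr(day_indices, "exclusions") <- NULL

  report <- list(config = cfg, day_indices = day_indices,
                 exclusions = exclusions)

  modeled <- day_indices[stats::complete.cases(
    day_indices[c("Perf", "S", "P", "A")]) & day_indices$Perf > 0, ]
  skip <- NULL
  if (nrow(modeled) < 10) {
    skip <- if (all(!is.finite(day_indices$A)))
      "Accuracy index degenerate: no stable ellipsoid fits (near-singular catch scatter)"
    else "too few complete participant-days for modelling"
  } else if (any(!is.finite(c(modeled$S, modeled$P, modeled$A)))) {
    skip <- "non-finite indices"
  } else {
    std <- tryCatch(standardize_indices(modeled), error = function(e) e)
    if (inherits(std, "error")) {
      skip <- paste("degenerate index distribution:", conditionMessage(std))
    } else if (any(vapply(std[c("Z_P", "Z_A", "Z_S")],
                          function(x) stats::sd(x) == 0, TRUE)) ||
               stats::sd(modeled$Perf) == 0) {
      skip <- "degenerate (constant) index or performance distribution"
    }
  }
  if (is.null(skip)) {
    report$standardized <- std
    report$diagnostics <- association_diagnostics(std)
    fits <- list(
      gamma_log = fit_glm(Perf ~ Z_P + Z_A + Z_S, std, family = "gamma_log"),
      normal_identity = fit_glm(Perf ~ Z_P + Z_A + Z_S, std,
                                family = "normal_identity")
    )
    report$models <- lapply(fits, function(f) list(
      coefficients = wald_inference(f),
      metrics = model_metrics(f),
      by_day = daywise_metrics(f, std),
      loso = loso_cv(Perf ~ Z_P + Z_A + Z_S, std, family = f$family),
      residuals = residual_outlier_summary(f)
    ))
    if (cfg$run_sensitivity)
      report$sensitivity <- sensitivity_suite(std)$table
    report$summary_by_group <- summarize_by_group(std)
  } else {
    message("modelling stage skipped: ", skip)
    report$skipped_reason <- skip
    report$summary_by_group <- summarize_by_group(day_indices)
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Median and IQR summaries per day and group
#'
#' Type-7 (linear interpolation) quantiles of performance and the
#' standardized indices for each day-by-group cell.
#'
#' @param day_indices data frame with `day`, `group` and any of `Perf`,
#'   `Z_S`, `Z_P`, `Z_A`.
#' @export
summarize_by_group <- function(day_indices) {
  metrics <- intersect(c("Perf", "Z_S", "Z_P", "Z_A"), names(day_indices))
  cells <- expand.grid(day = sort(unique(day_indices$day)),
                       group = sort(unique(day_indices$group)),
                       metric = metrics, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    x <- day_indices[day_indices$day == cells$day[i] &
                       day_indices$group == cells$group[i], cells$metric[i]]
    x <- x[is.finite(x)]
    q <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                        names = FALSE) else rep(NA_real_, 3)
    data.frame(day = cells$day[i], group = cells$group[i],
               metric = cells$metric[i], median = q[2], q25 = q[1],
               q75 = q[3], n = length(x), stringsAsFactors = FALSE)
  }))
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$day_indices,
                   file.path(out_dir, "day_indices.csv"), row.names = FALSE)
  if (!is.null(report$standardized))
    utils::write.csv(report$standardized,
                     file.path(out_dir, "day_indices_standardized.csv"),
                     row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary_by_group,
                   file.path(out_dir, "summary_by_group.csv"),
                   row.names = FALSE)
  if (!is.null(report$models)) {
    utils::write.csv(report$models$gamma_log$coefficients,
                     file.path(out_dir, "gamma_log_coefficients.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      met <- lapply(report$models, function(m)
        c(m$metrics, loso = m$loso[c("R2", "RMSE", "MAE")]))
      jsonlite::write_json(met, file.path(out_dir, "model_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out_dir)
}
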