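# Generative twin of the day-level performance model: Gamma response with a
# log link on the standardized skill indices.

#' Configuration for the Gamma performance generator
#'
#' @param beta coefficient vector `(intercept, beta_P, beta_A, beta_S)` on
#'   the log-mean scale. Defaults are the fitted coefficients of the
#'   three-index Gamma-Log model.
#' @param dispersion Gamma dispersion `phi > 0`; response variance is
#'   `phi * mu^2`.
#' @param seed integer seed.
#' @export
perf_gen_config <- function(beta = c(intercept = 2.5563, Z_P = 0.4073,
                                     Z_A = 0.1669, Z_S = 0.5279),
                            dispersion = 0.5, seed = 1L) {
  stopifnot_scalar(dispersion, "dispersion", positive = TRUE)
  if (length(beta) != 4) stop("beta must have length 4", call. = FALSE)
  structure(list(beta = beta, dispersion = dispersion, seed = seed),
            class = "perf_gen_config")
}

#' Draw day-level performance from the Gamma-Log generative model
#'
#' `Perf ~ Gamma(mu, phi)` with
#' `log(mu) = beta0 + beta_P Z_P + beta_A Z_A + beta_S Z_S`, parameterized
#' as shape `1/phi` and scale `mu * phi` so that `E[Perf] = mu` and
#' `Var[Perf] = phi * mu^2`.
#'
#' @param indices data frame with columns `Z_P`, `Z_A`, `Z_S` (standardized
#'   indices).
#' @param cfg a [perf_gen_config()].
#' @return `indices` with columns `mu` (true mean) and `Perf` appended.
#' @export
generate_performance <- function(indices, cfg = perf_gen_config()) {
  stopifnot(inherits(cfg, "perf_gen_config"))
  need <- c("Z_P", "Z_A", "Z_S")
  if (!all(need %in% names(indices)))
    stop("indices must contain Z_P, Z_A, Z_S", call. = FALSE)
  if (!all(is.finite(as.matrix(indices[need]))))
    stop("standardized indices must be finite", call. = FALSE)
  eta <- cfg$beta[1] + cfg$beta[2] * indices$Z_P +
    cfg$beta[3] * indices$Z_A + cfg$beta[4] * indices$Z_S
  mu <- exp(eta)
  phi <- cfg$dispersion
  with_seed(cfg$seed, {
    perf <- stats::rgamma(length(mu), shape = 1 / phi, scale = mu * phi)
  })
  indices$mu <- mu
  indices$Perf <- perf
  indices
}

#' Draw standardized skill indices with a realistic correlation structure
#'
#' Samples `(Z_P, Z_A, Z_S)` from a zero-mean trivariate Gaussian whose
#' correlations default to the observed pairwise index correlations
#' (r_PA = 0.579, r_PS = 0.329, r_AS = 0.185), then applies the robust
#' z-transform so the columns have median 0 and unit robust scale.
#'
#' @param n number of participant-day rows.
#' @param corr 3x3 correlation matrix in order (P, A, S).
#' @param seed integer seed.
#' @export
simulate_indices <- function(n, corr = index_corr_default(), seed = 1L) {
  with_seed(seed, {
    z <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = corr)
  })
  out <- data.frame(Z_P = z[, 1], Z_A = z[, 2], Z_S = z[, 3])
  for (j in names(out)) out[[j]] <- as.numeric(robust_z(out[[j]]))
  out
}

index_corr_default <- function() {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.579
  m[1, 3] <- m[3, 1] <- 0.329
  m[2, 3] <- m[3, 2] <- 0.185
  m
}
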