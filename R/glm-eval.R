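# Inference tables, fit metrics, day-wise evaluation, cross-validation and
# the sensitivity-model suite for the performance GLMs.

#' Wald inference table from coefficients and standard errors
#'
#' `z = beta / SE`, two-sided normal p-values, 95% CI as
#' `beta +/- 1.96 SE`, and multiplicative effects `exp(beta)` for log-link
#' models.
#'
#' @param beta,se named coefficient and standard-error vectors.
#' @param exp_beta whether to report `exp(beta)`.
#' @return data frame with columns `term`, `beta`, `se`, `z`, `p`,
#'   `ci_lo`, `ci_hi` (and `exp_beta`).
#' @export
wald_table <- function(beta, se, exp_beta = TRUE) {
  z <- beta / se
  out <- data.frame(
    term = names(beta) %||% paste0("b", seq_along(beta) - 1),
    beta = as.numeric(beta), se = as.numeric(se), z = as.numeric(z),
    p = 2 * stats::pnorm(-abs(as.numeric(z))),
    ci_lo = as.numeric(beta - 1.96 * se),
    ci_hi = as.numeric(beta + 1.96 * se),
    stringsAsFactors = FALSE
  )
  if (exp_beta) out$exp_beta <- exp(out$beta)
  rownames(out) <- NULL
  out
}

#' Wald inference for a fitted GLM
#'
#' @param fit a converged `glm_fit`.
#' @export
wald_inference <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"), fit$converged)
  wald_table(fit$beta, fit$se, exp_beta = fit$family == "gamma_log")
}

#' Akaike information criterion from a log-likelihood
#'
#' `AIC = -2 logLik + 2k`, where `k` counts the regression coefficients
#' (dispersion profiled out).
#' @param loglik log-likelihood at the ML dispersion.
#' @param k number of regression coefficients.
#' @export
aic_value <- function(loglik, k) -2 * loglik + 2 * k

#' In-sample fit metrics for a GLM
#'
#' Likelihood-based criteria (log-likelihood, AIC with `k` = number of
#' regression coefficients, Cox-Snell pseudo-R2 against the intercept-only
#' fit of the same family) plus response-scale R2, RMSE and MAE.
#'
#' @param fit a converged `glm_fit`.
#' @return list with `loglik`, `aic`, `pseudo_R2_cs`, `R2`, `RMSE`, `MAE`.
#' @export
model_metrics <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"), fit$converged)
  y <- fit$y; mu <- fit$fitted
  null_fit <- fit_glm(y ~ 1, data.frame(y = y), family = fit$family)
  cs <- 1 - exp((2 / fit$n) * (null_fit$loglik - fit$loglik))
  sse <- sum((y - mu)^2); sst <- sum((y - mean(y))^2)
  list(
    loglik = fit$loglik,
    aic = aic_value(fit$loglik, fit$k),
    pseudo_R2_cs = cs,
    R2 = 1 - sse / sst,
    RMSE = sqrt(mean((y - mu)^2)),
    MAE = mean(abs(y - mu))
  )
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject the model is refitted on all other subjects and the
#' held-out rows are predicted; held-out predictions are pooled and scored
#' on the response scale, with the total sum of squares taken about the
#' pooled observed mean.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param family GLM family (see [fit_glm()]).
#' @param subject name of the subject-identifier column.
#' @return list with `R2`, `RMSE`, `MAE`, `n_folds`, `dropped_folds`.
#' @export
loso_cv <- function(formula, data, family = "gamma_log",
                    subject = "participant") {
  ids <- unique(data[[subject]])
  if (length(ids) < 3)
    stop("LOSO-CV needs at least 3 subjects", call. = FALSE)
  obs <- numeric(); pred <- numeric(); dropped <- character()
  for (id in ids) {
    train <- data[data[[subject]] != id, , drop = FALSE]
    test <- data[data[[subject]] == id, , drop = FALSE]
    fit <- tryCatch(fit_glm(formula, train, family = family),
                    error = function(e) NULL)
    if (is.null(fit)) {
      dropped <- c(dropped, as.character(id))
      warning(sprintf("LOSO fold for subject %s did not converge; dropped", id),
              call. = FALSE)
      next
    }
    p <- predict(fit, test)
    yv <- stats::model.response(stats::model.frame(formula, test))
    ok <- is.finite(p) & is.finite(yv)
    obs <- c(obs, yv[ok]); pred <- c(pred, p[ok])
  }
  sse <- sum((obs - pred)^2); sst <- sum((obs - mean(obs))^2)
  list(R2 = 1 - sse / sst, RMSE = sqrt(mean((obs - pred)^2)),
       MAE = mean(abs(obs - pred)),
       n_folds = length(ids) - length(dropped), dropped_folds = dropped)
}

#' Day-wise fit metrics
#'
#' R2 and RMSE within each day's rows using the pooled fit's predictions.
#' Negative within-day R2 (the pooled fit explaining less than the within-
#' day mean) is reported as 0.000 and flagged.
#'
#' @param fit a converged `glm_fit`.
#' @param data the data the fit was estimated on.
#' @param day name of the day column.
#' @export
daywise_metrics <- function(fit, data, day = "day") {
  mf <- stats::model.frame(fit$terms, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  mu <- predict(fit, data)
  ok <- is.finite(y) & is.finite(mu)
  y <- y[ok]; mu <- mu[ok]; days <- data[[day]][ok]
  do.call(rbind, lapply(sort(unique(days)), function(d) {
    i <- days == d
    sse <- sum((y[i] - mu[i])^2); sst <- sum((y[i] - mean(y[i]))^2)
    r2 <- if (sst == 0) -Inf else 1 - sse / sst
    data.frame(day = d, R2 = max(r2, 0), RMSE = sqrt(mean((y[i] - mu[i])^2)),
               n = sum(i), floored = r2 < 0)
  }))
}

#' Residual summary inside the non-outlier performance range
#'
#' Upper-tail outliers are defined on the observed response as
#' `y > median(y) + 3 * 1.4826 * MAD(y)`; the median residual and median
#' absolute residual are reported over the remaining rows.
#'
#' @param fit a converged `glm_fit`.
#' @return list with `cutoff`, `median_residual`, `median_abs_residual`,
#'   `n_excluded`.
#' @export
residual_outlier_summary <- function(fit) {
  y <- fit$y
  med <- stats::median(y)
  cutoff <- med + 3 * 1.4826 * stats::median(abs(y - med))
  keep <- y <= cutoff
  res <- (y - fit$fitted)[keep]
  list(cutoff = cutoff, median_residual = stats::median(res),
       median_abs_residual = stats::median(abs(res)),
       n_excluded = sum(!keep))
}

#' Sensitivity-model suite for the performance GLM
#'
#' Fits the extensions of the base three-index model: pairwise skill
#' interactions, Group and Day fixed effects (treatment coding, reference
#' Normal-g and Day 1), and participant fixed intercepts; optionally a
#' median-imputed full-dataset refit (missing `Z_S` set to the standardized
#' median, 0).
#'
#' @param data data frame with columns `Perf`, `Z_P`, `Z_A`, `Z_S`,
#'   `group`, `day`, `participant`.
#' @param full_data optional unfiltered data frame (may contain missing
#'   `Z_S`) for the imputation row.
#' @param family GLM family.
#' @return list with `table` (model, k, aic, R2, RMSE per design) and
#'   `fits`.
#' @export
sensitivity_suite <- function(data, full_data = NULL, family = "gamma_log") {
  data$group <- stats::relevel(factor(data$group), ref = "Normal-g")
  data$day <- stats::relevel(factor(data$day), ref = sort(unique(as.character(data$day)))[1])
  data$participant <- factor(data$participant)
  base <- Perf ~ Z_P + Z_A + Z_S
  inter <- Perf ~ Z_P + Z_A + Z_S + Z_P:Z_A + Z_P:Z_S + Z_A:Z_S
  gd <- stats::update(inter, . ~ . + group + day)
  subj <- stats::update(gd, . ~ . + participant)
  designs <- list(base = base, interactions = inter,
                  interactions_group_day = gd,
                  interactions_group_day_subject = subj)
  fits <- list()
  rows <- list()
  for (nm in names(designs)) {
    fit <- tryCatch(fit_glm(designs[[nm]], data, family = family,
                            drop_aliased = TRUE),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[nm]] <- data.frame(model = nm, k = NA, aic = NA, R2 = NA,
                               RMSE = NA, note = conditionMessage(fit))
      next
    }
    m <- model_metrics(fit)
    fits[[nm]] <- fit
    note <- if (length(fit$aliased))
      paste("aliased columns dropped:",
            paste(fit$aliased, collapse = ", ")) else ""
    rows[[nm]] <- data.frame(model = nm, k = fit$k, aic = m$aic, R2 = m$R2,
                             RMSE = m$RMSE, note = note)
  }
  if (!is.null(full_data)) {
    fd <- full_data
    fd$Z_S[!is.finite(fd$Z_S)] <- 0
    fit <- fit_glm(base, fd, family = family)
    m <- model_metrics(fit)
    fits[["base_imputed_full"]] <- fit
    rows[["base_imputed_full"]] <- data.frame(
      model = "base_imputed_full", k = fit$k, aic = m$aic, R2 = m$R2,
      RMSE = m$RMSE, note = "missing Z_S imputed to 0")
  }
  list(table = do.call(rbind, rows), fits = fits)
}
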