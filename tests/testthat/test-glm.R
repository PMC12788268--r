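make_gamma_fixture <- function(n = 30, seed = 1, phi = 0.4,
                               beta = c(1.5, 0.6, -0.3)) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  mu <- exp(beta[1] + beta[2] * x1 + beta[3] * x2)
  data.frame(y = rgamma(n, shape = 1 / phi, scale = mu * phi),
             x1 = x1, x2 = x2)
}

test_that("intercept-only Gamma fit returns log of the mean", {
  d <- make_gamma_fixture(40, seed = 2)
  fit <- fit_glm(y ~ 1, d, family = "gamma_log")
  expect_equal(unname(fit$beta), log(mean(d$y)), tolerance = 1e-9)
})

test_that("IRLS Gamma fit matches direct likelihood maximization", {
  for (seed in 1:3) {
    d <- make_gamma_fixture(30, seed = seed)
    fit <- fit_glm(y ~ x1 + x2, d, family = "gamma_log")
    # independent oracle: maximize the Gamma log-likelihood numerically
    # over (beta, log alpha) with a generic optimizer
    X <- cbind(1, d$x1, d$x2)
    nll <- function(par) {
      mu <- exp(drop(X %*% par[1:3])); a <- exp(par[4])
      -sum(dgamma(d$y, shape = a, scale = mu / a, log = TRUE))
    }
    opt <- optim(c(fit$beta + 0.05, 0), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(max(abs(fit$beta - opt$par[1:3])), 1e-6)
    expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
  }
})

test_that("Normal-Identity fit reproduces closed-form least squares", {
  d <- make_gamma_fixture(25, seed = 4)
  fit <- fit_glm(y ~ x1 + x2, d, family = "normal_identity")
  X <- cbind(1, d$x1, d$x2)
  beta_ols <- drop(solve(crossprod(X), crossprod(X, d$y)))
  expect_equal(unname(fit$beta), beta_ols, tolerance = 1e-12)
  # dispersion = SSE/(n-k), classic OLS variance
  expect_equal(fit$dispersion,
               sum((d$y - X %*% beta_ols)^2) / (nrow(d) - 3), tolerance = 1e-12)
})

test_that("Gamma-Log predictions are strictly positive", {
  d <- make_gamma_fixture(30, seed = 5)
  fit <- fit_glm(y ~ x1 + x2, d, family = "gamma_log")
  far <- data.frame(x1 = c(-50, 50), x2 = c(50, -50))
  expect_true(all(predict(fit, far) > 0))
})

test_that("fit errors distinguish bad responses and rank deficiency", {
  d <- make_gamma_fixture(20, seed = 6)
  d$y[1] <- -1
  expect_error(fit_glm(y ~ x1, d, family = "gamma_log"), "positive")
  d2 <- make_gamma_fixture(20, seed = 7)
  d2$x3 <- d2$x1
  expect_error(fit_glm(y ~ x1 + x3, d2), "rank deficient")
})

test_that("Wald arithmetic: zero coefficient gives unit effect and symmetric CI", {
  tab <- wald_table(c(a = 0, b = 0.5), c(a = 0.2, b = 0.1))
  expect_equal(tab$exp_beta[1], 1)
  expect_equal(tab$ci_lo[1], -tab$ci_hi[1])
  expect_equal(tab$ci_hi[2], 0.5 + 1.96 * 0.1)
  expect_equal(tab$p[1], 1)
})

test_that("model metrics behave at the boundaries", {
  d <- make_gamma_fixture(40, seed = 8)
  fit <- fit_glm(y ~ x1 + x2, d, family = "gamma_log")
  m <- model_metrics(fit)
  expect_equal(m$aic, -2 * fit$loglik + 2 * 3)
  expect_gte(m$RMSE, m$MAE)
  # intercept-only model: Cox-Snell exactly zero
  fit0 <- fit_glm(y ~ 1, d, family = "gamma_log")
  expect_equal(model_metrics(fit0)$pseudo_R2_cs, 0, tolerance = 1e-8)
  expect_lt(abs(model_metrics(fit0)$R2), 1e-10)
})

test_that("LOSO-CV generalizes when signal is strong and fails under the null", {
  # near-noiseless: held-out R2 close to 1
  z <- simulate_indices(57, seed = 31)
  d <- generate_performance(z, perf_gen_config(dispersion = 1e-4, seed = 32))
  d$participant <- rep(1:19, each = 3)
  cv <- loso_cv(Perf ~ Z_P + Z_A + Z_S, d)
  expect_gte(cv$R2, 0.95)

  # null: response independent of predictors -> non-positive mean R2
  r2s <- vapply(1:20, function(i) {
    zi <- simulate_indices(57, seed = 100 + i)
    set.seed(200 + i)
    zi$Perf <- rgamma(57, shape = 2, scale = 5)
    zi$participant <- rep(1:19, each = 3)
    loso_cv(Perf ~ Z_P + Z_A + Z_S, zi)$R2
  }, 0)
  expect_lte(mean(r2s), 0)

  two <- data.frame(Perf = rgamma(6, 2), Z_P = rnorm(6), Z_A = rnorm(6),
                    Z_S = rnorm(6), participant = rep(1:2, 3))
  expect_error(loso_cv(Perf ~ Z_P + Z_A + Z_S, two), "at least 3")
})

test_that("day-wise metrics floor negative R2 at zero and flag it", {
  z <- simulate_indices(60, seed = 41)
  d <- generate_performance(z, perf_gen_config(seed = 42))
  d$day <- rep(c(1, 5, 10), 20)
  fit <- fit_glm(Perf ~ Z_P + Z_A + Z_S, d, family = "gamma_log")
  by_day <- daywise_metrics(fit, d)
  expect_equal(nrow(by_day), 3)
  expect_true(all(by_day$R2 >= 0))
  # constant observed response in a day -> R2 reported 0 and flagged
  d2 <- d
  d2$Perf[d2$day == 1] <- 5
  fit2 <- fit_glm(Perf ~ Z_P + Z_A + Z_S, d2, family = "gamma_log")
  bd2 <- daywise_metrics(fit2, d2)
  expect_equal(bd2$R2[bd2$day == 1], 0)
  expect_true(bd2$floored[bd2$day == 1])
})

test_that("residual summary excludes MAD-based upper-tail outliers", {
  d <- data.frame(y = 1:10, x = rnorm(10))
  fit <- fit_glm(y ~ 1, d, family = "normal_identity")
  rs <- residual_outlier_summary(fit)
  expect_equal(rs$cutoff, 5.5 + 3 * 1.4826 * 2.5)
  expect_equal(rs$n_excluded, 0)

  set.seed(9)
  d2 <- data.frame(y = c(rgamma(30, 4, 1), 1000))
  fit2 <- fit_glm(y ~ 1, d2, family = "gamma_log")
  expect_equal(residual_outlier_summary(fit2)$n_excluded, 1)
})

test_that("sensitivity suite fits the extended designs", {
  z <- simulate_indices(57, seed = 51)
  d <- generate_performance(z, perf_gen_config(seed = 52))
  d$participant <- rep(1:19, each = 3)
  d$day <- rep(c(1, 5, 10), 19)
  d$group <- ifelse(d$participant <= 10, "Low-g", "Normal-g")
  full <- rbind(d, transform(d[1:3, ], Z_S = NA, participant = 20))
  out <- sensitivity_suite(d, full_data = full)
  expect_setequal(out$table$model,
                  c("base", "interactions", "interactions_group_day",
                    "interactions_group_day_subject", "base_imputed_full"))
  expect_equal(out$table$k[out$table$model == "base"], 4)
  expect_equal(out$table$k[out$table$model == "interactions"], 7)
  expect_true(all(is.finite(out$table$aic)))
  # participant intercepts absorb participant-level heterogeneity
  d3 <- d
  set.seed(60)
  offs <- rnorm(19, sd = 0.8)[d3$participant]
  d3$Perf <- d3$Perf * exp(offs)
  out3 <- sensitivity_suite(d3)
  aics <- out3$table
  expect_lt(aics$aic[aics$model == "interactions_group_day_subject"],
            aics$aic[aics$model == "base"])
})

test_that("interaction-free truth keeps interaction CIs covering zero", {
  covered <- 0L; total <- 0L
  for (i in 1:60) {
    z <- simulate_indices(57, seed = 300 + i)
    d <- generate_performance(z, perf_gen_config(seed = 400 + i))
    fit <- fit_glm(Perf ~ Z_P + Z_A + Z_S + Z_P:Z_S, d, family = "gamma_log")
    tab <- wald_inference(fit)
    row <- tab[tab$term == "Z_P:Z_S", ]
    covered <- covered + (row$ci_lo <= 0 && row$ci_hi >= 0)
    total <- total + 1L
  }
  expect_gte(covered / total, 0.8)
})
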