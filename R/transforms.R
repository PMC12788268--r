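# Day-level performance metric and the monotone + robust-z preprocessing
# of the three skill indices, plus association diagnostics.

#' Day-level performance from per-trial catch counts
#'
#' Mean successful-catch count over the ten best trials pooled across the
#' day's real-world sessions. Days with fewer than ten trials fall back to
#' the mean of all trials.
#'
#' @param trial_catch_counts integer vector of per-trial successful-catch
#'   counts.
#' @return the performance value, or `NA` for an empty day.
#' @export
perf_metric <- function(trial_catch_counts) {
  x <- trial_catch_counts[is.finite(trial_catch_counts)]
  if (!length(x)) return(NA_real_)
  top <- sort(x, decreasing = TRUE)[seq_len(min(10L, length(x)))]
  mean(top)
}

#' Logit transform for the Prediction index
#'
#' Clips to `[eps, 1 - eps]` (default `eps = 1e-4`) before the logit, so
#' boundary values stay finite.
#'
#' @param p values in `[0, 1]`.
#' @param eps clipping constant.
#' @export
logit_transform <- function(p, eps = 1e-4) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("Prediction values must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Negative log transform for the Accuracy index
#'
#' Larger transformed values correspond to tighter catch clustering.
#'
#' @param a positive ellipsoid-volume geometric means.
#' @export
neglog_transform <- function(a) {
  if (any(a <= 0, na.rm = TRUE))
    stop("Accuracy values must be > 0", call. = FALSE)
  -log(a)
}

#' Robust z-score via median and MAD
#'
#' `z = (x - median(x)) / (1.4826 * MAD(x))`, where
#' `MAD = median(|x - median(x)|)` and 1.4826 is the Gaussian consistency
#' constant. When the MAD is zero the standard deviation is used instead
#' and the result carries attribute `degenerate_scale = TRUE`.
#'
#' @param x numeric vector (missing values propagated, ignored for the
#'   location/scale estimates).
#' @export
robust_z <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("need at least 2 finite values", call. = FALSE)
  med <- stats::median(x[ok])
  mad_raw <- stats::median(abs(x[ok] - med))
  if (mad_raw > 0) {
    z <- (x - med) / (1.4826 * mad_raw)
  } else {
    s <- stats::sd(x[ok])
    if (s == 0) stop("degenerate scale: all values identical", call. = FALSE)
    z <- (x - med) / s
    attr(z, "degenerate_scale") <- TRUE
  }
  z
}

#' Transform and standardize a merged day-level index table
#'
#' Applies the monotone transforms (logit for P, negative log for A, S
#' unchanged) and the robust z-transform, pooling the location/scale
#' estimates over all modelled rows.
#'
#' @param d data frame with columns `P`, `A`, `S` (missing entries allowed;
#'   they stay missing).
#' @return `d` with `P_t`, `A_t`, `S_t`, `Z_P`, `Z_A`, `Z_S` appended, and
#'   the pooled medians/MADs in attribute `scaling` (so the transform is
#'   reproducible and invertible).
#' @export
standardize_indices <- function(d) {
  d$P_t <- logit_transform(d$P)
  d$A_t <- neglog_transform(d$A)
  d$S_t <- d$S
  scaling <- list(eps = 1e-4)
  for (nm in c("P", "A", "S")) {
    x <- d[[paste0(nm, "_t")]]
    z <- robust_z(x)
    d[[paste0("Z_", nm)]] <- as.numeric(z)
    ok <- is.finite(x)
    med <- stats::median(x[ok])
    scaling[[nm]] <- list(median = med,
                          mad = stats::median(abs(x[ok] - med)))
  }
  attr(d, "scaling") <- scaling
  d
}

#' Pairwise correlations and variance inflation factors
#'
#' Pearson correlations (with p-values) among the standardized indices and
#' VIFs from ordinary least squares of each predictor on the other two
#' (`VIF_j = 1 / (1 - R2_j)`).
#'
#' @param z data frame with columns `Z_P`, `Z_A`, `Z_S` (complete rows
#'   used).
#' @return list with `correlations` (data frame pair/r/p) and `vif` (named
#'   vector).
#' @export
association_diagnostics <- function(z) {
  need <- c("Z_P", "Z_A", "Z_S")
  z <- z[stats::complete.cases(z[need]), need]
  if (any(vapply(z, stats::sd, 0) == 0))
    stop("constant predictor column: correlations undefined", call. = FALSE)
  pairs <- utils::combn(need, 2)
  cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ct <- stats::cor.test(z[[pairs[1, i]]], z[[pairs[2, i]]])
    data.frame(pair = paste(pairs[1, i], pairs[2, i], sep = "-"),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  vif <- vapply(need, function(j) {
    # a perfectly collinear predictor triggers lm's perfect-fit warning;
    # that case is reported as an infinite VIF below
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(setdiff(need, j), j),
                        data = z))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  list(correlations = cors, vif = vif)
}
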