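#' Error metrics of a prediction set
#'
#' Mean bias error, absolute mean bias error, root mean square error,
#' NMAD of the residuals (1.4826 times their median absolute deviation),
#' signed and absolute mean percent errors, and the Nash-Sutcliffe model
#' efficiency. The efficiency defaults to the standard form
#' `eta = 1 - sum((pred - act)^2) / sum((act - mean(act))^2)` (1 for a
#' perfect prediction); `eta_as_printed = TRUE` replaces the denominator
#' deviations with `pred - mean(act)`.
#'
#' @param pred,act numeric vectors of equal nonzero length; `act` must be
#'   nonzero for the percent errors.
#' @param eta_as_printed use the predicted-value denominator variant.
#' @return List of class `error_report`: `mbe`, `ambe`, `rmse`,
#'   `nmad_resid` (kg/ha scale), `re_pct`, `ae_pct`, `eta`.
#' @export
error_metrics <- function(pred, act, eta_as_printed = FALSE) {
  n <- length(pred)
  if (n == 0L || length(act) != n) stop("pred and act must have equal nonzero length")
  if (any(act == 0)) stop("numeric-domain error: zero actual value")
  r <- pred - act
  den <- if (eta_as_printed) sum((pred - mean(act))^2) else sum((act - mean(act))^2)
  eta <- if (den == 0 && sum(r^2) == 0) 1 else 1 - sum(r^2) / den
  structure(list(mbe = mean(r), ambe = mean(abs(r)), rmse = sqrt(mean(r^2)),
                 nmad_resid = 1.4826 * stats::median(abs(r - stats::median(r))),
                 re_pct = 100 * mean(r / act), ae_pct = 100 * mean(abs(r / act)),
                 eta = eta),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> MBE %.2f AMBE %.2f RMSE %.2f NMAD %.2f | RE %.2f%% AE %.2f%% | eta %.3f\n",
              x$mbe, x$ambe, x$rmse, x$nmad_resid, x$re_pct, x$ae_pct, x$eta))
  invisible(x)
}

#' Robust linear fit with bisquare weighting
#'
#' Fits `y = a x + b` by iteratively reweighted least squares with Tukey
#' bisquare weights (tuning constant 4.685, scale re-estimated each
#' iteration as the NMAD of the residuals), at most `max_iter` iterations or
#' until the coefficients change by less than `tol`. Studentized residuals,
#' outlier flags at the two-tailed t threshold, and the R-squared on the
#' non-outlier set are attached via [studentized_outliers()].
#'
#' @param x,y measured and predicted values (length >= 3).
#' @param c_tukey bisquare tuning constant.
#' @param max_iter,tol IRLS controls.
#' @param alpha significance level for outlier flagging.
#' @return List of class `robust_fit`: `a` (slope), `b` (intercept), `r2`,
#'   `residuals`, `sr` (studentized residuals), `outliers` (logical),
#'   `max_abs_sr`, `threshold`, `rmse`, `nmad`, `n_iter`.
#' @export
robust_linear_fit <- function(x, y, c_tukey = 4.685, max_iter = 50L,
                              tol = 1e-8, alpha = 0.05) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 paired points")
  if (stats::sd(x) == 0) stop("fit error: degenerate x (zero variance)")
  X <- cbind(1, x)
  beta <- stats::coef(stats::lm.fit(X, y))
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- 1.4826 * stats::median(abs(r - stats::median(r)))
    if (s == 0) break
    u <- as.numeric(r) / (c_tukey * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2L) break
    new <- stats::coef(stats::lm.wfit(X, y, w))
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  r <- as.numeric(y - X %*% beta)
  fit <- structure(list(a = unname(beta[2]), b = unname(beta[1]),
                        x = x, y = y, residuals = r, n_iter = it),
                   class = "robust_fit")
  so <- studentized_outliers(fit, alpha = alpha)
  keep <- !so$outliers
  ybar <- mean(y[keep])
  fit$r2 <- 1 - sum(r[keep]^2) / sum((y[keep] - ybar)^2)
  fit$sr <- so$sr
  fit$outliers <- so$outliers
  fit$max_abs_sr <- max(abs(so$sr))
  fit$threshold <- so$threshold
  fit$rmse <- sqrt(mean(r[keep]^2))
  fit$nmad <- 1.4826 * stats::median(abs(r[keep] - stats::median(r[keep])))
  fit
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> y = %.4f x + %.4f, R2 %.4f, %d outlier(s), max |sr| %.3f\n",
              x$a, x$b, x$r2, sum(x$outliers), x$max_abs_sr))
  invisible(x)
}

#' Studentized residuals and outlier flags
#'
#' Externally studentized residuals of a straight-line fit:
#' `sr_i = r_i / sqrt(MS_Res(-i) * (1 - h_ii))`, with the mean squared
#' residual recomputed leaving observation i out and `h_ii` the hat-matrix
#' leverage. Observations whose `|sr|` exceeds the two-tailed t quantile
#' with `n - p - 1` degrees of freedom are flagged.
#'
#' @param fit a `robust_fit` (or any list with `x` and `residuals`).
#' @param alpha two-tailed significance level.
#' @return List `sr`, `outliers` (logical), `threshold`, `df`.
#' @export
studentized_outliers <- function(fit, alpha = 0.05) {
  x <- as.numeric(fit$x)
  r <- as.numeric(fit$residuals)
  n <- length(r)
  p <- 2L
  if (n <= p + 1L) stop("degrees-of-freedom error: need n > p + 1")
  X <- cbind(1, x)
  h <- rowSums((X %*% solve(crossprod(X))) * X)
  sse <- sum(r^2)
  ms_loo <- (sse - r^2 / (1 - h)) / (n - p - 1L)
  ms_loo <- pmax(ms_loo, .Machine$double.eps)
  sr <- r / sqrt(ms_loo * (1 - h))
  thr <- stats::qt(1 - alpha / 2, df = n - p - 1L)
  list(sr = sr, outliers = abs(sr) > thr, threshold = thr, df = n - p - 1L)
}

#' Robust Jarque-Bera normality test
#'
#' The robust variant of the Jarque-Bera statistic with MAD-based scale:
#' skewness and kurtosis moment ratios are computed with the robust scale
#' `J = sqrt(pi / 2) * mean(|x - median(x)|)` in place of the sample SD,
#' `RJB = n / C1 * (m3 / J^3)^2 + n / C2 * (m4 / J^4 - 3)^2` with `C1 = 6`,
#' `C2 = 64`, and compared to the chi-squared(2) critical value.
#'
#' @param values numeric sample, length >= 10.
#' @param alpha significance level.
#' @return List `statistic`, `p_value`, `critical`, `reject`.
#' @export
robust_jarque_bera <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 10L) stop("sample-size error: need n >= 10")
  J <- sqrt(pi / 2) * mean(abs(values - stats::median(values)))
  if (J == 0) stop("degenerate sample: zero robust scale")
  xc <- values - mean(values)
  m3 <- mean(xc^3); m4 <- mean(xc^4)
  stat <- n / 6 * (m3 / J^3)^2 + n / 64 * (m4 / J^4 - 3)^2
  crit <- stats::qchisq(1 - alpha, df = 2)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       critical = crit, reject = stat > crit)
}

#' Absolute errors grouped by family
#'
#' Mean per-plot absolute percent error of the test predictions grouped by
#' family, restricted to families represented by `min_n` to `max_n` test
#' plots, sorted ascending (best-predicted families first).
#'
#' @param ae_per_plot per-plot absolute errors (percent), test set.
#' @param family_labels family label per test plot.
#' @param min_n,max_n family-size window.
#' @return data.frame `family`, `n`, `mean_ae_pct`, sorted by `mean_ae_pct`.
#' @export
family_errors <- function(ae_per_plot, family_labels, min_n = 4L, max_n = 6L) {
  stopifnot(length(ae_per_plot) == length(family_labels))
  agg <- stats::aggregate(list(mean_ae_pct = ae_per_plot),
                          by = list(family = family_labels), FUN = mean)
  cnt <- table(family_labels)
  agg$n <- as.integer(cnt[agg$family])
  agg <- agg[agg$n >= min_n & agg$n <= max_n, c("family", "n", "mean_ae_pct")]
  agg <- agg[order(agg$mean_ae_pct), ]
  rownames(agg) <- NULL
  agg
}

#' Evaluation report for a fitted model
#'
#' Bundles the full assessment of one `fit_result`: train/test error metrics,
#' the bisquare robust fit of predicted on measured yield with studentized
#' outliers, and the family-grouped test errors.
#'
#' @param fit a `fit_result` from [fit_model()].
#' @param eta_as_printed passed to [error_metrics()].
#' @return List `metrics` (data.frame, rows train/test), `robust_fits`
#'   (list train/test), `family_errors` (data.frame).
#' @export
evaluate_model <- function(fit, eta_as_printed = FALSE) {
  pr <- fit$predictions
  metrics <- do.call(rbind, lapply(c("train", "test"), function(s) {
    i <- pr$split == s
    em <- error_metrics(pr$predicted[i], pr$actual[i],
                        eta_as_printed = eta_as_printed)
    cbind(data.frame(dataset = s, stringsAsFactors = FALSE),
          as.data.frame(unclass(em)))
  }))
  fits <- lapply(c(train = "train", test = "test"), function(s) {
    i <- pr$split == s
    robust_linear_fit(pr$actual[i], pr$predicted[i])
  })
  te <- pr$split == "test"
  fam <- family_errors(100 * abs((pr$predicted[te] - pr$actual[te]) / pr$actual[te]),
                       pr$family[te])
  list(metrics = metrics, robust_fits = fits, family_errors = fam)
}
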