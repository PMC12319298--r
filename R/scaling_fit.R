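# Bivariate scaling estimation in log-log space: standardized major axis
# (model II) and OLS fits, slope/elevation tests, quadratic curvature,
# segmented fits and AIC model comparison. All logarithms are base 10.

new_scaling_fit <- function(method, X, Y, x_var, y_var, transform) {
  n <- length(X)
  if (n < 3L) stop_validation("need at least 3 observations, got ", n)
  sx <- stats::sd(X); sy <- stats::sd(Y)
  if (sx == 0 || sy == 0)
    stop_validation("degenerate fit: zero variance in ",
                    if (sx == 0) x_var else y_var)
  r <- stats::cor(X, Y)
  # Two-sided p for zero association (Pearson).
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  if (method == "SMA") {
    slope <- (if (r < 0) -1 else 1) * sy / sx
    intercept <- mean(Y) - slope * mean(X)
    B <- stats::qf(0.95, 1, n - 2) * (1 - r^2) / (n - 2)
    ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  } else {
    slope <- r * sy / sx
    intercept <- mean(Y) - slope * mean(X)
    se <- sy / sx * sqrt(max(0, 1 - r^2) / (n - 2))
    ci <- slope + c(-1, 1) * stats::qt(0.975, n - 2) * se
  }
  structure(list(method = method, slope = slope, intercept = intercept,
                 slope_ci = ci, r2 = r^2, p = p, n = n,
                 x_var = x_var, y_var = y_var, transform = transform,
                 X = X, Y = Y),
            class = "scaling_fit")
}

#' Standardized major axis (model II) fit
#'
#' Fits a line to (optionally log10-transformed) data by minimizing residual
#' variation in both axes: `|slope| = s_y / s_x` with the sign of the
#' correlation, the standard estimator for allometric power-law exponents.
#' The 95% CI uses the standard SMA interval
#' `slope * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = F(0.95; 1, n-2) * (1 - r^2) / (n - 2)`, and the p-value is the
#' two-sided Pearson test of zero association.
#'
#' Transform labels are `"<x>-<y>"`: e.g. `"log10-log10"` fits
#' `log10(y) ~ log10(x)` (a power law, slope = exponent, intercept =
#' log10 of the normalization), `"linear-log10"` fits `log10(y) ~ x`
#' (an exponential law).
#'
#' @param x,y Observations; must be positive on any log-transformed axis.
#' @param transform One of `"log10-log10"`, `"log10-linear"`,
#'   `"linear-log10"`, `"none"`.
#' @param x_var,y_var Variable labels carried into the result.
#' @return A `scaling_fit` object: `method`, `slope`, `intercept`,
#'   `slope_ci`, `r2`, `p`, `n`, plus the transformed data for downstream
#'   tests.
#' @examples
#' x <- seq(0.1, 10, length.out = 50)
#' sma_fit(x, 10 * x^0.25)            # slope 0.25, intercept 1, r2 = 1
#' @export
sma_fit <- function(x, y, transform = "log10-log10",
                    x_var = deparse(substitute(x)),
                    y_var = deparse(substitute(y))) {
  tr <- apply_transform(x, y, transform)
  new_scaling_fit("SMA", tr$x, tr$y, x_var, y_var, tr$transform)
}

#' Ordinary least squares fit on the same interface as [sma_fit()]
#'
#' For noisy data the OLS slope is attenuated relative to SMA by the factor
#' `|r|`; the two coincide exactly on noiseless data.
#'
#' @inheritParams sma_fit
#' @return A `scaling_fit` object with `method = "OLS"`.
#' @export
ols_fit <- function(x, y, transform = "log10-log10",
                    x_var = deparse(substitute(x)),
                    y_var = deparse(substitute(y))) {
  tr <- apply_transform(x, y, transform)
  Y <- tr$y
  if (stats::sd(Y) == 0) {
    # Constant response: slope 0 by definition; bypass the degenerate check.
    return(structure(list(method = "OLS", slope = 0, intercept = mean(Y),
                          slope_ci = c(0, 0), r2 = 0, p = 1,
                          n = length(Y), x_var = x_var, y_var = y_var,
                          transform = tr$transform, X = tr$x, Y = Y),
                     class = "scaling_fit"))
  }
  new_scaling_fit("OLS", tr$x, tr$y, x_var, y_var, tr$transform)
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s ~ %s  [%s]\n", x$method, x$y_var, x$x_var,
              x$transform))
  cat(sprintf("  slope     %.6g  (95%% CI %.6g to %.6g)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  cat(sprintf("  r2 = %.4g, p = %s, n = %d\n", x$r2, format_p(x$p), x$n))
  invisible(x)
}

#' Test an SMA slope against a hypothesized value
#'
#' Tests `slope = b0` via the correlation between the SMA residual and fitted
#' axes: under the null, `(y - b0 x)` and `(y + b0 x)` are uncorrelated.
#' Testing a fit against its own slope gives p = 1 exactly.
#'
#' @param fit A `scaling_fit` from [sma_fit()].
#' @param b0 Hypothesized slope (finite, non-zero).
#' @return Two-sided p-value.
#' @export
sma_slope_test <- function(fit, b0) {
  stopifnot(inherits(fit, "scaling_fit"))
  check_scalar(b0, "b0")
  if (b0 == 0) stop_validation("b0 must be non-zero")
  # Moment form avoids catastrophic cancellation when b0 equals the fitted
  # slope (where the residual-axis covariance is analytically zero).
  sx2 <- stats::var(fit$X); sy2 <- stats::var(fit$Y)
  sxy <- stats::cov(fit$X, fit$Y)
  cov_uv <- sy2 - b0^2 * sx2
  var_u <- sy2 + b0^2 * sx2 - 2 * b0 * sxy
  var_v <- sy2 + b0^2 * sx2 + 2 * b0 * sxy
  if (var_u <= 0 || var_v <= 0) return(1)
  r <- cov_uv / sqrt(var_u * var_v)
  if (abs(cov_uv) < 1e-12 * (sy2 + b0^2 * sx2)) r <- 0
  n <- fit$n
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

sma_slope_se <- function(fit) {
  abs(fit$slope) * sqrt(max(0, 1 - fit$r2) / (fit$n - 2))
}

check_same_transform <- function(fit_a, fit_b) {
  if (!identical(fit_a$transform, fit_b$transform))
    stop_validation("fits use incompatible transforms: ", fit_a$transform,
                    " vs ", fit_b$transform)
}

#' Compare the slopes of two SMA fits
#'
#' Wald comparison of two independently fitted SMA slopes, using the
#' large-sample slope standard error `|b| sqrt((1 - r^2)/(n - 2))`.
#' Symmetric in its arguments.
#'
#' @param fit_a,fit_b Two `scaling_fit` objects on the same transform.
#' @return Two-sided p-value.
#' @export
sma_slope_difference_test <- function(fit_a, fit_b) {
  check_same_transform(fit_a, fit_b)
  se <- sqrt(sma_slope_se(fit_a)^2 + sma_slope_se(fit_b)^2)
  if (se == 0) return(if (fit_a$slope == fit_b$slope) 1 else 0)
  z <- (fit_a$slope - fit_b$slope) / se
  2 * stats::pnorm(-abs(z))
}

#' Compare the elevations (intercepts) of two SMA fits under a common slope
#'
#' Estimates a common slope as the inverse-variance weighted mean of the two
#' SMA slopes, then Wald-tests the difference in elevations
#' `mean(Y) - b_common * mean(X)`, propagating both the residual variation
#' about the common-slope line and the uncertainty of the common slope
#' itself. Symmetric in its arguments.
#'
#' @inheritParams sma_slope_difference_test
#' @return Two-sided p-value.
#' @export
sma_elevation_test <- function(fit_a, fit_b) {
  check_same_transform(fit_a, fit_b)
  va <- sma_slope_se(fit_a)^2; vb <- sma_slope_se(fit_b)^2
  bc <- if (va == 0 && vb == 0) mean(c(fit_a$slope, fit_b$slope))
        else if (va == 0) fit_a$slope
        else if (vb == 0) fit_b$slope
        else (fit_a$slope / va + fit_b$slope / vb) / (1 / va + 1 / vb)
  var_bc <- if (va == 0 || vb == 0) 0 else 1 / (1 / va + 1 / vb)
  elev <- function(fit) mean(fit$Y) - bc * mean(fit$X)
  res_var <- function(fit) stats::var(fit$Y - bc * fit$X) / fit$n
  dx <- mean(fit_a$X) - mean(fit_b$X)
  se <- sqrt(res_var(fit_a) + res_var(fit_b) + dx^2 * var_bc)
  if (se == 0) return(if (elev(fit_a) == elev(fit_b)) 1 else 0)
  z <- (elev(fit_a) - elev(fit_b)) / se
  2 * stats::pnorm(-abs(z))
}

#' Quadratic curvature in log-log space
#'
#' OLS fit of `Y ~ X + X^2` on the transformed scale. A positive quadratic
#' coefficient indicates upward curvature (widening accelerating toward the
#' base), a negative one downward curvature; an exact power law gives zero.
#'
#' @inheritParams sma_fit
#' @return List with `coefficient` (the quadratic term), `ci` (95%),
#'   `p`, and the underlying `lm` fit.
#' @export
quadratic_curvature <- function(x, y, transform = "log10-log10") {
  tr <- apply_transform(x, y, transform)
  if (length(tr$x) < 4L) stop_validation("need at least 4 observations")
  dat <- data.frame(X = tr$x, Y = tr$y)
  fit <- stats::lm(Y ~ X + I(X^2), data = dat)
  if (any(is.na(stats::coef(fit))))
    stop_validation("degenerate fit: collinear design (too few distinct x)")
  est <- stats::coef(fit)[["I(X^2)"]]
  ci <- stats::confint(fit)["I(X^2)", ]
  p <- summary(fit)$coefficients["I(X^2)", 4]
  list(coefficient = est, ci = unname(ci), p = p, fit = fit)
}

#' Continuous two-segment (breakpoint) fit
#'
#' Fits `Y = a + b1 X + b2 max(X - c, 0)` by exhaustive grid search of the
#' breakpoint `c` over 200 interior x-quantiles (1%-99%), minimizing RSS;
#' ties break deterministically to the smaller breakpoint. Candidates with
#' fewer than 5 distinct x values on either side are excluded.
#'
#' @inheritParams sma_fit
#' @param n_breakpoints Currently only 1 is supported.
#' @return A `piecewise_fit` object: `breakpoint`, `left_slope`,
#'   `right_slope`, `intercept`, `rss`, `rss_line` (single-line RSS) and
#'   `no_meaningful_break` (TRUE when the break does not improve on a single
#'   line beyond numerical tolerance).
#' @export
piecewise_fit <- function(x, y, n_breakpoints = 1,
                          transform = "log10-log10") {
  if (n_breakpoints != 1)
    stop_validation("only a single breakpoint is supported")
  tr <- apply_transform(x, y, transform)
  X <- tr$x; Y <- tr$y
  if (length(X) < 10L) stop_validation("need at least 10 observations")
  cand <- unique(stats::quantile(X, probs = seq(0.01, 0.99,
                                                length.out = 200),
                                 names = FALSE, type = 7))
  ux <- sort(unique(X))
  ok <- vapply(cand, function(cc) sum(ux < cc) >= 5 && sum(ux > cc) >= 5,
               logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L)
    stop_validation("insufficient distinct x values for a breakpoint fit")
  rss_at <- function(cc) {
    h <- pmax(X - cc, 0)
    f <- stats::lm.fit(cbind(1, X, h), Y)
    sum(f$residuals^2)
  }
  rss <- vapply(cand, rss_at, numeric(1))
  best <- cand[which.min(rss)]   # which.min takes the first (smallest) tie
  h <- pmax(X - best, 0)
  f <- stats::lm.fit(cbind(1, X, h), Y)
  co <- f$coefficients
  line <- stats::lm.fit(cbind(1, X), Y)
  rss_line <- sum(line$residuals^2)
  rss_best <- sum(f$residuals^2)
  structure(list(breakpoint = best,
                 left_slope = unname(co[2]),
                 right_slope = unname(co[2] + co[3]),
                 intercept = unname(co[1]),
                 rss = rss_best, rss_line = rss_line,
                 no_meaningful_break =
                   (rss_line - rss_best) <= 1e-10 * max(rss_line, 1e-12),
                 transform = tr$transform, n = length(X)),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise fit [%s]: breakpoint at %.6g\n", x$transform,
              x$breakpoint))
  cat(sprintf("  slopes %.6g -> %.6g; RSS %.6g (single line %.6g)%s\n",
              x$left_slope, x$right_slope, x$rss, x$rss_line,
              if (x$no_meaningful_break) "  [no meaningful break]" else ""))
  invisible(x)
}

#' Compare functional forms for a scaling relationship
#'
#' Fits five candidate models to the *same* response scale `log10(y)` so
#' that RSS-based AIC values, `n log(RSS/n) + 2k`, are comparable:
#'
#' * `power`: `log10(y) ~ log10(x)` (k = 2)
#' * `exponential`: `log10(y) ~ x` (k = 2)
#' * `logarithmic`: `log10(y) = log10(a + b log(x))`, by nonlinear least
#'   squares (k = 2)
#' * `quadratic`: `log10(y) ~ log10(x) + log10(x)^2` (k = 3)
#' * `piecewise`: two-segment fit in log-log space (k = 4; the breakpoint
#'   counts as a parameter)
#'
#' A candidate that fails to fit (e.g. the logarithmic model on data where
#' `a + b log(x)` goes non-positive) is reported as unavailable rather than
#' failing the comparison. Ties in AIC resolve to the earlier candidate in
#' the order above.
#'
#' @param x,y Positive observations.
#' @return A `model_comparison` object: data frame of `model`, `k`, `rss`,
#'   `aic`, `delta_aic`, plus `winner`.
#' @export
model_compare <- function(x, y) {
  check_positive(x, "x"); check_positive(y, "y")
  Y <- log10(y); X <- log10(x)
  n <- length(Y)
  cand <- list()
  add <- function(model, k, rss) {
    cand[[length(cand) + 1L]] <<- data.frame(model = model, k = k,
                                             rss = rss,
                                             stringsAsFactors = FALSE)
  }
  add("power", 2, sum(stats::lm.fit(cbind(1, X), Y)$residuals^2))
  add("exponential", 2, sum(stats::lm.fit(cbind(1, x), Y)$residuals^2))
  log_rss <- tryCatch(suppressWarnings({
    start_fit <- stats::lm.fit(cbind(1, log(x)), y)
    fit <- stats::nls(Y ~ log10(a + b * log(x)),
                      start = list(a = max(start_fit$coefficients[1],
                                           1e-6),
                                   b = start_fit$coefficients[2]),
                      control = stats::nls.control(warnOnly = TRUE,
                                                   maxiter = 200))
    sum(stats::residuals(fit)^2)
  }), error = function(e) NA_real_)
  add("logarithmic", 2, log_rss)
  add("quadratic", 3, sum(stats::lm.fit(cbind(1, X, X^2), Y)$residuals^2))
  pw_rss <- tryCatch(piecewise_fit(x, y)$rss, error = function(e) NA_real_)
  add("piecewise", 4, pw_rss)
  tab <- do.call(rbind, cand)
  tab$aic <- ifelse(is.na(tab$rss) | tab$rss <= 0,
                    ifelse(is.na(tab$rss), NA_real_, -Inf),
                    n * log(tab$rss / n)) + 2 * tab$k
  ok <- which(!is.na(tab$aic))
  winner <- tab$model[ok[which.min(tab$aic[ok])]]
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  structure(list(table = tab, winner = winner, n = n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison on log10(y) response (n =", x$n, ")\n")
  print(x$table, row.names = FALSE)
  cat("winner:", x$winner, "\n")
  invisible(x)
}

#' Exponential-decay fit of thickness-to-span ratios along the path
#'
#' SMA fit of `log10((t/b)^2)` on relative path position `L/H`. On data
#' following `tb2 = A exp(-k L/H)` the fitted slope is `-k / ln(10)`.
#' Relative rather than absolute path length is used because sap tension
#' depends on both position and total path length, so `L/H` standardizes
#' across trees of different heights.
#'
#' @param tb2 Positive thickness-to-span ratios.
#' @param L_rel Relative path positions in (0, 1].
#' @return A `scaling_fit` object (transform `"linear-log10"`).
#' @export
tb2_decay_fit <- function(tb2, L_rel) {
  check_positive(tb2, "tb2")
  if (any(!is.finite(L_rel) | L_rel <= 0 | L_rel > 1))
    stop_validation("L_rel must lie in (0, 1]")
  if (stats::sd(log10(tb2)) == 0) {
    # Constant reinforcement: a decay rate of zero, not a degenerate fit.
    Y <- log10(tb2)
    return(structure(list(method = "SMA", slope = 0, intercept = mean(Y),
                          slope_ci = c(0, 0), r2 = 0, p = 1,
                          n = length(Y), x_var = "L_rel", y_var = "tb2",
                          transform = "linear-log10", X = L_rel, Y = Y),
                     class = "scaling_fit"))
  }
  sma_fit(L_rel, tb2, transform = "linear-log10",
          x_var = "L_rel", y_var = "tb2")
}
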