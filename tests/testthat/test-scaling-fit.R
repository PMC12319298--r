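test_that("SMA slope matches the closed-form moment ratio on any data", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(10:300, 1)
    x <- rlnorm(n, 0, 1); y <- rlnorm(n, 0, 1.4)
    f <- sma_fit(x, y)
    expect_equal(abs(f$slope), sd(log10(y)) / sd(log10(x)),
                 tolerance = 1e-12)
    expect_equal(sign(f$slope), sign(cor(log10(x), log10(y))))
    expect_equal(f$intercept,
                 mean(log10(y)) - f$slope * mean(log10(x)),
                 tolerance = 1e-12)
    expect_true(f$slope_ci[1] <= f$slope && f$slope <= f$slope_ci[2])
  }
})

test_that("noiseless power laws are recovered exactly", {
  x <- seq(0.1, 10, length.out = 60)
  f <- sma_fit(x, 10 * x^0.25)
  expect_equal(f$slope, 0.25, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  o <- ols_fit(x, 10 * x^0.25)
  expect_equal(o$slope, f$slope, tolerance = 1e-12)
  expect_equal(o$intercept, f$intercept, tolerance = 1e-12)
})

test_that("SMA is symmetric under axis exchange, OLS is not", {
  set.seed(2)
  x <- rlnorm(200); y <- (2 * x)^0.4 * rlnorm(200, 0, 0.2)
  f_xy <- sma_fit(x, y); f_yx <- sma_fit(y, x)
  expect_equal(f_xy$slope, 1 / f_yx$slope, tolerance = 1e-12)
  o_xy <- ols_fit(x, y); o_yx <- ols_fit(y, x)
  expect_false(isTRUE(all.equal(o_xy$slope, 1 / o_yx$slope,
                                tolerance = 1e-6)))
})

test_that("OLS attenuates relative to SMA by the correlation factor", {
  set.seed(3)
  x <- rlnorm(500, 0, 0.8)
  y <- 5 * x^0.3 * rlnorm(500, 0, 0.15)   # response noise only
  s <- sma_fit(x, y); o <- ols_fit(x, y)
  expect_lt(abs(o$slope), abs(s$slope))
  r <- cor(log10(x), log10(y))
  expect_equal(o$slope, r * sd(log10(y)) / sd(log10(x)),
               tolerance = 1e-12)
  # constant response: slope 0 by convention
  expect_equal(ols_fit(x, rep(2, 500))$slope, 0)
  # SMA refuses the degenerate case
  expect_error(sma_fit(x, rep(2, 500)), "degenerate")
})

test_that("slope test is exact against the fitted slope and powerful otherwise", {
  x <- seq(0.5, 20, length.out = 400)
  f <- sma_fit(x, 3 * x^0.25)
  expect_equal(sma_slope_test(f, f$slope), 1)
  expect_lt(sma_slope_test(f, 0.5), 1e-10)
  # minimal n = 3 stays well defined
  set.seed(4)
  f3 <- sma_fit(rlnorm(3), rlnorm(3))
  p3 <- sma_slope_test(f3, 0.7)
  expect_true(p3 > 0 && p3 <= 1)
})

test_that("slope-difference and elevation tests separate known generators", {
  set.seed(5)
  mk <- function(n, slope, intercept) {
    s <- sma_consistent_sample(n, slope, intercept, sd_x = 0.15)
    sma_fit(s$x, s$y)
  }
  fa <- mk(4000, 0.32, 1.0); fb <- mk(4000, 0.42, 1.0)
  expect_lt(sma_slope_difference_test(fa, fb), 0.001)
  expect_equal(sma_slope_difference_test(fa, fb),
               sma_slope_difference_test(fb, fa))
  # identical data: both tests return 1
  expect_equal(sma_slope_difference_test(fa, fa), 1)
  expect_equal(sma_elevation_test(fa, fa), 1)
  # same slope, different normalizations (stem vs root intercepts)
  set.seed(51)
  fc <- mk(4000, 0.42, log10(1.45)); fd <- mk(4000, 0.42, log10(2.19))
  expect_lt(sma_elevation_test(fc, fd), 0.001)
  expect_gt(sma_slope_difference_test(fc, fd), 0.05)
  # incompatible transforms refuse to compare
  flin <- sma_fit(1:50, (1:50)^1.1, transform = "none")
  expect_error(sma_slope_difference_test(fa, flin), "incompatible")
})

test_that("quadratic curvature recovers constructed coefficients", {
  # noiseless constructions: lm warns about the perfect fit, which is the
  # point of the oracle
  x <- 10^seq(-1, 1, length.out = 100)
  flat <- suppressWarnings(quadratic_curvature(x, 5 * x^0.3))
  expect_lt(abs(flat$coefficient), 1e-10)
  X <- log10(x)
  up <- suppressWarnings(quadratic_curvature(x, 10^(X + 0.07 * X^2)))
  expect_equal(up$coefficient, 0.07, tolerance = 1e-10)
  down <- suppressWarnings(quadratic_curvature(x, 10^(X - 0.2 * X^2)))
  expect_lt(down$coefficient, 0)
  expect_error(quadratic_curvature(rep(2, 10), rlnorm(10)), "degenerate")
})

test_that("piecewise fits locate a known kink and flag pure lines", {
  set.seed(6)
  x <- seq(0.2, 4, length.out = 500)
  y <- ifelse(x < 2, 1 + 0.1 * x, 1 + 0.1 * 2 + 0.5 * (x - 2)) +
    rnorm(500, 0, 0.01)
  pw <- piecewise_fit(x, y, transform = "none")
  expect_lt(abs(pw$breakpoint - 2), 0.1)
  expect_equal(pw$left_slope, 0.1, tolerance = 0.05)
  expect_equal(pw$right_slope, 0.5, tolerance = 0.05)
  expect_false(pw$no_meaningful_break)
  # deterministic: same data, same breakpoint
  expect_identical(pw$breakpoint,
                   piecewise_fit(x, y, transform = "none")$breakpoint)
  # a pure line has no meaningful break
  line <- piecewise_fit(x, 2 + 3 * x, transform = "none")
  expect_true(line$no_meaningful_break)
  expect_error(piecewise_fit(x[1:5], y[1:5], transform = "none"),
               "at least 10")
  expect_error(piecewise_fit(rep(c(1, 2), 25), rnorm(50),
                             transform = "none"),
               "distinct")
})

test_that("AIC model comparison identifies generating forms", {
  set.seed(7)
  x <- rlnorm(1000, 0, 0.7)
  pow <- 4 * x^0.3 * rlnorm(1000, 0, 0.05)
  mc_pow <- model_compare(x, pow)
  expect_equal(mc_pow$winner, "power")
  expo <- 2 * exp(-0.8 * x) * rlnorm(1000, 0, 0.05)
  mc_exp <- model_compare(x, expo)
  expect_equal(mc_exp$winner, "exponential")
  # structural invariants hold even for small noisy samples
  mc_small <- model_compare(rlnorm(20), rlnorm(20))
  tab <- mc_small$table
  expect_true(all(tab$delta_aic >= 0, na.rm = TRUE))
  expect_equal(tab$model[which.min(tab$aic)], mc_small$winner)
  expect_setequal(tab$model, c("power", "exponential", "logarithmic",
                               "quadratic", "piecewise"))
})

test_that("thickness-to-span decay fit recovers the generator rate", {
  set.seed(8)
  L_rel <- runif(3000, 0.02, 1)
  tb2 <- 0.8 * exp(-1.5 * L_rel) * 10^rnorm(3000, 0, 0.03)
  f <- tb2_decay_fit(tb2, L_rel)
  expect_equal(f$slope, -1.5 / log(10), tolerance = 0.02)
  expect_lt(f$slope_ci[1], f$slope)
  expect_gt(f$slope_ci[2], f$slope)
  # constant reinforcement: zero slope; increasing: positive slope
  expect_equal(tb2_decay_fit(rep(0.3, 50), runif(50))$slope, 0)
  inc <- tb2_decay_fit(0.1 * exp(2 * L_rel), L_rel)
  expect_gt(inc$slope, 0)
  expect_error(tb2_decay_fit(c(0.1, 0.2), c(0.5, 1.5)), "L_rel")
})
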