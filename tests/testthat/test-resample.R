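test_that("bin planning returns the finest feasible log-spaced binning", {
  set.seed(1)
  vals <- 10^runif(10000, 0, 3)   # uniform in log10
  plan <- plan_bins(vals, min_count = 100)
  expect_equal(plan$n_bins, 30)
  expect_true(all(plan$counts >= 100))
  # counting oracle: hist() with right-open bins and a closed last bin
  # uses exactly the same convention
  lv <- log10(vals)
  edges <- seq(min(lv), max(lv), length.out = 31)
  oracle <- hist(lv, breaks = edges, plot = FALSE, right = FALSE)$counts
  expect_equal(unname(plan$counts), oracle[oracle > 0])
  expect_equal(sum(plan$counts), length(vals))
  expect_equal(plan$n_min, min(plan$counts))
  expect_equal(plan$n_max, max(plan$counts))
})

test_that("bin planning agrees with an exhaustive feasibility search", {
  set.seed(2)
  vals <- 10^runif(250, 0, 1)
  feasible <- function(k) {
    edges <- seq(0, 1, length.out = k + 1)
    counts <- tabulate(findInterval(log10(vals), edges,
                                    rightmost.closed = TRUE), nbins = k)
    occ <- counts[counts > 0]
    length(occ) >= 2 && all(occ >= 100)
  }
  best <- suppressWarnings(max(c(-Inf, (2:30)[vapply(2:30, feasible,
                                                     logical(1))])))
  if (is.finite(best)) {
    expect_equal(plan_bins(vals, min_count = 100)$n_bins, best)
  } else {
    expect_error(plan_bins(vals, min_count = 100), "infeasible")
  }
  expect_error(plan_bins(rep(5, 500)), "identical")
})

test_that("balancing conserves bin counts and retains raw records", {
  set.seed(3)
  # three log-decade clusters with counts 120 / 1100 / 4000
  vals <- c(10^runif(120, 0, 0.8), 10^runif(1100, 1.1, 1.9),
            10^runif(4000, 2.2, 3.0))
  rec <- data.frame(id = seq_along(vals), L_m = vals)
  plan <- plan_bins(rec$L_m, min_count = 100, max_bins = 3,
                    variable = "L_m")
  expect_equal(sort(plan$counts), c(120, 1100, 4000))

  sub <- subsample_balance(rec, plan, seed = 1)
  expect_equal(nrow(sub), 3 * plan$n_min)
  expect_false(any(duplicated(sub$id)))   # without replacement

  boot <- bootstrap_balance(rec, plan, seed = 1)
  expect_equal(nrow(boot), 3 * plan$n_max)
  expect_true(all(rec$id %in% boot$id))   # every raw record retained
  bin_of <- plan$bin_of[match(boot$id, rec$id)]
  expect_true(all(tabulate(bin_of) == plan$n_max))

  # seeded determinism
  expect_identical(subsample_balance(rec, plan, seed = 7),
                   subsample_balance(rec, plan, seed = 7))
  expect_identical(bootstrap_balance(rec, plan, seed = 7),
                   bootstrap_balance(rec, plan, seed = 7))
  expect_false(identical(bootstrap_balance(rec, plan, seed = 7),
                         bootstrap_balance(rec, plan, seed = 8)))
})

test_that("already balanced bins pass through the bootstrap untouched", {
  vals <- rep(10^seq(0.1, 2.9, length.out = 150), each = 2)
  rec <- data.frame(id = seq_along(vals), L_m = sort(vals))
  plan <- plan_bins(rec$L_m, min_count = 100, max_bins = 3,
                    variable = "L_m")
  expect_equal(plan$n_min, plan$n_max)
  boot <- bootstrap_balance(rec, plan, seed = 1)
  expect_identical(boot$id, rec$id)
})

test_that("iterated fitting on noiseless data converges immediately", {
  L <- 10^seq(-2, 1.4, length.out = 2000)
  rec <- data.frame(L_m = L, d_um = 10 * L^0.25)
  out <- iterate_fit(rec, "L_m", "bootstrap", fit_spec("L_m", "d_um"),
                     n_iterations = 20, seed = 1)
  expect_equal(out$slopes, rep(0.25, 20), tolerance = 1e-12)
  expect_equal(out$aggregate_slope, 0.25, tolerance = 1e-12)
  expect_true(out$converged)
  expect_true(out$aggregate_ci[1] <= out$aggregate_slope &&
              out$aggregate_slope <= out$aggregate_ci[2])
})

test_that("subsampling and bootstrapping estimate the same exponent", {
  rec <- shoot_records(generate_conduits(recovery_config(seed = 13)))
  spec <- fit_spec("L_m", "d_um")
  boot <- iterate_fit(rec, "L_m", "bootstrap", spec, n_iterations = 60,
                      seed = 5)
  sub <- iterate_fit(rec, "L_m", "subsample", spec, n_iterations = 60,
                     seed = 5)
  expect_lt(abs(boot$aggregate_slope - sub$aggregate_slope), 0.01)
  # the subsample spread must straddle the bootstrap centre
  expect_true(sub$aggregate_ci[1] <= boot$aggregate_slope &&
              boot$aggregate_slope <= sub$aggregate_ci[2])
})

test_that("iterated fits are deterministic end-to-end under a seed", {
  rec <- shoot_records(generate_conduits(small_config()))
  spec <- fit_spec("L_m", "d_um")
  a <- iterate_fit(rec, "L_m", "bootstrap", spec, n_iterations = 15,
                   seed = 3, min_count = 50)
  b <- iterate_fit(rec, "L_m", "bootstrap", spec, n_iterations = 15,
                   seed = 3, min_count = 50)
  expect_identical(a$slopes, b$slopes)
  expect_identical(a$aggregate_ci, b$aggregate_ci)
})

test_that("fitting averaged sample diameters underestimates the exponent", {
  # Counts grow with L (trunk cap vs leaf dozens): averaging each sample to
  # one hydraulic diameter removes the conduit-level scatter whose
  # inflation the balanced conduit-level fit retains, so the averaged-data
  # exponent comes out smaller.
  rec <- shoot_records(generate_conduits(
    recovery_config(sigma_log_d = 0.15, seed = 17)))
  per_sample <- do.call(rbind, lapply(split(rec, rec$sample_id), function(s)
    data.frame(L_m = s$L_m[1], d_h = hydraulic_diameter(s$d_um))))
  averaged <- sma_fit(per_sample$L_m, per_sample$d_h)
  balanced <- iterate_fit(rec, "L_m", "bootstrap", fit_spec("L_m", "d_um"),
                          n_iterations = 60, seed = 2)
  expect_lt(averaged$slope, balanced$aggregate_slope)
})
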