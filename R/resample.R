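# Bin-balanced resampling. Conduit tables are massively unbalanced: a single
# trunk core contributes thousands of conduits while a leaf section
# contributes dozens, so naive pooled fits are dominated by a few path
# positions. Balancing equalizes counts across equally spaced logarithmic
# bins of the predictor before fitting, either by subsampling every bin down
# to the smallest bin or by bootstrapping every bin up to the largest.

#' Plan equally spaced logarithmic bins
#'
#' Divides positive measurements into bins equally spaced in log10 and
#' chooses the *largest* number of bins (up to `max_bins`) for which every
#' occupied bin holds at least `min_count` observations — the finest
#' resolution consistent with the minimum-count constraint. Values on an
#' interior edge fall in the right bin; the last bin is closed on the right.
#' Empty bins (possible with gappy data) are treated as absent: they are
#' excluded from the minimum-count constraint and flagged in the plan.
#'
#' @param values Positive measurements (the binning variable).
#' @param min_count Minimum observations required in every occupied bin.
#' @param max_bins Upper bound for the bin search.
#' @param variable Name of the binning variable (for downstream joins).
#' @return A `binning_plan`: `variable`, `edges` (log10-spaced boundaries on
#'   the original scale), `n_bins` (requested), `counts` (occupied bins
#'   only), `bin_of` (per-value occupied-bin index), `n_min`, `n_max`,
#'   `n_empty` (count of empty interior bins).
#' @export
plan_bins <- function(values, min_count = 100, max_bins = 30,
                      variable = "value") {
  check_positive(values, "values")
  check_scalar(min_count, "min_count", lower = 1)
  check_scalar(max_bins, "max_bins", lower = 2)
  lv <- log10(values)
  lo <- min(lv); hi <- max(lv)
  if (lo == hi)
    stop_validation("binning infeasible: all values identical")
  assign_bins <- function(k) {
    # [e_i, e_{i+1}) bins: values on an interior edge go right; the last
    # bin is closed on the right.
    edges <- seq(lo, hi, length.out = k + 1L)
    findInterval(lv, edges, rightmost.closed = TRUE)
  }
  for (k in seq(from = max_bins, to = 2L)) {
    idx <- assign_bins(k)
    counts <- tabulate(idx, nbins = k)
    occupied <- which(counts > 0L)
    if (length(occupied) >= 2L && all(counts[occupied] >= min_count)) {
      bin_of <- match(idx, occupied)
      return(structure(list(variable = variable,
                            edges = 10^seq(lo, hi, length.out = k + 1L),
                            n_bins = k,
                            counts = counts[occupied],
                            occupied = occupied,
                            bin_of = bin_of,
                            n_min = min(counts[occupied]),
                            n_max = max(counts[occupied]),
                            n_empty = k - length(occupied)),
                       class = "binning_plan"))
    }
  }
  stop_validation("binning infeasible: no number of bins between 2 and ",
                  max_bins, " keeps every occupied bin at >= ", min_count,
                  " observations")
}

#' @export
print.binning_plan <- function(x, ...) {
  cat(sprintf("Binning plan on %s: %d log10-spaced bins (%d occupied)\n",
              x$variable, x$n_bins, length(x$counts)))
  cat(sprintf("  counts %s (min %d, max %d)%s\n",
              paste(x$counts, collapse = ", "), x$n_min, x$n_max,
              if (x$n_empty > 0)
                sprintf("  [%d empty bin(s) treated as absent]", x$n_empty)
              else ""))
  invisible(x)
}

plan_for_records <- function(records, plan) {
  if (!plan$variable %in% names(records))
    stop_validation("records lack the binning column ", plan$variable)
  if (length(plan$bin_of) != nrow(records))
    stop_validation("plan was built for ", length(plan$bin_of),
                    " records, got ", nrow(records))
  split(seq_len(nrow(records)), plan$bin_of)
}

#' Balance a conduit table by subsampling each bin to the smallest bin
#'
#' Samples, without replacement, exactly `n_min` records from every occupied
#' bin, where `n_min` is the smallest occupied-bin count in the plan.
#'
#' @param records Data frame the plan was built on (same row order).
#' @param plan A [plan_bins()] result for `records[[plan$variable]]`.
#' @param seed Integer seed; identical seeds give identical selections.
#' @return Balanced data frame with `n_min * n_occupied_bins` rows.
#' @export
subsample_balance <- function(records, plan, seed = 1) {
  bins <- plan_for_records(records, plan)
  set.seed(seed)
  idx <- unlist(lapply(bins, function(b)
    b[sample.int(length(b), plan$n_min)]), use.names = FALSE)
  records[idx, , drop = FALSE]
}

#' Balance a conduit table by bootstrapping each bin up to the largest bin
#'
#' Every occupied bin keeps all of its raw records and is augmented with
#' `n_max - n_bin` records resampled from itself with replacement, so each
#' bin ends with exactly `n_max` records and every raw record is retained.
#'
#' @inheritParams subsample_balance
#' @return Balanced data frame with `n_max * n_occupied_bins` rows.
#' @export
bootstrap_balance <- function(records, plan, seed = 1) {
  bins <- plan_for_records(records, plan)
  set.seed(seed)
  idx <- unlist(lapply(bins, function(b) {
    extra <- plan$n_max - length(b)
    if (extra > 0L) c(b, b[sample.int(length(b), extra, replace = TRUE)])
    else b
  }), use.names = FALSE)
  records[idx, , drop = FALSE]
}

#' Specification of one scaling fit inside the resampling loop
#'
#' @param x_var,y_var Column names of predictor and response.
#' @param transform Transform label as in [sma_fit()].
#' @param method `"sma"` or `"ols"`.
#' @return A plain list consumed by [iterate_fit()].
#' @export
fit_spec <- function(x_var, y_var, transform = "log10-log10",
                     method = c("sma", "ols")) {
  list(x_var = x_var, y_var = y_var, transform = transform,
       method = match.arg(method))
}

# Moment-based slope and parametric CI, shared with sma_fit/ols_fit but
# avoiding per-iteration object construction in the hot loop.
slope_from_moments <- function(X, Y, method) {
  n <- length(X)
  sx <- stats::sd(X); sy <- stats::sd(Y)
  if (sx == 0 || sy == 0)
    stop_validation("degenerate fit: zero variance inside an iteration")
  r <- stats::cor(X, Y)
  if (method == "sma") {
    slope <- (if (r < 0) -1 else 1) * sy / sx
    B <- stats::qf(0.95, 1, n - 2) * (1 - r^2) / (n - 2)
    ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  } else {
    slope <- r * sy / sx
    se <- sy / sx * sqrt(max(0, 1 - r^2) / (n - 2))
    ci <- slope + c(-1, 1) * stats::qt(0.975, n - 2) * se
  }
  intercept <- mean(Y) - slope * mean(X)
  c(slope, ci, intercept)
}

#' Iterated balanced resampling and fitting
#'
#' The core bias-correction procedure: for each iteration, balance the
#' dataset over logarithmic bins of `binning_variable` (by subsampling or
#' bootstrapping), fit the requested scaling relationship, and record the
#' slope. The aggregate slope is the mean of per-iteration slopes and the
#' aggregate CI the 2.5/97.5 percentiles of per-iteration slopes; the
#' per-iteration parametric CIs are also stored, but note that under
#' bootstrap augmentation these reflect an inflated sample size and are
#' anti-conservative. A running mean of the slope (the stability trace) is
#' kept, and the run is flagged converged when that mean varies by less than
#' `stability_tol` over the last half of the iterations.
#'
#' @param records Conduit table (rows with non-finite `x_var`, `y_var` or
#'   binning values are dropped first).
#' @param binning_variable Column to bin on (`"L_m"` or `"D_mm"` normally).
#' @param mode `"bootstrap"` or `"subsample"`.
#' @param spec A [fit_spec()].
#' @param n_iterations Number of iterations; defaults to 1000 for bootstrap
#'   and 10000 for subsampling.
#' @param seed Integer seed for the whole run.
#' @param stability_tol Convergence tolerance for the stability trace.
#' @param min_count,max_bins Passed to [plan_bins()].
#' @return A `resample_outcome`: `mode`, `slopes`, `intercepts`, `cis`
#'   (n x 2), `aggregate_slope`, `aggregate_intercept`, `aggregate_ci`,
#'   `n_iterations`, `stability_trace`, `converged`, `plan`, `spec`.
#' @export
iterate_fit <- function(records, binning_variable, mode = c("bootstrap",
                                                            "subsample"),
                        spec, n_iterations = NULL, seed = 1,
                        stability_tol = 1e-3, min_count = 100,
                        max_bins = 30) {
  mode <- match.arg(mode)
  if (is.null(n_iterations))
    n_iterations <- if (mode == "bootstrap") 1000L else 10000L
  check_scalar(n_iterations, "n_iterations", lower = 1)
  keep <- is.finite(records[[binning_variable]]) &
    is.finite(records[[spec$x_var]]) & is.finite(records[[spec$y_var]])
  records <- records[keep, , drop = FALSE]
  plan <- plan_bins(records[[binning_variable]], min_count = min_count,
                    max_bins = max_bins, variable = binning_variable)
  bins <- split(seq_len(nrow(records)), plan$bin_of)
  tr <- apply_transform(records[[spec$x_var]], records[[spec$y_var]],
                        spec$transform)
  X <- tr$x; Y <- tr$y
  raw_idx <- unlist(bins, use.names = FALSE)

  slopes <- numeric(n_iterations)
  intercepts <- numeric(n_iterations)
  cis <- matrix(NA_real_, n_iterations, 2L,
                dimnames = list(NULL, c("lower", "upper")))
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    idx <- if (mode == "subsample") {
      unlist(lapply(bins, function(b)
        b[sample.int(length(b), plan$n_min)]), use.names = FALSE)
    } else {
      extras <- lapply(bins, function(b) {
        m <- plan$n_max - length(b)
        if (m > 0L) b[sample.int(length(b), m, replace = TRUE)] else
          integer(0)
      })
      c(raw_idx, unlist(extras, use.names = FALSE))
    }
    res <- tryCatch(slope_from_moments(X[idx], Y[idx], spec$method),
                    error = function(e)
                      stop("fit failed at iteration ", it, ": ",
                           conditionMessage(e), call. = FALSE))
    slopes[it] <- res[1]; cis[it, ] <- res[2:3]; intercepts[it] <- res[4]
  }
  trace <- cumsum(slopes) / seq_len(n_iterations)
  half <- trace[seq.int(max(1L, floor(n_iterations / 2)), n_iterations)]
  converged <- (max(half) - min(half)) < stability_tol
  structure(list(mode = mode,
                 slopes = slopes, intercepts = intercepts, cis = cis,
                 aggregate_slope = mean(slopes),
                 aggregate_intercept = mean(intercepts),
                 aggregate_ci = unname(stats::quantile(slopes,
                                                       c(0.025, 0.975))),
                 n_iterations = n_iterations,
                 stability_trace = trace, converged = converged,
                 plan = plan, spec = spec, seed = seed),
            class = "resample_outcome")
}

#' @export
print.resample_outcome <- function(x, ...) {
  cat(sprintf("Balanced %s fit (%d iterations%s)\n", x$mode,
              x$n_iterations,
              if (x$converged) ", stability trace converged" else ""))
  cat(sprintf("  %s slope of %s ~ %s: %.4f (across-iteration 95%% CI %.4f to %.4f)\n",
              toupper(x$spec$method), x$spec$y_var, x$spec$x_var,
              x$aggregate_slope, x$aggregate_ci[1], x$aggregate_ci[2]))
  cat(sprintf("  bins on %s: %d occupied, counts %d to %d\n",
              x$plan$variable, length(x$plan$counts), x$plan$n_min,
              x$plan$n_max))
  invisible(x)
}
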