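# Shared fixtures: all synthetic, built in code.

# A small but structurally complete generator configuration: every organ
# class, realistic imbalance, quick to draw.
small_config <- function(..., seed = 42) {
  taper_config(n_species = 1, n_trees_per_species = 2,
               count_model = list(coef = 2, cap = 300, floor = 10,
                                  leaf_range = c(10, 30)),
               seed = seed, ...)
}

# Mid-size configuration used where exponent recovery is measured.
recovery_config <- function(..., seed = 1) {
  taper_config(n_species = 3, n_trees_per_species = 3,
               count_model = list(coef = 5, cap = 800, floor = 15,
                                  leaf_range = c(10, 50)),
               seed = seed, ...)
}

SHOOT_ORGANS <- c("leaf", "twig", "branch", "trunk")

shoot_records <- function(records) {
  records[records$organ %in% SHOOT_ORGANS, , drop = FALSE]
}

# Bivariate sample under the matched-error structure for which the SMA
# estimator is consistent: scatter on both axes with sd ratio equal to the
# slope. Returns data on the original (power-law) scale.
sma_consistent_sample <- function(n, slope = 0.23, intercept = 1,
                                  sd_x = 0.25, spread = 1) {
  xi <- stats::rnorm(n, 0, spread)
  x <- xi + stats::rnorm(n, 0, sd_x)
  y <- intercept + slope * xi + stats::rnorm(n, 0, abs(slope) * sd_x)
  list(x = 10^x, y = 10^y)
}
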