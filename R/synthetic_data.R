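# Synthetic conduit-table generator. Emulates the statistical structure of
# quantitative wood-anatomy datasets sampled along the whole hydraulic path:
# log-normal conduit diameters whose median follows d = d0 * L^alpha,
# organ diameters tied to path length by a power law, thickness-to-span
# ratios decaying exponentially in relative position L/H, an earlywood/
# latewood mixture, and order-of-magnitude imbalance in conduit counts
# across path-length bins.

#' Generator configuration
#'
#' Builds and validates the configuration for [generate_conduits()]. The
#' defaults encode the study conditions the package is designed around:
#' five conifer species, path-length scaling exponent `alpha_true = 0.23`,
#' root diameter-scaling exponent `beta_root_true = 0.42` with normalization
#' 2.19, a stem length-diameter relation chosen so that the implied stem
#' diameter-scaling exponent is 0.32, a thickness-to-span intercept of 0.8
#' decaying at rate 1.5 in `L/H`, and an 81% latewood share.
#'
#' Multiplicative (log-normal) scatter is applied to conduit diameters
#' (`sigma_log_d`, log10 scale) and, with the matched standard deviation
#' `sigma_log_d / slope`, to organ external diameters. Under that error
#' structure the standardized major axis estimator is consistent for the
#' generating exponent, which is the property the recovery tests exercise.
#'
#' @param n_species,n_trees_per_species Number of species and trees each.
#' @param height_range Range (m) from which each tree's total path length
#'   `H` is drawn uniformly.
#' @param alpha_true Path-length scaling exponent for conduit diameter.
#' @param d0_true Normalization (um at L = 1 m) for the path-length law.
#' @param sigma_log_d Log10 standard deviation of conduit-diameter scatter.
#' @param beta_root_true,d0_root_true Root diameter-scaling exponent and its
#'   normalization (um at D = 1 mm).
#' @param tb2_intercept Thickness-to-span ratio target at `L/H = 0`
#'   (earlywood baseline).
#' @param tb2_decay_rate Exponential decay rate of the `(t/b)^2` target in
#'   relative path position `L/H`.
#' @param sigma_log_tb2 Log10 standard deviation of `(t/b)^2` scatter.
#' @param latewood_fraction Proportion of conduits drawn as latewood.
#' @param latewood_tb2_multiplier Multiplicative reinforcement of the
#'   `(t/b)^2` target in latewood conduits (>= 1).
#' @param stem_length_diameter_exponent Exponent `gamma` of the stem
#'   length-diameter relation `L = stem_ld_coef * D^gamma` (D in mm). The
#'   implied stem diameter-scaling exponent is `alpha_true * gamma`.
#' @param stem_ld_coef Coefficient of the stem length-diameter relation.
#' @param count_model List with elements `coef`, `cap`, `floor` (conduits per
#'   sample = `clamp(round(coef * D_mm^2), floor, cap)`) and `leaf_range`
#'   (uniform integer range for leaf samples, which have no D). The default
#'   reproduces the order-of-magnitude count imbalance of real datasets.
#' @param seed Integer root seed; per-tree substreams are derived from it so
#'   that regeneration is reproducible tree by tree.
#' @return An object of class `taper_config`.
#' @export
taper_config <- function(n_species = 5,
                         n_trees_per_species = 5,
                         height_range = c(15, 30),
                         alpha_true = 0.23,
                         d0_true = 6,
                         sigma_log_d = 0.05,
                         beta_root_true = 0.42,
                         d0_root_true = 2.19,
                         tb2_intercept = 0.8,
                         tb2_decay_rate = 1.5,
                         sigma_log_tb2 = 0.2,
                         latewood_fraction = 0.81,
                         latewood_tb2_multiplier = 4,
                         stem_length_diameter_exponent = 0.32 / 0.23,
                         stem_ld_coef = 0.065,
                         count_model = list(coef = 20, cap = 5000,
                                            floor = 20,
                                            leaf_range = c(20, 100)),
                         seed = 1) {
  cfg <- list(n_species = n_species,
              n_trees_per_species = n_trees_per_species,
              height_range = height_range,
              alpha_true = alpha_true, d0_true = d0_true,
              sigma_log_d = sigma_log_d,
              beta_root_true = beta_root_true,
              d0_root_true = d0_root_true,
              tb2_intercept = tb2_intercept,
              tb2_decay_rate = tb2_decay_rate,
              sigma_log_tb2 = sigma_log_tb2,
              latewood_fraction = latewood_fraction,
              latewood_tb2_multiplier = latewood_tb2_multiplier,
              stem_length_diameter_exponent = stem_length_diameter_exponent,
              stem_ld_coef = stem_ld_coef,
              count_model = count_model,
              seed = seed)
  class(cfg) <- "taper_config"
  validate_taper_config(cfg)
  cfg
}

validate_taper_config <- function(cfg) {
  check_scalar(cfg$n_species, "n_species", lower = 1)
  check_scalar(cfg$n_trees_per_species, "n_trees_per_species", lower = 1)
  if (length(cfg$height_range) != 2L || any(cfg$height_range <= 0) ||
      diff(cfg$height_range) < 0)
    stop_validation("height_range must be two positive increasing values")
  check_scalar(cfg$alpha_true, "alpha_true", lower = 0, open_lower = TRUE)
  check_scalar(cfg$d0_true, "d0_true", lower = 0, open_lower = TRUE)
  check_scalar(cfg$sigma_log_d, "sigma_log_d", lower = 0)
  check_scalar(cfg$beta_root_true, "beta_root_true", lower = 0,
               open_lower = TRUE)
  check_scalar(cfg$d0_root_true, "d0_root_true", lower = 0,
               open_lower = TRUE)
  check_scalar(cfg$tb2_intercept, "tb2_intercept", lower = 0,
               open_lower = TRUE)
  check_scalar(cfg$tb2_decay_rate, "tb2_decay_rate")
  check_scalar(cfg$sigma_log_tb2, "sigma_log_tb2", lower = 0)
  check_scalar(cfg$latewood_fraction, "latewood_fraction", 0, 1)
  check_scalar(cfg$latewood_tb2_multiplier, "latewood_tb2_multiplier",
               lower = 1)
  check_scalar(cfg$stem_length_diameter_exponent,
               "stem_length_diameter_exponent", lower = 0, open_lower = TRUE)
  check_scalar(cfg$stem_ld_coef, "stem_ld_coef", lower = 0,
               open_lower = TRUE)
  cm <- cfg$count_model
  if (!is.list(cm) || !all(c("coef", "cap", "floor", "leaf_range") %in%
                           names(cm)))
    stop_validation("count_model must list coef, cap, floor, leaf_range")
  if (cm$cap < cm$floor || cm$floor < 1 || cm$coef <= 0)
    stop_validation("count_model: need coef > 0 and cap >= floor >= 1")
  # Structural bound: a (t/b)^2 target implying walls > 10x the span is
  # treated as an impossible configuration (negative decay rates can push
  # the target there at L/H = 1).
  worst <- cfg$tb2_intercept * cfg$latewood_tb2_multiplier *
    exp(max(0, -cfg$tb2_decay_rate))
  if (worst > 100)
    stop_validation("configuration implies (t/b)^2 targets above 100 ",
                    "(structurally impossible walls); got ", signif(worst, 4))
  invisible(cfg)
}

#' @export
print.taper_config <- function(x, ...) {
  cat("Synthetic conduit-table generator configuration\n")
  flat <- x[setdiff(names(x), "count_model")]
  for (nm in names(flat))
    cat(sprintf("  %-32s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  cm <- x$count_model
  cat(sprintf("  %-32s coef=%g cap=%g floor=%g leaf=[%g,%g]\n", "count_model",
              cm$coef, cm$cap, cm$floor, cm$leaf_range[1], cm$leaf_range[2]))
  invisible(x)
}

# Draw from a log10-uniform distribution.
rlog10unif <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

# Positive truncated-normal draw by rejection (redraws non-positive or
# non-finite values).
rtrunc_pos <- function(n, mean, sd, lower = 0, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- !is.finite(out) | out <= lower | out >= upper
  tries <- 0L
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- !is.finite(out) | out <= lower | out >= upper
    tries <- tries + 1L
    if (tries > 1000L) stop_validation("rejection sampling failed to ",
                                       "produce draws in (", lower, ",",
                                       upper, ")")
  }
  out
}

# Number of conduits measured in one tissue sample.
sample_count <- function(cm, D_mm) {
  if (is.na(D_mm)) {
    lo <- cm$leaf_range[1]; hi <- cm$leaf_range[2]
    sample(seq.int(lo, hi), 1L)
  } else {
    min(cm$cap, max(cm$floor, round(cm$coef * D_mm^2)))
  }
}

# One sampling position: organ, path position L, external diameter D and the
# latent size driving conduit diameter in roots.
tree_sample_plan <- function(cfg, H) {
  gamma <- cfg$stem_length_diameter_exponent
  a <- cfg$stem_ld_coef
  stem_D <- function(L) (L / a)^(1 / gamma)
  rows <- list()
  add <- function(organ, L, D, latent = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(organ = organ, L_m = L,
                                             D_mm = D, latent = latent,
                                             stringsAsFactors = FALSE)
  }
  for (k in 1:2) add("leaf", rlog10unif(1, 0.005, 0.05), NA_real_)
  L_twig <- rlog10unif(1, 0.05, 0.3); add("twig", L_twig, stem_D(L_twig))
  L_br <- rtrunc_pos(1, 1.0, 0.15, lower = 0.3, upper = min(2, H / 2))
  add("branch", L_br, stem_D(L_br))
  add("trunk", H, stem_D(H))
  # Roots: placed at the base of the path (L = H) and driven by their own
  # external diameter, not by L.
  root_spec <- list(coarse_root = c(3, 60), fine_root = c(0.8, 3),
                    very_fine_root = c(0.2, 0.8))
  n_per_root <- c(coarse_root = 1L, fine_root = 2L, very_fine_root = 2L)
  for (org in names(root_spec)) {
    for (k in seq_len(n_per_root[[org]])) {
      xi <- rlog10unif(1, root_spec[[org]][1], root_spec[[org]][2])
      add(org, H, xi, latent = xi)
    }
  }
  do.call(rbind, rows)
}

# Conduit-level columns for one tissue sample. The recorded external
# diameter carries conduit-level log-normal scatter with standard deviation
# sigma_log_d / slope around the sample's latent size, the matched-ratio
# error structure under which the SMA exponent estimator is consistent.
sample_conduits <- function(cfg, organ, L, H, D_mm, latent, n) {
  if (organ %in% ROOT_ORGANS) {
    med <- cfg$d0_root_true * latent^cfg$beta_root_true
    sig_D <- cfg$sigma_log_d / cfg$beta_root_true
  } else {
    med <- cfg$d0_true * L^cfg$alpha_true
    sig_D <- cfg$sigma_log_d /
      (cfg$alpha_true * cfg$stem_length_diameter_exponent)
  }
  if (!is.na(D_mm) && cfg$sigma_log_d > 0)
    D_mm <- D_mm * 10^stats::rnorm(n, 0, sig_D)
  d <- med * 10^stats::rnorm(n, 0, cfg$sigma_log_d)
  latewood <- stats::runif(n) < cfg$latewood_fraction
  tb2 <- cfg$tb2_intercept * exp(-cfg$tb2_decay_rate * L / H) *
    10^stats::rnorm(n, 0, cfg$sigma_log_tb2) *
    ifelse(latewood, cfg$latewood_tb2_multiplier, 1)
  t_double <- d * sqrt(tb2)        # span b = d, so (t/b)^2 = tb2 exactly
  x_tan <- t_double / 2            # tangential single wall
  # Radial walls jittered +10% so the tangential wall is the deterministic
  # minimum used by thickness_to_span().
  M_target <- ifelse(latewood, stats::runif(n, 1.05, 2.5),
                     stats::runif(n, 0.30, 0.95))
  d_rad <- 4 * x_tan / M_target    # Mork classification matches the label
  data.frame(organ = organ, L_m = L, H_m = H, D_mm = D_mm, d_um = d,
             d_rad_um = d_rad,
             wall_rad1_um = x_tan * 1.1, wall_rad2_um = x_tan * 1.1,
             wall_tan1_um = x_tan, wall_tan2_um = x_tan,
             wood_type = ifelse(latewood, "latewood", "earlywood"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic conduit table
#'
#' Draws a conduit-level dataset under the configured scaling laws. Each tree
#' contributes tissue samples spanning all seven organ classes: leaves in
#' `L` in (0, 0.05] m, twigs in (0.05, 0.3] m, branch bases near 1 m, the
#' trunk base at `L = H`, and roots at the base of the path with their own
#' external diameters. Conduit counts per sample follow the configured count
#' model (proportional to organ cross-sectional area, capped), producing the
#' strong bin imbalance the resampling module exists to correct. Identical
#' configurations (including the seed) yield identical tables.
#'
#' @param config A [taper_config()] object.
#' @return Data frame with one row per conduit and columns `species`,
#'   `tree_id`, `organ`, `sample_id`, `L_m`, `H_m`, `D_mm`, `d_um`,
#'   `d_rad_um`, `wall_rad1_um`, `wall_rad2_um`, `wall_tan1_um`,
#'   `wall_tan2_um`, `wood_type`.
#' @export
generate_conduits <- function(config = taper_config()) {
  validate_taper_config(config)
  species <- sprintf("SP%02d", seq_len(config$n_species))
  trees <- expand.grid(species = species,
                       tree = seq_len(config$n_trees_per_species),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(trees))
  for (i in seq_len(nrow(trees))) {
    tree_index <- i
    set.seed(child_seed(config$seed, tree_index))
    H <- stats::runif(1, config$height_range[1], config$height_range[2])
    plan <- tree_sample_plan(config, H)
    tree_id <- sprintf("%s_T%02d", trees$species[i], trees$tree[i])
    per_sample <- vector("list", nrow(plan))
    organ_counter <- integer(0)
    for (s in seq_len(nrow(plan))) {
      org <- plan$organ[s]
      organ_counter[org] <- if (is.na(organ_counter[org])) 1L else
        organ_counter[org] + 1L
      n <- sample_count(config$count_model, plan$D_mm[s])
      block <- sample_conduits(config, org, plan$L_m[s], H, plan$D_mm[s],
                               plan$latent[s], n)
      block$species <- trees$species[i]
      block$tree_id <- tree_id
      block$sample_id <- sprintf("%s_%s%d", tree_id, org,
                                 organ_counter[[org]])
      per_sample[[s]] <- block
    }
    out[[i]] <- do.call(rbind, per_sample)
  }
  res <- do.call(rbind, out)
  cols <- c("species", "tree_id", "organ", "sample_id", "L_m", "H_m",
            "D_mm", "d_um", "d_rad_um", "wall_rad1_um", "wall_rad2_um",
            "wall_tan1_um", "wall_tan2_um", "wood_type")
  res <- res[, cols]
  rownames(res) <- NULL
  if (any(!is.finite(res$d_um) | res$d_um <= 0) ||
      any(res[, grep("^wall_", names(res))] <= 0))
    stop_validation("generator produced non-positive measurements")
  res
}
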