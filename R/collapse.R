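# Numerical model of the tip-to-base water-potential gradient and the
# critical thickness-to-span ratio for conduit wall collapse.
#
# The hydraulic path is modelled as a series of vertically stacked pipes
# that widen from the leaf tip to the base following d = d0 * L^alpha,
# discretized into segments of length delta_l. Segment resistances follow
# Hagen-Poiseuille; the volumetric flow between fixed soil and leaf water
# potentials follows Darcy's law; the cumulative water potential along the
# path then sets the sap tension each wall must withstand, and plate-bending
# mechanics convert that tension into a critical (t/b)^2 below which the
# wall buckles. The gravitational pressure head (~0.01 MPa per metre) is
# deliberately omitted; it is small for the tree heights considered.

#' Configuration of the collapse-limit simulation
#'
#' Defaults reproduce the standard simulation: a 30 m path in 100 um
#' segments, widening exponent `alpha = 0.23`, sap viscosity 1.002e-9 MPa s,
#' leaf water potential -4.7 MPa (a measured drought minimum), soil water
#' potential -1.5 MPa (a typical wilting point), plate-bending coefficient
#' `beta_bend = 0.25` (the rectangular-plate value for span-to-length ratios
#' at or below 0.5, which conduit walls always satisfy) and a modulus of
#' rupture of 41.6 MPa (a green cell-wall species mean).
#'
#' Both the water-potential profile and the critical limit are invariant to
#' rescaling `d0` or `eta`: each enters flow and resistance as a common
#' factor that cancels in the potential drop.
#'
#' @param H Total path length (m).
#' @param delta_l Segment length (m); default 1e-4 (100 um).
#' @param alpha Path-scaling exponent (>= 0; 0 is the uniform pipe model).
#' @param d0 Diameter normalization (um at L = 1 m); cancels out.
#' @param eta Sap dynamic viscosity (MPa s); cancels out.
#' @param psi_leaf,psi_soil Leaf and soil water potentials (MPa);
#'   `psi_leaf < psi_soil <= 0`.
#' @param beta_bend Plate-bending coefficient (0, 0.5].
#' @param sigma_rupture Modulus of rupture of green cell-wall material
#'   (MPa).
#' @param species_sigma Optional named numeric vector of per-species moduli
#'   for [species_specific_limits()].
#' @return An object of class `collapse_config`.
#' @export
collapse_config <- function(H = 30, delta_l = 1e-4, alpha = 0.23, d0 = 10,
                            eta = 1.002e-9, psi_leaf = -4.7,
                            psi_soil = -1.5, beta_bend = 0.25,
                            sigma_rupture = 41.6, species_sigma = NULL) {
  check_scalar(H, "H", lower = 0, open_lower = TRUE)
  check_scalar(delta_l, "delta_l", lower = 0, open_lower = TRUE)
  if (H / delta_l < 10)
    stop_validation("need at least 10 segments: H/delta_l = ", H / delta_l)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop_validation("alpha must be >= 0 (0 is the uniform pipe model)")
  check_scalar(d0, "d0", lower = 0, open_lower = TRUE)
  check_scalar(eta, "eta", lower = 0, open_lower = TRUE)
  if (!(psi_leaf < psi_soil) || psi_soil > 0)
    stop_validation("require psi_leaf < psi_soil <= 0; got ", psi_leaf,
                    ", ", psi_soil)
  check_scalar(beta_bend, "beta_bend", lower = 0, upper = 0.5,
               open_lower = TRUE)
  check_scalar(sigma_rupture, "sigma_rupture", lower = 0, open_lower = TRUE)
  if (!is.null(species_sigma) &&
      (is.null(names(species_sigma)) || any(species_sigma <= 0)))
    stop_validation("species_sigma must be a named vector of positive moduli")
  structure(list(H = H, delta_l = delta_l, alpha = alpha, d0 = d0,
                 eta = eta, psi_leaf = psi_leaf, psi_soil = psi_soil,
                 beta_bend = beta_bend, sigma_rupture = sigma_rupture,
                 species_sigma = species_sigma),
            class = "collapse_config")
}

#' Discretize the hydraulic path into widening segments
#'
#' Builds `N = round(H / delta_l)` segments. Each segment carries an
#' *effective hydraulic diameter*: the power mean of `d(L) = d0 * L^alpha`
#' over the cell that reproduces the exact Hagen-Poiseuille resistance
#' integral, `d_eff = d0 * (delta_l / integral(L^-4alpha))^(1/4)`. With this
#' quadrature the node water potentials equal the continuum solution for
#' any segment length (for `alpha < 1/4`; see Details), rather than
#' converging slowly because of the near-singular resistance density at the
#' tip. The water potential at the tip boundary itself is `psi_leaf` by
#' definition and tip-end quantities use that exact boundary value.
#'
#' @details For `alpha >= 1/4` the continuum resistance integral diverges
#' at the tip (`L^-4alpha` is no longer integrable at 0); the first cell
#' then falls back to the midpoint-rule diameter `d0 (delta_l/2)^alpha`, a
#' regularization equivalent to capping conduit narrowing below the first
#' half-cell. All remaining cells still use the exact integral.
#'
#' @param config A [collapse_config()].
#' @return A `path_profile` data frame with columns `segment`, `L_mid`
#'   (segment midpoint), `L_node` (proximal node position), `L_rel` (node
#'   position over H) and `d_um` (effective hydraulic diameter), plus the
#'   config as an attribute. Subsequent steps append columns.
#' @export
build_path_profile <- function(config = collapse_config()) {
  stopifnot(inherits(config, "collapse_config"))
  N <- round(config$H / config$delta_l)
  i <- seq_len(N)
  dl <- config$delta_l
  a4 <- 4 * config$alpha
  L0 <- (i - 1) * dl
  L1 <- i * dl
  # Exact cell integral of L^(-4 alpha); the first cell needs the
  # singularity-aware branch.
  I <- if (a4 == 0) {
    rep(dl, N)
  } else if (a4 < 1) {
    (L1^(1 - a4) - L0^(1 - a4)) / (1 - a4)
  } else {
    head_cell <- dl * (dl / 2)^(-a4)   # midpoint regularization at the tip
    rest <- if (a4 == 1) log(L1[-1] / L0[-1]) else
      (L1[-1]^(1 - a4) - L0[-1]^(1 - a4)) / (1 - a4)
    c(head_cell, rest)
  }
  d <- config$d0 * (dl / I)^(1 / 4)
  profile <- data.frame(segment = i, L_mid = (i - 0.5) * dl,
                        L_node = L1, L_rel = L1 / config$H, d_um = d)
  attr(profile, "config") <- config
  class(profile) <- c("path_profile", "data.frame")
  profile
}

profile_config <- function(profile) {
  cfg <- attr(profile, "config")
  if (is.null(cfg)) stop_validation("profile lacks its configuration")
  cfg
}

#' Hagen-Poiseuille resistance of each path segment
#'
#' `r_i = 128 * eta * delta_l / (pi * d_i^4)` with the diameter converted
#' from um to m. Resistance falls steeply (fourth power) as conduits widen
#' toward the base.
#'
#' @param profile A `path_profile` with diameters.
#' @return The profile with column `r_MPa_s_m3` appended.
#' @export
segment_resistances <- function(profile) {
  cfg <- profile_config(profile)
  check_positive(profile$d_um, "segment diameters")
  d_m <- profile$d_um * 1e-6
  profile$r_MPa_s_m3 <- 128 * cfg$eta * cfg$delta_l / (pi * d_m^4)
  profile
}

#' Water-potential and sap-tension profile along the path
#'
#' Total resistance `R = sum(r_i)`; Darcy flow
#' `Q = (psi_soil - psi_leaf) / R`; water potential at the proximal node of
#' segment i is `psi_i = psi_leaf + Q * cumsum(r)[i]`, rising monotonically
#' from `psi_leaf` at the tip boundary to exactly `psi_soil` at the base.
#' Sap tension is `P_i = |psi_i|`.
#'
#' @param profile A `path_profile` with resistances.
#' @return The profile with columns `psi_MPa` and `P_MPa` appended and
#'   attributes `R_total` and `Q`.
#' @export
water_potential_profile <- function(profile) {
  cfg <- profile_config(profile)
  if (is.null(profile$r_MPa_s_m3))
    profile <- segment_resistances(profile)
  R <- sum(profile$r_MPa_s_m3)
  if (R <= 0) stop_validation("total resistance must be positive")
  Q <- (cfg$psi_soil - cfg$psi_leaf) / R
  psi <- cfg$psi_leaf + Q * cumsum(profile$r_MPa_s_m3)
  profile$psi_MPa <- psi
  profile$P_MPa <- abs(psi)
  attr(profile, "R_total") <- R
  attr(profile, "Q") <- Q
  profile
}

#' Critical thickness-to-span ratio along the path
#'
#' Rearranging the rectangular-plate bending relation, the wall collapses
#' when `(t/b)^2` falls below `P * beta_bend / sigma`, so walls near the tip
#' (highest tension) need roughly three times the reinforcement of walls at
#' the base under the default water potentials. The exact endpoint values
#' are `|psi_leaf| * beta_bend / sigma` at the tip boundary and
#' `|psi_soil| * beta_bend / sigma` at the base, independent of `alpha`.
#'
#' @param profile A `path_profile`; missing upstream columns are computed.
#' @param sigma Optional modulus of rupture overriding the configured one
#'   (used for species-specific limits).
#' @return The profile with column `tb2_crit` appended and attributes
#'   `tb2_crit_tip` and `tb2_crit_base` (the exact boundary values).
#' @export
critical_limit_profile <- function(profile, sigma = NULL) {
  cfg <- profile_config(profile)
  if (is.null(profile$psi_MPa)) profile <- water_potential_profile(profile)
  s <- if (is.null(sigma)) cfg$sigma_rupture else
    check_scalar(sigma, "sigma", lower = 0, open_lower = TRUE)
  profile$tb2_crit <- profile$P_MPa * cfg$beta_bend / s
  attr(profile, "tb2_crit_tip") <- abs(cfg$psi_leaf) * cfg$beta_bend / s
  attr(profile, "tb2_crit_base") <- abs(cfg$psi_soil) * cfg$beta_bend / s
  profile
}

#' Full path profile in one call
#'
#' Convenience wrapper running [build_path_profile()],
#' [segment_resistances()], [water_potential_profile()] and
#' [critical_limit_profile()].
#'
#' @inheritParams build_path_profile
#' @return A complete `path_profile`.
#' @export
path_profile <- function(config = collapse_config()) {
  critical_limit_profile(water_potential_profile(segment_resistances(
    build_path_profile(config))))
}

# Interpolate the critical limit at arbitrary relative positions, using the
# exact tip boundary node (L_rel = 0, tension |psi_leaf|) plus the segment
# proximal nodes.
crit_at_L_rel <- function(profile, L_rel) {
  if (is.null(profile$tb2_crit))
    stop_validation("profile lacks tb2_crit; run critical_limit_profile()")
  xs <- c(0, profile$L_rel)
  ys <- c(attr(profile, "tb2_crit_tip"), profile$tb2_crit)
  stats::approx(xs, ys, xout = L_rel, rule = 2)$y
}

#' Collapse safety factors for measured conduits
#'
#' The safety factor of a conduit is its observed thickness-to-span ratio
#' divided by the critical ratio at its relative path position (interpolated
#' from the simulated profile; because the widening law is a pure power law,
#' the potential profile depends on position only through `L/H`, so one
#' profile serves trees of any height). Conduits with safety factor strictly
#' below 1 are flagged as predicted to collapse; a conduit exactly at the
#' limit counts as safe.
#'
#' @param records Conduit table; [conduit_metrics()] columns are computed if
#'   absent.
#' @param profile A complete `path_profile` (see [path_profile()]).
#' @return A `safety_assessment`: per-conduit data frame (`tb2`,
#'   `tb2_crit`, `safety_factor`, `collapse_flag`, `wood_type`, `organ`),
#'   plus summaries: `fraction_safe`, `median_safety`, `iqr_safety`, and
#'   breakdowns `by_wood_type` and `by_organ`.
#' @export
safety_factors <- function(records, profile) {
  if (!all(c("tb2", "L_rel") %in% names(records)))
    records <- conduit_metrics(records)
  if (any(!is.finite(records$L_rel) | records$L_rel < 0 |
          records$L_rel > 1))
    stop_validation("conduit L_rel outside [0, 1]")
  crit <- crit_at_L_rel(profile, records$L_rel)
  sf <- records$tb2 / crit
  per <- data.frame(organ = records$organ, wood_type = records$wood_type,
                    L_rel = records$L_rel, tb2 = records$tb2,
                    tb2_crit = crit, safety_factor = sf,
                    collapse_flag = sf < 1, stringsAsFactors = FALSE)
  summarize <- function(dat) {
    q <- stats::quantile(dat$safety_factor, c(0.25, 0.5, 0.75))
    data.frame(n = nrow(dat),
               n_collapse = sum(dat$collapse_flag),
               fraction_safe = mean(!dat$collapse_flag),
               median_safety = unname(q[2]),
               iqr_lower = unname(q[1]), iqr_upper = unname(q[3]))
  }
  by_group <- function(key) {
    groups <- split(per, per[[key]])
    out <- do.call(rbind, lapply(groups, summarize))
    out <- cbind(stats::setNames(data.frame(names(groups),
                                            stringsAsFactors = FALSE), key),
                 out)
    rownames(out) <- NULL
    out
  }
  overall <- summarize(per)
  structure(list(per_conduit = per,
                 fraction_safe = overall$fraction_safe,
                 n_collapse = overall$n_collapse,
                 median_safety = overall$median_safety,
                 iqr_safety = c(overall$iqr_lower, overall$iqr_upper),
                 by_wood_type = by_group("wood_type"),
                 by_organ = by_group("organ")),
            class = "safety_assessment")
}

#' @export
print.safety_assessment <- function(x, ...) {
  cat(sprintf("Collapse safety assessment: %d conduits, %.2f%% safe (%d flagged)\n",
              nrow(x$per_conduit), 100 * x$fraction_safe, x$n_collapse))
  cat(sprintf("  median safety factor %.2f (IQR %.2f to %.2f)\n",
              x$median_safety, x$iqr_safety[1], x$iqr_safety[2]))
  cat("  by wood type:\n")
  print(x$by_wood_type, row.names = FALSE)
  invisible(x)
}

#' Species-specific collapse limits and assessments
#'
#' Re-evaluates the critical limit with each species' own modulus of rupture
#' (the limit scales inversely with the modulus) and assesses each species'
#' conduits against its own profile.
#'
#' @param records Conduit table with a `species` column.
#' @param config A [collapse_config()]; its `species_sigma` field (or the
#'   `species_sigma` argument) must name every species present.
#' @param species_sigma Optional named vector overriding the configured map.
#' @return Named list of `safety_assessment` objects, one per species.
#' @export
species_specific_limits <- function(records, config = collapse_config(),
                                    species_sigma = NULL) {
  sig <- if (!is.null(species_sigma)) species_sigma else
    config$species_sigma
  if (is.null(sig))
    stop_validation("no species_sigma map supplied")
  present <- unique(records$species)
  missing <- setdiff(present, names(sig))
  if (length(missing))
    stop_validation("missing modulus of rupture for species: ",
                    paste(missing, collapse = ", "))
  base <- water_potential_profile(segment_resistances(
    build_path_profile(config)))
  out <- lapply(present, function(sp) {
    prof <- critical_limit_profile(base, sigma = sig[[sp]])
    safety_factors(records[records$species == sp, , drop = FALSE], prof)
  })
  names(out) <- present
  out
}
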