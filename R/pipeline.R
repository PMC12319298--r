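# End-to-end orchestration: ingest or generate a conduit table, derive
# metrics, run balanced scaling fits, simulate the collapse limit, assess
# safety, and write a reproducible report bundle.

#' Pipeline configuration
#'
#' @param input Either a path to a conduit CSV or a [taper_config()] (the
#'   default generates synthetic data).
#' @param outdir Output directory for the report bundle.
#' @param mode Resampling mode for the scaling fits.
#' @param n_iterations Iterations per balanced fit (NULL = mode default).
#' @param min_count,max_bins Binning constraints (see [plan_bins()]).
#' @param fit_specs Named list of per-relationship specifications; each
#'   element lists `organs` (subset of [organ_levels()]), `bin_var` and a
#'   [fit_spec()]. The default covers the three diameter relationships:
#'   conduit diameter vs path length through the shoot, and conduit
#'   diameter vs external diameter for stems and for roots.
#' @param collapse A [collapse_config()]; its `alpha` and `d0` are replaced
#'   by the fitted shoot values when available.
#' @param seed Root seed propagated to every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = taper_config(),
                            outdir = tempfile("xylemtaper-run-"),
                            mode = c("bootstrap", "subsample"),
                            n_iterations = NULL,
                            min_count = 100, max_bins = 30,
                            fit_specs = default_fit_specs(),
                            collapse = collapse_config(),
                            seed = 1) {
  mode <- match.arg(mode)
  if (is.character(input) && !file.exists(input))
    stop_validation("input file does not exist: ", input)
  structure(list(input = input, outdir = outdir, mode = mode,
                 n_iterations = n_iterations, min_count = min_count,
                 max_bins = max_bins, fit_specs = fit_specs,
                 collapse = collapse, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_fit_specs <- function() {
  list(
    shoots_d_vs_L = list(
      organs = c("leaf", "twig", "branch", "trunk"),
      bin_var = "L_m", spec = fit_spec("L_m", "d_um")),
    stems_d_vs_D = list(
      organs = c("twig", "branch", "trunk"),
      bin_var = "D_mm", spec = fit_spec("D_mm", "d_um")),
    roots_d_vs_D = list(
      organs = c("coarse_root", "fine_root", "very_fine_root"),
      bin_var = "D_mm", spec = fit_spec("D_mm", "d_um"))
  )
}

#' Validate a conduit CSV on disk
#'
#' Reads the file leniently (case-insensitive headers, no hard failure) and
#' reports every row-level schema violation.
#'
#' @param path CSV path.
#' @return A data frame of findings as in [conduit_findings()]; zero rows
#'   means the file is clean.
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop_validation("unreadable file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  canon <- c(MANDATORY_COLS, "wood_type")
  idx <- match(tolower(names(raw)), tolower(canon))
  names(raw)[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  for (col in intersect(NUMERIC_COLS, names(raw))) {
    if (!is.numeric(raw[[col]]))
      raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  conduit_findings(raw)
}

write_fit_csv <- function(fits, path) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(relationship = nm, method = toupper(f$spec$method),
               mode = f$mode,
               slope = f$aggregate_slope,
               ci_lower = f$aggregate_ci[1], ci_upper = f$aggregate_ci[2],
               intercept = f$aggregate_intercept,
               n_iterations = f$n_iterations,
               converged = f$converged,
               n_bins = length(f$plan$counts),
               n_min = f$plan$n_min, n_max = f$plan$n_max,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) load or generate and validate the conduit table;
#' (2) derive conduit metrics and organ summaries; (3) balanced SMA fits
#' with curvature checks and model comparison for each configured
#' relationship; (4) the exponential decay fit of `(t/b)^2` against `L/H`;
#' (5) collapse-limit simulation (using the fitted shoot exponent) and
#' safety assessment; (6) a machine-readable manifest (seed, config hash,
#' input hash, stage status). Any stage failure halts the run with the stage
#' name; outputs of completed stages are retained next to a `FAILED` marker.
#' Reruns with the same configuration and seed produce identical numeric
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the conduit table, organ summary, fits
#'   (`resample_outcome` objects), curvature and model-comparison results,
#'   the `tb2` decay fit, the path profile, the safety assessment and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  current <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("FAILED at stage:", current),
                 conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    stop("pipeline stage '", current, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    current <- "ingest"
    message("[", current, "] loading conduit table")
    records <- if (is.character(config$input)) {
      read_conduit_table(config$input)
    } else {
      generate_conduits(config$input)
    }
    validate_conduits(records)
    stages <- c(stages, current)

    current <- "metrics"
    message("[", current, "] deriving conduit metrics")
    records <- conduit_metrics(records)
    summary_tab <- organ_summary(records)
    utils::write.csv(summary_tab,
                     file.path(config$outdir, "organ_summary.csv"),
                     row.names = FALSE)
    stages <- c(stages, current)

    current <- "scaling_fits"
    message("[", current, "] balanced scaling fits")
    fits <- list(); curvature <- list(); comparisons <- list()
    spec_names <- names(config$fit_specs)
    for (k in seq_along(config$fit_specs)) {
      fs <- config$fit_specs[[k]]
      sub <- records[records$organ %in% fs$organs &
                     is.finite(records[[fs$spec$x_var]]), , drop = FALSE]
      out <- iterate_fit(sub, fs$bin_var, mode = config$mode,
                         spec = fs$spec,
                         n_iterations = config$n_iterations,
                         seed = child_seed(config$seed, k),
                         min_count = config$min_count,
                         max_bins = config$max_bins)
      fits[[spec_names[k]]] <- out
      # Curvature and functional-form comparison on one balanced dataset.
      bal <- bootstrap_balance(sub, out$plan,
                               seed = child_seed(config$seed, 100 + k))
      curvature[[spec_names[k]]] <-
        quadratic_curvature(bal[[fs$spec$x_var]], bal[[fs$spec$y_var]])
      comparisons[[spec_names[k]]] <-
        model_compare(bal[[fs$spec$x_var]], bal[[fs$spec$y_var]])
    }
    write_fit_csv(fits, file.path(config$outdir, "scaling_fits.csv"))
    stages <- c(stages, current)

    current <- "tb2_decay"
    message("[", current, "] thickness-to-span decay fit")
    decay <- tb2_decay_fit(records$tb2, records$L_rel)
    stages <- c(stages, current)

    current <- "collapse"
    message("[", current, "] collapse-limit simulation")
    ccfg <- config$collapse
    if ("shoots_d_vs_L" %in% names(fits)) {
      f <- fits$shoots_d_vs_L
      ccfg <- collapse_config(H = ccfg$H, delta_l = ccfg$delta_l,
                              alpha = max(0, f$aggregate_slope),
                              d0 = 10^f$aggregate_intercept,
                              eta = ccfg$eta, psi_leaf = ccfg$psi_leaf,
                              psi_soil = ccfg$psi_soil,
                              beta_bend = ccfg$beta_bend,
                              sigma_rupture = ccfg$sigma_rupture,
                              species_sigma = ccfg$species_sigma)
    }
    profile <- path_profile(ccfg)
    prof_out <- as.data.frame(profile)
    keep_every <- max(1L, floor(nrow(prof_out) / 2000))
    utils::write.csv(prof_out[seq(1, nrow(prof_out), by = keep_every), ],
                     file.path(config$outdir, "collapse_profile.csv"),
                     row.names = FALSE)
    assessment <- safety_factors(records, profile)
    utils::write.csv(assessment$by_organ,
                     file.path(config$outdir, "safety_by_organ.csv"),
                     row.names = FALSE)
    utils::write.csv(assessment$by_wood_type,
                     file.path(config$outdir, "safety_by_wood_type.csv"),
                     row.names = FALSE)
    stages <- c(stages, current)

    current <- "manifest"
    results <- list(
      seed = config$seed,
      mode = config$mode,
      n_records = nrow(records),
      fits = lapply(fits, function(f) list(
        slope = f$aggregate_slope, ci = f$aggregate_ci,
        intercept = f$aggregate_intercept, converged = f$converged)),
      curvature = lapply(curvature, function(q) q$coefficient),
      model_winner = lapply(comparisons, function(m) m$winner),
      tb2_decay = list(slope = decay$slope,
                       rate_natural_log = -decay$slope * log(10),
                       p = decay$p),
      collapse = list(alpha = ccfg$alpha,
                      tb2_crit_tip = attr(profile, "tb2_crit_tip"),
                      tb2_crit_base = attr(profile, "tb2_crit_base"),
                      fraction_safe = assessment$fraction_safe,
                      median_safety = assessment$median_safety))
    jsonlite::write_json(results,
                         file.path(config$outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_file <- file.path(config$outdir, "config.dput")
    dput(unclass_deep(config), file = cfg_file)
    input_hash <- if (is.character(config$input))
      unname(tools::md5sum(config$input)) else NA_character_
    manifest <- list(package = "xylemtaper",
                     version = as.character(utils::packageVersion(
                       "xylemtaper")),
                     r_version = R.version.string,
                     seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_file)),
                     input = if (is.character(config$input)) config$input
                             else "synthetic",
                     input_hash = input_hash,
                     stages_complete = c(stages, "manifest"))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(records = records, organ_summary = summary_tab,
                   fits = fits, curvature = curvature,
                   model_comparisons = comparisons, tb2_decay = decay,
                   profile = profile, assessment = assessment,
                   manifest = manifest, outdir = config$outdir))
  }, error = on_fail)
}

# Strip classes recursively so dput() output is plain and stable.
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
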