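# Conduit-level anatomy metrics: thickness-to-span ratio, Mork's index,
# hydraulic diameter, organ summaries.

#' Thickness-to-span ratio of a conduit wall
#'
#' Computes `(t/b)^2`, the squared ratio of the double wall thickness to the
#' lumen span, which quantifies the resistance of a conduit wall to bending
#' collapse. Following standard practice, the *smallest* of the four measured
#' single walls (two radial, two tangential) is used, since that wall is the
#' one most susceptible to collapse; the double wall thickness is twice the
#' single wall. The span paired with the minimum wall is taken as the lumen
#' diameter (circular-equivalent), not a direction-specific chord.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param wall_rad1,wall_rad2 Radial single-wall thicknesses (um).
#' @param wall_tan1,wall_tan2 Tangential single-wall thicknesses (um).
#' @param span Lumen span `b` (um), normally the lumen diameter `d`.
#' @return Numeric vector of `(t/b)^2` values (dimensionless, > 0).
#' @examples
#' thickness_to_span(1, 1, 1, 1, span = 20)       # (2/20)^2 = 0.01
#' thickness_to_span(1.5, 1.6, 1.0, 1.1, span = 10) # min wall 1.0 -> 0.04
#' @export
thickness_to_span <- function(wall_rad1, wall_rad2, wall_tan1, wall_tan2,
                              span) {
  walls <- cbind(wall_rad1, wall_rad2, wall_tan1, wall_tan2)
  check_positive(as.numeric(walls), "wall thicknesses")
  check_positive(span, "span")
  t_double <- 2 * do.call(pmin, as.data.frame(walls))
  (t_double / span)^2
}

#' Mork's index and wood-type classification
#'
#' Mork's index `M = 4 * x_tan / d_rad`, where `x_tan` is the mean tangential
#' single-wall thickness and `d_rad` the radial lumen diameter. The factor of
#' 4 accounts for the duality and double thickness of adjacent cell walls.
#' Cells with `M > 1` are classified as latewood; `M <= 1` (including the
#' boundary) as earlywood. Tangential rather than radial wall thickness is
#' used because the latter is sensitive to sectioning artifacts such as pit
#' chamber widening.
#'
#' @param x_tan Mean tangential single-wall thickness (um), vectorized.
#' @param d_rad Radial lumen diameter (um), vectorized.
#' @return Numeric vector of Mork's index values.
#' @seealso [classify_wood_type()]
#' @examples
#' mork_index(1, 4)   # 1.0 -> earlywood (boundary)
#' mork_index(2, 4)   # 2.0 -> latewood
#' @export
mork_index <- function(x_tan, d_rad) {
  check_positive(x_tan, "x_tan")
  check_positive(d_rad, "d_rad")
  4 * x_tan / d_rad
}

#' @rdname mork_index
#' @param M Mork's index values as returned by [mork_index()].
#' @return `classify_wood_type()` returns a character vector with values
#'   `"latewood"` (`M > 1`) or `"earlywood"` (`M <= 1`).
#' @export
classify_wood_type <- function(M) {
  ifelse(M > 1, "latewood", "earlywood")
}

#' Hydraulic diameter of a set of conduits
#'
#' Conductivity-weighted mean lumen diameter `d_h = sum(d^5) / sum(d^4)`.
#' Unlike the arithmetic mean, `d_h` weights wide (earlywood) conduits more
#' heavily, reflecting their disproportionate contribution to hydraulic
#' conductivity. It always satisfies `mean(d) <= d_h <= max(d)`.
#'
#' @param d Positive conduit diameters (um).
#' @return A single hydraulic diameter (um).
#' @examples
#' hydraulic_diameter(c(10, 10, 10))  # 10
#' hydraulic_diameter(c(1, 2))        # 33/17
#' @export
hydraulic_diameter <- function(d) {
  check_positive(d, "d")
  sum(d^5) / sum(d^4)
}

#' Derive per-conduit metrics for a conduit table
#'
#' Adds the derived columns `tb2` (thickness-to-span ratio), `mork_M`,
#' `wood_type` and `L_rel = L/H` (relative path position) to a conduit table.
#' An existing `wood_type` column is overwritten so that the classification
#' is always consistent with Mork's index. The tangential wall thickness used
#' for Mork's index is the mean of the two tangential single walls.
#'
#' @param records Conduit table as produced by [generate_conduits()] or
#'   [read_conduit_table()].
#' @return The input data frame with columns `tb2`, `mork_M`, `wood_type`,
#'   `L_rel` appended.
#' @export
conduit_metrics <- function(records) {
  validate_conduits(records)
  records$tb2 <- thickness_to_span(records$wall_rad1_um, records$wall_rad2_um,
                                   records$wall_tan1_um, records$wall_tan2_um,
                                   span = records$d_um)
  x_tan <- (records$wall_tan1_um + records$wall_tan2_um) / 2
  records$mork_M <- mork_index(x_tan, records$d_rad_um)
  records$wood_type <- classify_wood_type(records$mork_M)
  records$L_rel <- records$L_m / records$H_m
  records
}

#' Per-organ summary of conduit diameters and wall reinforcement
#'
#' One row per organ class present in the data, in axial order from leaf to
#' very fine root. Organ classes with no records are omitted. Counts sum to
#' the number of input records.
#'
#' @param records Conduit table; derived metrics are computed if absent.
#' @return Data frame with columns `organ`, `n`, `mean_d_um`, `median_d_um`,
#'   `hydraulic_d_um`, `mean_tb2`, `median_tb2`, `n_earlywood`, `n_latewood`.
#' @export
organ_summary <- function(records) {
  if (!all(c("tb2", "mork_M") %in% names(records)))
    records <- conduit_metrics(records)
  organs <- ORGAN_LEVELS[ORGAN_LEVELS %in% unique(records$organ)]
  rows <- lapply(organs, function(org) {
    sub <- records[records$organ == org, , drop = FALSE]
    data.frame(
      organ = org,
      n = nrow(sub),
      mean_d_um = mean(sub$d_um),
      median_d_um = stats::median(sub$d_um),
      hydraulic_d_um = hydraulic_diameter(sub$d_um),
      mean_tb2 = mean(sub$tb2),
      median_tb2 = stats::median(sub$tb2),
      n_earlywood = sum(sub$wood_type == "earlywood"),
      n_latewood = sum(sub$wood_type == "latewood"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
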