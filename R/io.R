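# Reading, writing and validating conduit tables (CSV, UTF-8, "." decimal).

MANDATORY_COLS <- c("species", "tree_id", "organ", "sample_id", "L_m",
                    "H_m", "D_mm", "d_um", "d_rad_um", "wall_rad1_um",
                    "wall_rad2_um", "wall_tan1_um", "wall_tan2_um")
NUMERIC_COLS <- c("L_m", "H_m", "D_mm", "d_um", "d_rad_um", "wall_rad1_um",
                  "wall_rad2_um", "wall_tan1_um", "wall_tan2_um")

#' Row-level validation findings for a conduit table
#'
#' Checks every row of a conduit table against the schema invariants:
#' numeric measurement fields, positive diameters and wall thicknesses,
#' `0 < L <= H`, and organ labels drawn from [organ_levels()]. `D_mm` may be
#' missing (leaves carry no external diameter) but must be positive where
#' present.
#'
#' @param records Data frame to check.
#' @return Data frame of findings with columns `row`, `column`, `issue`;
#'   zero rows for a clean table.
#' @export
conduit_findings <- function(records) {
  findings <- list()
  note <- function(row, column, issue) {
    findings[[length(findings) + 1L]] <<- data.frame(
      row = row, column = column, issue = issue, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_cols)) {
    note(NA_integer_, paste(missing_cols, collapse = ","),
         "mandatory column missing")
    return(do.call(rbind, findings))
  }
  for (col in NUMERIC_COLS) {
    if (!is.numeric(records[[col]])) {
      note(NA_integer_, col, "non-numeric measurement column")
    }
  }
  if (length(findings)) return(do.call(rbind, findings))

  bad_organ <- which(!(records$organ %in% ORGAN_LEVELS))
  for (r in bad_organ) note(r, "organ",
                            paste0("unknown organ label '",
                                   records$organ[r], "'"))
  pos_cols <- setdiff(NUMERIC_COLS, c("D_mm", "H_m"))
  for (col in pos_cols) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    for (r in bad) note(r, col, "non-positive or missing measurement")
  }
  bad_D <- which(!is.na(records$D_mm) &
                 (!is.finite(records$D_mm) | records$D_mm <= 0))
  for (r in bad_D) note(r, "D_mm", "non-positive external diameter")
  bad_H <- which(!is.finite(records$H_m) | records$H_m <= 0)
  for (r in bad_H) note(r, "H_m", "non-positive total path length")
  bad_L <- which(is.finite(records$L_m) & is.finite(records$H_m) &
                 records$L_m > records$H_m)
  for (r in bad_L) note(r, "L_m", "L exceeds total path length H")
  if (length(findings) == 0L)
    return(data.frame(row = integer(0), column = character(0),
                      issue = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, findings)
  out[order(out$row), , drop = FALSE]
}

#' Validate a conduit table, stopping on the first problem
#'
#' @param records Data frame to check.
#' @return The input, invisibly, if valid; otherwise a validation error
#'   naming the first offending row and column.
#' @export
validate_conduits <- function(records) {
  f <- conduit_findings(records)
  if (nrow(f) > 0L) {
    stop_validation("invalid conduit table: ", f$issue[1L], " (row ",
                    f$row[1L], ", column ", f$column[1L], "); ",
                    nrow(f), " finding(s) in total")
  }
  invisible(records)
}

#' Write a conduit table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every double exactly.
#'
#' @param records Conduit table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conduit_table <- function(records, path) {
  validate_conduits(records)
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.17g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a conduit table from CSV
#'
#' Headers are matched case-insensitively against the canonical schema and
#' normalized. Unknown extra columns are preserved untouched after the
#' canonical columns. A missing `wood_type` column is recomputed from Mork's
#' index. Rows violating the schema invariants raise a row-indexed
#' validation error.
#'
#' @param path CSV file path.
#' @return Conduit table data frame.
#' @export
read_conduit_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  canon <- c(MANDATORY_COLS, "wood_type")
  idx <- match(tolower(names(raw)), tolower(canon))
  names(raw)[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  for (col in intersect(NUMERIC_COLS, names(raw))) {
    if (!is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(raw[[col]]))
      introduced <- which(is.na(coerced) & !is.na(raw[[col]]) &
                          raw[[col]] != "")
      if (length(introduced))
        stop_validation("non-numeric value in column ", col, " at row ",
                        introduced[1L])
      raw[[col]] <- coerced
    }
  }
  validate_conduits(raw)
  if (!"wood_type" %in% names(raw)) {
    x_tan <- (raw$wall_tan1_um + raw$wall_tan2_um) / 2
    raw$wood_type <- classify_wood_type(mork_index(x_tan, raw$d_rad_um))
  }
  extras <- setdiff(names(raw), canon)
  raw[, c(canon, extras), drop = FALSE]
}
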