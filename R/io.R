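#' Construct / validate a peak-intensity table
#'
#' The canonical container for peak intensities from 1H-15N correlation
#' spectra. Columns: residue_id (character), field_mhz, temp_k, condition
#' ("reference" for the zero-delay I0 row, "cpmg" for dispersion points, or
#' a free tag for relaxation series), nu_cpmg_hz (NA on reference rows) and
#' intensity. Exactly one reference row is required per
#' residue/field/temperature group containing cpmg rows, and reference
#' intensities must be positive.
#'
#' @param df data frame with the columns above
#' @return the validated table, classed \code{peak_intensity_table}
#' @export
peak_intensity_table <- function(df) {
  validate_peak_table(df)
}

validate_peak_table <- function(df) {
  need <- c("residue_id", "field_mhz", "temp_k", "condition",
            "nu_cpmg_hz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table missing required column(s): ",
         paste(miss, collapse = ", "))
  df$residue_id <- as.character(df$residue_id)
  ref <- df$condition == "reference"
  if (any(ref & (!is.finite(df$intensity) | df$intensity <= 0)))
    stop("reference (I0) intensities must be strictly positive")
  grp <- interaction(df$residue_id, df$field_mhz, df$temp_k, drop = TRUE)
  nref <- tapply(ref, grp, sum)
  has_cpmg <- tapply(df$condition == "cpmg", grp, any)
  bad <- names(nref)[has_cpmg & nref != 1L]
  if (length(bad))
    stop("peak table groups without exactly one reference row: ",
         paste(head(bad, 5), collapse = "; "))
  class(df) <- unique(c("peak_intensity_table", class(df)))
  df
}

#' Write / read the peak-intensity CSV
#'
#' Comma-separated, "." decimal, UTF-8, header row; columns as in
#' [peak_intensity_table()]. Reading validates row by row and reports the
#' offending line number (header is line 1).
#'
#' @param table a peak-intensity table
#' @param path file path
#' @return \code{read_peak_table} returns a validated
#'   \code{peak_intensity_table}
#' @export
write_peak_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_id", "field_mhz", "temp_k", "condition",
            "nu_cpmg_hz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$intensity) |
                 (df$condition == "reference" & df$intensity <= 0) |
                 (df$condition != "reference" & df$intensity < 0))
  if (length(bad))
    stop("invalid intensity in '", path, "' on line ", bad[1] + 1L,
         " (value ", df$intensity[bad[1]], ")")
  peak_intensity_table(df)
}

#' Write / read chemical-shift series CSV
#'
#' Columns: residue_id, axis_value (temperature in K or ligand
#' concentration in M), h_ppm, n_ppm.
#'
#' @param df data frame with those columns
#' @param path file path
#' @export
write_shift_table <- function(df, path) {
  need <- c("residue_id", "axis_value", "h_ppm", "n_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("shift table missing: ",
                         paste(miss, collapse = ", "))
  write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_id", "axis_value", "h_ppm", "n_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("'", path, "' missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$axis_value))
  if (length(bad))
    stop("non-numeric axis_value in '", path, "' on line ", bad[1] + 1L)
  df
}

#' Export dispersion curves as CSV
#'
#' Columns: residue_id, field_mhz, temp_k, nu_cpmg_hz, r2eff, r2eff_err.
#' @param dataset a \code{dispersion_dataset}
#' @param path file path
#' @export
write_dispersion_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @export
read_dispersion_csv <- function(path) {
  dispersion_dataset(read.csv(path, stringsAsFactors = FALSE))
}
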