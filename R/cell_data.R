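# Gridded cell-table handling: validation, filtering, derived variables,
# hemisphere splits and standardization.

# climate columns required after derivation; AET is kept but never used as
# a predictor (it mixes water and energy), WD = PET - AET stands in for it
.climate_required <- c("AP", "MPDM", "MAT", "MTCM", "PET")
.core_columns <- c("cell_id", "lat_deg", "lon_deg", "land_fraction",
                   "richness", .climate_required)

#' Water and energy predictor sets
#'
#' The two candidate predictor sets: water (annual precipitation `AP`,
#' minimum precipitation of the driest month `MPDM`, water deficit
#' `WD = PET - AET`) and energy (mean annual temperature `MAT`, minimum
#' temperature of the coldest month `MTCM`, potential evapotranspiration
#' `PET`), plus their union as `"combined"`.
#'
#' @param name one of `"water"`, `"energy"`, `"combined"`.
#' @return An object of class `variable_set`: a list with `name` and the
#'   ordered character vector `members`.
#' @examples
#' variable_set("water")$members
#' @export
variable_set <- function(name = c("water", "energy", "combined")) {
  name <- match.arg(name)
  members <- switch(name,
    water = c("AP", "MPDM", "WD"),
    energy = c("MAT", "MTCM", "PET"),
    combined = c("AP", "MPDM", "WD", "MAT", "MTCM", "PET"))
  structure(list(name = name, members = members), class = "variable_set")
}

#' @export
print.variable_set <- function(x, ...) {
  cat("Variable set '", x$name, "': ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.members <- function(predictors) {
  if (inherits(predictors, "variable_set")) predictors$members
  else as.character(predictors)
}

#' Validate a data frame as a cell table
#'
#' Checks the schema of a gridded cell table: required columns present and
#' numeric, latitudes within \[-90, 90\], land fractions within \[0, 1\],
#' richness a non-negative integer, and cell ids / coordinate pairs unique.
#' `AET` or a pre-derived `WD` column must be present so that water deficit
#' is available downstream.
#'
#' @param x a data frame.
#' @param require_richness set `FALSE` for climate-only tables (e.g. the
#'   output of [generate_cells()] before richness is attached).
#' @return `x` with class `cell_table` prepended; row order preserved.
#' @export
as_cell_table <- function(x, require_richness = TRUE) {
  stopifnot(is.data.frame(x))
  needed <- .core_columns
  if (!require_richness) needed <- setdiff(needed, "richness")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("AET" %in% names(x)) && !("WD" %in% names(x))) {
    stop("cell table needs either 'AET' (to derive WD) or a 'WD' column",
         call. = FALSE)
  }
  num_cols <- setdiff(intersect(c(needed, "AET", "WD"), names(x)), "cell_id")
  for (cl in num_cols) {
    if (!is.numeric(x[[cl]])) {
      stop("column '", cl, "' must be numeric", call. = FALSE)
    }
  }
  bad_lat <- which(is.na(x$lat_deg) | abs(x$lat_deg) > 90)
  if (length(bad_lat) > 0) {
    stop("latitude out of [-90, 90] (or missing) in row(s): ",
         paste(utils::head(bad_lat, 5), collapse = ", "), call. = FALSE)
  }
  bad_lon <- which(is.na(x$lon_deg) | abs(x$lon_deg) > 360)
  if (length(bad_lon) > 0) {
    stop("longitude missing or out of range in row(s): ",
         paste(utils::head(bad_lon, 5), collapse = ", "), call. = FALSE)
  }
  bad_land <- which(!is.na(x$land_fraction) &
                      (x$land_fraction < 0 | x$land_fraction > 1))
  if (length(bad_land) > 0) {
    stop("land_fraction outside [0, 1] in row(s): ",
         paste(utils::head(bad_land, 5), collapse = ", "), call. = FALSE)
  }
  if ("richness" %in% names(x) && require_richness) {
    r <- x$richness
    bad_rich <- which(is.na(r) | r < 0 | r != round(r))
    if (length(bad_rich) > 0) {
      stop("richness must be a non-negative integer; offending row(s): ",
           paste(utils::head(bad_rich, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(x$cell_id)) {
    stop("duplicate cell_id value(s): ",
         paste(utils::head(unique(x$cell_id[duplicated(x$cell_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x[c("lat_deg", "lon_deg")])) {
    stop("duplicate (lat_deg, lon_deg) coordinate pair(s)", call. = FALSE)
  }
  class(x) <- unique(c("cell_table", class(x)))
  x
}

#' Read a cell table from CSV
#'
#' Reads a UTF-8 CSV with one row per grid cell (columns `cell_id`,
#' `lat_deg`, `lon_deg`, `land_fraction`, `richness`, `AP`, `MPDM`, `MAT`,
#' `MTCM`, `PET`, `AET`; missing values as empty fields or `NA`) and
#' validates it with [as_cell_table()].
#'
#' @param path path to the CSV file.
#' @return A validated `cell_table`, row order preserved.
#' @export
load_cell_table <- function(path) {
  x <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  as_cell_table(x)
}

#' Write a cell table to CSV
#'
#' @param x a `cell_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Filter cells by land fraction and climate completeness
#'
#' Removes cells with less than `min_land` land surface (strictly less:
#' a cell at exactly the threshold is retained) and cells with any missing
#' climate value, the two exclusion rules applied to the gridded richness
#' data before analysis.  Removal counts are attached as the
#' `filter_report` attribute and can be exported with
#' [write_filter_report()].
#'
#' @param x a `cell_table`.
#' @param min_land land-fraction threshold (default 0.25, i.e. 25%).
#' @return The filtered `cell_table`; errors if nothing survives.
#' @export
filter_cells <- function(x, min_land = 0.25) {
  stopifnot(inherits(x, "cell_table"))
  n_input <- nrow(x)
  low_land <- !is.na(x$land_fraction) & x$land_fraction < min_land
  low_land[is.na(x$land_fraction)] <- TRUE
  clim_cols <- intersect(c(.climate_required, "AET", "WD"), names(x))
  clim <- as.data.frame(x)[clim_cols]
  missing_clim <- rowSums(is.na(clim)) > 0
  drop <- low_land | missing_clim
  out <- x[!drop, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no cells remain after filtering (", n_input, " removed)",
         call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    n_input = n_input,
    n_low_land = sum(low_land),
    n_missing_climate = sum(missing_clim & !low_land),
    n_kept = nrow(out),
    min_land = min_land)
  out
}

#' Export the cell-exclusion report as JSON
#'
#' @param x a filtered `cell_table` (output of [filter_cells()]).
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) stop("no filter_report attribute; run filter_cells() first")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Derive water deficit WD = PET - AET
#'
#' Adds the drought index `WD` (same units as `PET`/`AET`, mm/yr) as
#' potential minus actual evapotranspiration.  `AET` is retained in the
#' table but is never used as a predictor, since it reflects both water
#' and energy.  Negative values (possible as an aggregation artifact of
#' averaging the two surfaces separately) are permitted with a warning.
#'
#' @param x a `cell_table` containing `PET` and `AET`.
#' @return The table with a `WD` column added (or recomputed).
#' @export
derive_water_deficit <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  if (!all(c("PET", "AET") %in% names(x))) {
    stop("deriving WD requires both 'PET' and 'AET' columns", call. = FALSE)
  }
  wd <- x$PET - x$AET
  n_neg <- sum(wd < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " cell(s) have AET > PET; negative WD retained",
            call. = FALSE)
  }
  x$WD <- wd
  x
}

#' Standardize to zero mean and unit sample standard deviation
#'
#' Centers and scales using the sample (n - 1 denominator) standard
#' deviation, the convention used throughout the latitudinal-trend
#' regressions so that slopes are comparable across responses.
#'
#' @param x numeric vector, length at least 2, non-constant.
#' @return The standardized vector.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("zscore needs at least 2 values", call. = FALSE)
  if (anyNA(x)) stop("zscore input contains missing values", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zscore input is constant; standard deviation is zero",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Split a cell table into hemispheres
#'
#' Partitions by cell-center latitude.  Cells at exactly 0 degrees go
#' north by convention; with 1-degree cells centered at half-degree
#' latitudes the boundary case does not arise on regular grids.
#'
#' @param x a `cell_table`.
#' @return A list with components `north` (`lat_deg >= 0`) and `south`
#'   (`lat_deg < 0`); their union is the input.
#' @export
split_hemispheres <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  north <- x[x$lat_deg >= 0, , drop = FALSE]
  south <- x[x$lat_deg < 0, , drop = FALSE]
  rownames(north) <- NULL
  rownames(south) <- NULL
  list(north = north, south = south)
}
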