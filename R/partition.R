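# Per-cell variation partitioning of local explained variance.

#' Partition local explained variance into pure and shared fractions
#'
#' For each cell, the local R^2 of the combined model (`R_t`) is split
#' against the water-only (`R_w`) and energy-only (`R_e`) local R^2:
#' pure energy `R_pe = R_t - R_w`, pure water `R_pw = R_t - R_e`, and the
#' shared fraction `R_w + R_e - R_t`.  Because the three fits are nested
#' weighted least-squares problems sharing the same per-cell weights, the
#' pure fractions are non-negative up to floating-point error; values in
#' `(-1e-9, 0)` are clamped to zero (the shared fraction is then
#' recomputed so the identity `R_pw + R_pe + shared = R_t` holds exactly),
#' while anything below `-1e-9` signals an internal inconsistency and
#' raises an error.
#'
#' @param fit_water,fit_energy,fit_combined `gwr_fit`s over the same cells
#'   with the same kernel; the combined predictors must contain both the
#'   water and energy predictors.
#' @return A data frame of class `partition_table`: `cell_id`, `lat_deg`,
#'   `lon_deg`, `R_w`, `R_e`, `R_t`, `R_pw`, `R_pe`, `shared`.  Cells
#'   unreliable in any of the three fits carry `NA` throughout.  The
#'   kernel is attached as attribute `kernel`.
#' @export
partition_local <- function(fit_water, fit_energy, fit_combined) {
  for (f in list(fit_water, fit_energy, fit_combined)) {
    stopifnot(inherits(f, "gwr_fit"))
  }
  ids <- fit_combined$locals$cell_id
  if (!identical(fit_water$locals$cell_id, ids) ||
      !identical(fit_energy$locals$cell_id, ids)) {
    stop("the three fits must cover the same cells in the same order",
         call. = FALSE)
  }
  kc <- fit_combined$kernel
  for (f in list(fit_water, fit_energy)) {
    if (!identical(f$kernel$family, kc$family) ||
        !identical(f$kernel$bandwidth_km, kc$bandwidth_km)) {
      stop("kernel mismatch between fits", call. = FALSE)
    }
  }
  if (!all(fit_water$predictors %in% fit_combined$predictors) ||
      !all(fit_energy$predictors %in% fit_combined$predictors)) {
    stop("combined model must nest the water and energy predictor sets",
         call. = FALSE)
  }
  R_w <- fit_water$locals$local_R2
  R_e <- fit_energy$locals$local_R2
  R_t <- fit_combined$locals$local_R2
  ok <- fit_water$locals$reliable & fit_energy$locals$reliable &
    fit_combined$locals$reliable & !is.na(R_w) & !is.na(R_e) & !is.na(R_t)
  R_w[!ok] <- NA_real_; R_e[!ok] <- NA_real_; R_t[!ok] <- NA_real_
  R_pw <- R_t - R_e
  R_pe <- R_t - R_w
  neg <- pmin(R_pw, R_pe, na.rm = FALSE)
  bad <- which(!is.na(neg) & neg < -1e-9)
  if (length(bad) > 0) {
    stop("negative pure fraction beyond tolerance at cell(s) ",
         paste(utils::head(ids[bad], 5), collapse = ", "),
         " (min ", signif(min(neg[bad]), 4),
         "): nested local fits are inconsistent", call. = FALSE)
  }
  R_pw <- pmax(R_pw, 0)
  R_pe <- pmax(R_pe, 0)
  shared <- R_t - R_pw - R_pe
  out <- data.frame(cell_id = ids,
                    lat_deg = fit_combined$locals$lat_deg,
                    lon_deg = fit_combined$locals$lon_deg,
                    R_w = R_w, R_e = R_e, R_t = R_t,
                    R_pw = R_pw, R_pe = R_pe, shared = shared)
  attr(out, "kernel") <- kc
  class(out) <- c("partition_table", "data.frame")
  out
}

#' Write a partition table to CSV
#'
#' @param x a `partition_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}
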