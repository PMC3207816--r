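# Great-circle distances, the two fixed spatial kernels, and the weight
# structures shared by GWR and the spatial-lag SAR models.

.EARTH_RADIUS_KM <- 6371.0

#' Specify a spatial kernel
#'
#' A fixed (non-adaptive) kernel: either the bi-square function, a
#' continuous near-Gaussian taper `(1 - (d/b)^2)^2` reaching zero at the
#' bandwidth `b`, or the moving window, which weights all cells within the
#' bandwidth equally.  The same kernel is used to weight the local GWR
#' fits and to build the SAR neighborhood, so the spatial scale of the two
#' analyses matches.
#'
#' @param family `"bisquare"` or `"moving_window"`.
#' @param bandwidth_km positive bandwidth `b` in km (1200 and 1800 km are
#'   the scales used for 1-degree richness grids spanning ~10,000 km).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("bisquare", 1200)
#' @export
kernel_spec <- function(family = c("bisquare", "moving_window"),
                        bandwidth_km) {
  family <- match.arg(family)
  if (!is.numeric(bandwidth_km) || length(bandwidth_km) != 1 ||
      !is.finite(bandwidth_km) || bandwidth_km <= 0) {
    stop("bandwidth_km must be a single positive number", call. = FALSE)
  }
  structure(list(family = family, bandwidth_km = as.numeric(bandwidth_km)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Spatial kernel: ", x$family, ", bandwidth ", x$bandwidth_km,
      " km\n", sep = "")
  invisible(x)
}

#' @export
format.kernel_spec <- function(x, ...) {
  paste0(x$family, "_", format(x$bandwidth_km, trim = TRUE))
}

#' Great-circle (haversine) distance in km
#'
#' Haversine distance on a sphere of radius 6371 km; vectorized and
#' symmetric.  One degree of longitude at the equator is about 111.19 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (!all(is.finite(lat1), is.finite(lon1), is.finite(lat2),
           is.finite(lon2))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90)) {
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  }
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Pairwise great-circle distance matrix
#'
#' @param lat,lon coordinate vectors in degrees (equal length).
#' @return A symmetric `n x n` matrix of distances in km with zero
#'   diagonal.
#' @export
distance_matrix_km <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  if (!all(is.finite(lat), is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  rad <- pi / 180
  phi <- lat * rad
  lam <- lon * rad
  sdlat <- sin(outer(phi, phi, "-") / 2)^2
  sdlon <- sin(outer(lam, lam, "-") / 2)^2
  a <- sdlat + outer(cos(phi), cos(phi)) * sdlon
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * .EARTH_RADIUS_KM * asin(sqrt(a))
  diag(d) <- 0
  d
}

#' Evaluate a kernel weight
#'
#' Bi-square: `(1 - (d/b)^2)^2` for `d < b`, zero beyond (the taper is
#' already zero at `d = b`).  Moving window: 1 for `d <= b` (boundary
#' inclusive), zero beyond.
#'
#' @param d_km non-negative distance(s) in km.
#' @param spec a [kernel_spec()].
#' @return Weight(s) in \[0, 1\].
#' @examples
#' kernel_weight(600, kernel_spec("bisquare", 1200))
#' @export
kernel_weight <- function(d_km, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (any(d_km < 0)) stop("distances must be non-negative", call. = FALSE)
  b <- spec$bandwidth_km
  if (spec$family == "bisquare") {
    w <- ifelse(d_km < b, (1 - (d_km / b)^2)^2, 0)
  } else {
    w <- ifelse(d_km <= b, 1, 0)
  }
  w
}

#' Build a spatial weight structure
#'
#' Pairwise kernel weights from great-circle distances between cell
#' centers.  GWR uses raw weights including the focal cell (weight 1 at
#' distance 0); the SAR models use a zero-diagonal, row-standardized
#' matrix, the dominant convention for spatial-lag models (it bounds the
#' upper end of the autoregressive-parameter search interval at 1).
#'
#' @param cells a `cell_table` (or any data frame with `lat_deg`,
#'   `lon_deg`).
#' @param spec a [kernel_spec()].
#' @param include_self keep the diagonal (weight at distance 0)?
#' @param row_standardize divide each row by its sum?  Errors if any row
#'   has no neighbor (bandwidth too small for the grid).
#' @param distances optional precomputed distance matrix (km), e.g. from
#'   [distance_matrix_km()], reused across kernels on the same grid.
#' @return An object of class `spatial_weights`: list with the `n x n`
#'   matrix `W`, `n`, the kernel, the two flags, pre-standardization row
#'   sums (for the symmetric eigenvalue computation) and the cell ids.
#' @export
build_weights <- function(cells, spec, include_self = FALSE,
                          row_standardize = FALSE, distances = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  n <- nrow(cells)
  if (is.null(n) || n < 2) stop("need at least 2 cells", call. = FALSE)
  D <- if (is.null(distances)) {
    distance_matrix_km(cells$lat_deg, cells$lon_deg)
  } else {
    stopifnot(nrow(distances) == n, ncol(distances) == n)
    distances
  }
  W <- kernel_weight(D, spec)
  if (!include_self) diag(W) <- 0
  row_sums <- rowSums(W)
  if (row_standardize) {
    empty <- which(row_sums == 0)
    if (length(empty) > 0) {
      stop(length(empty), " cell(s) have no neighbor within the ",
           spec$bandwidth_km, " km bandwidth (first: row ", empty[1],
           "); widen the bandwidth", call. = FALSE)
    }
    W <- W / row_sums
  }
  structure(list(W = W, n = n, kernel = spec,
                 include_self = include_self,
                 row_standardized = row_standardize,
                 row_sums = row_sums,
                 cell_id = cells$cell_id),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights: ", x$n, " cells, kernel ", format(x$kernel),
      if (x$row_standardized) ", row-standardized" else "",
      if (x$include_self) ", self included" else ", zero diagonal",
      "\n", sep = "")
  invisible(x)
}

#' Export non-zero weights as an edge list
#'
#' @param w a `spatial_weights` object.
#' @return A data frame with columns `i`, `j`, `w` (1-based indices, only
#'   non-zero entries).
#' @export
weights_edge_list <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  idx <- which(w$W != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = w$W[idx])
}
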