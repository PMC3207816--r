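# Moran's I and distance-band correlograms of local GWR results.

#' Moran's I
#'
#' The classical global autocorrelation statistic
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the centered values and
#' `S0` the sum of all weights.  The diagonal of the weight matrix must be
#' zero.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @param weights a `spatial_weights` object or a plain `n x n` matrix of
#'   non-negative weights with zero diagonal.
#' @return The Moran's I statistic.
#' @export
morans_i <- function(values, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else as.matrix(weights)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Moran's I needs at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (any(diag(W) != 0)) {
    stop("weight matrix must have a zero diagonal", call. = FALSE)
  }
  s0 <- sum(W)
  if (s0 <= 0) stop("all weights are zero", call. = FALSE)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("values are constant", call. = FALSE)
  (n / s0) * drop(crossprod(z, W %*% z)) / denom
}

#' Moran's I correlogram over distance bands
#'
#' Computes Moran's I per distance band using binary weights: a pair
#' `(i, j)`, `i != j`, enters band `[lo, hi)` when `lo <= d_ij < hi`
#' (the last band is right-closed so exhaustive bands cover every pair).
#' An optional permutation test shuffles the values over the cells and
#' reports a two-sided p-value per band, centered on the permutation
#' mean.  Used on local GWR output surfaces, the correlogram shows the
#' inherent autocorrelation that the overlapping local datasets create
#' and that motivates evaluating latitudinal trends with SAR models.
#'
#' @param values numeric vector aligned with `cells`.
#' @param cells a `cell_table` (or data frame with `lat_deg`, `lon_deg`).
#' @param bin_edges ascending distance-band edges in km; default 10
#'   equal-width bands up to the maximum pairwise distance.
#' @param n_bins number of default bands when `bin_edges` is `NULL`.
#' @param n_permutations permutations for the optional test (0 = off).
#' @param distances optional precomputed distance matrix in km.
#' @return A data frame of class `correlogram`: `bin_lo`, `bin_hi`,
#'   `morans_i`, `pairs` (ordered pair count), and `p` if permutations
#'   were requested.  Empty bands carry `NA`.
#' @export
correlogram <- function(values, cells, bin_edges = NULL, n_bins = 10,
                        n_permutations = 0, distances = NULL) {
  values <- as.numeric(values)
  n <- nrow(cells)
  stopifnot(length(values) == n)
  if (anyNA(values)) stop("values contain NA; drop those cells first",
                          call. = FALSE)
  D <- if (is.null(distances)) {
    distance_matrix_km(cells$lat_deg, cells$lon_deg)
  } else distances
  if (is.null(bin_edges)) {
    bin_edges <- seq(0, max(D), length.out = n_bins + 1)
  }
  bin_edges <- sort(as.numeric(bin_edges))
  if (length(bin_edges) < 3) stop("need at least 2 bins", call. = FALSE)
  n_b <- length(bin_edges) - 1
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("values are constant", call. = FALSE)
  off <- !diag(n)
  I_obs <- rep(NA_real_, n_b)
  pairs <- integer(n_b)
  p_val <- rep(NA_real_, n_b)
  perms <- if (n_permutations > 0) {
    replicate(n_permutations, sample.int(n))
  } else NULL
  for (b in seq_len(n_b)) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1]
    A <- if (b == n_b) (D >= lo & D <= hi) else (D >= lo & D < hi)
    A <- A & off
    pairs[b] <- sum(A)
    if (pairs[b] == 0) next
    Am <- A * 1
    cross <- drop(crossprod(z, Am %*% z))
    I_obs[b] <- (n / pairs[b]) * cross / denom
    if (!is.null(perms)) {
      I_perm <- vapply(seq_len(n_permutations), function(k) {
        zp <- z[perms[, k]]
        (n / pairs[b]) * drop(crossprod(zp, Am %*% zp)) / denom
      }, numeric(1))
      ctr <- mean(I_perm)
      p_val[b] <- (1 + sum(abs(I_perm - ctr) >= abs(I_obs[b] - ctr))) /
        (n_permutations + 1)
    }
  }
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1],
                    morans_i = I_obs,
                    pairs = pairs)
  if (!is.null(perms)) out$p <- p_val
  class(out) <- c("correlogram", "data.frame")
  out
}
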