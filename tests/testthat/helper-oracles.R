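# Independent long-hand oracles and small in-code fixtures.  The oracles
# deliberately use the naive textbook formulas (explicit normal
# equations, double loops, dense matrices) so they share no code with the
# implementation paths they check.

# brute-force weighted least squares via explicit normal equations,
# with the weighted R^2 around the weighted mean
oracle_wls <- function(X, y, w) {
  Wm <- diag(w)
  A <- t(X) %*% Wm %*% X
  beta <- solve(A, t(X) %*% Wm %*% y)
  fitted <- X %*% beta
  ybar <- sum(w * y) / sum(w)
  rss <- sum(w * (y - fitted)^2)
  tss <- sum(w * (y - ybar)^2)
  list(beta = drop(beta), r2 = 1 - rss / tss)
}

# Moran's I by an explicit double loop
oracle_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      num <- num + W[i, j] * z[i] * z[j]
      s0 <- s0 + W[i, j]
    }
  }
  (n / s0) * num / sum(z^2)
}

# dense hat-matrix rows for a GWR fit: S[i, ] = x_i' (X'W_i X)^-1 X' W_i
oracle_gwr_hat_trace <- function(X, y, D, kernel) {
  n <- nrow(X)
  tr <- 0
  for (i in 1:n) {
    w <- gwrshift::kernel_weight(D[, i], kernel)
    A <- t(X) %*% (w * X)
    s_row <- drop(t(X[i, ]) %*% solve(A, t(w * X)))
    tr <- tr + s_row[i]
  }
  tr
}

# a small well-formed cell-table data frame built in code
small_cell_df <- function(n = 3) {
  data.frame(cell_id = paste0("c", seq_len(n)),
             lat_deg = seq(0.5, by = 1, length.out = n),
             lon_deg = rep(-60.5, n),
             land_fraction = rep(0.8, n),
             richness = seq_len(n) * 3,
             AP = 2000 + seq_len(n), MPDM = 80 + seq_len(n),
             MAT = 25 - seq_len(n) * 0.1, MTCM = 20 - seq_len(n) * 0.1,
             PET = 1500 + seq_len(n), AET = 1200 + seq_len(n),
             stringsAsFactors = FALSE)
}

# a compact synthetic grid for fast end-to-end tests (~300-500 cells)
small_scenario <- function(seed = 1, ...) {
  scenario_config(lat_range = c(-15, 15), lon_range = c(-70, -60),
                  seed = seed, ...)
}

small_grid <- function(seed = 1, ...) {
  derive_water_deficit(filter_cells(
    simulate_palm_grid(small_scenario(seed = seed, ...))))
}

# minimal gwr_fit stand-in for partition arithmetic tests
fake_fit <- function(r2, predictors, kernel = kernel_spec("bisquare", 1200),
                     reliable = TRUE) {
  n <- length(r2)
  structure(list(predictors = predictors, kernel = kernel,
                 locals = data.frame(cell_id = paste0("c", seq_len(n)),
                                     lat_deg = seq(0.5, by = 1,
                                                   length.out = n),
                                     lon_deg = rep(-60.5, n),
                                     local_R2 = r2,
                                     reliable = rep(reliable, length.out = n)),
                 n = n),
            class = "gwr_fit")
}

# fake partition table with a chosen response surface
fake_partition <- function(lat, values,
                           kernel = kernel_spec("bisquare", 1200)) {
  n <- length(lat)
  out <- data.frame(cell_id = paste0("c", seq_len(n)),
                    lat_deg = lat,
                    lon_deg = rep(-60.5, n),
                    R_w = values, R_e = values, R_t = values,
                    R_pw = values, R_pe = values,
                    shared = rep(0, n))
  attr(out, "kernel") <- kernel
  class(out) <- c("partition_table", "data.frame")
  out
}
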