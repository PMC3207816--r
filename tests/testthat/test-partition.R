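test_that("pure and shared fractions follow the partition arithmetic", {
  kern <- kernel_spec("bisquare", 1200)
  fw <- fake_fit(0.7, c("AP", "MPDM", "WD"), kern)
  fe <- fake_fit(0.6, c("MAT", "MTCM", "PET"), kern)
  fc <- fake_fit(0.9, c("AP", "MPDM", "WD", "MAT", "MTCM", "PET"), kern)
  part <- partition_local(fw, fe, fc)
  expect_equal(part$R_pe, 0.2)
  expect_equal(part$R_pw, 0.3)
  expect_equal(part$shared, 0.4)
  expect_equal(part$R_pw + part$R_pe + part$shared, part$R_t,
               tolerance = 1e-15)

  # unreliable cell in one fit propagates NA
  fw2 <- fake_fit(c(0.7, 0.7), c("AP"), kern, reliable = c(TRUE, FALSE))
  fe2 <- fake_fit(c(0.6, 0.6), c("MAT"), kern)
  fc2 <- fake_fit(c(0.9, 0.9), c("AP", "MAT"), kern)
  part2 <- partition_local(fw2, fe2, fc2)
  expect_true(is.na(part2$R_t[2]) && is.na(part2$R_pw[2]))
  expect_false(anyNA(part2[1, c("R_w", "R_e", "R_t")]))
})

test_that("structural mismatches and impossible fractions are rejected", {
  kern <- kernel_spec("bisquare", 1200)
  fw <- fake_fit(0.7, "AP", kern)
  fe <- fake_fit(0.6, "MAT", kern)
  fc <- fake_fit(0.9, c("AP", "MAT"), kern)

  # kernel mismatch
  fe_k <- fake_fit(0.6, "MAT", kernel_spec("bisquare", 1800))
  expect_error(partition_local(fw, fe_k, fc), "kernel")

  # non-nested predictors
  fc_bad <- fake_fit(0.9, c("AP", "PET"), kern)
  expect_error(partition_local(fw, fe, fc_bad), "nest")

  # combined R^2 below a component beyond tolerance: inconsistency
  fc_low <- fake_fit(0.5, c("AP", "MAT"), kern)
  expect_error(partition_local(fw, fe, fc_low), "negative pure fraction")

  # cell-set mismatch
  fw3 <- fake_fit(c(0.7, 0.7), "AP", kern)
  expect_error(partition_local(fw3, fe, fc), "same cells")
})

test_that("partition identities hold on real nested GWR fits", {
  tab <- small_grid(seed = 3)
  kern <- kernel_spec("bisquare", 1200)
  D <- distance_matrix_km(tab$lat_deg, tab$lon_deg)
  fw <- fit_gwr(tab, variable_set("water"), kern, distances = D)
  fe <- fit_gwr(tab, variable_set("energy"), kern, distances = D)
  fc <- fit_gwr(tab, variable_set("combined"), kern, distances = D)
  part <- partition_local(fw, fe, fc)
  ok <- !is.na(part$R_t)
  expect_true(all(part$R_t[ok] >= pmax(part$R_w[ok], part$R_e[ok]) - 1e-12))
  expect_true(all(abs(part$R_pw + part$R_pe + part$shared -
                        part$R_t)[ok] < 1e-12))
  expect_true(all(part$R_pw[ok] >= 0 & part$R_pe[ok] >= 0))
  expect_true(all(part[ok, c("R_w", "R_e", "R_t")] <= 1))
})

# For the collinearity properties the local windows must contain many
# independent climate patches, otherwise within-window sampling
# correlation between the composites masks the imposed global
# correlation; hence the shorter smoothing range and bandwidth here.
test_that("orthogonal water and energy fields leave little shared variance", {
  kern <- kernel_spec("bisquare", 600)
  shared_at <- function(rho) {
    tab <- small_grid(seed = 13, rho_we = rho, climate_trend = 0,
                      smooth_range_km = 200)
    D <- distance_matrix_km(tab$lat_deg, tab$lon_deg)
    part <- partition_local(
      fit_gwr(tab, variable_set("water"), kern, distances = D),
      fit_gwr(tab, variable_set("energy"), kern, distances = D),
      fit_gwr(tab, variable_set("combined"), kern, distances = D))
    mean(part$shared, na.rm = TRUE)
  }
  s0 <- shared_at(0)
  # systematically small under orthogonality (per-cell values fluctuate
  # with within-window sampling correlation, but the average does not)
  expect_lt(s0, 0.15)
  # and far below the strongly collinear case on the same seed
  expect_lt(s0, shared_at(0.8) / 3)
})

test_that("shared variance rises monotonically with water-energy collinearity", {
  kern <- kernel_spec("bisquare", 600)
  rhos <- c(0, 0.2, 0.4, 0.6, 0.8)
  mean_shared <- matrix(NA_real_, length(rhos), 3)
  for (i in seq_along(rhos)) {
    for (s in 1:3) {
      tab <- small_grid(seed = 100 + s, rho_we = rhos[i],
                        climate_trend = 0, smooth_range_km = 200)
      D <- distance_matrix_km(tab$lat_deg, tab$lon_deg)
      part <- partition_local(
        fit_gwr(tab, variable_set("water"), kern, distances = D),
        fit_gwr(tab, variable_set("energy"), kern, distances = D),
        fit_gwr(tab, variable_set("combined"), kern, distances = D))
      mean_shared[i, s] <- mean(part$shared, na.rm = TRUE)
    }
  }
  rho_s <- cor(rhos, rowMeans(mean_shared), method = "spearman")
  expect_gte(rho_s, 0.8)
})
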