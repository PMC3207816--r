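test_that("generation is deterministic under a fixed seed", {
  cfg <- small_scenario(seed = 42)
  a <- simulate_palm_grid(cfg)
  b <- simulate_palm_grid(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_other <- simulate_palm_grid(small_scenario(seed = 43))
  expect_false(identical(a$richness, c_other$richness))
})

test_that("climate fields carry the imposed latitudinal structure and collinearity", {
  cells <- generate_cells(scenario_config(seed = 7))
  expect_gte(nrow(cells), 1000)
  alat <- abs(cells$lat_deg)
  expect_lt(cor(cells$MAT, alat), 0)
  expect_lt(cor(cells$AP, alat), 0)
  expect_true(all(cells$PET - cells$AET >= 0))  # WD non-negative
  expect_true(all(cells$land_fraction >= 0.3 & cells$land_fraction <= 1))

  # realized latent cross-correlation is pinned at rho_we
  lat <- attr(cells, "latents")
  expect_equal(cor(lat$L_w, lat$L_e), 0.3, tolerance = 0.1)
  lat8 <- attr(generate_cells(scenario_config(seed = 8, rho_we = 0.8)),
               "latents")
  expect_equal(cor(lat8$L_w, lat8$L_e), 0.8, tolerance = 0.1)
})

test_that("richness is a non-negative integer surface peaking near the equator", {
  cells <- simulate_palm_grid("predictor_shift", seed = 3)
  r <- cells$richness
  expect_true(all(r >= 0))
  expect_equal(r, round(r))
  alat <- abs(cells$lat_deg)
  expect_gt(mean(r[alat < 10]), mean(r[alat > 25]))
})

test_that("scenario presets encode their documented structure", {
  st <- scenario("stationary")
  expect_equal(c(st$b_w1, st$b_e1), c(0, 0))
  ps <- scenario("predictor_shift")
  expect_true(ps$b_w1 > 0 && ps$b_e1 > 0)
  expect_equal(scenario("collinear")$rho_we, 0.8)
  expect_gt(scenario("shift_with_sac")$error_range_km, 0)
  expect_error(scenario("atlantis"), "stationary.*predictor_shift")
})

test_that("a noiseless stationary surface is recovered exactly by the combined model", {
  tab <- small_grid(seed = 6, b_w1 = 0, b_e1 = 0, noise_sd = 0,
                    baseline = 300)
  fit <- fit_gwr(tab, variable_set("combined"),
                 kernel_spec("bisquare", 1200))
  # richness is linear in the six variables up to integer rounding
  expect_gt(min(fit$locals$local_R2, na.rm = TRUE), 0.99)
})

test_that("water-driven richness is detected by model selection across seeds", {
  kern <- kernel_spec("bisquare", 1200)
  wins <- vapply(1:20, function(s) {
    tab <- small_grid(seed = 200 + s, b_e0 = 0, b_e1 = 0)
    aicc_w <- fit_gwr(tab, variable_set("water"), kern)$aicc
    aicc_e <- fit_gwr(tab, variable_set("energy"), kern)$aicc
    aicc_w < aicc_e
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("GWR recovers the true latitude-varying water coefficient surface", {
  cells <- simulate_palm_grid("predictor_shift", seed = 11)
  tab <- derive_water_deficit(filter_cells(cells))
  fit <- fit_gwr(tab, variable_set("combined"),
                 kernel_spec("bisquare", 1200))
  truth <- attr(cells, "truth")
  # map raw-variable coefficients back to the W-index scale:
  # beta_w_hat = sum_k betahat_k * scale_k * sd(scores) * loading_k
  v <- truth$water$loadings
  s <- truth$water$scale * truth$score_sd["water"]
  est <- as.matrix(fit$locals[, c("AP", "MPDM", "WD")]) %*% (v * s)
  interior <- abs(tab$lat_deg) < 28 &
    tab$lon_deg > min(tab$lon_deg) + 3 & tab$lon_deg < max(tab$lon_deg) - 3
  expect_gte(cor(est[interior], truth$cells$beta_w[interior]), 0.7)
})
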