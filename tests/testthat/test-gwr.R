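test_that("local weighted least squares matches the normal-equations oracle", {
  set.seed(21)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(2, 1.5, -0.7)) + rnorm(n)
  w <- runif(n, 0.05, 1)
  fit <- local_wls(X, y, w)
  ref <- oracle_wls(X, y, w)
  expect_equal(unname(fit$coefficients), unname(ref$beta),
               tolerance = 1e-8)
  expect_equal(fit$local_R2, ref$r2, tolerance = 1e-8)
  expect_true(fit$reliable)

  # uniform weights reduce to ordinary least squares
  fit1 <- local_wls(X, y, rep(1, n))
  lmref <- lm.fit(X, y)
  expect_equal(unname(fit1$coefficients), unname(lmref$coefficients),
               tolerance = 1e-10)

  # exact linear response: R^2 = 1
  ylin <- drop(X %*% c(1, 2, 3))
  expect_equal(local_wls(X, ylin, w)$local_R2, 1, tolerance = 1e-12)

  # too few positive weights: unreliable flag, not an exception
  w0 <- c(1, 1, 1, rep(0, n - 3))
  fit0 <- local_wls(X, y, w0)
  expect_false(fit0$reliable)
  expect_true(all(is.na(fit0$coefficients)))
})

test_that("GWR with an all-covering moving window reproduces global OLS exactly", {
  tab <- small_grid(seed = 5)
  kern <- kernel_spec("moving_window", 1e6)
  gfit <- fit_gwr(tab, variable_set("water"), kern)
  ofit <- aicc_ols(tab, variable_set("water"))
  p1 <- length(ofit$coefficients)
  for (cn in names(ofit$coefficients)) {
    expect_equal(gfit$locals[[cn]], rep(unname(ofit$coefficients[cn]),
                                        nrow(tab)),
                 tolerance = 1e-10)
  }
  expect_equal(gfit$trace_S, p1, tolerance = 1e-8)
  expect_equal(gfit$aicc, ofit$aicc, tolerance = 1e-8)
  expect_equal(unique(gfit$locals$local_R2), ofit$r2, tolerance = 1e-10)
})

test_that("hat-matrix trace matches dense full-matrix assembly", {
  set.seed(40)
  cells <- data.frame(cell_id = 1:40,
                      lat_deg = runif(40, -10, 10),
                      lon_deg = runif(40, -70, -60),
                      land_fraction = 1,
                      richness = rpois(40, 20),
                      AP = rnorm(40, 2000, 300), MPDM = rnorm(40, 80, 20),
                      MAT = rnorm(40, 25, 2), MTCM = rnorm(40, 20, 2),
                      PET = rnorm(40, 1500, 100), AET = rnorm(40, 1200, 100))
  tab <- as_cell_table(cells)
  kern <- kernel_spec("bisquare", 900)
  fit <- fit_gwr(tab, c("AP", "MAT"), kern)
  X <- cbind(1, tab$AP, tab$MAT)
  D <- distance_matrix_km(tab$lat_deg, tab$lon_deg)
  expect_equal(fit$trace_S, oracle_gwr_hat_trace(X, tab$richness, D, kern),
               tolerance = 1e-10)
})

test_that("the corrected AIC follows the small-sample formula and is scale invariant", {
  set.seed(8)
  n <- 10
  cells <- data.frame(cell_id = 1:n, lat_deg = runif(n, -5, 5),
                      lon_deg = runif(n, -65, -60), land_fraction = 1,
                      richness = rpois(n, 30),
                      AP = rnorm(n, 2000, 400), MPDM = rnorm(n, 80, 10),
                      MAT = rnorm(n, 25, 3), MTCM = rnorm(n, 20, 3),
                      PET = rnorm(n, 1500, 150), AET = rnorm(n, 1200, 100))
  tab <- as_cell_table(cells)
  fit <- aicc_ols(tab, "AP")
  lmfit <- lm(richness ~ AP, data = tab)
  rss <- sum(resid(lmfit)^2)
  tr <- 2  # intercept + slope
  hand <- 2 * n * log(sqrt(rss / n)) + n * log(2 * pi) +
    n * (n + tr) / (n - 2 - tr)
  expect_equal(fit$aicc, hand, tolerance = 1e-9)

  # affine rescaling of a predictor leaves AICc unchanged
  tab2 <- tab
  tab2$AP <- (tab2$AP - 1000) / 250
  expect_equal(aicc_ols(tab2, "AP")$aicc, fit$aicc, tolerance = 1e-9)
  kern <- kernel_spec("bisquare", 700)
  expect_equal(fit_gwr(tab2, "AP", kern)$aicc,
               fit_gwr(tab, "AP", kern)$aicc, tolerance = 1e-8)

  # AICc undefined when the effective parameters approach n
  expect_error(fit_gwr(tab, "AP", kernel_spec("moving_window", 1)),
               "AICc undefined")
})

test_that("local R^2 never decreases when a predictor is added at fixed weights", {
  set.seed(31)
  n <- 25
  X1 <- cbind(1, rnorm(n))
  X2 <- cbind(X1, rnorm(n))
  y <- rnorm(n)
  for (rep in 1:10) {
    w <- runif(n, 0.01, 1)
    expect_gte(local_wls(X2, y, w)$local_R2,
               local_wls(X1, y, w)$local_R2 - 1e-12)
  }
})

test_that("all-subsets selection enumerates 7 models and finds the true driver", {
  tab <- small_grid(seed = 2)
  kern <- kernel_spec("bisquare", 1200)
  sel <- select_model(tab, variable_set("water"), kern)
  expect_equal(nrow(sel), 7)
  expect_equal(sort(sel$k), c(1, 1, 1, 2, 2, 2, 3))
  expect_equal(sum(sel$best), 1)
  expect_equal(sel$delta_aicc[sel$best], 0)
  expect_true(all(sel$delta_aicc >= 0))

  # richness built from AP alone: AP in the winning subset across seeds
  hits <- vapply(1:20, function(s) {
    cfg <- small_scenario(seed = s)
    cells <- generate_cells(cfg)
    set.seed(s + 1000)
    df <- as.data.frame(cells)
    df$richness <- round(pmax(0, 20 + 0.04 * df$AP +
                                rnorm(nrow(df), sd = 6)))
    tab_s <- derive_water_deficit(filter_cells(as_cell_table(df)))
    sel_s <- select_model(tab_s, variable_set("water"), kern)
    "AP" %in% attr(sel_s, "best_members")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("combined model is the ordered de-duplicated union, water first", {
  comb <- combined_model(c("AP", "MPDM", "WD"), c("MAT", "MTCM", "PET"))
  expect_s3_class(comb, "variable_set")
  expect_equal(comb$members, c("AP", "MPDM", "WD", "MAT", "MTCM", "PET"))
  overlap <- combined_model(c("AP", "WD"), c("WD", "PET"))
  expect_equal(overlap$members, c("AP", "WD", "PET"))
  expect_error(combined_model(character(0), character(0)))
})

test_that("local coefficient spread shrinks as the bandwidth grows on stationary data", {
  tab <- small_grid(seed = 9, b_w1 = 0, b_e1 = 0)
  f1 <- fit_gwr(tab, "AP", kernel_spec("bisquare", 1200))
  f2 <- fit_gwr(tab, "AP", kernel_spec("bisquare", 1800))
  expect_lt(sd(f2$locals$AP), sd(f1$locals$AP))
})
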