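test_that("CSV loading validates schema, types and ranges", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- small_cell_df()
  write.csv(df, path, row.names = FALSE)
  tab <- load_cell_table(path)
  expect_s3_class(tab, "cell_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cell_id, df$cell_id)
  expect_true(is.numeric(tab$AP) && is.numeric(tab$richness))

  # missing column named in the error
  write.csv(df[setdiff(names(df), "richness")], path, row.names = FALSE)
  expect_error(load_cell_table(path), "richness")

  # out-of-range latitude identifies the row
  bad <- df; bad$lat_deg[2] <- 95
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cell_table(path), "latitude.*2")

  # duplicate ids
  dup <- df; dup$cell_id[2] <- dup$cell_id[1]; dup$lat_deg[2] <- 10.5
  write.csv(dup, path, row.names = FALSE)
  expect_error(load_cell_table(path), "duplicate cell_id")

  # non-numeric climate
  write.csv(df, path, row.names = FALSE)
  raw <- read.csv(path, colClasses = "character")
  raw$AP[1] <- "wet"
  write.csv(raw, path, row.names = FALSE)
  expect_error(load_cell_table(path), "AP")
})

test_that("land-fraction filter is strict at the 25% boundary and drops missing climate", {
  df <- small_cell_df(5)
  df$land_fraction <- c(0.24, 0.25, 0.9, 0.8, 0.7)
  df$PET[4] <- NA
  tab <- as_cell_table(df)
  out <- filter_cells(tab)
  expect_equal(out$cell_id, c("c2", "c3", "c5"))  # 0.24 out, 0.25 in
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_low_land, 1)
  expect_equal(rep$n_missing_climate, 1)
  expect_equal(rep$n_kept, 3)

  # clean table returned unchanged, and filtering is idempotent
  clean <- as_cell_table(small_cell_df(4))
  once <- filter_cells(clean)
  expect_equal(as.data.frame(once), as.data.frame(clean),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(filter_cells(once)), as.data.frame(once),
               ignore_attr = TRUE)

  # everything removed is an error
  allbad <- as_cell_table(transform(small_cell_df(3), land_fraction = 0.1))
  expect_error(filter_cells(allbad), "no cells remain")
})

test_that("water deficit is PET - AET, negatives warn, and derivation commutes with filtering", {
  df <- small_cell_df(3)
  df$PET <- c(1500, 1300, 1000)
  df$AET <- c(1200, 1300, 1100)
  tab <- as_cell_table(df)
  expect_warning(out <- derive_water_deficit(tab), "AET > PET")
  expect_equal(out$WD, c(300, 0, -100))

  noaet <- df[setdiff(names(df), "AET")]
  noaet$WD <- 100  # schema satisfied via WD, but derivation needs AET
  expect_error(derive_water_deficit(as_cell_table(noaet)), "AET")

  df2 <- small_cell_df(6)
  df2$land_fraction[2] <- 0.1
  tab2 <- as_cell_table(df2)
  a <- filter_cells(derive_water_deficit(tab2))
  b <- derive_water_deficit(filter_cells(tab2))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("zscore standardizes with the sample sd and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(7)
  x <- rnorm(50, 10, 4)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(c(5, 5, 5)), "constant")
  expect_error(zscore(3), "at least 2")
})

test_that("hemisphere split is disjoint, exhaustive, with the equator going north", {
  df <- small_cell_df(4)
  df$lat_deg <- c(0.5, -0.5, 0, -12.5)
  tab <- as_cell_table(df)
  h <- split_hemispheres(tab)
  expect_equal(h$north$cell_id, c("c1", "c3"))
  expect_equal(h$south$cell_id, c("c2", "c4"))
  expect_equal(nrow(h$north) + nrow(h$south), nrow(tab))
  expect_length(intersect(h$north$cell_id, h$south$cell_id), 0)
})

test_that("variable sets have the documented members and order", {
  expect_equal(variable_set("water")$members, c("AP", "MPDM", "WD"))
  expect_equal(variable_set("energy")$members, c("MAT", "MTCM", "PET"))
  expect_equal(variable_set("combined")$members,
               c("AP", "MPDM", "WD", "MAT", "MTCM", "PET"))
  expect_error(variable_set("fire"))
})
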