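test_that("reclassify maps codes totally and preserves the grid", {
  r <- random_raster(10, 10, seed = 1)
  ident <- class_scheme(1:7, lu_classes())
  expect_identical(reclassify(r, ident)$values, r$values)

  merge2 <- land_raster(matrix(c(11L, 12L), 1, 2))
  sch <- class_scheme(c(11, 12), c("cropland", "cropland"))
  expect_true(all(reclassify(merge2, sch)$values == 1L))

  expect_error(reclassify(land_raster(matrix(c(11L, 99L), 1, 2)), sch),
               "unmapped raster code\\(s\\): 99")
})

test_that("reclassified class counts equal sums of source-code counts", {
  set.seed(21)
  codes <- c(11, 12, 21, 31, 41, 46, 51, 63, 66)
  classes <- c("cropland", "cropland", "forest", "grassland", "water",
               "wetland", "built_up", "bare", "bare")
  v <- matrix(sample(codes, 400, replace = TRUE), 20, 20)
  v[sample(400, 17)] <- NA
  r <- land_raster(v)
  rc <- reclassify(r, class_scheme(codes, classes))
  expect_true(all(is.na(rc$values) == is.na(v)))
  for (cl in unique(classes)) {
    src <- codes[classes == cl]
    expect_equal(sum(rc$values == match(cl, lu_classes()), na.rm = TRUE),
                 sum(v %in% src))
  }
})

test_that("class_areas counts cells and converts units; nodata excluded", {
  r <- land_raster(matrix(1L, 10, 10), cell_area_hm2 = 100)
  a <- class_areas(r)
  expect_equal(a$area_km2, c(100, rep(0, 6)))
  expect_equal(a$area_hm2, a$area_km2 * 100)

  empty <- land_raster(matrix(NA_integer_, 5, 5))
  expect_true(all(class_areas(empty)$area_km2 == 0))

  rr <- random_raster(17, 13, seed = 8, cell_area_hm2 = 25)
  a2 <- class_areas(rr)
  for (k in 1:7)
    expect_equal(a2$area_km2[k], sum(rr$values == k) * 0.25)
})

test_that("area change table reproduces the published variation and rate cells", {
  at <- area_change_table(hubei_landuse_areas())
  expect_equal(at$variation["1995-2015", "cropland"], -2047.36, tolerance = 1e-9)
  expect_equal(round(at$rate["1995-2015", "cropland"], 2), -2.96)
  expect_equal(at$variation["1995-2015", "built_up"], 2148.49, tolerance = 1e-9)
  expect_equal(round(at$rate["1995-2015", "built_up"], 2), 43.37)
  expect_equal(round(at$rate["1995-2015", "wetland"], 2), 56.90)
  # ratios sum to 100 per date; variation is an exact difference
  expect_true(all(abs(rowSums(at$ratio) - 100) < 1e-9))
  expect_equal(at$variation["2010-2015", ],
               at$area["2015", ] - at$area["2010", ])
})

test_that("zero-baseline rates are flagged NA, unchanged areas give zero", {
  m <- rbind(`1` = c(0, 100, 50, 10, 5, 1, 4), `2` = c(20, 100, 50, 10, 5, 1, 4))
  at <- area_change_table(m)
  expect_true(is.na(at$rate["1-2", "cropland"]))
  expect_equal(nrow(at$undefined_rates), 1)
  expect_equal(at$variation["1-2", "forest"], 0)
  expect_equal(at$rate["1-2", "forest"], 0)
})

test_that("transfer matrix cross-tabulates areas exactly", {
  r <- random_raster(12, 12, seed = 3)
  tm_id <- transfer_matrix(r, r)
  expect_true(all(tm_id$area[row(tm_id$area) != col(tm_id$area)] == 0))
  expect_equal(diag(tm_id$P)[diag(tm_id$area) > 0],
               rep(1, sum(diag(tm_id$area) > 0)), ignore_attr = TRUE)

  r1 <- land_raster(matrix(c(1L, 1L), 1, 2))
  r2 <- land_raster(matrix(c(1L, 7L), 1, 2))
  tm <- transfer_matrix(r1, r2)
  expect_equal(tm$area["cropland", "cropland"], 1)
  expect_equal(tm$area["cropland", "built_up"], 1)
  expect_equal(tm$P["cropland", c("cropland", "built_up")], c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_true("forest" %in% tm$empty_from)

  expect_error(transfer_matrix(r1, random_raster(3, 3, 1)), "grid mismatch")
})

test_that("transfer matrix equals a brute-force per-pixel tally", {
  a <- random_raster(20, 20, seed = 5)
  b <- random_raster(20, 20, seed = 6)
  a$values[sample(400, 10)] <- NA
  b$values[sample(400, 10)] <- NA
  tm <- transfer_matrix(a, b)
  for (i in 1:7) for (j in 1:7)
    expect_equal(tm$area[i, j],
                 sum(a$values == i & b$values == j, na.rm = TRUE))
})

test_that("mass conservation and Markov chaining hold on the common mask", {
  sp <- landscape_spec(seed = 13, nrows = 50, ncols = 50, n_dates = 3)
  rs <- simulate_landscape(sp)
  tm <- transfer_matrix(rs[[1]], rs[[2]])
  a1 <- class_areas(rs[[1]])$area_km2
  a2 <- class_areas(rs[[2]])$area_km2
  expect_equal(unname(rowSums(tm$area)), a1)
  expect_equal(unname(colSums(tm$area)), a2)
  # areas(t) %*% P reproduces areas(t+1) exactly on observed data
  expect_equal(unname(as.vector(a1 %*% tm$P)), a2)
})

test_that("ASCII grid round-trips values, nodata and cell size", {
  r <- random_raster(8, 11, seed = 4, cell_area_hm2 = 400)  # 2-km cells
  r$values[c(3, 40)] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_identical(r2$values, r$values)
  expect_equal(r2$cell_area_hm2, 400)
})
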