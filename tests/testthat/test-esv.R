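coef_tab <- esv_coefficients()
areas_tab <- hubei_landuse_areas()

test_that("standard equivalent value is one seventh of weighted output value", {
  one <- data.frame(crop = "x", yield_per_area = 1, sown_area = 123, price = 7)
  expect_identical(standard_equivalent_value(one), 1)

  two <- data.frame(crop = c("a", "b"), yield_per_area = c(7, 14),
                    sown_area = c(50, 50), price = c(1, 1))
  expect_equal(standard_equivalent_value(two), 1.5)

  set.seed(31)
  for (rep in 1:5) {
    cr <- simulate_crop_table(seed = rep, n_crops = 6)
    oracle <- sum(cr$yield_per_area * cr$sown_area * cr$price) /
      (7 * sum(cr$sown_area))
    expect_equal(standard_equivalent_value(cr), oracle, tolerance = 1e-12)
  }

  expect_error(standard_equivalent_value(
    data.frame(yield_per_area = 1, sown_area = 0, price = 1)), "sown area")
  expect_error(standard_equivalent_value(
    data.frame(yield_per_area = -1, sown_area = 1, price = 1)), "negative")
})

test_that("coefficient scaling is homogeneous in En", {
  eq <- matrix(1, 7, 11)
  sc <- scale_coefficients(eq, 2516.20)
  expect_true(all(sc$values == 2516.20))
  base <- scale_coefficients(coef_tab$values, 1)
  doubled <- scale_coefficients(coef_tab$values, 2)
  expect_equal(doubled$values, 2 * base$values)
  expect_error(scale_coefficients(eq, 0), "En")
})

test_that("packaged coefficient table has consistent totals and signs", {
  # published per-class totals, to the printed rounding
  expect_equal(unname(coef_tab$class_totals["cropland"]), 1643.03, tolerance = 0.025 / 1643)
  expect_equal(unname(coef_tab$class_totals["forest"]), 7778.70, tolerance = 0.025 / 7778)
  expect_equal(unname(coef_tab$class_totals["water"]), 28916.87, tolerance = 0.025 / 28916)
  expect_equal(coef_tab$class_totals, rowSums(coef_tab$values))
  expect_true(all(coef_tab$values["built_up", ] == 0))
  expect_lt(coef_tab$values["cropland", "WS"], 0)   # net water consumer
})

test_that("ESV by type matches published class values", {
  a1995 <- subset(areas_tab, date == 1995)
  et <- esv_by_type(a1995, coef_tab)
  esv <- setNames(et$esv, et$class)
  expect_equal(round(esv[["cropland"]] / 1e9, 2), 11.35)
  expect_equal(round(esv[["forest"]] / 1e9, 2), 72.70)
  expect_equal(round(attr(et, "total") / 1e9, 2), 118.08)
  expect_equal(esv[["built_up"]], 0)

  zero <- esv_by_type(rep(0, 7), coef_tab)
  expect_equal(attr(zero, "total"), 0)
})

test_that("ESV by function matches published function values", {
  a1995 <- subset(areas_tab, date == 1995)
  ef <- esv_by_function(a1995, coef_tab)
  esv <- setNames(ef$esv, ef$fun)
  expect_equal(round(esv[["HR"]] / 1e9, 2), 39.63)
  expect_equal(round(esv[["CR"]] / 1e9, 2), 23.80)

  # single class, single nonzero coefficient -> exact product
  m <- matrix(0, 7, 11); m[2, 5] <- 3.5
  co <- scale_coefficients(m, 1)
  ef2 <- esv_by_function(c(0, 10, 0, 0, 0, 0, 0), co, unit = "hm2")
  expect_equal(attr(ef2, "total"), 35)
  expect_equal(ef2$esv[ef2$fun == "CR"], 35)
})

test_that("additivity and linearity hold on arbitrary inputs", {
  set.seed(77)
  for (rep in 1:5) {
    a <- runif(7, 0, 1e6)
    tot_type <- attr(esv_by_type(a, coef_tab), "total")
    tot_fun <- attr(esv_by_function(a, coef_tab), "total")
    expect_equal(tot_type, tot_fun, tolerance = 1e-6)
    expect_equal(attr(esv_by_type(3 * a, coef_tab), "total"), 3 * tot_type,
                 tolerance = 1e-9)
    sv <- attr(esv_by_function(a, coef_tab), "service_totals")
    expect_equal(sum(sv), tot_fun, tolerance = 1e-6)
  }
})

test_that("esv_variety returns interval differences, zero for identical dates", {
  m <- rbind(`1` = runif(7, 0, 1e5), `2` = runif(7, 0, 1e5))
  va <- esv_variety(rbind(m, `3` = m[2, ]), coef_tab)
  expect_equal(unname(va$total["2-3"]), 0)
  two <- esv_assessment(m, coef_tab)
  expect_equal(unname(two$variety_total),
               unname(two$totals[2] - two$totals[1]))
})

test_that("zonal ESV partitions the global total exactly", {
  r <- random_raster(24, 24, seed = 12)
  co <- coef_tab

  one <- generate_zones(24, 24, 1, 1)
  z1 <- zonal_esv(r, one, co)
  expect_equal(sum(z1$esv), attr(esv_by_type(r, co), "total"))

  # uniform landscape, two half-grids -> equal halves
  ru <- land_raster(matrix(2L, 24, 24), levels = lu_classes())
  half <- generate_zones(24, 24, 1, 2)
  zh <- zonal_esv(ru, half, co)
  expect_equal(zh$esv[1], zh$esv[2])

  # random landscape + 4 zones vs brute-force per-zone recomputation
  z4 <- generate_zones(24, 24, 2, 2)
  zz <- zonal_esv(r, z4, co)
  for (id in 1:4) {
    cells <- r$values[z4$map == id]
    oracle <- sum(co$class_totals[cells] * r$cell_area_hm2)
    expect_equal(zz$esv[id], oracle)
  }
  expect_equal(sum(zz$esv), attr(esv_by_type(r, co), "total"))

  # unzoned cells are flagged, never dropped
  zx <- z4; zx$map[1, 1] <- NA
  expect_warning(res <- zonal_esv(r, zx, co), "unassigned")
  expect_equal(sum(res$esv) + attr(res, "unassigned"),
               attr(esv_by_type(r, co), "total"))
})
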