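test_that("contiguity neighbour counts are exact on a 2x2 zone grid", {
  z <- generate_zones(10, 10, 2, 2)
  rook <- zone_weights(z, scheme = "rook")
  expect_true(all(lengths(rook$neighbours) == 2))
  queen <- zone_weights(z, scheme = "queen")
  expect_true(all(lengths(queen$neighbours) == 3))
  self <- zone_weights(z, scheme = "queen", include_self = TRUE)
  expect_true(all(lengths(self$neighbours) == 4))
  expect_true(all(mapply(function(nb, i) i %in% nb,
                         self$neighbours, seq_along(self$neighbours))))
})

test_that("contiguity is symmetric and matches the dense oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    z <- generate_zones(12 + seed, 15, 3, sample(2:4, 1))
    for (scheme in c("queen", "rook")) {
      w <- zone_weights(z, scheme = scheme)
      W <- dense_contiguity(z$map, diagonal = scheme == "queen")
      for (i in seq_along(w$ids)) {
        expect_equal(w$neighbours[[i]], unname(which(W[i, ] == 1)))
        expect_equal(which(W[i, ] == 1), which(W[, i] == 1))  # symmetry
      }
    }
  }
})

test_that("row-standardised rows sum to one; weight lists round-trip", {
  z <- generate_zones(10, 10, 3, 3)
  w <- zone_weights(z, style = "W")
  expect_true(all(abs(vapply(w$weights, sum, numeric(1)) - 1) < 1e-12))
  path <- withr::local_tempfile(fileext = ".txt")
  write_weights_list(w, path)
  df <- read_weights_list(path)
  expect_equal(nrow(df), sum(lengths(w$neighbours)))
  expect_equal(sum(df$w), sum(unlist(w$weights)), tolerance = 1e-9)
})

test_that("Moran's I is -1 on the rook checkerboard and positive on blocks", {
  z <- generate_zones(2, 2, 2, 2)
  w <- zone_weights(z, scheme = "rook", style = "B")
  m <- global_morans_i(c(1, -1, -1, 1), w, nsim = 0)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expectation, -1 / 3)

  chain <- generate_zones(1, 4, 1, 4)
  wc <- zone_weights(chain, scheme = "rook", style = "B")
  expect_gt(global_morans_i(c(10, 10, 1, 1), wc, nsim = 0)$I, 0)
})

test_that("Moran's I matches the dense double-loop oracle to 1e-12", {
  for (seed in 1:4) {
    set.seed(100 + seed)
    z <- generate_zones(10, 10, 5, 5)   # 25 zones
    x <- rnorm(25, 100, 20)
    for (style in c("B", "W")) {
      w <- zone_weights(z, scheme = "queen", style = style)
      W <- dense_contiguity(z$map, diagonal = TRUE)
      if (style == "W") W <- row_standardize(W)
      expect_equal(global_morans_i(x, w, nsim = 0)$I, moran_oracle(x, W),
                   tolerance = 1e-12)
    }
  }
})

test_that("Moran's I errors on constant fields and self-weights", {
  z <- generate_zones(6, 6, 2, 2)
  w <- zone_weights(z)
  expect_error(global_morans_i(rep(5, 4), w, nsim = 0), "constant field")
  ws <- zone_weights(z, include_self = TRUE)
  expect_error(global_morans_i(rnorm(4), ws, nsim = 0), "self")
})

test_that("permutation null mean is near -1/(n-1) and p-values are sane", {
  set.seed(9)
  z <- generate_zones(12, 12, 4, 4)
  w <- zone_weights(z, style = "W")
  x <- rnorm(16)
  m <- global_morans_i(x, w, nsim = 999, seed = 4)
  mc_err <- 3 * sd(m$perm) / sqrt(length(m$perm))
  expect_lt(abs(mean(m$perm) - m$expectation), mc_err)
  expect_true(m$p_value > 0 && m$p_value <= 1)
  # fixed seed -> identical inference
  m2 <- global_morans_i(x, w, nsim = 999, seed = 4)
  expect_identical(m$p_value, m2$p_value)
})

test_that("Moran scatter uses standardised values and their spatial lag", {
  z <- generate_zones(9, 9, 3, 3)
  w <- zone_weights(z, style = "W")
  x <- rnorm(9, 50, 5)
  m <- global_morans_i(x, w, nsim = 0)
  expect_equal(m$scatter$z, (x - mean(x)) / sd(x))
  expect_equal(cor(m$scatter$z, x), 1)
})

test_that("Gi* matches the direct-formula oracle to 1e-12", {
  for (seed in 1:4) {
    set.seed(200 + seed)
    z <- generate_zones(8, 8, 4, 4)   # 16 zones
    x <- runif(16, 10, 1000)
    w <- zone_weights(z, scheme = "queen", style = "B", include_self = TRUE)
    W <- dense_contiguity(z$map, diagonal = TRUE, include_self = TRUE)
    expect_equal(getis_ord_gstar(x, w)$z, gstar_oracle(x, W),
                 tolerance = 1e-12)
  }
})

test_that("Gi* flags a dominant zone and its neighbours as the top hot spots", {
  z <- generate_zones(12, 12, 4, 4)
  w <- zone_weights(z, style = "B", include_self = TRUE)
  x <- rep(1, 16); x[6] <- 100     # interior zone (row 2, col 2)
  g <- getis_ord_gstar(x, w)
  nbset <- w$neighbours[[6]]                  # focal zone plus neighbours
  expect_true(all(g$z[nbset] > 0))
  expect_true(min(g$z[nbset]) > max(g$z[-nbset]))
  expect_error(getis_ord_gstar(rep(2, 16), w), "S = 0")
  wm <- zone_weights(z, style = "B")
  expect_error(getis_ord_gstar(x, wm), "include_self")
})

test_that("Gi* z is invariant to shifts and positive scalings", {
  set.seed(15)
  z <- generate_zones(10, 10, 5, 5)
  w <- zone_weights(z, style = "B", include_self = TRUE)
  x <- rgamma(25, 5, 0.1)
  z0 <- getis_ord_gstar(x, w)$z
  expect_equal(getis_ord_gstar(x + 1234, w)$z, z0, tolerance = 1e-9)
  expect_equal(getis_ord_gstar(x * 7.5, w)$z, z0, tolerance = 1e-9)
})

test_that("hot/cold classification brackets the confidence thresholds", {
  z <- c(0, 1.64, 1.65, 1.96, 2.0, 2.58, -1.7, -1.96, -2.58, -3.1)
  cls <- classify_hotspots(z)
  expect_equal(as.character(cls),
               c("not_significant", "not_significant", "hot90", "hot95",
                 "hot95", "hot99", "cold90", "cold95", "cold99", "cold99"))
  expect_true(is.na(classify_hotspots(NA_real_)))
  expect_true(is.ordered(cls))
})

test_that("neighbourhoods spanning all zones yield flagged undefined scores", {
  # middle zone of a 3-strip partition neighbours every zone:
  # its weight row is all ones and the variance term collapses to zero
  z <- generate_zones(2, 3, 1, 3)
  w <- zone_weights(z, scheme = "queen", style = "B", include_self = TRUE)
  g <- getis_ord_gstar(c(1, 5, 9), w)
  expect_true(all(is.na(g$z[lengths(w$neighbours) == 3])))
  expect_true(length(attr(g, "undefined")) >= 1)
})
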