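#' Specify a synthetic multi-date landscape
#'
#' Defines the study conditions for a simulated categorical landscape:
#' grid size, cell area, initial class proportions and a row-stochastic
#' class transition matrix applied between consecutive dates. The
#' simulator emulates multi-date 1-km land-use rasters whose class
#' transitions follow a first-order Markov process (notably built-up
#' expansion consuming cropland and forest), which is exactly the
#' generative reading of a land-use transfer probability matrix.
#'
#' @param seed Integer seed governing all stochastic draws.
#' @param nrows,ncols Grid dimensions (positive integers).
#' @param cell_area_hm2 Cell area in hectares (default 100 = 1 km2).
#' @param initial_proportions Numeric vector of 7 nonnegative class
#'   proportions summing to 1 (order of [lu_classes()]).
#' @param transition_matrix 7 x 7 row-stochastic matrix; entry (i, j) is
#'   the probability that a cell of class i at date t is class j at t+1.
#' @param n_dates Number of dates to simulate (>= 2).
#' @param spatial_smoothing Integer neighbourhood radius; if > 0 the
#'   initial field is passed through a modal (majority) filter of that
#'   radius to produce clumped rather than i.i.d. patterns. Transitions
#'   remain independent per cell.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(seed = 1L,
                           nrows = 100L, ncols = 100L,
                           cell_area_hm2 = 100,
                           initial_proportions = c(0.37, 0.50, 0.04, 0.05, 0.006, 0.004, 0.03),
                           transition_matrix = default_transition_matrix(),
                           n_dates = 2L,
                           spatial_smoothing = 0L) {
  k <- length(lu_classes())
  if (nrows < 1 || ncols < 1) stop("grid dimensions must be positive")
  if (n_dates < 2) stop("`n_dates` must be >= 2")
  p0 <- as.numeric(initial_proportions)
  if (length(p0) != k || any(p0 < 0) || abs(sum(p0) - 1) > 1e-12)
    stop("`initial_proportions` must be ", k, " nonnegative values summing to 1")
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(k, k)) || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("`transition_matrix` must be ", k, "x", k, " row-stochastic (rows sum to 1)")
  dimnames(P) <- list(lu_classes(), lu_classes())
  structure(
    list(seed = as.integer(seed), nrows = as.integer(nrows), ncols = as.integer(ncols),
         cell_area_hm2 = cell_area_hm2, initial_proportions = p0,
         transition_matrix = P, n_dates = as.integer(n_dates),
         spatial_smoothing = as.integer(spatial_smoothing)),
    class = "landscape_spec")
}

#' Default built-up expansion transition matrix
#'
#' A mildly urbanizing regime: most classes persist with high
#' probability, cropland and forest leak a few percent per step into
#' built-up land, and built-up land is nearly absorbing -- the signature
#' transformation of a rapidly urbanizing province.
#'
#' @return A 7 x 7 row-stochastic matrix in [lu_classes()] order.
#' @export
default_transition_matrix <- function() {
  k <- length(lu_classes())
  P <- diag(k)
  dimnames(P) <- list(lu_classes(), lu_classes())
  leak <- function(from, to, p) {
    P[from, from] <<- P[from, from] - sum(p)
    P[from, to] <<- p
  }
  leak("cropland", c("built_up", "forest", "water"), c(0.030, 0.010, 0.005))
  leak("forest", c("built_up", "cropland", "grassland"), c(0.008, 0.008, 0.004))
  leak("grassland", c("built_up", "forest"), c(0.010, 0.010))
  leak("water", "wetland", 0.010)
  leak("wetland", "water", 0.020)
  leak("bare", "grassland", 0.020)
  P
}

#' Simulate a multi-date categorical landscape
#'
#' Date 1 is drawn i.i.d. from the initial proportions (optionally
#' clumped by a modal filter); each later date resamples every cell's
#' class independently from the transition-matrix row of its current
#' class. Identical seeds give identical output.
#'
#' @param spec A [landscape_spec()].
#' @return A list of `n_dates` [land_raster()] objects (dates `1..n`).
#' @export
simulate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  k <- length(lu_classes())
  set.seed(spec$seed)
  n <- spec$nrows * spec$ncols
  v <- matrix(sample.int(k, n, replace = TRUE, prob = spec$initial_proportions),
              spec$nrows, spec$ncols)
  if (spec$spatial_smoothing > 0L)
    v <- modal_filter(v, spec$spatial_smoothing, k)
  out <- vector("list", spec$n_dates)
  out[[1]] <- land_raster(v, spec$cell_area_hm2, date = 1L, levels = lu_classes())
  P <- spec$transition_matrix
  for (t in 2:spec$n_dates) {
    u <- stats::runif(n)
    cum <- P[v, , drop = FALSE]            # n x k row of probabilities per cell
    cum <- t(apply(cum, 1L, cumsum))
    nxt <- 1L + rowSums(cum < u)           # inverse-CDF draw per cell
    v <- matrix(as.integer(nxt), spec$nrows, spec$ncols)
    out[[t]] <- land_raster(v, spec$cell_area_hm2, date = t, levels = lu_classes())
  }
  attr(out, "spec") <- spec
  out
}

# modal (majority) filter with square neighbourhood of given radius;
# ties broken by lowest class index for determinism
modal_filter <- function(v, radius, k) {
  nr <- nrow(v); nc <- ncol(v)
  counts <- matrix(0L, nr * nc, k)
  for (di in -radius:radius) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    for (dj in -radius:radius) {
      cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
      shifted <- v[ri, cj, drop = FALSE]
      counts[cbind(seq_len(nr * nc), as.vector(shifted))] <-
        counts[cbind(seq_len(nr * nc), as.vector(shifted))] + 1L
    }
  }
  matrix(max.col(counts, ties.method = "first"), nr, nc)
}

#' Partition a grid into contiguous rectangular zones
#'
#' Tiles an `nrows x ncols` grid into `zrows x zcols` rectangular zones
#' of near-equal size (row/column breaks from an even split, remainders
#' spread over the leading bands). Zones stand in for administrative
#' units: each carries a unique id, its cell count and its geometric
#' centroid in planar km (origin at the grid's bottom-left corner).
#'
#' @param nrows,ncols Grid dimensions.
#' @param zrows,zcols Number of zone bands per dimension
#'   (`zrows <= nrows`, `zcols <= ncols`).
#' @param cell_area_hm2 Cell area in hectares (drives the km scale).
#' @return An object of class `zone_grid`: list with `map` (integer
#'   matrix of zone ids), `zones` (data.frame `zone_id`, `n_cells`,
#'   `x`, `y` centroids in km) and `cell_size_km`.
#' @export
generate_zones <- function(nrows, ncols, zrows, zcols, cell_area_hm2 = 100) {
  if (nrows < 1 || ncols < 1 || zrows < 1 || zcols < 1)
    stop("dimensions must be positive")
  if (zrows > nrows || zcols > ncols)
    stop("more zones than cells in one dimension")
  rb <- split_bands(nrows, zrows)
  cb <- split_bands(ncols, zcols)
  map <- outer(rb, cb, function(i, j) (i - 1L) * zcols + j)
  cs <- sqrt(cell_area_hm2 / 100)
  xs <- (seq_len(ncols) - 0.5) * cs
  ys <- (nrows - seq_len(nrows) + 0.5) * cs
  ids <- seq_len(zrows * zcols)
  n_cells <- tabulate(map, nbins = length(ids))
  cx <- vapply(ids, function(z) mean(xs[col(map)[map == z]]), numeric(1))
  cy <- vapply(ids, function(z) mean(ys[row(map)[map == z]]), numeric(1))
  structure(
    list(map = map,
         zones = data.frame(zone_id = ids, n_cells = n_cells, x = cx, y = cy),
         cell_size_km = cs),
    class = "zone_grid")
}

split_bands <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' @export
print.zone_grid <- function(x, ...) {
  cat("<zone_grid> ", nrow(x$zones), " zones on ", nrow(x$map), " x ",
      ncol(x$map), " cells (", x$cell_size_km, " km cells)\n", sep = "")
  invisible(x)
}

#' Simulate a crop economics table
#'
#' Draws reproducible grain-crop records (yield per hectare, sown area,
#' farm-gate price) from log-uniform ranges, the input needed to compute
#' the standard equivalent value of cropland. Default ranges bracket
#' provincial grain statistics: yields 3-9 t/hm2, sown areas 1e5-1e6
#' hm2, prices 2000-3000 currency/t. The ranges and seed are recorded
#' as attributes of the returned table.
#'
#' @param seed Integer seed.
#' @param n_crops Number of crops (>= 1).
#' @param yield_range,area_range,price_range Length-2 positive ranges for
#'   the log-uniform draws.
#' @return A data.frame with columns `crop`, `yield_per_area` (t/hm2),
#'   `sown_area` (hm2), `price` (currency/t).
#' @export
simulate_crop_table <- function(seed = 1L, n_crops = 6L,
                                yield_range = c(3, 9),
                                area_range = c(1e5, 1e6),
                                price_range = c(2000, 3000)) {
  if (n_crops < 1) stop("`n_crops` must be >= 1")
  stopifnot(all(yield_range > 0), all(area_range > 0), all(price_range > 0))
  set.seed(seed)
  runif_log <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  out <- data.frame(
    crop = paste0("crop_", seq_len(n_crops)),
    yield_per_area = runif_log(n_crops, yield_range),
    sown_area = runif_log(n_crops, area_range),
    price = runif_log(n_crops, price_range))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "ranges") <- list(yield = yield_range, area = area_range, price = price_range)
  out
}
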