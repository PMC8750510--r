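#' Per-class areas of a reclassified raster
#'
#' Counts cells per canonical class and converts to area. Nodata cells
#' are excluded.
#'
#' @param raster A reclassified [land_raster()] (values 1-7).
#' @return A data.frame with columns `class`, `n_cells`, `area_km2`,
#'   `area_hm2` in canonical class order.
#' @export
class_areas <- function(raster) {
  stopifnot(inherits(raster, "land_raster"))
  k <- length(lu_classes())
  v <- raster$values[!is.na(raster$values)]
  if (length(v) && (min(v) < 1L || max(v) > k))
    stop("raster holds codes outside 1..", k, "; reclassify first")
  n <- tabulate(v, nbins = k)
  data.frame(class = lu_classes(), n_cells = n,
             area_km2 = n * raster$cell_area_hm2 / 100,
             area_hm2 = n * raster$cell_area_hm2)
}

# coerce the various per-date area inputs to a dates x classes km2 matrix
as_area_matrix <- function(areas, dates = NULL) {
  k <- length(lu_classes())
  if (is.data.frame(areas) && all(c("date", "class", "area_km2") %in% names(areas))) {
    d <- unique(areas$date)
    m <- matrix(NA_real_, length(d), k, dimnames = list(as.character(d), lu_classes()))
    m[cbind(match(areas$date, d), match(areas$class, lu_classes()))] <- areas$area_km2
    if (anyNA(m)) stop("incomplete date x class area table")
    return(m)
  }
  if (is.list(areas) && !is.data.frame(areas)) {   # list of class_areas() frames or rasters
    rows <- lapply(areas, function(a) {
      if (inherits(a, "land_raster")) a <- class_areas(a)
      stats::setNames(a$area_km2, a$class)[lu_classes()]
    })
    m <- do.call(rbind, rows)
    colnames(m) <- lu_classes()
    rownames(m) <- as.character(
      if (!is.null(dates)) dates
      else if (!is.null(names(areas))) names(areas)
      else seq_along(areas))
    return(m)
  }
  m <- as.matrix(areas)
  if (ncol(m) != k) stop("area matrix must have ", k, " class columns")
  colnames(m) <- lu_classes()
  if (!is.null(dates)) rownames(m) <- as.character(dates)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}

#' Area-change accounting across dates
#'
#' From per-date, per-class areas computes the standard change table:
#' area ratios (percent of the per-date total), the variation
#' (later minus earlier area, km2) and the rate of change
#' (variation / earlier area x 100) for every consecutive date pair and
#' for the overall first-to-last interval. All arithmetic is at full
#' precision; the print method rounds to 2 decimals.
#'
#' A rate whose baseline area is zero is undefined and reported as `NA`
#' (flagged in the `undefined_rates` attribute), never as Inf.
#'
#' @param areas Per-date areas: a dates x classes matrix (km2), a tidy
#'   data.frame (`date`, `class`, `area_km2`), or a list of
#'   [class_areas()] results / rasters.
#' @param dates Optional date labels overriding those found in `areas`.
#' @return An object of class `area_change_table`: list with matrices
#'   `area` (km2), `ratio` (percent), `variation` (km2), `rate`
#'   (percent) and a data.frame `intervals`.
#' @export
area_change_table <- function(areas, dates = NULL) {
  m <- as_area_matrix(areas, dates)
  if (nrow(m) < 2) stop("need areas for at least 2 dates")
  if (any(m < 0)) stop("negative areas")
  ratio <- sweep(m, 1L, rowSums(m), "/") * 100
  d <- rownames(m)
  pairs <- cbind(seq_len(nrow(m) - 1L), seq(2L, nrow(m)))
  if (nrow(m) > 2) pairs <- rbind(pairs, c(1L, nrow(m)))
  variation <- m[pairs[, 2], , drop = FALSE] - m[pairs[, 1], , drop = FALSE]
  base <- m[pairs[, 1], , drop = FALSE]
  rate <- ifelse(base > 0, variation / base * 100, NA_real_)
  lab <- paste(d[pairs[, 1]], d[pairs[, 2]], sep = "-")
  rownames(variation) <- rownames(rate) <- lab
  structure(
    list(area = m, ratio = ratio, variation = variation, rate = rate,
         intervals = data.frame(from = d[pairs[, 1]], to = d[pairs[, 2]],
                                label = lab, stringsAsFactors = FALSE),
         undefined_rates = which(is.na(rate) & variation != 0, arr.ind = TRUE)),
    class = "area_change_table")
}

#' @export
print.area_change_table <- function(x, digits = 2, ...) {
  cat("Land-use area accounting (km2)\n\nArea (km2)\n")
  print(round(x$area, digits))
  cat("\nArea ratio (%)\n")
  print(round(x$ratio, digits))
  cat("\nVariation (km2)\n")
  print(round(x$variation, digits))
  cat("\nRate of change (%)\n")
  print(round(x$rate, digits))
  if (nrow(x$undefined_rates))
    cat("\nNote: rates with zero baseline area are undefined (NA).\n")
  invisible(x)
}

#' Land-use transfer matrix between two dates
#'
#' Cross-tabulates cell classes at two dates into a from-class x
#' to-class area matrix (the land-use application of a Markov state
#' transition), plus its row-stochastic probability form. Cells that are
#' nodata at either date are excluded from both marginals, so row sums
#' equal date-t class areas and column sums equal date-t+1 class areas
#' on the common valid mask, exactly.
#'
#' @param raster_t,raster_t1 Reclassified [land_raster()] objects on the
#'   same grid with equal cell areas.
#' @return An object of class `transfer_matrix`: list with `area`
#'   (km2 matrix), `P` (row-stochastic probabilities; rows with zero
#'   area are all-zero and listed in `empty_from`), and `dates`.
#' @export
transfer_matrix <- function(raster_t, raster_t1) {
  stopifnot(inherits(raster_t, "land_raster"), inherits(raster_t1, "land_raster"))
  if (!identical(dim(raster_t$values), dim(raster_t1$values)))
    stop("grid mismatch: rasters have different dimensions")
  if (raster_t$cell_area_hm2 != raster_t1$cell_area_hm2)
    stop("grid mismatch: rasters have different cell areas")
  k <- length(lu_classes())
  a <- raster_t$values; b <- raster_t1$values
  mask <- !is.na(a) & !is.na(b)
  av <- a[mask]; bv <- b[mask]
  if (length(av) && (min(c(av, bv)) < 1L || max(c(av, bv)) > k))
    stop("raster holds codes outside 1..", k, "; reclassify first")
  counts <- matrix(0, k, k, dimnames = list(lu_classes(), lu_classes()))
  tab <- table(factor(av, levels = seq_len(k)), factor(bv, levels = seq_len(k)))
  counts[] <- as.numeric(tab)
  area <- counts * raster_t$cell_area_hm2 / 100
  rs <- rowSums(area)
  P <- area / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  structure(
    list(area = area, P = P, empty_from = lu_classes()[rs == 0],
         dates = c(raster_t$date, raster_t1$date),
         cell_area_hm2 = raster_t$cell_area_hm2),
    class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, digits = 2, ...) {
  cat("Land-use transfer matrix (km2)")
  if (length(x$dates) == 2) cat(", ", x$dates[1], " -> ", x$dates[2], sep = "")
  cat("\n")
  print(round(x$area, digits))
  cat("\nTransition probabilities\n")
  print(round(x$P, 4))
  if (length(x$empty_from))
    cat("Rows with no area at the first date:",
        paste(x$empty_from, collapse = ", "), "\n")
  invisible(x)
}

#' Write a labelled class-by-class matrix as CSV
#'
#' Shared CSV writer for transfer matrices and change tables; a leading
#' comment line states the units.
#' @param x A `transfer_matrix` or plain matrix.
#' @param path Output path.
#' @param comment Header comment (units).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, comment = "# units: km2") {
  m <- if (inherits(x, "transfer_matrix")) x$area else as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.csv(as.data.frame(m), con, row.names = TRUE)
  invisible(path)
}
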