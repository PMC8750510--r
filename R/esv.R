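#' ESV service-function codes and groups
#'
#' The eleven ecosystem service functions of the equivalent-factor
#' framework, grouped into four top-level services.
#'
#' @return `esv_functions()`: character vector of the 11 function codes
#'   (FP food production, RMP raw material production, WS water supply,
#'   GR gas regulation, CR climate regulation, PE purifying environment,
#'   HR hydrological regulation, SC soil conservation, MNS maintaining
#'   nutrient supply, MB maintaining biodiversity, AL aesthetic
#'   landscape). `esv_services()`: named vector mapping each function to
#'   its top-level service.
#' @export
esv_functions <- function() {
  c("FP", "RMP", "WS", "GR", "CR", "PE", "HR", "SC", "MNS", "MB", "AL")
}

#' @rdname esv_functions
#' @export
esv_services <- function() {
  c(FP = "provisioning", RMP = "provisioning", WS = "provisioning",
    GR = "regulating", CR = "regulating", PE = "regulating", HR = "regulating",
    SC = "supporting", MNS = "supporting", MB = "supporting",
    AL = "cultural")
}

# construct the esv_coef S3 object from a classes x functions matrix
new_esv_coef <- function(values, currency = "USD") {
  k <- length(lu_classes()); f <- length(esv_functions())
  stopifnot(is.matrix(values), nrow(values) == k, ncol(values) == f)
  dimnames(values) <- list(lu_classes(), esv_functions())
  structure(
    list(values = values, class_totals = rowSums(values),
         services = esv_services(), currency = currency,
         unit = paste0(currency, " hm-2 a-1")),
    class = "esv_coef")
}

#' Ecosystem-services value coefficient table
#'
#' Loads a per-class, per-function coefficient table VCif (currency per
#' hectare per year). The packaged default is the grain-yield-corrected
#' provincial table for a central-China study region, in USD: six valued
#' classes by eleven functions. Built-up land carries no coefficients in
#' the source table and is represented explicitly as a zero row so class
#' sets stay aligned with transfer matrices. Coefficients may be
#' negative (cropland's water supply is -31.60: paddy agriculture is a
#' net water consumer).
#'
#' @param path CSV with columns `class`, `function`, `service`, `value`;
#'   `NULL` loads the packaged table.
#' @param currency Currency label carried as metadata (no conversion is
#'   ever performed).
#' @return An object of class `esv_coef`: list with `values` (7 x 11
#'   matrix), `class_totals` (VCi, the row sums), `services`, `currency`.
#' @export
esv_coefficients <- function(path = NULL, currency = "USD") {
  if (is.null(path))
    path <- system.file("extdata", "esv_coefficients_hubei_usd.csv",
                        package = "esvland", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("class", "function", "value")
  if (!all(need %in% names(df))) stop("coefficient CSV needs columns: ",
                                      paste(need, collapse = ", "))
  m <- matrix(0, length(lu_classes()), length(esv_functions()),
              dimnames = list(lu_classes(), esv_functions()))
  ci <- match(df$class, lu_classes()); fi <- match(df[["function"]], esv_functions())
  if (anyNA(ci)) stop("unknown class in coefficient CSV: ",
                      paste(unique(df$class[is.na(ci)]), collapse = ", "))
  if (anyNA(fi)) stop("unknown function code in coefficient CSV: ",
                      paste(unique(df[["function"]][is.na(fi)]), collapse = ", "))
  m[cbind(ci, fi)] <- df$value
  new_esv_coef(m, currency)
}

#' @export
print.esv_coef <- function(x, ...) {
  cat("ESV coefficient table (", x$unit, ")\n", sep = "")
  print(round(x$values, 2))
  cat("\nPer-class totals (VCi):\n")
  print(round(x$class_totals, 2))
  invisible(x)
}

#' Standard equivalent value from crop economics
#'
#' The monetary value of one standard equivalent factor: one-seventh of
#' the sown-area-weighted mean annual grain output value per hectare,
#'
#'   En = (1/7) * sum_i(p_i * q_i * m_i) / M,   M = sum_i m_i
#'
#' where q_i is yield per hectare, p_i the price and m_i the sown area
#' of crop i. Weighting by sown area makes the numerator total output
#' value (currency) and the result currency per hectare.
#'
#' @param crops Data.frame with columns `yield_per_area`, `sown_area`,
#'   `price` (see [simulate_crop_table()]).
#' @return The equivalent value En (currency per hm2).
#' @export
standard_equivalent_value <- function(crops) {
  need <- c("yield_per_area", "sown_area", "price")
  if (!all(need %in% names(crops)))
    stop("crop table needs columns: ", paste(need, collapse = ", "))
  q <- crops$yield_per_area; m <- crops$sown_area; p <- crops$price
  if (any(q < 0) || any(m < 0) || any(p < 0)) stop("negative crop inputs")
  M <- sum(m)
  if (M <= 0) stop("total sown area is zero")
  sum(p * q * m) / M / 7
}

#' Scale equivalent factors into value coefficients
#'
#' Multiplies a dimensionless per-class, per-function equivalent-factor
#' table by the standard equivalent value En to obtain coefficients in
#' currency per hectare per year. The packaged [esv_coefficients()]
#' table is already scaled and is used directly when no regional crop
#' data are at hand.
#'
#' @param equivalents 7 x 11 matrix of equivalent factors (or an
#'   `esv_coef` whose values are factors).
#' @param En Standard equivalent value (> 0), from
#'   [standard_equivalent_value()].
#' @param currency Currency label for the result.
#' @return An `esv_coef` object.
#' @export
scale_coefficients <- function(equivalents, En, currency = "CNY") {
  if (!is.numeric(En) || length(En) != 1L || En <= 0) stop("`En` must be > 0")
  m <- if (inherits(equivalents, "esv_coef")) equivalents$values else as.matrix(equivalents)
  new_esv_coef(m * En, currency)
}

# normalize an area argument to a named hm2 vector over lu_classes()
as_area_hm2 <- function(areas, unit = c("km2", "hm2")) {
  unit <- match.arg(unit)
  if (inherits(areas, "land_raster")) {
    a <- class_areas(areas)
    return(stats::setNames(a$area_hm2, a$class))
  }
  if (is.data.frame(areas)) {
    if ("area_hm2" %in% names(areas))
      return(stats::setNames(areas$area_hm2, areas$class)[lu_classes()])
    if ("area_km2" %in% names(areas))
      return(stats::setNames(areas$area_km2 * 100, areas$class)[lu_classes()])
    stop("area data.frame needs `area_km2` or `area_hm2`")
  }
  v <- as.numeric(areas)
  if (length(v) != length(lu_classes())) stop("need one area per class")
  if (!is.null(names(areas))) v <- v[match(lu_classes(), names(areas))]
  if (anyNA(v)) stop("areas missing for some classes")
  stats::setNames(if (unit == "km2") v * 100 else v, lu_classes())
}

#' ESV by land-use class
#'
#' Per-class ecosystem services value: ESV_i = A_i x VC_i, with A_i the
#' class area in hectares and VC_i the per-class total coefficient.
#'
#' @param areas Per-class areas: a named vector, a [class_areas()]
#'   data.frame, or a reclassified raster. Bare numeric vectors are
#'   interpreted in the unit given by `unit`.
#' @param coeffs An [esv_coefficients()] table.
#' @param unit Unit of a bare numeric `areas` vector (`"km2"` default).
#' @return Data.frame `class`, `area_hm2`, `vc`, `esv` with the total in
#'   attribute `total`.
#' @export
esv_by_type <- function(areas, coeffs, unit = c("km2", "hm2")) {
  stopifnot(inherits(coeffs, "esv_coef"))
  a <- as_area_hm2(areas, unit)
  if (any(a < 0)) stop("negative areas")
  esv <- a * coeffs$class_totals
  out <- data.frame(class = lu_classes(), area_hm2 = unname(a),
                    vc = unname(coeffs$class_totals), esv = unname(esv))
  attr(out, "total") <- sum(esv)
  attr(out, "currency") <- coeffs$currency
  out
}

#' ESV by service function
#'
#' Per-function ecosystem services value: ESV_f = sum_i A_i x VC_if,
#' plus subtotals for the four top-level services.
#'
#' @inheritParams esv_by_type
#' @return Data.frame `service`, `fun`, `esv`; attributes `total` and
#'   `service_totals`.
#' @export
esv_by_function <- function(areas, coeffs, unit = c("km2", "hm2")) {
  stopifnot(inherits(coeffs, "esv_coef"))
  a <- as_area_hm2(areas, unit)
  if (any(a < 0)) stop("negative areas")
  esv <- as.vector(a %*% coeffs$values)
  names(esv) <- esv_functions()
  svc <- coeffs$services[esv_functions()]
  out <- data.frame(service = unname(svc), fun = esv_functions(), esv = unname(esv))
  attr(out, "total") <- sum(esv)
  attr(out, "service_totals") <- tapply(esv, svc, sum)[unique(unname(svc))]
  attr(out, "currency") <- coeffs$currency
  out
}

#' Multi-date ESV assessment with change tables
#'
#' Runs the full valuation over a per-date area table: ESV by class, by
#' function and by top-level service for every date, plus the "variety"
#' (difference) tables over every consecutive interval and the overall
#' first-to-last interval. This is the computation behind the classic
#' class-wise and function-wise ESV summary tables.
#'
#' @param areas Per-date areas as accepted by [area_change_table()].
#' @param coeffs An [esv_coefficients()] table.
#' @param dates Optional date labels.
#' @return Object of class `esv_assessment`: matrices `by_class`
#'   (dates x classes, currency), `by_function` (dates x 11),
#'   `by_service` (dates x 4), `totals`, and the corresponding
#'   `variety_*` interval matrices.
#' @export
esv_assessment <- function(areas, coeffs, dates = NULL) {
  stopifnot(inherits(coeffs, "esv_coef"))
  m <- as_area_matrix(areas, dates)            # km2
  a <- m * 100                                 # hm2
  by_class <- sweep(a, 2L, coeffs$class_totals, "*")
  by_fun <- a %*% coeffs$values
  svc <- coeffs$services[esv_functions()]
  by_svc <- t(apply(by_fun, 1L, function(r) tapply(r, svc, sum)))
  by_svc <- by_svc[, unique(unname(svc)), drop = FALSE]
  totals <- rowSums(by_class)
  n <- nrow(m)
  pairs <- cbind(seq_len(n - 1L), seq(2L, n))
  if (n > 2) pairs <- rbind(pairs, c(1L, n))
  lab <- paste(rownames(m)[pairs[, 1]], rownames(m)[pairs[, 2]], sep = "-")
  diffm <- function(x) {
    d <- x[pairs[, 2], , drop = FALSE] - x[pairs[, 1], , drop = FALSE]
    rownames(d) <- lab
    d
  }
  structure(
    list(by_class = by_class, by_function = by_fun, by_service = by_svc,
         totals = totals,
         variety_class = diffm(by_class), variety_function = diffm(by_fun),
         variety_service = diffm(by_svc),
         variety_total = stats::setNames(totals[pairs[, 2]] - totals[pairs[, 1]], lab),
         intervals = lab, currency = coeffs$currency),
    class = "esv_assessment")
}

#' @export
print.esv_assessment <- function(x, billions = TRUE, digits = 2, ...) {
  s <- if (billions) 1e9 else 1
  u <- paste0(x$currency, if (billions) " billion" else "")
  cat("ESV by land-use type (", u, ")\n", sep = "")
  print(round(cbind(x$by_class / s, Total = x$totals / s), digits))
  cat("\nESV variety by type (", u, ")\n", sep = "")
  print(round(cbind(x$variety_class / s, Total = x$variety_total / s), digits))
  cat("\nESV by service function (", u, ")\n", sep = "")
  print(round(cbind(x$by_function / s, Total = x$totals / s), digits))
  cat("\nESV variety by function (", u, ")\n", sep = "")
  print(round(cbind(x$variety_function / s, Total = x$variety_total / s), digits))
  cat("\nESV by top-level service (", u, ")\n", sep = "")
  print(round(x$by_service / s, digits))
  invisible(x)
}

#' ESV variety (differences) between dated results
#'
#' Convenience wrapper returning only the change tables of an
#' [esv_assessment()].
#'
#' @inheritParams esv_assessment
#' @return List of matrices `by_class`, `by_function`, `by_service`,
#'   `total` over consecutive intervals plus the overall interval.
#' @export
esv_variety <- function(areas, coeffs, dates = NULL) {
  z <- esv_assessment(areas, coeffs, dates)
  list(by_class = z$variety_class, by_function = z$variety_function,
       by_service = z$variety_service, total = z$variety_total)
}

#' Zonal ESV over a partitioned landscape
#'
#' Per-zone ecosystem services value: within each zone, class areas (in
#' hectares) times per-class coefficients, summed. Zone values sum to
#' the global ESV exactly. Cells whose zone id is missing are
#' accumulated into a flagged `unassigned` attribute, never dropped
#' silently.
#'
#' @param raster A reclassified [land_raster()].
#' @param zones A [generate_zones()] partition on the same grid.
#' @param coeffs An [esv_coefficients()] table.
#' @return Data.frame `zone_id`, `x`, `y`, `esv`; attributes
#'   `unassigned` (currency in unzoned cells) and `currency`.
#' @export
zonal_esv <- function(raster, zones, coeffs) {
  stopifnot(inherits(raster, "land_raster"), inherits(zones, "zone_grid"),
            inherits(coeffs, "esv_coef"))
  if (!identical(dim(raster$values), dim(zones$map)))
    stop("zone partition does not cover the raster grid")
  v <- raster$values
  z <- zones$map
  ok <- !is.na(v)
  vc <- coeffs$class_totals
  cellv <- vc[v[ok]] * raster$cell_area_hm2     # currency per cell
  zid <- z[ok]
  assigned <- !is.na(zid)
  esv <- vapply(zones$zones$zone_id,
                function(id) sum(cellv[assigned & zid == id]), numeric(1))
  out <- data.frame(zone_id = zones$zones$zone_id,
                    x = zones$zones$x, y = zones$zones$y, esv = esv)
  unas <- sum(cellv[!assigned])
  if (unas != 0)
    warning("cells outside all zones hold ESV ", format(unas),
            "; reported in attr(, 'unassigned')")
  attr(out, "unassigned") <- unas
  attr(out, "currency") <- coeffs$currency
  out
}
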