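#' Canonical land-use classes
#'
#' The fixed seven-class land-use scheme used throughout the package:
#' cropland, forest, grassland, water, wetland, bare and built-up land.
#' All matrices (areas, transfer matrices, value coefficients) are ordered
#' by this vector so results are directly comparable.
#'
#' @return Character vector of the seven class names, in canonical order.
#' @export
lu_classes <- function() {
  c("cropland", "forest", "grassland", "water", "wetland", "bare", "built_up")
}

#' Create a categorical land-use raster
#'
#' A lightweight container for a dated categorical grid on a planar
#' coordinate system. Cells hold integer class codes; `NA` marks nodata.
#' The grid is row-major with origin at the top-left corner; planar
#' coordinates (km) place the bottom-left corner of the grid at (0, 0)
#' with y increasing northwards.
#'
#' @param values Integer matrix of class codes (`NA` = nodata).
#' @param cell_area_hm2 Area of one cell in hectares. The default 100 hm2
#'   corresponds to a 1 km x 1 km cell.
#' @param date Optional date label (year or character).
#' @param levels Optional character vector naming the codes `1..k`; set by
#'   [reclassify()] to [lu_classes()].
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(values, cell_area_hm2 = 100, date = NULL, levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_area_hm2) || length(cell_area_hm2) != 1L || cell_area_hm2 <= 0)
    stop("`cell_area_hm2` must be a single positive number")
  structure(
    list(values = values, cell_area_hm2 = as.numeric(cell_area_hm2),
         date = date, levels = levels),
    class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat("<land_raster> ", nrow(x$values), " x ", ncol(x$values),
      " cells, ", x$cell_area_hm2, " hm2/cell", sep = "")
  if (!is.null(x$date)) cat(", date ", x$date, sep = "")
  cat("\n")
  tab <- table(factor(x$values[!is.na(x$values)]))
  if (length(tab)) {
    lab <- names(tab)
    if (!is.null(x$levels)) {
      idx <- suppressWarnings(as.integer(names(tab)))
      ok <- !is.na(idx) & idx >= 1L & idx <= length(x$levels)
      lab[ok] <- x$levels[idx[ok]]
    }
    cat("  codes: ", paste0(lab, " (", as.integer(tab), ")", collapse = ", "), "\n", sep = "")
  }
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  nodata cells:", n_na, "\n")
  invisible(x)
}

#' @export
as.matrix.land_raster <- function(x, ...) x$values

#' @export
dim.land_raster <- function(x) dim(x$values)

# cell edge length in km implied by the cell area (100 hm2 = 1 km2)
cell_size_km <- function(r) sqrt(r$cell_area_hm2 / 100)

#' Build a reclassification scheme
#'
#' Maps raw integer raster codes onto the canonical seven-class scheme.
#' The mapping must be total over the codes present in a raster:
#' [reclassify()] raises an error listing any unmapped code rather than
#' dropping cells silently.
#'
#' @param codes Integer vector of raw codes.
#' @param classes Character vector (same length) of target classes; each
#'   must be one of [lu_classes()].
#' @return A named integer vector (class index 1-7, named by raw code)
#'   with class `class_scheme`.
#' @examples
#' # merge two cropland legends (codes 11, 12) into one class
#' class_scheme(c(11, 12, 21), c("cropland", "cropland", "forest"))
#' @export
class_scheme <- function(codes, classes) {
  codes <- as.integer(codes)
  if (length(codes) != length(classes)) stop("`codes` and `classes` lengths differ")
  if (anyDuplicated(codes)) stop("duplicated raw codes in scheme")
  idx <- match(classes, lu_classes())
  if (anyNA(idx))
    stop("unknown target class(es): ", paste(unique(classes[is.na(idx)]), collapse = ", "))
  structure(stats::setNames(idx, codes), class = "class_scheme")
}

#' Reclassify a raster to the canonical class scheme
#'
#' @param raster A [land_raster()].
#' @param scheme A [class_scheme()], or a named vector mapping raw codes to
#'   class names.
#' @return A `land_raster` with values 1-7 and `levels` set to
#'   [lu_classes()]; nodata cells are preserved.
#' @export
reclassify <- function(raster, scheme) {
  stopifnot(inherits(raster, "land_raster"))
  if (!inherits(scheme, "class_scheme"))
    scheme <- class_scheme(names(scheme), as.character(scheme))
  v <- raster$values
  present <- unique(v[!is.na(v)])
  unmapped <- setdiff(present, as.integer(names(scheme)))
  if (length(unmapped))
    stop("unmapped raster code(s): ", paste(sort(unmapped), collapse = ", "))
  out <- v
  out[] <- unname(scheme[as.character(v)])
  land_raster(out, cell_area_hm2 = raster$cell_area_hm2, date = raster$date,
              levels = lu_classes())
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange for categorical grids: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of integer codes, top row first. `cellsize` is in km;
#' the cell area in hm2 is derived as `cellsize^2 * 100`.
#'
#' @param raster A [land_raster()].
#' @param path File path.
#' @return `read_ascii_grid` returns a `land_raster`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "land_raster"))
  v <- raster$values
  cs <- cell_size_km(raster)
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", format(cs, digits = 15)),
    "NODATA_value -9999")
  body <- apply(v, 1L, function(row) {
    row[is.na(row)] <- -9999L
    paste(row, collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param date Optional date label attached to the raster read back.
#' @export
read_ascii_grid <- function(path, date = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- if (!is.null(hdr$cellsize)) hdr$cellsize else 1
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) stop("ASCII grid row count mismatch in ", path)
  v <- t(vapply(body, function(l) as.integer(strsplit(trimws(l), "[[:space:]]+")[[1]]),
                integer(hdr$ncols), USE.NAMES = FALSE))
  v[v == nodata] <- NA_integer_
  land_raster(v, cell_area_hm2 = cs^2 * 100, date = date)
}
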