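#' Packaged per-date land-use area table
#'
#' Per-class areas (km2) of a seven-class provincial land-use
#' classification at five dates (1995-2015 in five-year steps), as
#' published summary statistics. Together with [esv_coefficients()] this
#' drives the "table mode" of [run_pipeline()], which reproduces the
#' full ESV accounting without any raster input.
#'
#' @param path CSV with columns `date`, `class`, `area_km2`; `NULL`
#'   loads the packaged table.
#' @return A tidy data.frame `date`, `class`, `area_km2`.
#' @export
hubei_landuse_areas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hubei_landuse_areas_km2.csv",
                        package = "esvland", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a pipeline configuration
#'
#' Validates and normalises the configuration for [run_pipeline()].
#' Exactly one input mode applies:
#'
#' * `mode = "tables"`: no rasters; per-date class areas (packaged
#'   table by default) feed the change accounting and valuation only.
#' * `mode = "synthetic"`: a [landscape_spec()] simulates the rasters.
#' * `mode = "rasters"`: ASCII-grid paths by date, with a class scheme
#'   CSV mapping raw codes onto the canonical classes.
#'
#' @param mode `"tables"`, `"synthetic"` or `"rasters"`.
#' @param areas Optional per-date area table for table mode (default:
#'   the packaged one).
#' @param spec A [landscape_spec()] (synthetic mode).
#' @param raster_paths Named character vector (names = dates) of ASCII
#'   grid paths (raster mode).
#' @param scheme_path CSV (`code`, `class`) for reclassification in
#'   raster mode; `NULL` if rasters already hold canonical codes 1-7.
#' @param coeffs_path Coefficient CSV; `NULL` for the packaged table.
#' @param crops_path Optional crop economics CSV (`crop`,
#'   `yield_per_area`, `sown_area`, `price`); when supplied the standard
#'   equivalent value is computed and reported in the manifest.
#' @param zones `zrows`/`zcols` of the zone partition (synthetic and
#'   raster modes), as a length-2 integer vector.
#' @param weights_scheme `"queen"` or `"rook"` contiguity.
#' @param n_permutations Permutations for Moran inference.
#' @param seed Integer seed for all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("tables", "synthetic", "rasters"),
                            areas = NULL, spec = NULL, raster_paths = NULL,
                            scheme_path = NULL, coeffs_path = NULL,
                            crops_path = NULL, zones = c(5L, 5L),
                            weights_scheme = "queen",
                            n_permutations = 999L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && !inherits(spec, "landscape_spec"))
    stop("synthetic mode needs a `landscape_spec`")
  if (mode == "rasters") {
    if (is.null(raster_paths) || length(raster_paths) < 2)
      stop("raster mode needs >= 2 dated raster paths")
    missing <- raster_paths[!file.exists(raster_paths)]
    if (length(missing))
      stop("raster file(s) not found: ", paste(missing, collapse = ", "))
    if (!is.null(scheme_path) && !file.exists(scheme_path))
      stop("scheme file not found: ", scheme_path)
  }
  for (p in c(coeffs_path, crops_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  structure(
    list(mode = mode, areas = areas, spec = spec, raster_paths = raster_paths,
         scheme_path = scheme_path, coeffs_path = coeffs_path,
         crops_path = crops_path, zones = as.integer(zones),
         weights_scheme = weights_scheme,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `spec` is given as
#' a mapping of [landscape_spec()] fields (with `transition_matrix` as a
#' list of rows).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) {
    sp <- y$spec
    if (!is.null(sp$transition_matrix))
      sp$transition_matrix <- do.call(rbind, sp$transition_matrix)
    y$spec <- do.call(landscape_spec, sp)
  }
  if (!is.null(y$raster_paths)) y$raster_paths <- unlist(y$raster_paths)
  if (!is.null(y$zones)) y$zones <- unlist(y$zones)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, per the configured mode: landscape simulation or raster
#' ingestion, reclassification, per-date area accounting, transfer
#' matrices over consecutive dates, ESV valuation by class and function,
#' zonal ESV, Moran's I and Gi* hot-spot analysis per date, and the
#' center-of-gravity trajectory. Table mode stops after the valuation
#' stage (it has no spatial support). A stage failure aborts with an
#' error naming the stage.
#'
#' The run is deterministic given the configuration and seed; the
#' manifest records seed, package and R versions and per-stage shapes.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param out_dir Optional directory: results are additionally written
#'   as CSV (plus a JSON manifest).
#' @return Object of class `esv_pipeline`: list with (as applicable)
#'   `rasters`, `zones`, `area_table`, `transfers`, `esv`, `zonal`,
#'   `moran`, `hotspots`, `gravity`, `En`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  coeffs <- stage("coefficients", esv_coefficients(config$coeffs_path))
  En <- NULL
  if (!is.null(config$crops_path))
    En <- stage("equivalent_value",
                standard_equivalent_value(utils::read.csv(config$crops_path)))

  res <- list(config = config, En = En)
  if (config$mode == "tables") {
    areas <- if (is.null(config$areas)) hubei_landuse_areas() else config$areas
    res$area_table <- stage("area_change", area_change_table(areas))
    res$esv <- stage("valuation", esv_assessment(areas, coeffs))
  } else {
    rasters <- if (config$mode == "synthetic") {
      stage("simulate", simulate_landscape(config$spec))
    } else {
      stage("ingest", {
        rs <- Map(read_ascii_grid, config$raster_paths,
                  names(config$raster_paths))
        if (!is.null(config$scheme_path)) {
          sc <- utils::read.csv(config$scheme_path, stringsAsFactors = FALSE)
          sch <- class_scheme(sc$code, sc$class)
          rs <- lapply(rs, reclassify, scheme = sch)
        } else {
          rs <- lapply(rs, function(r) { r$levels <- lu_classes(); r })
        }
        rs
      })
    }
    res$rasters <- rasters
    dates <- vapply(rasters, function(r) as.character(r$date), character(1))
    res$zones <- stage("zones",
      generate_zones(nrow(rasters[[1]]$values), ncol(rasters[[1]]$values),
                     config$zones[1], config$zones[2],
                     rasters[[1]]$cell_area_hm2))
    res$area_table <- stage("area_change",
      area_change_table(lapply(rasters, class_areas), dates = dates))
    res$transfers <- stage("transfer", {
      tr <- Map(transfer_matrix, rasters[-length(rasters)], rasters[-1])
      names(tr) <- paste(dates[-length(dates)], dates[-1], sep = "-")
      tr
    })
    res$esv <- stage("valuation",
      esv_assessment(lapply(rasters, class_areas), coeffs, dates = dates))
    res$zonal <- stage("zonal_esv", {
      z <- lapply(rasters, zonal_esv, zones = res$zones, coeffs = coeffs)
      names(z) <- dates
      z
    })
    w_moran <- stage("weights",
      zone_weights(res$zones, scheme = config$weights_scheme, style = "W"))
    w_gi <- zone_weights(res$zones, scheme = config$weights_scheme,
                         style = "B", include_self = TRUE)
    res$moran <- stage("moran", {
      mor <- lapply(res$zonal, function(z)
        global_morans_i(z$esv, w_moran, nsim = config$n_permutations,
                        seed = config$seed))
      mor
    })
    res$hotspots <- stage("hotspots",
      lapply(res$zonal, function(z) getis_ord_gstar(z$esv, w_gi)))
    res$gravity <- stage("gravity", {
      vals <- do.call(rbind, lapply(res$zonal, function(z) z$esv))
      rownames(vals) <- dates
      gravity_track(vals, res$zones$zones)
    })
  }
  res$manifest <- list(
    mode = config$mode, seed = config$seed,
    n_permutations = config$n_permutations,
    package_version = as.character(utils::packageVersion("esvland")),
    r_version = R.version.string,
    n_dates = nrow(res$area_table$area),
    n_classes = length(lu_classes()),
    n_zones = if (!is.null(res$zones)) nrow(res$zones$zones) else 0L,
    total_esv = unname(res$esv$totals))
  class(res) <- "esv_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.esv_pipeline <- function(x, ...) {
  cat("<esv_pipeline> mode:", x$config$mode, "\n")
  cat("  dates:", paste(rownames(x$area_table$area), collapse = ", "), "\n")
  cat("  total ESV (", x$esv$currency, " billion): ",
      paste(format(round(x$esv$totals / 1e9, 2), trim = TRUE), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$moran))
    cat("  Moran's I:",
        paste(format(vapply(x$moran, `[[`, numeric(1), "I"), digits = 3),
              collapse = ", "), "\n")
  invisible(x)
}

# write the result bundle as CSVs + JSON manifest
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  at <- res$area_table
  utils::write.csv(round(at$area, 6), p("areas_km2.csv"))
  utils::write.csv(round(at$ratio, 6), p("area_ratio_pct.csv"))
  utils::write.csv(round(at$variation, 6), p("area_variation_km2.csv"))
  utils::write.csv(round(at$rate, 6), p("area_rate_pct.csv"))
  utils::write.csv(round(cbind(res$esv$by_class, Total = res$esv$totals) / 1e9, 6),
                   p("esv_by_class_billion.csv"))
  utils::write.csv(round(cbind(res$esv$by_function, Total = res$esv$totals) / 1e9, 6),
                   p("esv_by_function_billion.csv"))
  utils::write.csv(round(cbind(res$esv$variety_class,
                               Total = res$esv$variety_total) / 1e9, 6),
                   p("esv_variety_class_billion.csv"))
  utils::write.csv(round(cbind(res$esv$variety_function,
                               Total = res$esv$variety_total) / 1e9, 6),
                   p("esv_variety_function_billion.csv"))
  if (!is.null(res$transfers))
    for (nm in names(res$transfers))
      write_matrix_csv(res$transfers[[nm]], p(paste0("transfer_", nm, ".csv")))
  if (!is.null(res$zonal)) {
    zz <- do.call(rbind, Map(function(d, z) cbind(date = d, z),
                             names(res$zonal), res$zonal))
    utils::write.csv(zz, p("zonal_esv.csv"), row.names = FALSE)
  }
  if (!is.null(res$moran)) {
    mo <- data.frame(date = names(res$moran),
                     I = vapply(res$moran, `[[`, numeric(1), "I"),
                     expectation = vapply(res$moran, `[[`, numeric(1), "expectation"),
                     p_value = vapply(res$moran, `[[`, numeric(1), "p_value"))
    utils::write.csv(mo, p("moran.csv"), row.names = FALSE)
    sc <- do.call(rbind, Map(function(d, m) cbind(date = d, m$scatter),
                             names(res$moran), res$moran))
    utils::write.csv(sc, p("moran_scatter.csv"), row.names = FALSE)
  }
  if (!is.null(res$hotspots)) {
    hs <- do.call(rbind, Map(function(d, h) cbind(date = d, as.data.frame(h)),
                             names(res$hotspots), res$hotspots))
    utils::write.csv(hs, p("hotspots.csv"), row.names = FALSE)
  }
  if (!is.null(res$gravity)) {
    utils::write.csv(res$gravity$centroids, p("gravity_centroids.csv"),
                     row.names = FALSE)
    utils::write.csv(res$gravity$intervals, p("gravity_intervals.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Formatted report of pipeline tables
#'
#' Renders the change-accounting and valuation tables with conventional
#' rounding (areas and rates to 2 decimals, ESV in billions to 2
#' decimals) as fixed-width text. An empty result renders headers only.
#'
#' @param res An `esv_pipeline` result.
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
report_tables <- function(res) {
  stopifnot(inherits(res, "esv_pipeline"))
  out <- character()
  emit <- function(...) out <<- c(out, paste0(...))
  fmt <- function(m) utils::capture.output(print(round(m, 2)))
  at <- res$area_table
  emit("== Land-use areas (km2) =="); out <- c(out, fmt(at$area), "")
  emit("== Area ratio (%) =="); out <- c(out, fmt(at$ratio), "")
  emit("== Variation (km2) =="); out <- c(out, fmt(at$variation), "")
  emit("== Rate of change (%) =="); out <- c(out, fmt(at$rate), "")
  emit("== ESV by type (", res$esv$currency, " billion) ==")
  out <- c(out, fmt(cbind(res$esv$by_class, Total = res$esv$totals) / 1e9), "")
  emit("== ESV variety by type ==")
  out <- c(out, fmt(cbind(res$esv$variety_class, Total = res$esv$variety_total) / 1e9), "")
  emit("== ESV by function (", res$esv$currency, " billion) ==")
  out <- c(out, fmt(cbind(res$esv$by_function, Total = res$esv$totals) / 1e9), "")
  emit("== ESV variety by function ==")
  out <- c(out, fmt(cbind(res$esv$variety_function, Total = res$esv$variety_total) / 1e9), "")
  cat(out, sep = "\n")
  invisible(out)
}
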