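#' Value-weighted center of gravity
#'
#' The mass-weighted mean of zone coordinates,
#' xbar = sum(m_i x_i) / sum(m_i) (and likewise for y). With
#' nonnegative masses the centroid lies inside the convex hull of the
#' zone coordinates.
#'
#' @param masses Nonnegative zone masses (here zonal ESV); their sum
#'   must be positive.
#' @param x,y Zone coordinates (planar, same units, typically km).
#' @return Named numeric `c(x, y)`.
#' @export
esv_centroid <- function(masses, x, y) {
  if (length(masses) != length(x) || length(x) != length(y))
    stop("masses and coordinates must have equal length")
  if (any(masses < 0)) stop("negative mass")
  M <- sum(masses)
  if (M <= 0) stop("total mass is zero")
  c(x = sum(masses * x) / M, y = sum(masses * y) / M)
}

#' Shift angle between two centroids
#'
#' Direction of the displacement from `c1` to `c2` via the two-argument
#' arctangent (which absorbs the quadrant-adjustment coefficient of the
#' piecewise single-argument form). Two conventions are offered, since
#' field usage varies: `"east_ccw"` measures counterclockwise from due
#' east in [0, 360); `"north_cw"` is the compass bearing, clockwise from
#' due north.
#'
#' @param c1,c2 Length-2 centroids `(x, y)`.
#' @param convention `"east_ccw"` (default) or `"north_cw"`.
#' @return Angle in degrees in [0, 360).
#' @export
shift_angle <- function(c1, c2, convention = c("east_ccw", "north_cw")) {
  convention <- match.arg(convention)
  dx <- c2[[1]] - c1[[1]]; dy <- c2[[2]] - c1[[2]]
  if (dx == 0 && dy == 0) stop("identical centroids: angle undefined")
  a <- atan2(dy, dx) * 180 / pi
  if (convention == "north_cw") a <- 90 - a
  a %% 360
}

#' Shift distance between two centroids
#'
#' Euclidean displacement in the coordinate units (km for
#' [generate_zones()] partitions).
#'
#' @param c1,c2 Length-2 centroids `(x, y)`.
#' @return Distance (>= 0).
#' @export
shift_distance <- function(c1, c2) {
  sqrt((c2[[1]] - c1[[1]])^2 + (c2[[2]] - c1[[2]])^2)
}

#' Center-of-gravity trajectory of zonal ESV
#'
#' Tracks the ESV-weighted centroid across dates and summarises every
#' consecutive interval by its shift angle (both conventions) and
#' distance. An interval whose direction differs from the previous
#' interval's by more than 90 degrees is flagged as a reversal -- the
#' signature of a value surface whose drift changes regime (e.g. urban
#' expansion overturning a prior greening trend). Zero-length intervals
#' have undefined angles (`NA`) and never flag a reversal.
#'
#' @param values Zonal values by date: a dates x zones matrix, or a
#'   data.frame with columns `date`, `zone_id`, `esv`.
#' @param coords Zone coordinates: a data.frame with `zone_id`, `x`,
#'   `y` (e.g. the `zones` element of [generate_zones()], or a
#'   [zonal_esv()] result).
#' @return Object of class `gravity_track`: `centroids` (data.frame
#'   `date`, `x`, `y`) and `intervals` (data.frame `from`, `to`,
#'   `theta_east_ccw`, `theta_north_cw`, `distance`, `reversal`).
#' @export
gravity_track <- function(values, coords) {
  if (!all(c("zone_id", "x", "y") %in% names(coords)))
    stop("`coords` needs columns zone_id, x, y")
  if (is.data.frame(values)) {
    need <- c("date", "zone_id", "esv")
    if (!all(need %in% names(values)))
      stop("`values` data.frame needs columns ", paste(need, collapse = ", "))
    dates <- unique(values$date)
    m <- matrix(NA_real_, length(dates), nrow(coords),
                dimnames = list(as.character(dates), coords$zone_id))
    idx <- cbind(match(values$date, dates), match(values$zone_id, coords$zone_id))
    if (anyNA(idx)) stop("zone-set mismatch between `values` and `coords`")
    m[idx] <- values$esv
    if (anyNA(m)) stop("zone-set mismatch: some date/zone values missing")
    values <- m
  } else {
    values <- as.matrix(values)
    if (ncol(values) != nrow(coords))
      stop("zone-set mismatch: ", ncol(values), " value columns vs ",
           nrow(coords), " zones")
    if (is.null(rownames(values))) rownames(values) <- seq_len(nrow(values))
  }
  if (nrow(values) < 2) stop("need at least 2 dates")
  cents <- t(apply(values, 1L, function(m) esv_centroid(m, coords$x, coords$y)))
  centroids <- data.frame(date = rownames(values), x = cents[, 1], y = cents[, 2],
                          row.names = NULL)
  n <- nrow(centroids)
  iv <- data.frame(from = centroids$date[-n], to = centroids$date[-1],
                   theta_east_ccw = NA_real_, theta_north_cw = NA_real_,
                   distance = NA_real_, reversal = NA)
  for (i in seq_len(n - 1)) {
    c1 <- c(centroids$x[i], centroids$y[i])
    c2 <- c(centroids$x[i + 1], centroids$y[i + 1])
    iv$distance[i] <- shift_distance(c1, c2)
    if (iv$distance[i] > 0) {
      iv$theta_east_ccw[i] <- shift_angle(c1, c2, "east_ccw")
      iv$theta_north_cw[i] <- shift_angle(c1, c2, "north_cw")
    }
  }
  for (i in seq_len(n - 1)) {
    if (i == 1 || is.na(iv$theta_east_ccw[i]) || is.na(iv$theta_east_ccw[i - 1])) {
      iv$reversal[i] <- FALSE
      next
    }
    d <- abs(iv$theta_east_ccw[i] - iv$theta_east_ccw[i - 1]) %% 360
    if (d > 180) d <- 360 - d
    iv$reversal[i] <- d > 90
  }
  structure(list(centroids = centroids, intervals = iv), class = "gravity_track")
}

#' @export
print.gravity_track <- function(x, digits = 3, ...) {
  cat("ESV center-of-gravity trajectory\n\nCentroids:\n")
  df <- x$centroids; df$x <- round(df$x, digits); df$y <- round(df$y, digits)
  print(df, row.names = FALSE)
  cat("\nIntervals:\n")
  iv <- x$intervals
  for (nm in c("theta_east_ccw", "theta_north_cw", "distance"))
    iv[[nm]] <- round(iv[[nm]], digits)
  print(iv, row.names = FALSE)
  invisible(x)
}
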