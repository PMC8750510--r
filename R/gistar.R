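#' Getis-Ord Gi* hot-spot statistic
#'
#' The local Gi* z-score of zone i over values x:
#'
#'   Gi* = [sum_j w_ij x_j - xbar sum_j w_ij] /
#'         (S * sqrt((n sum_j w_ij^2 - (sum_j w_ij)^2) / (n - 1)))
#'
#' with xbar = sum_j x_j / n and S = sqrt(sum_j x_j^2 / n - xbar^2).
#' The focal zone is part of its own neighbourhood (w_ii > 0), so the
#' weights must be built with `include_self = TRUE`. Large positive
#' z marks a hot spot (the zone and its neighbours jointly high), large
#' negative a cold spot.
#'
#' Zones where the variance term under the root is not positive (a
#' neighbourhood covering essentially all zones) get an undefined score
#' (`NA`) and are flagged.
#'
#' @param x Numeric zone values.
#' @param weights A [zone_weights()] object with `include_self = TRUE`.
#' @return Object of class `hotspot_result`: data.frame `zone_id`, `z`,
#'   `p` (two-sided normal) and `class` (see [classify_hotspots()]);
#'   undefined zones in attribute `undefined`.
#' @export
getis_ord_gstar <- function(x, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (!weights$include_self)
    stop("Gi* requires weights with include_self = TRUE (w_ii > 0)")
  n <- length(weights$ids)
  if (length(x) != n) stop("`x` length must match the number of zones")
  if (n < 3) stop("need at least 3 zones")
  if (anyNA(x)) stop("missing zone values")
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  if (S == 0) stop("constant field, Gi* undefined (S = 0)")
  z <- numeric(n)
  bad <- logical(n)
  for (i in seq_len(n)) {
    wi <- weights$weights[[i]]
    nbi <- weights$neighbours[[i]]
    wsum <- sum(wi)
    den2 <- (n * sum(wi^2) - wsum^2) / (n - 1)
    if (den2 <= 0) { z[i] <- NA_real_; bad[i] <- TRUE; next }
    z[i] <- (sum(wi * x[nbi]) - xbar * wsum) / (S * sqrt(den2))
  }
  out <- data.frame(zone_id = weights$ids, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    class = classify_hotspots(z))
  attr(out, "undefined") <- weights$ids[bad]
  class(out) <- c("hotspot_result", "data.frame")
  out
}

#' Hot/cold-spot confidence classification
#'
#' Maps Gi* z-scores onto the conventional seven confidence classes with
#' boundaries at |z| = 1.65, 1.96 and 2.58 (90, 95, 99 percent). A score
#' exactly on a boundary belongs to the stronger (more significant)
#' class.
#'
#' @param z Numeric z-scores (`NA` allowed).
#' @return Ordered factor with levels `cold99 < cold95 < cold90 <
#'   not_significant < hot90 < hot95 < hot99`.
#' @export
classify_hotspots <- function(z) {
  lev <- c("cold99", "cold95", "cold90", "not_significant",
           "hot90", "hot95", "hot99")
  cls <- rep("not_significant", length(z))
  cls[which(z >= 1.65)] <- "hot90"
  cls[which(z >= 1.96)] <- "hot95"
  cls[which(z >= 2.58)] <- "hot99"
  cls[which(z <= -1.65)] <- "cold90"
  cls[which(z <= -1.96)] <- "cold95"
  cls[which(z <= -2.58)] <- "cold99"
  cls[is.na(z)] <- NA
  factor(cls, levels = lev, ordered = TRUE)
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat("Getis-Ord Gi* hot-spot analysis (", nrow(x), " zones)\n", sep = "")
  print(table(x$class))
  undef <- attr(x, "undefined")
  if (length(undef)) cat("undefined z for zones:", paste(undef, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hotspot_result <- function(object, ...) table(object$class)
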