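#' Global Moran's I with permutation inference
#'
#' The global spatial autocorrelation statistic
#'
#'   I = sum_ij W_ij (x_i - xbar)(x_j - xbar) / (S2 * sum_ij W_ij)
#'
#' with S2 the (population) variance of x. Under row-standardised
#' weights I lies in [-1, 1]; with binary weights it can slightly exceed
#' those bounds. The analytic null expectation E[I] = -1/(n-1) is
#' reported, and a permutation test randomly relabels values over zones
#' with a fixed seed.
#'
#' Island zones (no neighbours) are excluded from the statistic and
#' reported.
#'
#' @param x Numeric zone values (e.g. zonal ESV), one per zone of `weights`.
#' @param weights A [zone_weights()] object with `include_self = FALSE`.
#' @param nsim Number of permutations (default 999); 0 skips inference.
#' @param seed Optional integer seed for the permutations.
#' @param alternative `"greater"` (clustering, default), `"less"`, or
#'   `"two.sided"`.
#' @return Object of class `morans_i`: `I`, `expectation`, `p_value`,
#'   `perm` (permutation statistics), `scatter` (data.frame of
#'   standardised values and spatial lags, the Moran scatterplot), plus
#'   call metadata.
#' @export
global_morans_i <- function(x, weights, nsim = 999, seed = NULL,
                            alternative = c("greater", "less", "two.sided")) {
  stopifnot(inherits(weights, "spatial_weights"))
  alternative <- match.arg(alternative)
  if (weights$include_self)
    stop("Moran's I requires weights without self-neighbours")
  n <- length(weights$ids)
  if (length(x) != n) stop("`x` length must match the number of zones")
  if (n < 3) stop("need at least 3 zones")
  if (anyNA(x)) stop("missing zone values")
  if (stats::var(x) == 0) stop("constant field, Moran's I undefined")
  keep <- lengths(weights$neighbours) > 0L
  stat <- function(v) {
    z <- v - mean(v)
    s2 <- mean(z^2)
    lag <- spatial_lag(weights, z)
    sum(z[keep] * lag[keep]) / (s2 * sum_weights(weights))
  }
  I <- stat(x)
  perm <- NULL
  p <- NA_real_
  if (nsim > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(nsim), function(i) stat(sample(x)), numeric(1))
    pg <- (1 + sum(perm >= I)) / (nsim + 1)
    pl <- (1 + sum(perm <= I)) / (nsim + 1)
    p <- switch(alternative,
                greater = pg, less = pl,
                two.sided = min(1, 2 * min(pg, pl)))
  }
  z <- (x - mean(x)) / stats::sd(x)
  structure(
    list(I = I, expectation = -1 / (n - 1), p_value = p,
         alternative = alternative, nsim = nsim, perm = perm,
         n = n, islands = weights$islands,
         scatter = data.frame(zone_id = weights$ids, z = z,
                              lag = spatial_lag(weights, z))),
    class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat("Global Moran's I\n")
  cat("  I =", format(x$I, digits = 5),
      "  E[I] =", format(x$expectation, digits = 5),
      "  n =", x$n, "\n")
  if (!is.na(x$p_value))
    cat("  permutation p =", format(x$p_value, digits = 4),
        " (", x$nsim, " permutations, alternative: ", x$alternative, ")\n", sep = "")
  if (length(x$islands))
    cat("  islands excluded:", paste(x$islands, collapse = ", "), "\n")
  invisible(x)
}
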