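#' Contiguity spatial weights for a zone partition
#'
#' Builds a neighbour structure over zones from the zone-id matrix: two
#' zones are rook neighbours if any of their cells share an edge, and
#' queen neighbours if they share an edge or a corner. Weights are
#' binary (`style = "B"`) or row-standardised (`style = "W"`, each row
#' sums to 1). For the Getis-Ord Gi* statistic the focal zone belongs to
#' its own neighbourhood: set `include_self = TRUE` to add a unit
#' self-weight before any standardisation.
#'
#' Zones with no neighbours (possible only in degenerate partitions) are
#' flagged as islands and keep empty weight rows.
#'
#' @param zones A [generate_zones()] partition (or any `zone_grid`).
#' @param scheme `"queen"` (default) or `"rook"` contiguity.
#' @param style `"B"` binary or `"W"` row-standardised.
#' @param include_self Add a self-neighbour with unit weight (required
#'   for Gi*). Defaults to `FALSE`, the Moran's I form (w_ii = 0).
#' @return Object of class `spatial_weights`: list with `ids`,
#'   `neighbours` (list of integer indices), `weights` (list of numeric
#'   weights), `scheme`, `style`, `include_self`, `islands`.
#' @export
zone_weights <- function(zones, scheme = c("queen", "rook"),
                         style = c("B", "W"), include_self = FALSE) {
  stopifnot(inherits(zones, "zone_grid"))
  scheme <- match.arg(scheme)
  style <- match.arg(style)
  ids <- zones$zones$zone_id
  n <- length(ids)
  if (n < 2) stop("need at least 2 zones")
  m <- zones$map
  pairs <- adjacency_pairs(m, diagonal = scheme == "queen")
  nb <- rep(list(integer()), n)
  if (nrow(pairs)) {
    pi <- match(pairs[, 1], ids); pj <- match(pairs[, 2], ids)
    for (r in seq_len(nrow(pairs))) {
      nb[[pi[r]]] <- c(nb[[pi[r]]], pj[r])
      nb[[pj[r]]] <- c(nb[[pj[r]]], pi[r])
    }
    nb <- lapply(nb, function(v) sort(unique(v)))
  }
  islands <- ids[lengths(nb) == 0L]
  if (length(islands) == n) stop("all zones are islands: no contiguity structure")
  if (include_self) nb <- Map(function(v, i) sort(unique(c(v, i))), nb, seq_len(n))
  w <- lapply(nb, function(v) rep(1, length(v)))
  if (style == "W")
    w <- lapply(w, function(v) if (length(v)) v / sum(v) else v)
  structure(
    list(ids = ids, neighbours = nb, weights = w, scheme = scheme,
         style = style, include_self = include_self, islands = islands),
    class = "spatial_weights")
}

# unique adjacent zone-id pairs from a zone map (edge and optionally
# corner adjacency), excluding same-zone and NA pairs
adjacency_pairs <- function(m, diagonal = TRUE) {
  nr <- nrow(m); nc <- ncol(m)
  collect <- function(a, b) {
    keep <- !is.na(a) & !is.na(b) & a != b
    cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  }
  out <- rbind(
    collect(m[-nr, , drop = FALSE], m[-1, , drop = FALSE]),     # vertical edges
    collect(m[, -nc, drop = FALSE], m[, -1, drop = FALSE]))     # horizontal edges
  if (diagonal)
    out <- rbind(out,
      collect(m[-nr, -nc, drop = FALSE], m[-1, -1, drop = FALSE]),   # \ diagonal
      collect(m[-nr, -1, drop = FALSE], m[-1, -nc, drop = FALSE]))   # / diagonal
  unique(out)
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> ", length(x$ids), " zones, ", x$scheme,
      " contiguity, style ", x$style,
      if (x$include_self) ", self included" else "", "\n", sep = "")
  cat("  average neighbours:", round(mean(lengths(x$neighbours)), 2), "\n")
  if (length(x$islands)) cat("  islands:", paste(x$islands, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize spatial weights to a plain-text sparse list
#'
#' One `i j w` triple per line (zone ids, weight), a format any GIS or
#' spatial-stats tool can ingest.
#'
#' @param w A [zone_weights()] object.
#' @param path Output file.
#' @return `path` invisibly; `read_weights_list` returns a data.frame
#'   `i`, `j`, `w`.
#' @export
write_weights_list <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  rows <- unlist(lapply(seq_along(w$ids), function(i) {
    if (!length(w$neighbours[[i]])) return(character())
    paste(w$ids[i], w$ids[w$neighbours[[i]]], format(w$weights[[i]], digits = 15))
  }))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_weights_list
#' @export
read_weights_list <- function(path) {
  df <- utils::read.table(path, col.names = c("i", "j", "w"))
  df
}

# spatial lag: per-zone weighted sum of neighbour values
spatial_lag <- function(w, x) {
  vapply(seq_along(x),
         function(i) if (length(w$neighbours[[i]]))
           sum(w$weights[[i]] * x[w$neighbours[[i]]]) else NA_real_,
         numeric(1))
}

sum_weights <- function(w) sum(unlist(w$weights))
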