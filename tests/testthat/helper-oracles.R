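# Independent brute-force oracles, deliberately written as naive double
# loops over dense matrices so they share no code path with the package.

# dense contiguity matrix from a zone map: scan every pair of cells
dense_contiguity <- function(map, diagonal = TRUE, include_self = FALSE) {
  ids <- sort(unique(as.vector(map)))
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  nr <- nrow(map); nc <- ncol(map)
  for (i1 in seq_len(nr)) for (j1 in seq_len(nc)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (!diagonal && di != 0 && dj != 0) next
      i2 <- i1 + di; j2 <- j1 + dj
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      a <- map[i1, j1]; b <- map[i2, j2]
      if (!is.na(a) && !is.na(b) && a != b)
        W[as.character(a), as.character(b)] <- 1
    }
  }
  if (include_self) diag(W) <- 1
  W
}

row_standardize <- function(W) {
  rs <- rowSums(W)
  W / ifelse(rs > 0, rs, 1)
}

# Moran's I evaluated exactly as the defining double sum
moran_oracle <- function(x, W) {
  n <- length(x)
  xbar <- mean(x)
  s2 <- mean((x - xbar)^2)
  num <- 0
  for (i in 1:n) for (j in 1:n)
    num <- num + W[i, j] * (x[i] - xbar) * (x[j] - xbar)
  num / (s2 * sum(W))
}

# Gi* evaluated term by term from the defining formula
gstar_oracle <- function(x, W_self) {
  n <- length(x)
  xbar <- sum(x) / n
  S <- sqrt(sum(x^2) / n - xbar^2)
  vapply(1:n, function(i) {
    w <- W_self[i, ]
    num <- sum(w * x) - xbar * sum(w)
    den <- S * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1))
    num / den
  }, numeric(1))
}

# weights object from an explicit dense matrix (to drive package stats
# with arbitrary structures in tests)
weights_from_matrix <- function(W, include_self = FALSE) {
  n <- nrow(W)
  structure(
    list(ids = seq_len(n),
         neighbours = lapply(1:n, function(i) which(W[i, ] != 0)),
         weights = lapply(1:n, function(i) unname(W[i, W[i, ] != 0])),
         scheme = "custom", style = "B", include_self = include_self,
         islands = integer()),
    class = "spatial_weights")
}

# small reclassified raster with uniform random classes
random_raster <- function(nr, nc, seed, k = 7, cell_area_hm2 = 100) {
  set.seed(seed)
  land_raster(matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc),
              cell_area_hm2 = cell_area_hm2, levels = lu_classes())
}
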