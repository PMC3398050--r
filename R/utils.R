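# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# "Round to the nearest integer" with halves going up.
round_half_up <- function(x) floor(x + 0.5)

# Toroidal distance (in grid-cell units) between all pairs of cells of an
# nr x nc grid, row-major cell order.
torus_distance_matrix <- function(nr, nc) {
  idx <- 0:(nr * nc - 1)
  r <- idx %/% nc
  c <- idx %% nc
  dr <- abs(outer(r, r, "-"))
  dr <- pmin(dr, nr - dr)
  dc <- abs(outer(c, c, "-"))
  dc <- pmin(dc, nc - dc)
  sqrt(dr^2 + dc^2)
}

# Cached Cholesky factors for stationary Gaussian random fields with
# exponential covariance on a torus (keyed by grid shape and range).
.grf_cache <- new.env(parent = emptyenv())

# One draw of a zero-mean, unit-variance Gaussian random field with
# covariance exp(-d / range_m) on the toroidal grid. Returns a row-major
# vector of length nr * nc. Uses the current RNG stream.
gaussian_field <- function(nr, nc, range_m, resolution) {
  key <- paste(nr, nc, signif(range_m, 10), signif(resolution, 10), sep = "_")
  L <- .grf_cache[[key]]
  if (is.null(L)) {
    d <- torus_distance_matrix(nr, nc) * resolution
    cov <- exp(-d / range_m)
    # tiny ridge for numerical positive-definiteness
    L <- chol(cov + diag(1e-8, nrow(cov)))
    .grf_cache[[key]] <- L
  }
  as.vector(crossprod(L, rnorm(nr * nc)))
}

# row-major flattening helpers: C++ core indexes cells as row * nc + col
as_rowmajor <- function(mat) as.vector(t(mat))
from_rowmajor <- function(v, nr, nc) matrix(v, nrow = nr, ncol = nc, byrow = TRUE)

# 0-based row-major linear index <-> 1-based (row, col) matrix
idx0_to_cells <- function(idx0, nc) {
  cbind(row = idx0 %/% nc + 1L, col = idx0 %% nc + 1L)
}
cells_to_idx0 <- function(cells, nr, nc) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 2) stop("`cells` must be a two-column (row, col) matrix")
  r <- as.integer(cells[, 1]); c <- as.integer(cells[, 2])
  if (any(r < 1 | r > nr | c < 1 | c > nc)) stop("cell address outside grid")
  (r - 1L) * nc + (c - 1L)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop("`", name, "` must be a finite numeric scalar")
}
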