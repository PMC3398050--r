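# Shared fixtures: the published parameter estimates and small grids.

params_fitted <- hr_params(8.108, 0.222, 4.150)

uniform_grid <- function(v, nr = 7, nc = 7) {
  value_grid(matrix(v, nr, nc))
}

random_grid <- function(nr, nc, vmax = 2, seed = 1) {
  hrscape:::with_seed(seed, value_grid(matrix(runif(nr * nc, 0, vmax), nr, nc)))
}

# independent R-side connectivity check (rook adjacency, toroidal)
r_connected <- function(cells, nr, nc) {
  if (nrow(cells) == 0) return(FALSE)
  key <- function(rc) paste(rc[, 1], rc[, 2])
  inset <- key(cells)
  seen <- inset[1]
  frontier <- inset[1]
  while (length(frontier) > 0) {
    rc <- do.call(rbind, strsplit(frontier, " "))
    r <- as.integer(rc[, 1]); c <- as.integer(rc[, 2])
    nb <- rbind(cbind((r %% nr) + 1L, c), cbind(((r - 2) %% nr) + 1L, c),
                cbind(r, (c %% nc) + 1L), cbind(r, ((c - 2) %% nc) + 1L))
    nbk <- unique(paste(nb[, 1], nb[, 2]))
    frontier <- setdiff(intersect(nbk, inset), seen)
    seen <- union(seen, frontier)
  }
  length(seen) == nrow(cells)
}

# 1-D oracle: on a uniform grid net value depends only on area
uniform_nv <- function(area, v, params, form = "exponential") {
  S <- area * v
  B <- if (form == "exponential") {
    params[["p1"]] * (1 - exp(-params[["p2"]] * S))
  } else {
    params[["p1"]] * S / (params[["p2"]] + S)
  }
  B - params[["p3"]] - sqrt(area)
}
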