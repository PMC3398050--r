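#' Home-range model parameters
#'
#' The three free parameters of the mechanistic home-range model:
#' `p1` (> 0), the asymptotic resource benefit a home range can accrue;
#' `p2` (> 0), the rate at which benefits approach that asymptote per unit
#' of discounted habitat value; and `p3` (>= 0), the fixed, area-independent
#' home-range cost (basal demands). Benefits are a saturating function of
#' the overlap-discounted habitat value encompassed, costs are
#' `p3 + sqrt(area)`, and a home range is viable only when benefits
#' strictly exceed costs.
#'
#' @param p1,p2,p3 numeric scalars.
#' @return A named numeric vector of class `hr_params`.
#' @examples
#' hr_params(8.108, 0.222, 4.150)
#' @export
hr_params <- function(p1, p2, p3) {
  for (nm in c("p1", "p2", "p3")) stopifnot_scalar(get(nm), nm)
  if (p1 <= 0 || p2 <= 0) stop("`p1` and `p2` must be positive")
  if (p3 < 0) stop("`p3` must be non-negative")
  if (p1 <= p3)
    warning("p1 <= p3: no home range can be viable under these parameters")
  structure(c(p1 = unname(p1), p2 = unname(p2), p3 = unname(p3)),
            class = "hr_params")
}

#' @export
print.hr_params <- function(x, ...) {
  cat(sprintf("<hr_params> p1 = %g, p2 = %g, p3 = %g\n", x[1], x[2], x[3]))
  invisible(x)
}

benefit_form_code <- function(form = c("exponential", "hyperbolic")) {
  match(match.arg(form), c("exponential", "hyperbolic")) - 1L
}

check_overlap <- function(overlap, grid) {
  if (is.null(overlap)) overlap <- matrix(0L, nrow(grid$values), ncol(grid$values))
  overlap <- as.matrix(overlap)
  if (any(overlap < 0)) stop("overlap counts must be non-negative")
  if (!all(dim(overlap) == dim(grid$values)))
    stop("overlap grid shape does not match the value grid")
  overlap
}

#' Benefits, costs, and net value of a home range
#'
#' `hr_benefit()` computes the overlap-discounted resource total
#' `S = sum_c V_c / (1 + N_c)` over the home range's cells, where `N_c`
#' counts the *other* home ranges covering cell c, and returns the
#' saturating benefit `p1 * (1 - exp(-p2 * S))` (or, with
#' `form = "hyperbolic"`, `p1 * S / (p2 + S)`). `hr_cost()` returns
#' `p3 + sqrt(area)` with area in cells. `hr_net_value()` is their
#' difference; a home range is viable when it is strictly positive.
#'
#' @param cells two-column (row, col) matrix of 1-based cell addresses.
#' @param grid a [value_grid()].
#' @param overlap integer matrix of per-cell counts of other home ranges
#'   (`NULL` for none).
#' @param params an [hr_params()] vector.
#' @param form benefit curve: `"exponential"` (default) or `"hyperbolic"`.
#' @param area home-range area in cells (>= 1).
#' @return A numeric scalar.
#' @examples
#' g <- value_grid(matrix(1, 7, 7))
#' p <- hr_params(8.108, 0.222, 4.150)
#' hr_net_value(cbind(1:2, c(1, 1)), g, NULL, p)
#' @export
hr_benefit <- function(cells, grid, overlap = NULL, params,
                       form = c("exponential", "hyperbolic")) {
  form <- match.arg(form)
  overlap <- check_overlap(overlap, grid)
  cells <- as.matrix(cells)
  if (nrow(cells) == 0) stop("`cells` must be nonempty")
  idx <- cells[, 1] + (cells[, 2] - 1L) * nrow(grid$values)  # column-major
  S <- sum(grid$values[idx] / (1 + overlap[idx]))
  if (S <= 0) return(0)
  if (form == "exponential") params[["p1"]] * (1 - exp(-params[["p2"]] * S))
  else params[["p1"]] * S / (params[["p2"]] + S)
}

#' @rdname hr_benefit
#' @export
hr_cost <- function(area, params) {
  if (!is.numeric(area) || length(area) != 1 || area < 1)
    stop("`area` must be a single value >= 1")
  params[["p3"]] + sqrt(area)
}

#' @rdname hr_benefit
#' @export
hr_net_value <- function(cells, grid, overlap = NULL, params,
                         form = c("exponential", "hyperbolic")) {
  hr_benefit(cells, grid, overlap, params, form) -
    hr_cost(nrow(as.matrix(cells)), params)
}

new_home_range <- function(cells, grid, overlap, params, form) {
  structure(list(cells = cells,
                 benefit = hr_benefit(cells, grid, overlap, params, form),
                 cost = hr_cost(nrow(cells), params),
                 net_value = hr_net_value(cells, grid, overlap, params, form)),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("<home_range> %d cells, benefit %.3f, cost %.3f, net value %.3f\n",
              nrow(x$cells), x$benefit, x$cost, x$net_value))
  invisible(x)
}

#' Greedy optimization of a single home range
#'
#' Hill-climbs a home range to a local optimum of net value: at each step
#' all legal moves are enumerated — adding one frontier cell, adding an
#' ordered pair of cells, removing one cell, or removing an ordered pair
#' (every removal must keep the range rook-connected on the torus and at
#' least `min_cells` cells) — and the move with the greatest resulting net
#' value is applied if it strictly improves on the current value. Ties
#' resolve deterministically to the first move in a fixed lexicographic
#' enumeration. Terminates because net value strictly increases.
#'
#' @param cells starting cell set, a two-column (row, col) matrix (at
#'   least `min_cells` cells, rook-connected under toroidal adjacency).
#' @inheritParams hr_benefit
#' @param min_cells minimum home-range size in cells (default 4).
#' @return A `home_range` object at the local optimum.
#' @export
optimize_home_range <- function(cells, grid, overlap = NULL, params,
                                form = c("exponential", "hyperbolic"),
                                min_cells = 4) {
  form <- match.arg(form)
  overlap <- check_overlap(overlap, grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cells <- as.matrix(cells)
  if (nrow(cells) < min_cells) stop("starting range has fewer than `min_cells` cells")
  idx0 <- cells_to_idx0(cells, nr, nc)
  if (!cpp_is_connected(idx0, nr, nc)) stop("starting range is not connected")
  res <- cpp_optimize_range(as_rowmajor(grid$values), nr, nc, idx0,
                            as_rowmajor(overlap), params[["p1"]],
                            params[["p2"]], params[["p3"]],
                            benefit_form_code(form), as.integer(min_cells))
  new_home_range(idx0_to_cells(res$cells, nc), grid, overlap, params, form)
}

#' Establish the maximum number of viable home ranges on a grid
#'
#' Iteratively packs home ranges onto a habitat-value grid. Each new range
#' starts as the 2x2 block whose position maximizes net value given the
#' ranges already present; all ranges are then re-optimized round-robin
#' (one best move of up to two cells per range per pass, in order of
#' establishment) until a full pass changes nothing. If any range ends
#' with non-positive net value the whole set is re-established from
#' seeded random initial positions, up to `restarts` times. The reported
#' abundance is the largest count for which every range is simultaneously
#' viable (strictly positive net value); 0 is a legal outcome.
#'
#' @inheritParams hr_benefit
#' @param restarts number of random re-initializations tried before a
#'   candidate count is declared infeasible (default 20).
#' @param seed integer seed for the establishment algorithm's internal
#'   random number generator (independent of R's RNG stream).
#' @param max_ranges optional cap on the number of ranges attempted.
#' @param min_cells minimum home-range size in cells.
#' @return A `site_solution`: list with `home_ranges` (each a
#'   `home_range`), `overlap_counts` (per-cell coverage matrix),
#'   `abundance`, and `diagnostics`.
#' @examples
#' g <- value_grid(matrix(1.6, 7, 7))
#' establish_population(g, hr_params(8.108, 0.222, 4.150), seed = 1)
#' @export
establish_population <- function(grid, params, restarts = 20, seed = 1L,
                                 form = c("exponential", "hyperbolic"),
                                 max_ranges = NULL, min_cells = 4) {
  form <- match.arg(form)
  if (!inherits(grid, "value_grid")) stop("`grid` must be a value_grid")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (nr * nc < min_cells) stop("grid must hold at least one minimum-size range")
  # analytic cap on the feasible count: summed over ranges, the discounted
  # totals S never exceed sum(V) (a cell covered k times contributes V/k to
  # each coverer), and every viable range needs S above the level where
  # benefits first cover the minimum cost p3 + sqrt(min_cells)
  c0 <- params[["p3"]] + sqrt(min_cells)
  bound <- if (c0 >= params[["p1"]]) 0L else {
    s_min <- if (form == "exponential") {
      -log(1 - c0 / params[["p1"]]) / params[["p2"]]
    } else {
      c0 * params[["p2"]] / (params[["p1"]] - c0)
    }
    as.integer(floor(sum(grid$values) / s_min - 1e-12))
  }
  cap <- min(if (is.null(max_ranges)) nr * nc else as.integer(max_ranges),
             max(bound, 0L))
  res <- if (cap <= 0) {
    list(ranges = list(), cover = integer(nr * nc), abundance = 0L,
         restarts_used = 0L)
  } else {
    cpp_establish(as_rowmajor(grid$values), nr, nc, params[["p1"]],
                  params[["p2"]], params[["p3"]],
                  benefit_form_code(form), as.integer(restarts),
                  as.integer(seed), as.integer(min_cells), cap)
  }
  cover <- from_rowmajor(res$cover, nr, nc)
  ranges <- lapply(res$ranges, function(idx0) {
    cells <- idx0_to_cells(idx0, nc)
    self <- matrix(0L, nr, nc)
    self[cells] <- 1L
    new_home_range(cells, grid, cover - self, params, form)
  })
  sizes <- vapply(ranges, function(r) nrow(r$cells), numeric(1))
  shared <- vapply(ranges, function(r) {
    if (nrow(r$cells) == 0) return(0)
    mean(cover[r$cells] > 1)
  }, numeric(1))
  structure(list(
    home_ranges = ranges,
    overlap_counts = cover,
    abundance = res$abundance,
    resolution = grid$resolution,
    diagnostics = list(
      coverage_histogram = table(factor(cover, levels = 0:max(max(cover), 3))),
      mean_size = if (length(sizes)) mean(sizes) else NA_real_,
      mean_overlap_fraction = if (length(shared)) mean(shared) else NA_real_,
      restarts_used = res$restarts_used,
      seed = as.integer(seed),
      params = params,
      form = form)),
    class = "site_solution")
}

#' @export
print.site_solution <- function(x, ...) {
  cat(sprintf("<site_solution> %d home range(s) on a %d x %d grid\n",
              x$abundance, nrow(x$overlap_counts), ncol(x$overlap_counts)))
  if (x$abundance > 0)
    cat(sprintf("  mean size %.1f cells; mean shared fraction %.0f%%; restarts used %d\n",
                x$diagnostics$mean_size,
                100 * x$diagnostics$mean_overlap_fraction,
                x$diagnostics$restarts_used))
  invisible(x)
}

#' Coverage and overlap summaries of a site solution
#'
#' @param solution a `site_solution` from [establish_population()].
#' @return A list: `coverage_fractions` (fractions of grid cells covered
#'   by 0, 1, 2, and 3+ home ranges), `mean_size_cells` / `sd_size_cells`,
#'   the same in hectares (one 15-m cell = 225 m2), and
#'   `mean_shared_fraction`, the mean fraction of each home range shared
#'   with at least one other.
#' @export
overlap_stats <- function(solution) {
  if (!inherits(solution, "site_solution")) stop("`solution` must be a site_solution")
  cover <- solution$overlap_counts
  n <- length(cover)
  cf <- c("0" = mean(cover == 0), "1" = mean(cover == 1),
          "2" = mean(cover == 2), "3+" = mean(cover >= 3))
  sizes <- vapply(solution$home_ranges, function(r) nrow(r$cells), numeric(1))
  res <- if (is.null(solution$resolution)) 15 else solution$resolution
  ha <- res^2 / 1e4
  shared <- vapply(solution$home_ranges, function(r) mean(cover[r$cells] > 1),
                   numeric(1))
  list(coverage_fractions = cf,
       mean_size_cells = mean(sizes), sd_size_cells = sd(sizes),
       mean_size_ha = mean(sizes) * ha, sd_size_ha = sd(sizes) * ha,
       mean_shared_fraction = mean(shared))
}

#' Exhaustive search for the best single home range
#'
#' Enumerates every rook-connected cell set of `min_area` to `max_area`
#' cells on the toroidal grid (each set exactly once, by a
#' Redelmeier-style rooted enumeration) and returns the one with maximal
#' net value. Intended as an independent oracle for small grids; refuses
#' problems beyond 25 cells or `max_area > 8`.
#'
#' @inheritParams hr_benefit
#' @param max_area largest set size enumerated (<= 8).
#' @param min_area smallest admissible home range (default 4).
#' @return A `home_range`, with the number of sets enumerated in
#'   attribute `"n_sets"`.
#' @export
brute_force_best_home_range <- function(grid, overlap = NULL, params,
                                        max_area, min_area = 4,
                                        form = c("exponential", "hyperbolic")) {
  form <- match.arg(form)
  overlap <- check_overlap(overlap, grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (nr * nc > 25 || max_area > 8)
    stop("combinatorial limit exceeded: grid must be <= 25 cells and max_area <= 8")
  res <- cpp_best_connected_set(as_rowmajor(grid$values), nr, nc,
                                as_rowmajor(overlap), params[["p1"]],
                                params[["p2"]], params[["p3"]],
                                benefit_form_code(form),
                                as.integer(min_area), as.integer(max_area))
  out <- new_home_range(idx0_to_cells(res$cells, nc), grid, overlap, params, form)
  attr(out, "n_sets") <- res$n_sets
  out
}
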