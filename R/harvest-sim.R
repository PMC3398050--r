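#' Partial-harvest scenario definition
#'
#' A scenario fixes the stand-level intensity of basal-area removal, the
#' spatial pattern of the cut (every cell equally vs. disk-shaped removal
#' groups whose areas follow a lognormal with fixed mode and
#' pattern-specific variance), and whether post-harvest shrub cover
#' develops normally or is suppressed (as under chemical tending).
#'
#' @param intensity fraction of basal area removed, in \[0, 1\] (0 =
#'   unharvested; the study design used 0.30, 0.50, 0.70, 0.90).
#' @param pattern `"uniform"`, `"small_patch"`, or `"large_patch"`.
#' @param shrub_mode `"normal"` or `"suppressed"`.
#' @param seed integer seed for the scenario's stochastic layers.
#' @return A `harvest_scenario` list.
#' @export
harvest_scenario <- function(intensity,
                             pattern = c("uniform", "small_patch", "large_patch"),
                             shrub_mode = c("normal", "suppressed"),
                             seed = 1L) {
  stopifnot_scalar(intensity, "intensity")
  if (intensity < 0 || intensity > 1) stop("`intensity` must lie in [0, 1]")
  structure(list(intensity = intensity, pattern = match.arg(pattern),
                 shrub_mode = match.arg(shrub_mode), seed = as.integer(seed)),
            class = "harvest_scenario")
}

# lognormal patch-area presets (areas in cells): mode fixed at one cell,
# so meanlog = log(mode) + sdlog^2 = sdlog^2; aggregation grows with sdlog
patch_sdlog <- c(small_patch = 0.05, large_patch = 1.2)

#' Proportion-cut map for a harvest scenario
#'
#' Uniform pattern: every cell gets `PC = intensity`. Patch patterns:
#' disk-shaped removal groups with lognormally distributed areas (mode
#' one cell; sdlog 0.05 for small patches, 1.2 for large) are dropped at
#' random centres — overlapping groups saturate at full removal — until
#' the grid-mean proportion cut is within +/- `tol` of the requested
#' intensity. Per-cell PC is resolved on a `subcells x subcells` subgrid,
#' so group edges produce partially cut cells.
#'
#' @param scenario a [harvest_scenario()].
#' @param nrow,ncol grid dimensions in 15-m cells (default 14 x 14, a
#'   210 x 210 m stand).
#' @param subcells linear subdivisions per cell used to rasterise disks.
#' @param tol tolerance on the grid-mean proportion cut (absolute).
#' @param max_iter cap on group draws before giving up.
#' @return Matrix of per-cell proportion cut in \[0, 1\].
#' @export
apply_harvest_pattern <- function(scenario, nrow = 14, ncol = 14,
                                  subcells = 4, tol = 0.02, max_iter = 10000) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  if (scenario$intensity == 0) return(matrix(0, nrow, ncol))
  if (scenario$pattern == "uniform")
    return(matrix(scenario$intensity, nrow, ncol))
  sdlog <- patch_sdlog[[scenario$pattern]]
  meanlog <- sdlog^2  # mode = exp(meanlog - sdlog^2) = 1 cell
  fr <- nrow * subcells; fc <- ncol * subcells
  with_seed(scenario$seed, {
    cut <- matrix(FALSE, fr, fc)
    target <- scenario$intensity
    it <- 0
    while (mean(cut) < target - tol) {
      it <- it + 1
      if (it > max_iter) stop("requested intensity not attained within iteration cap")
      area <- rlnorm(1, meanlog, sdlog)              # cells
      r_sub <- sqrt(area / pi) * subcells            # disk radius, subcell units
      cy <- runif(1, 0, fr); cx <- runif(1, 0, fc)
      dy <- abs(seq_len(fr) - 0.5 - cy); dy <- pmin(dy, fr - dy)
      dx <- abs(seq_len(fc) - 0.5 - cx); dx <- pmin(dx, fc - dx)
      disk <- outer(dy^2, dx^2, "+") <= r_sub^2
      if (!any(disk)) {  # sub-subcell disk: mark the nearest subcell
        disk[ceiling(cy), ceiling(cx)] <- TRUE
      }
      new_cut <- cut | disk
      if (mean(new_cut) <= target + tol) cut <- new_cut
    }
    # aggregate subcells to per-cell proportion cut
    pc <- matrix(0, nrow, ncol)
    for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
      pc[i, j] <- mean(cut[((i - 1) * subcells + 1):(i * subcells),
                           ((j - 1) * subcells + 1):(j * subcells)])
    }
    pc
  })
}

#' Habitat-component responses to harvesting
#'
#' Empirical linear and piecewise responses linking stand structure to
#' the four vole habitat resources: shade declines linearly with gap
#' light (`Shade = 3.6802 - 0.0132 GLI`), substrate value rises with the
#' proportion of coniferous basal area
#' (`Substrate = 0.1193 + 0.1816 PCBA`), late-decay downed woody debris
#' declines with the proportion of basal area cut
#' (`DWD = 2.2035 - 1.8336 PC`, floored at 0), and shrub cover is either
#' unaffected (`normal`) or — under post-harvest tending — unchanged
#' below 33% local cut, reduced to 40% of its baseline above 67%, with a
#' linear ramp between (`suppressed`).
#'
#' @param gli gap light index, percent of full sun in \[0, 100\].
#' @param pcba proportion coniferous basal area in \[0, 1\].
#' @param pc proportion of basal area cut in \[0, 1\].
#' @param baseline unharvested shrub-cover value (>= 0).
#' @param mode `"normal"` or `"suppressed"`.
#' @return Numeric habitat-component values (vectorised).
#' @export
shade_from_gli <- function(gli) {
  if (any(gli < 0 | gli > 100)) stop("`gli` must lie in [0, 100]")
  3.6802 - 0.0132 * gli
}

#' @rdname shade_from_gli
#' @export
substrate_from_pcba <- function(pcba) {
  if (any(pcba < 0 | pcba > 1)) stop("`pcba` must lie in [0, 1]")
  0.1193 + 0.1816 * pcba
}

#' @rdname shade_from_gli
#' @export
dwd_from_cut <- function(pc) {
  if (any(pc < 0 | pc > 1)) stop("`pc` must lie in [0, 1]")
  pmax(2.2035 - 1.8336 * pc, 0)
}

#' @rdname shade_from_gli
#' @export
shrub_scenario <- function(pc, baseline, mode = c("normal", "suppressed")) {
  mode <- match.arg(mode)
  if (any(pc < 0 | pc > 1)) stop("`pc` must lie in [0, 1]")
  if (any(baseline < 0)) stop("`baseline` must be non-negative")
  if (mode == "normal") return(rep(baseline, length(pc)))
  f <- ifelse(pc < 1 / 3, 1,
              ifelse(pc > 2 / 3, 0.4, 1 - 0.6 * (pc - 1 / 3) / (1 / 3)))
  baseline * f
}

#' Autocorrelated lognormal scatter
#'
#' Multiplies a layer by lognormal deviates with unit mean and a target
#' coefficient of variation, spatially arranged by rank-matching the
#' deviates to a seeded Gaussian random field with exponential covariance
#' (range `range_m` metres, toroidal distances). Rank matching imposes
#' the field's spatial correlation while preserving the lognormal
#' marginal exactly. `cv = 0` returns the input unchanged.
#'
#' @param values numeric matrix to perturb.
#' @param cv coefficient of variation of the multiplicative deviates.
#' @param range_m autocorrelation range of the exponential covariance, m.
#' @param resolution cell size in metres.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return Matrix of the same shape.
#' @export
autocorrelated_lognormal_scatter <- function(values, cv, range_m = 30,
                                             resolution = 15, seed = NULL) {
  values <- as.matrix(values)
  if (cv < 0) stop("`cv` must be non-negative")
  if (cv == 0) return(values)
  nr <- nrow(values); nc <- ncol(values)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    dev <- rlnorm(nr * nc, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    field <- gaussian_field(nr, nc, range_m, resolution)
    arranged <- sort(dev)[rank(field, ties.method = "first")]
    values * from_rowmajor(arranged, nr, nc)
  })
}

#' Synthetic gap-light layer
#'
#' A documented non-canonical placeholder for a forest light model:
#' `GLI = clamp(10 + 85 * smoothed(PC), 0, 100)`, where `smoothed` is a
#' 3 x 3 toroidal box mean. Unharvested cells sit near 10% full sun under
#' a closed canopy; a fully cut neighbourhood reaches 95%.
#'
#' @param pc matrix of per-cell proportion cut.
#' @return Matrix of gap light index values.
#' @export
synthetic_gli <- function(pc) {
  pc <- as.matrix(pc)
  nr <- nrow(pc); nc <- ncol(pc)
  sm <- matrix(0, nr, nc)
  for (i in -1:1) for (j in -1:1) {
    sm <- sm + pc[((seq_len(nr) - 1 + i) %% nr) + 1,
                  ((seq_len(nc) - 1 + j) %% nc) + 1, drop = FALSE]
  }
  pmin(pmax(10 + 85 * sm / 9, 0), 100)
}

#' Run a partial-harvest scenario
#'
#' Generates `replicates` simulated stands for one scenario and predicts
#' vole abundance with both the mechanistic home-range model and the
#' habitat-value Poisson regression. Each replicate builds the
#' proportion-cut map, derives the gap-light, shade, substrate, downed
#' woody debris and shrub layers via the empirical response functions,
#' applies autocorrelated lognormal scatter to substrate, DWD and shrub,
#' maps habitat value through the coefficient set, and establishes home
#' ranges. Outputs per-replicate values and across-replicate summaries
#' (mean habitat value per cell, mean home-range size, home-range
#' overlap, and abundance under both predictors).
#'
#' @param scenario a [harvest_scenario()].
#' @param coefs coefficient configuration as returned by
#'   [default_habitat_coefs()] (a list with `coefs`, `baseline`,
#'   `shrub_baseline`).
#' @param params an [hr_params()] vector.
#' @param replicates number of simulated stands.
#' @param seed master seed; replicate r uses scenario layers seeded
#'   `seed + 97 * r` and establishment seed `seed + 97 * r + 1`.
#' @param nrow,ncol stand dimensions in cells.
#' @param scatter_cv named CVs of the lognormal scatter for substrate,
#'   dwd, and shrub layers.
#' @param autocorr_range scatter autocorrelation range in metres.
#' @param pcba_shape shape parameters of the Beta distribution the
#'   stand-level proportion coniferous is drawn from (centred on 0.5,
#'   stands about evenly split between deciduous and conifer).
#' @param regression `c(q0, q1)` log-link coefficients of the
#'   habitat-value regression used for the comparison predictor. The
#'   regression predicts abundance per `site_cells` of area, so its
#'   prediction is scaled by the stand/site area ratio.
#' @param site_cells the site area (in cells) the regression was
#'   calibrated on (default 49, a 7 x 7 trapping grid).
#' @param restarts establishment restarts.
#' @return A `harvest_result`: list with `scenario`, `replicates` (data
#'   frame) and `summary` (named means and SDs).
#' @export
run_scenario <- function(scenario, coefs = default_habitat_coefs(),
                         params = hr_params(8.108, 0.222, 4.150),
                         replicates = 15, seed = 1L, nrow = 14, ncol = 14,
                         scatter_cv = c(substrate = 0.45, dwd = 0.6, shrub = 0.4),
                         autocorr_range = 30, pcba_shape = c(8, 8),
                         regression = c(q0 = 0.856, q1 = 0.711),
                         site_cells = 49, restarts = 20) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  rows <- lapply(seq_len(replicates), function(r) {
    rseed <- scenario$seed + seed + 97L * r
    sc_r <- scenario
    sc_r$seed <- rseed
    pc <- apply_harvest_pattern(sc_r, nrow, ncol)
    layers <- with_seed(rseed + 13L, {
      gli <- synthetic_gli(pc)
      shade <- shade_from_gli(gli)
      pcba <- rbeta(1, pcba_shape[1], pcba_shape[2])
      substrate <- autocorrelated_lognormal_scatter(
        matrix(substrate_from_pcba(pcba), nrow, ncol),
        scatter_cv[["substrate"]], autocorr_range)
      dwd <- autocorrelated_lognormal_scatter(
        matrix(dwd_from_cut(pc), nrow, ncol), scatter_cv[["dwd"]],
        autocorr_range)
      shrub <- autocorrelated_lognormal_scatter(
        matrix(shrub_scenario(pc, coefs$shrub_baseline, scenario$shrub_mode),
               nrow, ncol),
        scatter_cv[["shrub"]], autocorr_range)
      list(shade = shade, substrate = substrate, dwd = dwd, shrub = shrub)
    })
    # scatter can push amounts beyond the coefficients' calibrated domain;
    # clamp to the integration cap (V_i saturates there anyway)
    resources <- lapply(names(layers), function(nm)
      resource_grid(nm, pmin(layers[[nm]],
                             coefs$coefs[[nm]]$integration_upper)))
    grid <- map_habitat_value(resources, coefs$coefs, baseline = coefs$baseline)
    sol <- establish_population(grid, params, restarts = restarts,
                                seed = rseed + 1L)
    os <- overlap_stats(sol)
    data.frame(replicate = r,
               mean_value = mean(grid$values),
               abundance_hr = sol$abundance,
               abundance_reg = exp(regression[["q0"]] +
                                     regression[["q1"]] * mean(grid$values)) *
                 (nrow * ncol) / site_cells,
               mean_size = os$mean_size_cells,
               shared_fraction = os$mean_shared_fraction)
  })
  reps <- do.call(rbind, rows)
  summ <- c(mean_value = mean(reps$mean_value),
            sd_value = sd(reps$mean_value),
            abundance_hr = mean(reps$abundance_hr),
            sd_abundance_hr = sd(reps$abundance_hr),
            abundance_reg = mean(reps$abundance_reg),
            sd_abundance_reg = sd(reps$abundance_reg),
            mean_size = mean(reps$mean_size, na.rm = TRUE),
            shared_fraction = mean(reps$shared_fraction, na.rm = TRUE))
  structure(list(scenario = scenario, replicates = reps, summary = summ),
            class = "harvest_result")
}

#' @export
print.harvest_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<harvest_result> intensity %.0f%%, %s pattern, %s shrub (%d replicates)\n",
              100 * x$scenario$intensity, x$scenario$pattern,
              x$scenario$shrub_mode, nrow(x$replicates)))
  cat(sprintf("  habitat value %.2f +/- %.2f | abundance HR %.1f +/- %.1f | regression %.1f\n",
              s["mean_value"], s["sd_value"], s["abundance_hr"],
              s["sd_abundance_hr"], s["abundance_reg"]))
  invisible(x)
}
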