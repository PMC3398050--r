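#' Site abundance data sets
#'
#' Bundles, for each site, a habitat-value grid and the observed
#' (detectability-corrected) abundance. This is the input to inverse
#' estimation of the home-range parameters.
#'
#' @param sites list of per-site entries, each a list with `id`, `grid`
#'   (a [value_grid()]) and `observed` (integer >= 0).
#' @return An `abundance_dataset`.
#' @export
abundance_dataset <- function(sites) {
  for (s in sites) {
    if (!inherits(s$grid, "value_grid")) stop("each site needs a value_grid")
    if (!is.numeric(s$observed) || s$observed < 0 || !is.finite(s$observed))
      stop("each site needs a non-negative observed abundance")
  }
  res <- vapply(sites, function(s) s$grid$resolution, numeric(1))
  if (length(unique(res)) > 1) stop("site grids differ in resolution")
  structure(list(sites = sites), class = "abundance_dataset")
}

#' @export
print.abundance_dataset <- function(x, ...) {
  y <- observed_abundances(x)
  cat(sprintf("<abundance_dataset> %d sites; observed abundance mean %.2f (range %d-%d)\n",
              length(x$sites), mean(y), min(y), max(y)))
  invisible(x)
}

#' @rdname abundance_dataset
#' @param data an `abundance_dataset`.
#' @export
observed_abundances <- function(data) {
  vapply(data$sites, function(s) as.numeric(s$observed), numeric(1))
}

#' Poisson log-likelihood of predicted abundances
#'
#' `sum_i [Y_i log(lambda_i) - lambda_i - log(Y_i!)]` with predictions
#' floored at 1e-9 so that zero-abundance predictions stay finite.
#'
#' @param observed non-negative integer counts.
#' @param predicted non-negative expected abundances (same length).
#' @return Numeric scalar log-likelihood.
#' @export
poisson_loglik <- function(observed, predicted) {
  if (any(observed < 0)) stop("`observed` must be non-negative")
  if (length(observed) != length(predicted)) stop("length mismatch")
  sum(dpois(observed, pmax(predicted, 1e-9), log = TRUE))
}

#' Model-predicted abundances for a data set
#'
#' Runs [establish_population()] on every site grid at the given
#' parameters. The establishment seed is fixed (optionally averaged over
#' `n_seeds` consecutive seeds) so the prediction is a deterministic
#' function of the parameters, as required by the annealing objective.
#'
#' @param params an [hr_params()] vector.
#' @param data an [abundance_dataset()].
#' @param establishment_seed base seed for the establishment algorithm.
#' @param restarts restarts per establishment run.
#' @param n_seeds number of establishment seeds to average over.
#' @param form benefit curve form.
#' @param max_ranges optional cap on the number of ranges attempted per
#'   site (predictions at the cap are censored). During fitting a cap
#'   well above the observed abundances bounds the cost of parameter
#'   regions that would pack the grid with dozens of ranges; the Poisson
#'   likelihood there is negligible either way.
#' @return Numeric vector of predicted abundances, one per site.
#' @export
predict_abundances <- function(params, data, establishment_seed = 1L,
                               restarts = 20, n_seeds = 1,
                               form = "exponential", max_ranges = NULL) {
  vapply(data$sites, function(s) {
    mean(vapply(seq_len(n_seeds), function(k)
      as.numeric(establish_population(s$grid, params, restarts = restarts,
                                      seed = establishment_seed + k - 1L,
                                      form = form,
                                      max_ranges = max_ranges)$abundance),
      numeric(1)))
  }, numeric(1))
}

#' Annealing configuration
#'
#' Settings for the simulated-annealing search over (p1, p2, p3):
#' geometric cooling (`temperature <- temperature * cooling_factor` after
#' each block of `steps_per_temperature` proposals, for `n_blocks`
#' blocks), Gaussian proposals with per-parameter scales (`p2` is
#' proposed on the log scale), rectangular parameter bounds enforced by
#' rejection, and a frozen establishment seed that makes the objective
#' deterministic. Proposal widths shrink with the square root of the
#' temperature ratio (floored at 10% of the configured scale), so the
#' chain mixes across the bounds while hot and resolves the fine
#' structure of the piecewise-constant likelihood surface once cold.
#'
#' @param initial_temperature starting temperature (log-likelihood units).
#' @param cooling_factor multiplicative cooling per block, in (0, 1).
#' @param steps_per_temperature proposals per block.
#' @param n_blocks number of cooling blocks.
#' @param proposal_scale named numeric: proposal SD for `p1` and `p3`,
#'   log-scale SD for `p2`.
#' @param bounds named list of `c(lower, upper)` per parameter.
#' @param inits list of starting parameter vectors, one chain per entry;
#'   dispersed starts guard against a single chain freezing in a poor
#'   basin.
#' @param seed seed for the annealing RNG (chain k uses `seed + k - 1`).
#' @param establishment_seed frozen seed passed to every establishment run.
#' @param restarts establishment restarts per evaluation.
#' @param n_establishment_seeds establishment seeds averaged per
#'   evaluation (1 = single frozen seed).
#' @param quench_rounds rounds of the deterministic quench that follows the
#'   chain: a compass search over the axis and diagonal directions of
#'   (p1, log p2, p3) accepting only strict improvements, with step sizes
#'   halved each round. The diagonal moves matter because near-equivalent
#'   prediction vectors form ridges along which p1 and p3 trade off; 0
#'   disables the stage.
#' @param quench_steps initial quench step sizes (log scale for `p2`).
#' @return An `annealing_config` list.
#' @export
annealing_config <- function(initial_temperature = 2.0, cooling_factor = 0.95,
                             steps_per_temperature = 50, n_blocks = 60,
                             proposal_scale = c(p1 = 0.5, p2 = 0.25, p3 = 0.3),
                             bounds = list(p1 = c(0.5, 20), p2 = c(0.01, 5),
                                           p3 = c(0, 10)),
                             inits = list(c(p1 = 6, p2 = 0.5, p3 = 3),
                                          c(p1 = 12, p2 = 0.1, p3 = 6)),
                             seed = 1L, establishment_seed = 1L,
                             restarts = 20, n_establishment_seeds = 1,
                             quench_rounds = 3,
                             quench_steps = c(p1 = 0.4, p2 = 0.08, p3 = 0.25)) {
  stopifnot(initial_temperature > 0, cooling_factor > 0, cooling_factor < 1,
            steps_per_temperature >= 1, n_blocks >= 1,
            all(proposal_scale > 0), quench_rounds >= 0,
            all(quench_steps > 0),
            bounds$p1[1] > 0, bounds$p2[1] > 0, bounds$p3[1] >= 0)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = steps_per_temperature,
                 n_blocks = n_blocks, proposal_scale = proposal_scale,
                 bounds = bounds, inits = inits, seed = seed,
                 establishment_seed = establishment_seed, restarts = restarts,
                 n_establishment_seeds = n_establishment_seeds,
                 quench_rounds = quench_rounds, quench_steps = quench_steps),
            class = "annealing_config")
}

#' Inverse estimation of home-range parameters
#'
#' Estimates (p1, p2, p3) from observed site abundances by maximizing the
#' Poisson log-likelihood of the abundances predicted by
#' [establish_population()], using Metropolis simulated annealing:
#' proposals are accepted with probability `exp(delta_LL / T)`, the
#' temperature cools geometrically, and the best parameters ever seen are
#' returned. Several shorter chains from dispersed starting points are run
#' by default and the overall best point is then refined by a
#' deterministic strict-improvement quench. Because establishment is
#' stochastic only through its own seeded RNG, freezing the establishment
#' seed makes the objective — and hence the whole fit — deterministic
#' given the configuration.
#'
#' The abundance surface is piecewise constant in the parameters, so many
#' parameter sets can be exactly likelihood-equivalent; the first-seen
#' optimum is kept. A flat-likelihood flag in the result warns when the
#' data never discriminated between parameter values (e.g. a single-site
#' data set).
#'
#' @param data an [abundance_dataset()] (at least 3 sites for the three
#'   free parameters to be identifiable).
#' @param config an [annealing_config()].
#' @param form benefit curve form.
#' @return An `hr_fit`: list with `params` (best-seen [hr_params()]),
#'   `loglik`, `predictions`, `trace` (one row per proposal), and
#'   `flat_likelihood`.
#' @export
fit_home_range_params <- function(data, config = annealing_config(),
                                  form = "exponential") {
  if (!inherits(data, "abundance_dataset")) stop("`data` must be an abundance_dataset")
  if (length(data$sites) < 3)
    warning("fewer than 3 sites: the three parameters are not identifiable")
  y <- observed_abundances(data)
  # censor predictions far above any observation: the likelihood out there
  # is negligible and un-capped establishment cost grows with the count
  cap <- as.integer(ceiling(3 * max(y, 1)) + 5)
  obj <- function(theta) {
    poisson_loglik(y, predict_abundances(
      suppressWarnings(hr_params(theta[1], theta[2], theta[3])), data,
      establishment_seed = config$establishment_seed,
      restarts = config$restarts,
      n_seeds = config$n_establishment_seeds, form = form,
      max_ranges = cap))
  }
  lo <- vapply(config$bounds, `[`, numeric(1), 1)
  hi <- vapply(config$bounds, `[`, numeric(1), 2)
  # where p1 <= p3 + sqrt(4) no home range can ever cover even the minimal
  # cost, every prediction is zero and the likelihood is constant: treat
  # that dead region as infeasible, like the rectangular bounds
  feasible <- function(th) all(th >= lo) && all(th <= hi) && th[1] > th[3] + 2
  with_seed(config$seed, {
    n_chains <- length(config$inits)
    n_total <- n_chains * config$n_blocks * config$steps_per_temperature
    trace <- data.frame(chain = integer(n_total), block = integer(n_total),
                        temperature = numeric(n_total),
                        p1 = numeric(n_total), p2 = numeric(n_total),
                        p3 = numeric(n_total), loglik = numeric(n_total),
                        accepted = logical(n_total),
                        best_loglik = numeric(n_total))
    best <- NULL; best_ll <- -Inf
    ll_seen <- c()
    row <- 0L
    for (chain in seq_len(n_chains)) {
      set.seed(config$seed + chain - 1L)
      cur <- pmin(pmax(as.numeric(config$inits[[chain]]), lo), hi)
      cur_ll <- obj(cur)
      ll_seen <- range(c(ll_seen, cur_ll))
      if (cur_ll > best_ll) { best <- cur; best_ll <- cur_ll }
      temp <- config$initial_temperature
      for (b in seq_len(config$n_blocks)) {
        # temperature-scaled proposal widths: wide while hot, fine when cold
        sc <- config$proposal_scale *
          max(sqrt(temp / config$initial_temperature), 0.1)
        for (s in seq_len(config$steps_per_temperature)) {
          row <- row + 1L
          prop <- c(cur[1] + rnorm(1, 0, sc[["p1"]]),
                    cur[2] * exp(rnorm(1, 0, sc[["p2"]])),
                    cur[3] + rnorm(1, 0, sc[["p3"]]))
          accepted <- FALSE
          prop_ll <- NA_real_
          if (feasible(prop)) {
            prop_ll <- obj(prop)
            ll_seen <- range(ll_seen, prop_ll)
            if (prop_ll >= cur_ll || runif(1) < exp((prop_ll - cur_ll) / temp)) {
              cur <- prop; cur_ll <- prop_ll
              accepted <- TRUE
              if (cur_ll > best_ll) { best <- cur; best_ll <- cur_ll }
            }
          }
          trace[row, ] <- list(chain, b, temp, prop[1], prop[2], prop[3],
                               prop_ll, accepted, best_ll)
        }
        temp <- temp * config$cooling_factor
      }
    }
    # deterministic quench: strict-improvement compass search around the
    # best-seen point, over axis and diagonal directions with halving steps
    if (config$quench_rounds > 0) {
      dirs <- as.matrix(expand.grid(p1 = -1:1, p2 = -1:1, p3 = -1:1))
      dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
      qs <- config$quench_steps
      for (round in seq_len(config$quench_rounds)) {
        improved <- TRUE
        sweeps <- 0
        while (improved && sweeps < 10) {
          improved <- FALSE
          sweeps <- sweeps + 1
          for (d in seq_len(nrow(dirs))) {
            cand <- c(best[1] + dirs[d, 1] * qs[["p1"]],
                      best[2] * exp(dirs[d, 2] * qs[["p2"]]),
                      best[3] + dirs[d, 3] * qs[["p3"]])
            if (!feasible(cand)) next
            cand_ll <- obj(cand)
            ll_seen <- range(ll_seen, cand_ll)
            if (cand_ll > best_ll + 1e-9) {
              best <- cand
              best_ll <- cand_ll
              improved <- TRUE
            }
          }
        }
        qs <- qs / 2
      }
    }
    params <- hr_params(best[1], best[2], best[3])
    structure(list(params = params, loglik = best_ll,
                   predictions = predict_abundances(
                     params, data,
                     establishment_seed = config$establishment_seed,
                     restarts = config$restarts,
                     n_seeds = config$n_establishment_seeds, form = form,
                     max_ranges = cap),
                   trace = trace,
                   flat_likelihood = diff(range(ll_seen)) < 1e-8,
                   config = config),
              class = "hr_fit")
  })
}

#' @export
print.hr_fit <- function(x, ...) {
  cat(sprintf("<hr_fit> logLik %.3f at p1 = %.3f, p2 = %.3f, p3 = %.3f\n",
              x$loglik, x$params[1], x$params[2], x$params[3]))
  cat(sprintf("  %d proposals, %.0f%% accepted%s\n", nrow(x$trace),
              100 * mean(x$trace$accepted),
              if (x$flat_likelihood) "; WARNING: likelihood surface was flat" else ""))
  invisible(x)
}
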