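#' Resource-use coefficients
#'
#' A coefficient describes the per-unit effect B of one habitat resource on
#' the (logit) probability of local use. The effect is either a constant
#' `b0`, or a four-parameter logistic function of site-level availability,
#' `B(h) = lower + (upper - lower) / (1 + exp((h - midpoint) / scale))`,
#' which with `scale > 0` declines from `upper` towards `lower` as the
#' resource becomes plentiful (selection weakens once the resource no
#' longer limits use).
#'
#' @param name resource identifier (`"shrub"`, `"dwd"`, `"shade"`,
#'   `"substrate"`, or any label).
#' @param mode `"constant"` or `"logistic"`.
#' @param b0 constant per-unit effect (mode `"constant"`).
#' @param lower,upper,midpoint,scale logistic parameters (mode
#'   `"logistic"`): asymptotes, availability at the half-way point, and the
#'   transition width.
#' @param integration_upper positive cap on the resource amount over which
#'   per-unit effects are integrated.
#' @return An object of class `resource_coef`.
#' @examples
#' resource_coef("shade", "constant", b0 = 0.5, integration_upper = 5)
#' @export
resource_coef <- function(name, mode = c("constant", "logistic"), b0 = NULL,
                          lower = NULL, upper = NULL, midpoint = NULL,
                          scale = NULL, integration_upper) {
  mode <- match.arg(mode)
  stopifnot_scalar(integration_upper, "integration_upper")
  if (integration_upper <= 0) stop("`integration_upper` must be > 0")
  if (mode == "constant") {
    stopifnot_scalar(b0, "b0")
    if (!is.null(lower) || !is.null(upper) || !is.null(midpoint) || !is.null(scale))
      stop("constant-mode coefficients take no logistic parameters")
    logistic <- NULL
  } else {
    for (nm in c("lower", "upper", "midpoint", "scale"))
      stopifnot_scalar(get(nm), nm)
    if (scale == 0) stop("logistic `scale` must be nonzero")
    logistic <- c(lower = lower, upper = upper, midpoint = midpoint, scale = scale)
    b0 <- NULL
  }
  structure(list(name = as.character(name), mode = mode, b0 = b0,
                 logistic = logistic, integration_upper = integration_upper),
            class = "resource_coef")
}

#' @export
print.resource_coef <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<resource_coef '%s'> constant b0 = %g (cap %g)\n",
                x$name, x$b0, x$integration_upper))
  } else {
    cat(sprintf(
      "<resource_coef '%s'> logistic [%g -> %g], midpoint %g, scale %g (cap %g)\n",
      x$name, x$logistic["upper"], x$logistic["lower"], x$logistic["midpoint"],
      x$logistic["scale"], x$integration_upper))
  }
  invisible(x)
}

#' Per-unit selection effect at a given availability
#'
#' Evaluates the coefficient's functional response B at one or more
#' availability values: the constant `b0` for constant-mode coefficients,
#' or the four-parameter logistic for availability-conditional ones.
#'
#' @param coef a [resource_coef()].
#' @param availability non-negative resource availability (vectorised).
#' @return Numeric vector of per-unit effects.
#' @export
functional_response <- function(coef, availability) {
  if (!inherits(coef, "resource_coef")) stop("`coef` must be a resource_coef")
  if (!is.numeric(availability) || any(!is.finite(availability)))
    stop("`availability` must be finite numeric")
  if (any(availability < 0)) stop("`availability` must be non-negative")
  if (coef$mode == "constant") return(rep(coef$b0, length(availability)))
  p <- coef$logistic
  p[["lower"]] + (p[["upper"]] - p[["lower"]]) /
    (1 + exp((availability - p[["midpoint"]]) / p[["scale"]]))
}

#' Cumulative habitat value contributed by a resource
#'
#' Integrates the per-unit effect from 0 up to `amount` by the composite
#' trapezoid rule, yielding the resource's contribution V_i to absolute
#' local habitat value. With the default `"sliding"` response the effect is
#' evaluated at each intermediate availability h as h runs from 0 to
#' `amount` — for a logistic effect that declines towards zero this
#' saturates, giving the characteristic threshold shape of habitat value.
#' With `"fixed"` the effect is held at `site_availability`, so
#' V_i = B(site_availability) * amount.
#'
#' The default step targets `integration_upper / 1000`, exact for constant
#' effects and accurate to well under 1e-4 for smooth logistic ones.
#'
#' @param coef a [resource_coef()].
#' @param amount resource amount(s) in `[0, integration_upper]` (vectorised).
#' @param response `"sliding"` (default) or `"fixed"`.
#' @param site_availability availability at which the effect is frozen when
#'   `response = "fixed"`.
#' @param n_steps number of trapezoid panels spanning
#'   `[0, integration_upper]`.
#' @return Numeric vector of V_i values.
#' @examples
#' cf <- resource_coef("x", "constant", b0 = 0.5, integration_upper = 10)
#' integrate_resource_value(cf, 2)  # 1.0
#' @export
integrate_resource_value <- function(coef, amount,
                                     response = c("sliding", "fixed"),
                                     site_availability = NULL,
                                     n_steps = 1000) {
  if (!inherits(coef, "resource_coef")) stop("`coef` must be a resource_coef")
  response <- match.arg(response)
  if (!is.numeric(amount) || any(!is.finite(amount)))
    stop("`amount` must be finite numeric")
  if (any(amount < 0) || any(amount > coef$integration_upper + 1e-9))
    stop("`amount` must lie in [0, integration_upper]")
  if (coef$mode == "constant") {
    b <- if (response == "fixed" && !is.null(site_availability))
      functional_response(coef, site_availability) else coef$b0
    return(b * amount)
  }
  if (response == "fixed") {
    if (is.null(site_availability))
      stop("`site_availability` is required for the fixed response")
    return(functional_response(coef, site_availability) * amount)
  }
  # cumulative trapezoid on a fixed node grid, then exact-node lookup /
  # panel-consistent interpolation for off-node amounts
  nodes <- seq(0, coef$integration_upper, length.out = n_steps + 1)
  b <- functional_response(coef, nodes)
  h <- nodes[2] - nodes[1]
  cum <- c(0, cumsum((b[-1] + b[-length(b)]) / 2 * h))
  i <- pmin(floor(amount / h), n_steps - 1)
  frac <- amount - nodes[i + 1]
  ba <- functional_response(coef, amount)
  cum[i + 1] + (b[i + 1] + ba) / 2 * frac
}

#' Map absolute habitat value from resource layers
#'
#' Computes per-cell habitat value `V = sum_i V_i(H_i) - baseline`, where
#' each V_i is the integrated cumulative effect of resource i
#' ([integrate_resource_value()]) and the baseline is the lowest-value
#' local habitat in the calibration data. With `baseline = "auto"` the
#' minimum summed value over the supplied grid's cells is used, so the
#' poorest cell maps exactly to 0. With a numeric baseline (carried over
#' from calibration data), cells poorer than that reference floor at 0.
#'
#' @param resources named list of [resource_grid()]s (congruent shapes).
#' @param coefs named list of [resource_coef()]s, one per resource.
#' @param baseline `"auto"` or a numeric calibration constant.
#' @param response passed to [integrate_resource_value()].
#' @return A [value_grid()] with the baseline used stored in the object.
#' @export
map_habitat_value <- function(resources, coefs, baseline = "auto",
                              response = c("sliding", "fixed")) {
  response <- match.arg(response)
  total <- sum_resource_values(resources, coefs, response)
  if (identical(baseline, "auto")) baseline <- min(total$sum)
  stopifnot_scalar(baseline, "baseline")
  v <- pmax(total$sum - baseline, 0)
  value_grid(v, total$resolution, baseline)
}

#' @rdname map_habitat_value
#' @param resource_sets a list of sites, each a named list of resource
#'   grids; the automatic baseline is the minimum summed value across the
#'   cells of *all* sites (the lowest-value local habitat in the data set).
#' @export
map_habitat_value_multi <- function(resource_sets, coefs, baseline = "auto",
                                    response = c("sliding", "fixed")) {
  response <- match.arg(response)
  totals <- lapply(resource_sets, sum_resource_values, coefs = coefs,
                   response = response)
  if (identical(baseline, "auto"))
    baseline <- min(vapply(totals, function(t) min(t$sum), numeric(1)))
  stopifnot_scalar(baseline, "baseline")
  lapply(totals, function(t)
    value_grid(pmax(t$sum - baseline, 0), t$resolution, baseline))
}

sum_resource_values <- function(resources, coefs, response) {
  if (length(resources) == 0) stop("no resource grids supplied")
  nms <- vapply(resources, function(g) g$name, character(1))
  names(resources) <- nms
  if (!all(nms %in% names(coefs)))
    stop("missing coefficient for resource(s): ",
         paste(setdiff(nms, names(coefs)), collapse = ", "))
  shp <- dim(resources[[1]]$values)
  acc <- matrix(0, shp[1], shp[2])
  for (i in seq_along(resources)) {
    g <- resources[[i]]
    nm <- g$name
    if (!all(dim(g$values) == shp)) stop("resource grids differ in shape")
    site_avail <- mean(g$values)
    vi <- integrate_resource_value(coefs[[nm]], as.vector(g$values),
                                   response = response,
                                   site_availability = site_avail)
    acc <- acc + matrix(vi, shp[1], shp[2])
  }
  list(sum = acc, resolution = resources[[1]]$resolution)
}

# ---- coefficient configuration files --------------------------------------

#' Read or write a coefficient configuration
#'
#' Coefficient sets are stored as YAML: a top-level `baseline` (optional)
#' and a `coefficients` block keyed by resource name, each entry giving
#' `mode`, `integration_upper` and either `b0` or the logistic parameters.
#'
#' @param path file path.
#' @param coefs named list of [resource_coef()]s.
#' @param baseline numeric calibration baseline to store.
#' @return `read_coef_config()` returns `list(coefs, baseline)`.
#' @export
read_coef_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  coefs <- lapply(names(cfg$coefficients), function(nm) {
    e <- cfg$coefficients[[nm]]
    if (identical(e$mode, "constant")) {
      resource_coef(nm, "constant", b0 = e$b0,
                    integration_upper = e$integration_upper)
    } else {
      resource_coef(nm, "logistic", lower = e$lower, upper = e$upper,
                    midpoint = e$midpoint, scale = e$scale,
                    integration_upper = e$integration_upper)
    }
  })
  names(coefs) <- names(cfg$coefficients)
  list(coefs = coefs, baseline = if (is.null(cfg$baseline)) 0 else cfg$baseline)
}

#' @rdname read_coef_config
#' @export
write_coef_config <- function(coefs, path, baseline = 0) {
  entries <- lapply(coefs, function(cf) {
    if (cf$mode == "constant") {
      list(mode = "constant", b0 = cf$b0,
           integration_upper = cf$integration_upper)
    } else {
      c(list(mode = "logistic"), as.list(cf$logistic),
        list(integration_upper = cf$integration_upper))
    }
  })
  yaml::write_yaml(list(baseline = baseline, coefficients = entries), path)
  invisible(path)
}
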