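#' Distribution specification for a model parameter
#'
#' Every model input carries a deterministic point estimate and, where the
#' parameter is sampled in probabilistic sensitivity analysis, a sampling
#' distribution.  Families follow decision-modelling convention: beta for
#' probabilities and utilities, gamma for costs (mean = shape x scale),
#' normal for costs with symmetric uncertainty, lognormal for relative
#' risks (parameterised by arithmetic mean and SE), and fixed for
#' quantities that are never sampled.
#'
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"lognormal"`,
#'   `"fixed"`.
#' @param point Deterministic point estimate.  For `"fixed"` this is the
#'   only information used.
#' @param alpha,beta Beta shape parameters (both > 0).
#' @param shape,scale Gamma shape/scale parameters (both > 0).
#' @param mean,se Mean and standard error for `"normal"` and
#'   `"lognormal"` (arithmetic scale).  `mean` defaults to `point`.
#' @param lower,upper Optional support bounds enforced on draws by
#'   truncation-by-rejection (e.g. costs >= 0, utilities <= 1).
#' @return An object of class `dist_spec`.
#' @examples
#' d <- dist_spec("beta", point = 0.765, alpha = 13, beta = 4.05)
#' dist_mean(d)
#' point_and_sample(d)              # point mode: 0.765
#' point_and_sample(d, seed = 1, mode = "sample")
#' @export
dist_spec <- function(family = c("beta", "gamma", "normal", "lognormal", "fixed"),
                      point, alpha = NULL, beta = NULL, shape = NULL,
                      scale = NULL, mean = NULL, se = NULL,
                      lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  if (!is.numeric(point) || length(point) != 1L || !is.finite(point))
    stop("'point' must be a single finite number", call. = FALSE)
  spec <- structure(
    list(family = family, point = point, alpha = alpha, beta = beta,
         shape = shape, scale = scale, mean = mean %||% point, se = se,
         lower = lower, upper = upper),
    class = "dist_spec")
  validate_dist_spec(spec)
}

validate_dist_spec <- function(spec) {
  f <- spec$family
  pos <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop(sprintf("%s distribution requires positive '%s'", f, nm),
           call. = FALSE)
  }
  switch(f,
    beta = { pos(spec$alpha, "alpha"); pos(spec$beta, "beta") },
    gamma = { pos(spec$shape, "shape"); pos(spec$scale, "scale") },
    normal = {
      if (is.null(spec$se) || !is.finite(spec$se) || spec$se < 0)
        stop("normal distribution requires nonnegative 'se'", call. = FALSE)
    },
    lognormal = {
      if (is.null(spec$se) || !is.finite(spec$se) || spec$se < 0)
        stop("lognormal distribution requires nonnegative 'se'", call. = FALSE)
      pos(spec$mean, "mean")
    },
    fixed = NULL)
  spec
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- switch(x$family,
    beta = sprintf("alpha=%g, beta=%g", x$alpha, x$beta),
    gamma = sprintf("shape=%g, scale=%g", x$shape, x$scale),
    normal = ,
    lognormal = sprintf("mean=%g, se=%g", x$mean, x$se),
    fixed = "")
  cat(sprintf("<dist_spec %s point=%g %s>\n", x$family, x$point, pars))
  invisible(x)
}

#' Analytic mean of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return The mean of the sampling distribution (the point value for
#'   `"fixed"`).
#' @export
dist_mean <- function(spec) {
  switch(spec$family,
    beta = spec$alpha / (spec$alpha + spec$beta),
    gamma = spec$shape * spec$scale,
    normal = spec$mean,
    lognormal = spec$mean,
    fixed = spec$point)
}

#' Analytic standard deviation of a distribution specification
#' @param spec A [dist_spec()].
#' @return Standard deviation (0 for `"fixed"`).
#' @export
dist_sd <- function(spec) {
  switch(spec$family,
    beta = {
      a <- spec$alpha; b <- spec$beta
      sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    },
    gamma = sqrt(spec$shape) * spec$scale,
    normal = spec$se,
    lognormal = spec$se,
    fixed = 0)
}

#' Draw from a distribution specification
#'
#' Lognormal draws use the arithmetic mean/SE parameterisation:
#' `sdlog^2 = log(1 + (se/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`.
#' Declared support bounds are enforced by rejection.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n = 1L) {
  draw <- function(m) {
    switch(spec$family,
      beta = stats::rbeta(m, spec$alpha, spec$beta),
      gamma = stats::rgamma(m, shape = spec$shape, scale = spec$scale),
      normal = stats::rnorm(m, spec$mean, spec$se),
      lognormal = {
        sdlog <- sqrt(log(1 + (spec$se / spec$mean)^2))
        stats::rlnorm(m, meanlog = log(spec$mean) - sdlog^2 / 2, sdlog = sdlog)
      },
      fixed = rep(spec$point, m))
  }
  x <- draw(n)
  bad <- which(x < spec$lower | x > spec$upper)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < spec$lower | x[bad] > spec$upper]
    tries <- tries + 1L
  }
  if (length(bad))
    stop("could not draw within declared support bounds", call. = FALSE)
  x
}

#' Point value or a single reproducible draw
#'
#' @param spec A [dist_spec()].
#' @param seed Integer seed used in sampling mode; ignored in point mode.
#' @param mode `"point"` (default) returns the deterministic value;
#'   `"sample"` returns one draw from the stated family.
#' @return A single numeric value.
#' @export
point_and_sample <- function(spec, seed = NULL, mode = c("point", "sample")) {
  mode <- match.arg(mode)
  if (mode == "point") return(spec$point)
  with_seed(seed, dist_sample(spec, 1L))
}

## internal: build a dist_spec from a config list entry
spec_from_config <- function(x, kind = c("probability", "utility", "cost",
                                         "rate", "rr", "other"),
                             name = "parameter") {
  kind <- match.arg(kind)
  bounds <- switch(kind,
    probability = c(0, 1),
    utility = c(-0.594, 1),
    cost = c(0, Inf),
    rate = c(0, 1),
    rr = c(0, Inf),
    other = c(-Inf, Inf))
  fam <- x$family %||% if (!is.null(x$alpha)) "beta" else
    if (!is.null(x$shape)) "gamma" else if (!is.null(x$se)) "normal" else "fixed"
  # gamma given as mean/SE (method of moments): shape = (m/se)^2, scale = se^2/m
  if (fam == "gamma" && is.null(x$shape) && !is.null(x$se)) {
    m <- x$point
    x$shape <- (m / x$se)^2
    x$scale <- x$se^2 / m
  }
  pt <- x$point %||% switch(fam,
    beta = x$alpha / (x$alpha + x$beta),
    gamma = x$shape * x$scale,
    stop(sprintf("config entry '%s' lacks a point value", name), call. = FALSE))
  tryCatch(
    dist_spec(fam, point = pt, alpha = x$alpha, beta = x$beta,
              shape = x$shape, scale = x$scale, mean = x$mean %||% pt,
              se = x$se, lower = bounds[1], upper = bounds[2]),
    error = function(e) stop(sprintf("config entry '%s': %s", name,
                                     conditionMessage(e)), call. = FALSE))
}
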