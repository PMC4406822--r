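#' Specify a prior distribution on the effect-size prior variance W
#'
#' Constructs a prior on `W`, the variance of the zero-mean normal prior on
#' the per-allele log odds ratio, restricted to a support `0 < a <= W <= b`.
#' Four families are available:
#'
#' * `"power"`: density proportional to `(V + W)^k`, `k < -1/2`;
#' * `"exponential"`: proportional to `exp(-c W / 2)`, `c > 0` (the only
#'   family that does not involve the data through `V`);
#' * `"hybrid"`: proportional to `(V + W)^k exp(-d / (2 (V + W)))`,
#'   `k < -1`, `d >= 0` (a shifted inverse-gamma on a restricted support);
#' * `"reciprocal"`: proportional to `(V + W)^{-1} exp(-(V + W) / 2)`, with
#'   no free hyperparameters.
#'
#' `V` is the asymptotic variance of the log odds ratio estimate (squared
#' standard error). The power, hybrid and reciprocal families use it purely
#' to make the downstream Bayes-factor integrals tractable; when a single
#' anchor value is needed across SNPs, the median per-SNP `V` is the
#' recommended choice.
#'
#' The normalizing constant over `[a, b]` is computed once at construction
#' (in closed form via log-space incomplete-gamma and power integrals) and
#' stored, so densities integrate to 1 on the support.
#'
#' @param family One of `"power"`, `"exponential"`, `"hybrid"`,
#'   `"reciprocal"`.
#' @param a,b Support bounds on `W`, `0 < a < b`. Units: variance of the
#'   log odds ratio.
#' @param k Power/hybrid exponent (dimensionless).
#' @param c Exponential rate (dimensionless), `> 0`.
#' @param d Hybrid scale (dimensionless), `>= 0`.
#' @param v Asymptotic-variance anchor `V` used by the power, hybrid and
#'   reciprocal families; ignored by the exponential family.
#' @return An object of class `prior_spec`.
#' @examples
#' spec <- prior_spec("power", a = 0.003, b = 0.1, k = -1.66, v = 0.00017)
#' prior_cdf(spec, c(0.0275, 0.0333))
#' prior_mean(spec)
#' @export
prior_spec <- function(family = c("power", "exponential", "hybrid", "reciprocal"),
                       a, b, k = NULL, c = NULL, d = NULL, v = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (!(a > 0 && b > a)) {
    abort("support must satisfy 0 < a < b (degenerate or inverted support rejected)")
  }
  needs_v <- family %in% c("power", "hybrid", "reciprocal")
  if (needs_v) {
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || v <= 0) {
      abort(sprintf("family '%s' requires a positive variance anchor v", family))
    }
  } else {
    v <- if (is.null(v)) NA_real_ else as.numeric(v)
  }
  switch(family,
    power = {
      if (is.null(k) || k >= -0.5) abort("power prior requires k < -1/2")
    },
    exponential = {
      if (is.null(c) || c <= 0) abort("exponential prior requires c > 0")
    },
    hybrid = {
      if (is.null(k) || k >= -1) abort("hybrid prior requires k < -1")
      if (is.null(d) || d < 0) abort("hybrid prior requires d >= 0")
    },
    reciprocal = NULL
  )
  spec <- structure(
    list(family = family, a = a, b = b,
         k = if (is.null(k)) NA_real_ else as.numeric(k),
         c = if (is.null(c)) NA_real_ else as.numeric(c),
         d = if (is.null(d)) NA_real_ else as.numeric(d),
         v = v),
    class = "prior_spec"
  )
  spec$log_norm <- log_normalizer(spec)
  spec
}

#' @export
print.prior_spec <- function(x, ...) {
  hp <- switch(x$family,
    power = sprintf("k = %g", x$k),
    exponential = sprintf("c = %g", x$c),
    hybrid = sprintf("k = %g, d = %g", x$k, x$d),
    reciprocal = "none"
  )
  cat(sprintf("<prior_spec> %s prior on W\n", x$family))
  cat(sprintf("  support: [%g, %g]\n", x$a, x$b))
  cat(sprintf("  hyperparameters: %s\n", hp))
  if (x$family != "exponential") cat(sprintf("  variance anchor V: %g\n", x$v))
  invisible(x)
}

# log kernel (unnormalized log density) of the family at W = w, using
# anchor variance v. Vectorized in w.
log_kernel <- function(spec, w, v = spec$v) {
  u <- v + w
  switch(spec$family,
    power = spec$k * log(u),
    exponential = -spec$c * w / 2,
    hybrid = {
      if (spec$d == 0) spec$k * log(u) else spec$k * log(u) - spec$d / (2 * u)
    },
    reciprocal = -log(u) - u / 2
  )
}

# log of the integral of the kernel over [a, b]; closed form per family.
log_normalizer <- function(spec, v = spec$v) {
  ua <- v + spec$a
  ub <- v + spec$b
  switch(spec$family,
    power = log_power_integral(ua, ub, spec$k),
    exponential = {
      # int_a^b exp(-c w / 2) dw = (2/c) exp(-c a / 2) (1 - exp(-c (b-a)/2))
      log(2 / spec$c) - spec$c * spec$a / 2 +
        log1p(-exp(-spec$c * (spec$b - spec$a) / 2))
    },
    hybrid = log_powexp_integral(ua, ub, spec$k, spec$d / 2),
    reciprocal = {
      g <- recip_antideriv(c(ua, ub))
      log(g[2] - g[1])
    }
  )
}

#' Normalized prior density of W
#'
#' Evaluates the density of `W` under a [prior_spec()], normalized so that
#' it integrates to 1 over the support `[a, b]`. Values outside the support
#' have density 0.
#'
#' @param spec A [prior_spec()].
#' @param w Numeric vector of evaluation points.
#' @param v Optional variance anchor overriding `spec$v` (used when the
#'   Bayes-factor machinery evaluates an empirical-family kernel at a
#'   SNP's own `V`).
#' @return Numeric vector of densities (per unit `W`).
#' @export
prior_density <- function(spec, w, v = spec$v) {
  stopifnot(inherits(spec, "prior_spec"))
  ln <- if (identical(v, spec$v)) spec$log_norm else log_normalizer(spec, v)
  out <- exp(log_kernel(spec, w, v) - ln)
  out[w < spec$a | w > spec$b] <- 0
  out
}

#' Prior distribution function of W
#'
#' Closed-form distribution functions for each family: the power family has
#' a polynomial form with a dedicated logarithmic branch at `k = -1`; the
#' exponential family is elementary; the hybrid family is a ratio of upper
#' incomplete gamma functions; the reciprocal family uses a logarithm plus
#' an alternating series, truncated when terms fall below 1e-12.
#'
#' Values below `a` map to 0 and above `b` to 1.
#'
#' @inheritParams prior_density
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
prior_cdf <- function(spec, w, v = spec$v) {
  stopifnot(inherits(spec, "prior_spec"))
  p <- switch(spec$family,
    power = cdf_power(w, spec$k, spec$a, spec$b, v),
    exponential = cdf_exponential(w, spec$c, spec$a, spec$b),
    hybrid = cdf_hybrid(w, spec$k, spec$d, spec$a, spec$b, v),
    reciprocal = cdf_reciprocal(w, spec$a, spec$b, v)
  )
  p[w <= spec$a] <- 0
  p[w >= spec$b] <- 1
  pmin(pmax(p, 0), 1)
}

# Raw family CDFs, callable without constructing a prior_spec (the
# hyperparameter fitting loop evaluates thousands of candidate specs).
cdf_power <- function(w, k, a, b, v) {
  w <- pmin(pmax(w, a), b)
  if (abs(k + 1) < 1e-10) {
    log((v + w) / (v + a)) / log((v + b) / (v + a))
  } else {
    ((v + w)^(k + 1) - (v + a)^(k + 1)) /
      ((v + b)^(k + 1) - (v + a)^(k + 1))
  }
}

cdf_exponential <- function(w, cc, a, b) {
  w <- pmin(pmax(w, a), b)
  # (exp(-c w/2) - exp(-c a/2)) / (exp(-c b/2) - exp(-c a/2)), written with
  # expm1 so the c -> 0 uniform limit is exact
  expm1(-cc * (w - a) / 2) / expm1(-cc * (b - a) / 2)
}

cdf_hybrid <- function(w, k, d, a, b, v) {
  if (d == 0) {
    return(cdf_power(w, k, a, b, v))
  }
  w <- pmin(pmax(w, a), b)
  shape <- -k - 1
  t_w <- d / (2 * (v + w))
  t_a <- d / (2 * (v + a)) # largest argument
  t_b <- d / (2 * (v + b))
  # Gamma(shape, t) underflows in linear space for large d and cancels for
  # tiny d; work on the log scale of whichever incomplete-gamma tail is
  # better conditioned at the largest argument.
  if (pgamma(t_a, shape) < 0.5) {
    num <- log_diff_exp(log_gamma_lower(t_a, shape), log_gamma_lower(t_w, shape))
    den <- log_diff_exp(log_gamma_lower(t_a, shape), log_gamma_lower(t_b, shape))
  } else {
    num <- log_diff_exp(log_gamma_upper(t_w, shape), log_gamma_upper(t_a, shape))
    den <- log_diff_exp(log_gamma_upper(t_b, shape), log_gamma_upper(t_a, shape))
  }
  out <- exp(num - den)
  out[w == a] <- 0 # log_diff_exp(x, x) is -Inf; make the boundary exact
  out
}

cdf_reciprocal <- function(w, a, b, v) {
  w <- pmin(pmax(w, a), b)
  g <- recip_antideriv(v + c(a, b, w))
  (g[-(1:2)] - g[1]) / (g[2] - g[1])
}

#' Prior mean of W
#'
#' Computes `E(W)` under a [prior_spec()]. The power family uses closed-form
#' polynomial/logarithmic antiderivatives (via `E(W) = E(V + W) - V`); the
#' other families use adaptive quadrature at relative tolerance 1e-9.
#'
#' @inheritParams prior_density
#' @return Scalar `E(W)`, guaranteed inside `[a, b]`.
#' @export
prior_mean <- function(spec, v = spec$v) {
  stopifnot(inherits(spec, "prior_spec"))
  if (spec$family == "power") {
    ua <- v + spec$a
    ub <- v + spec$b
    # E(V + W) = int u^{k+1} du / int u^k du
    eu <- exp(log_power_integral(ua, ub, spec$k + 1) -
                log_power_integral(ua, ub, spec$k))
    return(min(max(eu - v, spec$a), spec$b))
  }
  ln <- if (identical(v, spec$v)) spec$log_norm else log_normalizer(spec, v)
  m <- quad(function(w) w * exp(log_kernel(spec, w, v) - ln),
            spec$a, spec$b, rel.tol = 1e-9)$value
  min(max(m, spec$a), spec$b)
}

#' Mode of the hybrid prior
#'
#' The hybrid family is the only one with an interior stationary point; its
#' unconstrained mode is at `W = -(V + d / (2k))`, clipped to the support.
#'
#' @inheritParams prior_density
#' @param clip If `TRUE` (default), clip the stationary point to `[a, b]`.
#' @return The mode location. Errors for non-hybrid families, whose
#'   densities are monotone on the support.
#' @export
hybrid_mode <- function(spec, clip = TRUE, v = spec$v) {
  stopifnot(inherits(spec, "prior_spec"))
  if (spec$family != "hybrid") {
    abort(sprintf("mode formula applies to the hybrid family only, not '%s'",
                  spec$family))
  }
  m <- -(v + spec$d / (2 * spec$k))
  if (clip) min(max(m, spec$a), spec$b) else m
}

#' Prior quantile function
#'
#' Inverts [prior_cdf()] by vectorized bisection on `[a, b]`.
#'
#' @param spec A [prior_spec()].
#' @param p Vector of probabilities in `[0, 1]`.
#' @inheritParams prior_density
#' @return Vector of `W` quantiles.
#' @export
prior_quantile <- function(spec, p, v = spec$v) {
  stopifnot(inherits(spec, "prior_spec"), all(p >= 0 & p <= 1))
  lo <- rep(spec$a, length(p))
  hi <- rep(spec$b, length(p))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    below <- prior_cdf(spec, mid, v) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[p == 0] <- spec$a
  out[p == 1] <- spec$b
  out
}

#' Sample from a prior on W
#'
#' Inverse-CDF sampling through [prior_quantile()]; reproducible when a
#' seed is supplied.
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @inheritParams prior_density
#' @return Numeric vector of `n` draws in `[a, b]`.
#' @export
sample_prior <- function(spec, n, seed = NULL, v = spec$v) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  prior_quantile(spec, runif(n), v)
}

#' Serialize / deserialize a prior specification
#'
#' `prior_spec_to_list()` flattens a [prior_spec()] to a plain named list
#' (family, a, b, k, c, d, v) suitable for JSON or YAML; `as_prior_spec()`
#' rebuilds the object, revalidating all restrictions.
#'
#' @param spec A [prior_spec()].
#' @param x A named list as produced by `prior_spec_to_list()` (or parsed
#'   from a config file).
#' @return A named list, or a `prior_spec`.
#' @export
prior_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  keep <- spec[c("family", "a", "b", "k", "c", "d", "v")]
  keep[!vapply(keep, function(z) is.character(z) || !is.na(z), logical(1))] <- NULL
  keep
}

#' @rdname prior_spec_to_list
#' @export
as_prior_spec <- function(x) {
  if (inherits(x, "prior_spec")) return(x)
  stopifnot(is.list(x), !is.null(x$family))
  prior_spec(
    family = x$family, a = x$a, b = x$b,
    k = x$k, c = x$c, d = x$d, v = x$v
  )
}
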