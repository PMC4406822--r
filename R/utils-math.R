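# Numerical helpers shared by the prior families and the Bayes-factor
# integrals. Everything here works on the log scale so that very peaked
# kernels (e.g. power priors with k near -10) never overflow.

# log(exp(lx) - exp(ly)) for lx > ly, elementwise.
log_diff_exp <- function(lx, ly) {
  stopifnot(all(lx >= ly | is.na(lx) | is.na(ly)))
  lx + log1p(-exp(ly - lx))
}

# log of the upper incomplete gamma function Gamma(shape, x), shape > 0.
log_gamma_upper <- function(x, shape) {
  lgamma(shape) + pgamma(x, shape, lower.tail = FALSE, log.p = TRUE)
}

# log of the lower incomplete gamma function gamma(shape, x), shape > 0.
log_gamma_lower <- function(x, shape) {
  lgamma(shape) + pgamma(x, shape, lower.tail = TRUE, log.p = TRUE)
}

# log of int_{lo}^{hi} u^s du, 0 < lo < hi; handles the s = -1 log branch.
log_power_integral <- function(lo, hi, s) {
  if (abs(s + 1) < 1e-12) {
    return(log(log(hi / lo)))
  }
  if (s + 1 > 0) {
    log_diff_exp((s + 1) * log(hi), (s + 1) * log(lo)) - log(s + 1)
  } else {
    log_diff_exp((s + 1) * log(lo), (s + 1) * log(hi)) - log(-(s + 1))
  }
}

# log of int_{lo}^{hi} u^s exp(-q/u) du for q > 0, 0 < lo < hi, s < -1.
# Substituting t = q/u gives q^(s+1) * [Gamma(-s-1, q/hi) - Gamma(-s-1, q/lo)].
# The incomplete-gamma difference is taken on whichever tail cancels less.
log_powexp_integral <- function(lo, hi, s, q) {
  if (q <= 0) {
    return(log_power_integral(lo, hi, s))
  }
  shape <- -s - 1
  stopifnot(shape > 0)
  t_hi <- q / lo # larger argument
  t_lo <- q / hi
  if (q / lo < 1e-12) {
    # exp(-q/u) is 1 to double precision across the range
    return(log_power_integral(lo, hi, s))
  }
  if (pgamma(t_hi, shape) < 0.5) {
    lg <- log_diff_exp(log_gamma_lower(t_hi, shape), log_gamma_lower(t_lo, shape))
  } else {
    lg <- log_diff_exp(log_gamma_upper(t_lo, shape), log_gamma_upper(t_hi, shape))
  }
  (s + 1) * log(q) + lg
}

# Ein-type alternating series: sum_{n>=1} (-1)^n x^n / (n * n!).
# Used by the reciprocal prior's distribution function. Truncates when every
# term magnitude drops below 1e-12 (after at least 5 terms); if 500 terms do
# not converge the caller falls back to quadrature. Vectorized in x.
alternating_series <- function(x) {
  term <- -x # n = 1
  acc <- term
  n <- 1L
  repeat {
    n <- n + 1L
    term <- term * (-x) * (n - 1) / (n * n)
    acc <- acc + term
    if (n > 5L && max(abs(term)) < 1e-12) break
    if (n >= 500L) {
      acc[] <- NA_real_ # signal non-convergence
      break
    }
  }
  acc
}

# Antiderivative of u^{-1} exp(-u/2): ln(u) + sum_{n>=1} (-1)^n (u/2)^n/(n n!).
recip_antideriv <- function(u) {
  s <- alternating_series(u / 2)
  if (anyNA(s)) {
    # quadrature fallback, anchored at the smallest u requested
    u0 <- min(u)
    s <- vapply(seq_along(u), function(i) {
      if (u[i] == u0) return(0)
      integrate(function(t) exp(-t / 2) / t, u0, u[i],
                rel.tol = 1e-11)$value
    }, numeric(1))
    return(s + log(u / u0))
  }
  log(u) + s
}

# Adaptive quadrature with an informative error on failure.
quad <- function(f, lower, upper, rel.tol = 1e-9, subdivisions = 200L) {
  res <- tryCatch(
    integrate(f, lower, upper, rel.tol = rel.tol,
              subdivisions = subdivisions, stop.on.error = FALSE),
    error = function(e) NULL
  )
  if (is.null(res) || !res$message %in% c("OK", "roundoff error was detected")) {
    abort(sprintf(
      "adaptive quadrature failed on [%g, %g]: %s",
      lower, upper, if (is.null(res)) "integrate() error" else res$message
    ))
  }
  res
}
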