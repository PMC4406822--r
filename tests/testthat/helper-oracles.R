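# Independent oracles and fixture builders. These deliberately avoid the
# package's own computational paths: the logistic oracle is a subject-level
# Newton/IRLS solver, the BF oracle is plain arithmetic on the formula, and
# prior integrals are brute-force quadrature on the raw kernels.

# Subject-level IRLS for logit P(y=1) = b0 + b1 * x.
irls_logistic_oracle <- function(x, y, tol = 1e-12, maxit = 50) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    mu <- plogis(drop(X %*% beta))
    score <- drop(t(X) %*% (y - mu))
    info <- t(X) %*% (X * (mu * (1 - mu)))
    beta <- beta + solve(info, score)
    if (max(abs(score)) < tol) break
  }
  list(beta = unname(beta[2]), v = solve(info)[2, 2])
}

# Direct arithmetic on the Wakefield BF formula (kept separate from the
# package's log-space implementation).
wbf_oracle <- function(beta, v, w) {
  sqrt(v / (v + w)) * exp(beta^2 * w / (2 * v * (v + w)))
}

# Brute-force normalization/CDF oracle by fine quadrature on the raw
# kernel, independent of the package's closed forms.
kernel_fun <- function(family, k = NA, cc = NA, d = NA, v = NA) {
  switch(family,
    power = function(w) (v + w)^k,
    exponential = function(w) exp(-cc * w / 2),
    hybrid = function(w) (v + w)^k * exp(-d / (2 * (v + w))),
    reciprocal = function(w) exp(-(v + w) / 2) / (v + w)
  )
}

cdf_quadrature_oracle <- function(spec, w) {
  f <- kernel_fun(spec$family, spec$k, spec$c, spec$d, spec$v)
  z <- integrate(f, spec$a, spec$b, rel.tol = 1e-12)$value
  vapply(w, function(wi) {
    integrate(f, spec$a, wi, rel.tol = 1e-12)$value / z
  }, numeric(1))
}

# Prior-averaged BF by quadrature on the raw product, written without the
# package's u-substitution or log-space tricks (safe for the moderate
# effect sizes used in tests).
novel_bf_quadrature_oracle <- function(beta, v, spec) {
  f <- kernel_fun(spec$family, spec$k, spec$c, spec$d, v)
  z <- integrate(f, spec$a, spec$b, rel.tol = 1e-12)$value
  integrate(function(w) wbf_oracle(beta, v, w) * f(w) / z,
            spec$a, spec$b, rel.tol = 1e-12)$value
}

# Build an elicited_quantiles object whose derived (w, p) pairs and
# support (a, b) are exactly the requested ones, by inverting the OR
# mappings (round-trip is exact in double precision).
make_elicitation <- function(w, p, a, b, ref_percentile = 0.8) {
  elicited_quantiles(
    z = 100 * (2 * p - 1),
    pi_u = exp(qnorm(p) * sqrt(w)),
    pi_u_min = exp(qnorm(ref_percentile) * sqrt(a)),
    pi_u_max = exp(qnorm(ref_percentile) * sqrt(b)),
    ref_percentile = ref_percentile
  )
}

# Small deterministic genotype dataset with prescribed per-group genotype
# counts (g = 0, 1, 2).
counts_dataset <- function(case_counts, ctrl_counts) {
  g <- c(rep(0:2, case_counts), rep(0:2, ctrl_counts))
  status <- rep(c(1L, 0L), c(sum(case_counts), sum(ctrl_counts)))
  m <- matrix(g, ncol = 1, dimnames = list(NULL, "snp_a"))
  list(genotypes = m, status = status)
}

# Default grid of prior specs spanning all four families, used by the
# cross-path BF agreement tests.
spec_grid <- function(a = 0.003, b = 0.1) {
  list(
    prior_spec("power", a, b, k = -1.66, v = 0.00017),
    prior_spec("power", a, b, k = -5, v = 0.005),
    prior_spec("exponential", a, b, c = 145),
    prior_spec("exponential", a, b, c = 5),
    prior_spec("hybrid", a, b, k = -1.1, d = 0.01, v = 0.003),
    prior_spec("hybrid", a, b, k = -1.1, d = 1, v = 0.005),
    prior_spec("reciprocal", a, b, v = 0.003),
    prior_spec("reciprocal", a, b, v = 0.0004)
  )
}
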