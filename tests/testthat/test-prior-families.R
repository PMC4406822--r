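# Prior families on W: normalization, distribution functions, moments,
# modes, sampling, serialization.

test_that("densities integrate to 1 and CDFs match quadrature for all families", {
  for (spec in spec_grid()) {
    total <- integrate(function(w) prior_density(spec, w), spec$a, spec$b,
                       rel.tol = 1e-12)$value
    expect_equal(total, 1, tolerance = 1e-8,
                 label = sprintf("%s density integral", spec$family))
    expect_equal(prior_cdf(spec, spec$a), 0)
    expect_equal(prior_cdf(spec, spec$b), 1)
    ws <- seq(spec$a, spec$b, length.out = 23)[2:22]
    expect_equal(prior_cdf(spec, ws), cdf_quadrature_oracle(spec, ws),
                 tolerance = 1e-6,
                 label = sprintf("%s cdf vs quadrature", spec$family))
    expect_true(all(diff(prior_cdf(spec, seq(spec$a, spec$b, length.out = 101))) >= 0),
                label = sprintf("%s cdf monotone", spec$family))
  }
})

test_that("numerical derivative of the CDF recovers the density", {
  for (spec in spec_grid()) {
    ws <- seq(spec$a, spec$b, length.out = 13)[2:12]
    h <- (spec$b - spec$a) * 1e-6
    deriv <- (prior_cdf(spec, ws + h) - prior_cdf(spec, ws - h)) / (2 * h)
    expect_equal(deriv, prior_density(spec, ws), tolerance = 1e-4,
                 label = sprintf("%s dF/dw vs density", spec$family))
  }
})

test_that("power CDF approaches the k = -1 logarithmic branch continuously", {
  a <- 0.003; b <- 0.1; v <- 0.003
  ws <- seq(a, b, length.out = 11)[2:10]
  exact <- prior_cdf(prior_spec("power", a, b, k = -1, v = v), ws)
  for (k in c(-1 + 1e-6, -1 - 1e-6)) {
    near <- prior_cdf(prior_spec("power", a, b, k = k, v = v), ws)
    expect_lt(max(abs(near / exact - 1)), 1e-4)
  }
})

test_that("the exponential prior tends to the uniform as c tends to 0", {
  a <- 0.003; b <- 0.1
  spec <- prior_spec("exponential", a, b, c = 1e-9)
  ws <- seq(a, b, length.out = 7)
  expect_equal(prior_density(spec, ws), rep(1 / (b - a), 7), tolerance = 1e-6)
  expect_equal(prior_mean(spec), (a + b) / 2, tolerance = 1e-6)
})

test_that("density is zero outside the support and invalid hyperparameters are rejected", {
  spec <- prior_spec("power", 0.003, 0.1, k = -2, v = 0.003)
  expect_identical(prior_density(spec, c(0.001, 0.2)), c(0, 0))
  expect_error(prior_spec("power", 0.003, 0.1, k = -0.3, v = 0.003), "k < -1/2")
  expect_error(prior_spec("exponential", 0.003, 0.1, c = -1), "c > 0")
  expect_error(prior_spec("hybrid", 0.003, 0.1, k = -0.9, d = 0.1, v = 0.003), "k < -1")
  expect_error(prior_spec("hybrid", 0.003, 0.1, k = -1.5, d = -0.1, v = 0.003), "d >= 0")
  expect_error(prior_spec("power", 0.1, 0.1, k = -2, v = 0.003), "support")
  expect_error(prior_spec("power", 0.003, 0.1, k = -2), "variance anchor")
})

test_that("prior_mean stays inside the support and matches closed power form", {
  for (spec in spec_grid()) {
    m <- prior_mean(spec)
    expect_true(m >= spec$a && m <= spec$b)
  }
  # quadrature cross-check of the closed-form power path, incl. the
  # k = -1 and k = -2 antiderivative branches
  for (k in c(-0.7, -1, -1.66, -2, -5)) {
    spec <- prior_spec("power", 0.003, 0.1, k = k, v = 0.003)
    m_quad <- integrate(function(w) w * prior_density(spec, w),
                        spec$a, spec$b, rel.tol = 1e-11)$value
    expect_equal(prior_mean(spec), m_quad, tolerance = 1e-8,
                 label = sprintf("power mean, k = %g", k))
  }
})

test_that("E(W) is nondecreasing in V for power and reciprocal, not always for hybrid", {
  vs <- seq(1e-4, 0.03, length.out = 12)
  for (mk in list(function(v) prior_spec("power", 0.003, 0.1, k = -1.5, v = v),
                  function(v) prior_spec("reciprocal", 0.003, 0.1, v = v))) {
    ew <- vapply(vs, function(v) prior_mean(mk(v)), numeric(1))
    expect_true(all(diff(ew) >= -1e-10),
                label = sprintf("E(W) nondecreasing (%s)", mk(0.01)$family))
  }
  # a hybrid prior with large d concentrates mass high and E(W) can fall
  # as V grows
  ew_h <- vapply(vs, function(v) {
    prior_mean(prior_spec("hybrid", 0.003, 0.1, k = -8, d = 1, v = v))
  }, numeric(1))
  expect_true(any(diff(ew_h) < 0))
})

test_that("hybrid mode matches -(V + d/(2k)) and is a stationary maximum", {
  spec <- prior_spec("hybrid", 0.0001, 0.1, k = -1.1, d = 0.01, v = 0.003)
  m <- hybrid_mode(spec, clip = FALSE)
  expect_equal(m, -(0.003 + 0.01 / (2 * -1.1)), tolerance = 1e-12)
  # derivative of the density vanishes at the unclipped mode
  h <- 1e-7
  slope <- (prior_density(spec, m + h) - prior_density(spec, m - h)) / (2 * h)
  expect_lt(abs(slope) * (spec$b - spec$a) / prior_density(spec, m), 1e-6)
  # interior stationary point beats both endpoints
  expect_gt(prior_density(spec, m), prior_density(spec, spec$a))
  expect_gt(prior_density(spec, m), prior_density(spec, spec$b))
  # d -> 0 with k < -1: unclipped mode is -V < 0, so the clipped mode is a
  # and the density decreases over the support
  spec0 <- prior_spec("hybrid", 0.003, 0.1, k = -1.5, d = 1e-12, v = 0.003)
  expect_equal(hybrid_mode(spec0), spec0$a)
  dens <- prior_density(spec0, seq(spec0$a, spec0$b, length.out = 50))
  expect_true(all(diff(dens) < 0))
  expect_error(hybrid_mode(prior_spec("power", 0.003, 0.1, k = -2, v = 0.003)),
               "hybrid")
})

test_that("hybrid converges pointwise to the power family as d tends to 0", {
  ws <- seq(0.003, 0.1, length.out = 9)
  pow <- prior_density(prior_spec("power", 0.003, 0.1, k = -1.5, v = 0.003), ws)
  hyb <- prior_density(prior_spec("hybrid", 0.003, 0.1, k = -1.5, d = 1e-10,
                                  v = 0.003), ws)
  expect_equal(hyb, pow, tolerance = 1e-6)
})

test_that("inverse-CDF sampling reproduces the distribution and is deterministic", {
  for (spec in list(prior_spec("power", 0.003, 0.1, k = -1.66, v = 0.00017),
                    prior_spec("reciprocal", 0.003, 0.1, v = 0.003))) {
    x <- sample_prior(spec, 100000, seed = 42)
    expect_true(all(x >= spec$a & x <= spec$b))
    grid <- seq(spec$a, spec$b, length.out = 200)
    emp <- stats::ecdf(x)(grid)
    expect_lt(max(abs(emp - prior_cdf(spec, grid))), 0.01)
    expect_identical(x, sample_prior(spec, 100000, seed = 42))
  }
})

test_that("prior specs round-trip through the flat list serialization", {
  for (spec in spec_grid()) {
    back <- as_prior_spec(prior_spec_to_list(spec))
    expect_equal(back[c("family", "a", "b", "k", "c", "d", "v")],
                 spec[c("family", "a", "b", "k", "c", "d", "v")])
    ws <- seq(spec$a, spec$b, length.out = 5)
    expect_equal(prior_cdf(back, ws), prior_cdf(spec, ws))
  }
})
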