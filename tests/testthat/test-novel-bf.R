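# Prior-averaged Bayes factors: path agreement, bounds, limits, batching.

snp_points <- function() {
  expand.grid(beta = c(0, 0.02, 0.047, 0.1, 0.2),
              v = c(1.2e-4, 1e-3, 5e-3))
}

test_that("closed forms and quadrature agree with an independent quadrature oracle", {
  pts <- snp_points()
  for (spec in spec_grid()) {
    for (i in seq_len(nrow(pts))) {
      oracle <- novel_bf_quadrature_oracle(pts$beta[i], pts$v[i], spec)
      got <- priorbf:::log_novel_bf(pts$beta[i], pts$v[i], spec, "auto")
      expect_equal(exp(got$log_bf), oracle, tolerance = 1e-6,
                   label = sprintf("%s beta=%g v=%g (auto)", spec$family,
                                   pts$beta[i], pts$v[i]))
      quad <- priorbf:::log_novel_bf(pts$beta[i], pts$v[i], spec, "quadrature")
      expect_equal(exp(quad$log_bf), oracle, tolerance = 1e-6)
      expect_lte(quad$rel_err, 1e-6)
    }
  }
})

test_that("Monte-Carlo estimates agree with quadrature within sampling error", {
  pts <- snp_points()[c(2, 5, 9, 14), ]
  i_mc <- 0
  for (spec in spec_grid()) {
    for (i in seq_len(nrow(pts))) {
      i_mc <- i_mc + 1
      mc <- monte_carlo_bf(pts$beta[i], pts$v[i], spec, n_draws = 50000,
                           seed = 2400 + i_mc)
      oracle <- novel_bf_quadrature_oracle(pts$beta[i], pts$v[i], spec)
      # 3.5 SEs: the summand is right-skewed, so the estimated SE is
      # itself noisy at moderate draw counts
      expect_lt(abs(mc$bf - oracle), 3.5 * mc$se + 1e-12,
                label = sprintf("%s beta=%g v=%g (MC)", spec$family,
                                pts$beta[i], pts$v[i]))
    }
  }
  # determinism under a fixed seed
  spec <- spec_grid()[[1]]
  m1 <- monte_carlo_bf(0.05, 1e-3, spec, n_draws = 2000, seed = 99)
  m2 <- monte_carlo_bf(0.05, 1e-3, spec, n_draws = 2000, seed = 99)
  expect_identical(m1$bf, m2$bf)
  expect_error(monte_carlo_bf(0.05, 1e-3, spec, n_draws = 10), "1,000")
})

test_that("the averaged BF is bounded by the extreme fixed-W Wakefield BFs", {
  pts <- snp_points()
  for (spec in spec_grid()) {
    for (i in seq_len(nrow(pts))) {
      bf <- exp(priorbf:::log_novel_bf(pts$beta[i], pts$v[i], spec)$log_bf)
      ws <- seq(spec$a, spec$b, length.out = 200)
      wbfs <- wakefield_bf(pts$beta[i], pts$v[i], ws)
      expect_gte(bf, min(wbfs) * (1 - 1e-9))
      expect_lte(bf, max(wbfs) * (1 + 1e-9))
    }
  }
})

test_that("the averaged BF increases strictly with |beta| and is below 1 at beta = 0", {
  for (spec in spec_grid()[c(1, 3, 5, 7)]) {
    bfs <- vapply(seq(0, 0.3, length.out = 25), function(b) {
      exp(priorbf:::log_novel_bf(b, 1e-3, spec)$log_bf)
    }, numeric(1))
    expect_true(all(diff(bfs) > 0), label = spec$family)
    expect_lt(bfs[1], 1) # every sqrt(V/(V+W)) term is below 1
  }
})

test_that("a degenerate support reduces every family to the Wakefield BF at W = a", {
  a <- 0.003
  eps <- 1e-8
  mk <- list(
    function() prior_spec("power", a, a + eps, k = -1.66, v = 1e-4),
    function() prior_spec("exponential", a, a + eps, c = 145),
    function() prior_spec("hybrid", a, a + eps, k = -1.1, d = 0.01, v = 1e-4),
    function() prior_spec("reciprocal", a, a + eps, v = 1e-4)
  )
  for (f in mk) {
    spec <- f()
    bf <- exp(priorbf:::log_novel_bf(0.05, 1e-4, spec)$log_bf)
    expect_equal(bf, wakefield_bf(0.05, 1e-4, a), tolerance = 1e-3,
                 label = spec$family)
  }
})

test_that("a sharply concentrated power prior tracks the Wakefield BF at the lower bound", {
  spec <- prior_spec("power", 0.003, 0.1, k = -30, v = 1e-4)
  bf <- exp(priorbf:::log_novel_bf(0.08, 1e-3, spec)$log_bf)
  expect_equal(bf, wakefield_bf(0.08, 1e-3, 0.003), tolerance = 0.05)
  # hybrid mass piled near b behaves like WBF at the upper bound
  spec_h <- prior_spec("hybrid", 0.003, 0.1, k = -1.05, d = 3, v = 1e-3)
  bf_h <- exp(priorbf:::log_novel_bf(0.08, 1e-3, spec_h)$log_bf)
  expect_equal(bf_h, wakefield_bf(0.08, 1e-3, 0.1), tolerance = 0.05)
})

test_that("batch evaluation preserves order, handles invalid rows, and ranks", {
  spec <- prior_spec("power", 0.003, 0.1, k = -1.66, v = 0.00017)
  tab <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"),
    beta = c(0.05, 0.12, NA, 0.02),
    v = c(1e-3, 1e-3, 1e-3, 1e-3),
    maf = c(0.3, 0.2, 0.1, 0.4),
    valid = c(TRUE, TRUE, FALSE, TRUE)
  )
  res <- novel_bf(tab, spec)
  expect_identical(res$snp_id, tab$snp_id)
  expect_true(is.na(res$bf[3]))
  expect_equal(res$rank[order(-res$bf)][1:2], c(1, 2))
  # single row equals single call
  one <- novel_bf(tab[2, ], spec)
  expect_equal(one$bf, res$bf[2])
  # permuting input permutes output identically
  perm <- c(4, 2, 1, 3)
  res_p <- novel_bf(tab[perm, ], spec)
  expect_equal(res_p$bf, res$bf[perm])
  expect_equal(res_p$log10_bf, log10(res_p$bf))
  # ranking matches the independent quadrature oracle's ranking
  oracle_bf <- vapply(seq_len(nrow(tab)), function(i) {
    if (!tab$valid[i]) return(NA_real_)
    novel_bf_quadrature_oracle(tab$beta[i], tab$v[i], spec)
  }, numeric(1))
  expect_identical(order(-res$bf[res$valid]), order(-oracle_bf[tab$valid]))
})

test_that("BF results export as the ranked tab-separated table", {
  spec <- prior_spec("exponential", 0.003, 0.1, c = 50)
  tab <- tibble::tibble(snp_id = c("a", "b"), beta = c(0.1, 0.01),
                        v = c(1e-3, 1e-3), maf = c(0.2, 0.3))
  res <- novel_bf(tab, spec)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_bf_table(res, tf)
  back <- utils::read.delim(tf)
  expect_identical(names(back),
                   c("snp_id", "beta", "se", "maf", "bf", "log10_bf",
                     "rank", "method"))
  expect_equal(back$bf, res$bf, tolerance = 1e-10)
})
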