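#' Convert elicited odds-ratio quantiles to quantiles of W
#'
#' An expert states the upper limit `pi_u` of the central `z`% probability
#' interval for the odds ratio. Under the `N(0, W)` prior on the log odds
#' ratio this pins down the quantile of `W`:
#' `w = (ln(pi_u) / qnorm(p))^2` with `p = 1 - (1 - 0.01 z) / 2`.
#'
#' @param pi_u Upper OR limit(s) of the central interval(s), `> 1`.
#' @param z Central probability-interval level(s) in percent, in (0, 100).
#' @return A tibble with columns `z`, `pi_u`, `p` (the cumulative
#'   probability of the OR quantile) and `w` (the implied `W` quantile).
#' @examples
#' or_quantile_to_w(c(1.43, 1.21, 1.14), c(95, 75, 50))
#' @export
or_quantile_to_w <- function(pi_u, z) {
  if (any(pi_u <= 1)) abort("pi_u must exceed 1 (the logOR quantile must be positive)")
  if (any(z <= 0 | z >= 100)) abort("z must lie strictly inside (0, 100)")
  p <- 1 - (1 - 0.01 * z) / 2
  tibble(z = z, pi_u = pi_u, p = p, w = (log(pi_u) / qnorm(p))^2)
}

#' @rdname or_quantile_to_w
#' @param beta_p An elicited `p`-quantile of the log odds ratio itself
#'   (single-percentile variant `W = (beta_p / qnorm(p))^2`).
#' @param p Cumulative probability of that quantile, in (0.5, 1).
#' @export
logor_quantile_to_w <- function(beta_p, p) {
  if (any(p <= 0.5 | p >= 1)) abort("p must lie in (0.5, 1)")
  (beta_p / qnorm(p))^2
}

#' Support bounds for W from a plausible range of OR upper limits
#'
#' The expert gives the smallest and largest plausible values
#' (`pi_u_min`, `pi_u_max`) of the OR at a reference percentile (e.g. the
#' 80th); these map to the support `[a, b]` of `W` via
#' `a = (ln(pi_u_min) / qnorm(p))^2` and similarly for `b`. Note the
#' reference-percentile path uses `p` directly (an 80th OR percentile is
#' the upper limit of the central 60% interval).
#'
#' @param pi_u_min,pi_u_max Smallest and largest plausible OR upper limits
#'   at the reference percentile; both `> 1`, `pi_u_min < pi_u_max`.
#' @param ref_percentile Reference percentile as a probability in
#'   (0.5, 1); default 0.8.
#' @return A named list with elements `a` and `b` (full precision).
#' @examples
#' w_support(1.05, 1.3, 0.8) # a ~ 0.003, b ~ 0.1
#' @export
w_support <- function(pi_u_min, pi_u_max, ref_percentile = 0.8) {
  if (pi_u_min <= 1 || pi_u_max <= 1) abort("OR limits must exceed 1")
  if (pi_u_min >= pi_u_max) {
    abort("pi_u_min must be strictly below pi_u_max (degenerate support rejected)")
  }
  if (ref_percentile <= 0.5 || ref_percentile >= 1) {
    abort("ref_percentile must lie in (0.5, 1)")
  }
  q <- qnorm(ref_percentile)
  list(a = (log(pi_u_min) / q)^2, b = (log(pi_u_max) / q)^2)
}

#' Bundle an expert elicitation
#'
#' Light container validating the quantities an elicitation session
#' produces: central-interval levels with OR upper limits, and the
#' reference-percentile OR bounds that define the support of `W`.
#'
#' @param z Central probability-interval levels in percent (distinct,
#'   inside (0, 100)).
#' @param pi_u Matching upper OR limits, all `> 1`.
#' @param pi_u_min,pi_u_max Plausible OR bounds at the reference
#'   percentile.
#' @param ref_percentile Reference percentile (probability), default 0.8.
#' @return An object of class `elicited_quantiles`.
#' @examples
#' icogs_elicitation() # the bundled breast-cancer fine-mapping example
#' @export
elicited_quantiles <- function(z, pi_u, pi_u_min, pi_u_max,
                               ref_percentile = 0.8) {
  if (length(z) != length(pi_u)) abort("z and pi_u must have equal length")
  if (anyDuplicated(z)) abort("z levels must be distinct")
  quantiles <- or_quantile_to_w(pi_u, z) # validates z, pi_u
  support <- w_support(pi_u_min, pi_u_max, ref_percentile) # validates bounds
  structure(
    list(quantiles = quantiles, pi_u_min = pi_u_min, pi_u_max = pi_u_max,
         ref_percentile = ref_percentile, support = support),
    class = "elicited_quantiles"
  )
}

#' @export
print.elicited_quantiles <- function(x, ...) {
  cat("<elicited_quantiles>\n")
  cat(sprintf("  support from %g%% OR in [%g, %g]: a = %.4g, b = %.4g\n",
              100 * x$ref_percentile, x$pi_u_min, x$pi_u_max,
              x$support$a, x$support$b))
  print(x$quantiles)
  invisible(x)
}

#' The worked breast-cancer fine-mapping elicitation
#'
#' The elicitation used ahead of the iCOGS CASP8-region analysis: the 80th
#' OR percentile believed to lie in (1.05, 1.3), and upper OR limits 1.43,
#' 1.21, 1.14 for the central 95%, 75% and 50% intervals. The median
#' per-SNP `V` in that dataset was 0.00017.
#'
#' @return An [elicited_quantiles()] object.
#' @export
icogs_elicitation <- function() {
  elicited_quantiles(z = c(95, 75, 50), pi_u = c(1.43, 1.21, 1.14),
                     pi_u_min = 1.05, pi_u_max = 1.3, ref_percentile = 0.8)
}

#' Fit a prior family's hyperparameters to elicited W quantiles
#'
#' Minimizes the sum of squared differences between the family's
#' distribution function and the elicited cumulative probabilities,
#' `sum_i (F(w_i) - p_i)^2`, over the family's hyperparameters:
#'
#' * power: grid search over `k` in `[-10, -0.5)` at step 0.01;
#' * exponential: 1-D bounded minimization over `c` in (0, 1e4], refined
#'   from a log-spaced grid;
#' * hybrid: 2-D grid over `k` in `[-10, -1)` step 0.01 crossed with
#'   `d` in 0, 1e-4, 1e-3, ..., 10, followed by continuous refinement of
#'   `d` between its grid neighbours (`k` stays on the grid, so the
#'   power-nested `d = 0` edge is searched at the same resolution as the
#'   power family itself);
#' * reciprocal: no free hyperparameters, objective evaluated directly.
#'
#' @param family One of `"power"`, `"exponential"`, `"hybrid"`,
#'   `"reciprocal"`.
#' @param w Elicited `W` quantile values.
#' @param p Matching cumulative probabilities.
#' @param a,b Support bounds for `W`.
#' @param v Variance anchor (median per-SNP `V`); ignored by the
#'   exponential family.
#' @return An object of class `prior_fit`: list with `family`,
#'   `hyperparams` (named numeric), `ssq` (achieved objective), `spec`
#'   (the fitted [prior_spec()]) and `grid` (tibble of every
#'   hyperparameter value evaluated with its objective, for audit).
#' @examples
#' eq <- icogs_elicitation()
#' fit_hyperparameters("power", w = eq$quantiles$w, p = eq$quantiles$p,
#'                     a = 0.003, b = 0.1, v = 0.00017)
#' @export
fit_hyperparameters <- function(family = c("power", "exponential", "hybrid", "reciprocal"),
                                w, p, a, b, v = NULL) {
  family <- match.arg(family)
  stopifnot(length(w) == length(p), length(w) >= 1, a < b)
  if (any(w <= a | w >= b)) {
    warn("elicited quantile(s) outside the open support (a, b); CDF values are clamped")
  }
  if (family != "exponential" && (is.null(v) || v <= 0)) {
    abort(sprintf("family '%s' requires a positive variance anchor v", family))
  }
  fit <- switch(family,
    power = {
      ks <- round(seq(-10, -0.51, by = 0.01), 2)
      ssq <- vapply(ks, function(k) sum((cdf_power(w, k, a, b, v) - p)^2),
                    numeric(1))
      best <- which.min(ssq)
      list(hyperparams = c(k = ks[best]), ssq = ssq[best],
           grid = tibble(k = ks, ssq = ssq))
    },
    exponential = {
      obj <- function(cc) sum((cdf_exponential(w, cc, a, b) - p)^2)
      cs <- exp(seq(log(1e-2), log(1e4), length.out = 400))
      ssq <- vapply(cs, obj, numeric(1))
      best <- which.min(ssq)
      lo <- cs[max(best - 1, 1)]
      hi <- cs[min(best + 1, length(cs))]
      opt <- optimize(obj, lower = lo, upper = hi, tol = 1e-10)
      list(hyperparams = c(c = opt$minimum), ssq = opt$objective,
           grid = tibble(c = cs, ssq = ssq))
    },
    hybrid = {
      ks <- round(seq(-10, -1.01, by = 0.01), 2)
      ds <- c(0, 10^seq(-4, 1))
      grid <- expand.grid(k = ks, d = ds)
      obj2 <- function(k, d) sum((cdf_hybrid(w, k, d, a, b, v) - p)^2)
      grid$ssq <- map2_dbl(grid$k, grid$d, obj2)
      best <- which.min(grid$ssq)
      # refine d continuously between its grid neighbours; k stays on the
      # same 0.01 grid as the power search so the two nested families are
      # compared at equal search resolution
      k_best <- grid$k[best]
      di <- match(grid$d[best], ds)
      d_lo <- ds[max(di - 1, 1)]
      d_hi <- ds[min(di + 1, length(ds))]
      ref <- optimize(function(d) obj2(k_best, d), lower = d_lo,
                      upper = d_hi, tol = 1e-12)
      if (ref$objective <= grid$ssq[best]) {
        d_best <- ref$minimum
        ssq_best <- ref$objective
      } else {
        d_best <- grid$d[best]
        ssq_best <- grid$ssq[best]
      }
      list(hyperparams = c(k = k_best, d = d_best), ssq = ssq_best,
           grid = as_tibble(grid))
    },
    reciprocal = {
      ssq <- sum((cdf_reciprocal(w, a, b, v) - p)^2)
      list(hyperparams = numeric(0), ssq = ssq,
           grid = tibble(ssq = ssq))
    }
  )
  hp <- as.list(fit$hyperparams)
  spec <- prior_spec(family, a = a, b = b, k = hp$k, c = hp$c, d = hp$d, v = v)
  structure(
    list(family = family, hyperparams = fit$hyperparams, ssq = fit$ssq,
         spec = spec, grid = fit$grid,
         quantile_pairs = tibble(w = w, p = p)),
    class = "prior_fit"
  )
}

#' @export
print.prior_fit <- function(x, ...) {
  hp <- if (length(x$hyperparams) == 0) "none" else
    paste(sprintf("%s = %g", names(x$hyperparams), x$hyperparams),
          collapse = ", ")
  cat(sprintf("<prior_fit> %s family: %s (ssq = %.3g over %d quantile pairs)\n",
              x$family, hp, x$ssq, nrow(x$quantile_pairs)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prior_fit <- function(x, ...) {
  if (length(x$hyperparams) == 0) {
    return(tibble(term = character(0), estimate = numeric(0)))
  }
  tibble(term = names(x$hyperparams), estimate = unname(x$hyperparams))
}

#' @exportS3Method generics::glance
glance.prior_fit <- function(x, ...) {
  tibble(family = x$family, ssq = x$ssq,
         n_quantiles = nrow(x$quantile_pairs),
         a = x$spec$a, b = x$spec$b)
}

#' Fit all four prior families and select the best
#'
#' Runs the full elicitation pipeline: derives the support from the
#' reference-percentile OR bounds, converts each central-interval limit to
#' a `W` quantile, fits every family's hyperparameters by quantile-matching
#' least squares, and returns the family with the smallest achieved sum of
#' squares. Ties (within 1e-9, e.g. the hybrid family collapsing onto the
#' power family at `d = 0`) are broken by the fixed precedence
#' power > exponential > hybrid > reciprocal and flagged.
#'
#' @param elicited An [elicited_quantiles()] object.
#' @param v Variance anchor (median per-SNP `V`).
#' @return An object of class `prior_selection`: list with `best` (a
#'   `prior_fit`), `fits` (all four), `table` (per-family tibble of
#'   hyperparameters and ssq) and `tie` flag.
#' @examples
#' sel <- select_prior_family(icogs_elicitation(), v = 0.00017)
#' tidy(sel)
#' @export
select_prior_family <- function(elicited, v) {
  stopifnot(inherits(elicited, "elicited_quantiles"))
  a <- elicited$support$a
  b <- elicited$support$b
  fams <- c("power", "exponential", "hybrid", "reciprocal")
  fits <- lapply(fams, function(f) {
    fit_hyperparameters(f, w = elicited$quantiles$w, p = elicited$quantiles$p,
                        a = a, b = b, v = v)
  })
  names(fits) <- fams
  ssq <- vapply(fits, function(f) f$ssq, numeric(1))
  tied <- ssq <= min(ssq) + 1e-9
  best <- fams[which(tied)[1]] # precedence = declaration order
  tab <- bind_rows(lapply(fits, glance)) |>
    mutate(
      hyperparams = vapply(fits, function(f) {
        if (length(f$hyperparams) == 0) "" else
          paste(sprintf("%s=%.4g", names(f$hyperparams), f$hyperparams),
                collapse = ", ")
      }, character(1)),
      selected = .data$family == best
    )
  structure(
    list(best = fits[[best]], fits = fits, table = tab,
         tie = sum(tied) > 1, elicited = elicited, v = v),
    class = "prior_selection"
  )
}

#' @export
print.prior_selection <- function(x, ...) {
  cat("<prior_selection>\n")
  print(x$table)
  if (x$tie) cat("  note: tie on ssq broken by family precedence\n")
  cat(sprintf("  selected: %s\n", x$best$family))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prior_selection <- function(x, ...) {
  x$table
}

#' @exportS3Method generics::glance
glance.prior_selection <- function(x, ...) {
  glance(x$best) |> mutate(tie = x$tie)
}

#' Feedback quantiles for an elicited prior
#'
#' After fitting, relay back to the expert what the prior implies about
#' quantiles that were not elicited: for each probability, the `W`
#' quantile and the implied upper OR limit
#' `exp(qnorm(p) * sqrt(w_q))` under the central-interval convention.
#'
#' @param spec A [prior_spec()].
#' @param probs Probabilities in `[0, 1]`.
#' @return A tibble with columns `prob`, `w`, `or_upper`.
#' @export
feedback_quantiles <- function(spec, probs) {
  stopifnot(all(probs >= 0 & probs <= 1))
  wq <- prior_quantile(spec, probs)
  tibble(prob = probs, w = wq,
         or_upper = exp(qnorm(probs) * sqrt(wq)))
}
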