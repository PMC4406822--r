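#' Per-SNP univariate logistic association summaries
#'
#' Fits the single-SNP logistic model
#' `logit P(case) = beta0 + beta1 * x`, where `x` counts copies of the
#' minor allele (0/1/2), to every SNP in a genotype dataset and returns the
#' sufficient statistics the Bayes-factor machinery consumes: the MLE
#' `beta` of the per-allele log odds ratio, its standard error `se`, the
#' asymptotic variance `v = se^2`, and the pooled-sample minor allele
#' frequency.
#'
#' The fit is performed on the aggregated genotype-by-status count table
#' (a weighted binomial GLM on at most three design points), which yields
#' exactly the same MLE and observed-information standard error as a
#' subject-level fit. Alleles are always oriented so `beta` is per copy of
#' the minor allele (pooled MAF defines minor), so reported odds ratios may
#' be below 1.
#'
#' Monomorphic SNPs (or SNPs below `min_maf`) are flagged `valid = FALSE`
#' with a warning and excluded from downstream Bayes factors rather than
#' raising an error; non-convergence (e.g. complete separation) is an error
#' naming the SNP.
#'
#' @param data A `genotype_dataset` (as returned by
#'   [simulate_case_control()] or [read_genotypes()]), or a data frame /
#'   matrix of 0/1/2 minor-allele counts with subjects in rows.
#' @param status When `data` is a plain data frame or matrix: a 0/1 case
#'   indicator vector of length `nrow(data)`.
#' @param min_maf SNPs with pooled MAF below this are flagged invalid
#'   (default 0: only monomorphic SNPs are dropped). Property studies of
#'   the priors typically use 0.005, below which there is little power.
#' @return A tibble with columns `snp_id`, `beta`, `se`, `v`, `maf`,
#'   `valid`.
#' @examples
#' scen <- sim_scenario(n_snps = 12, n_cases = 300, n_controls = 300,
#'                      seed = 1)
#' dat <- simulate_case_control(scen)
#' association_summaries(dat)
#' @export
association_summaries <- function(data, status = NULL, min_maf = 0) {
  if (inherits(data, "genotype_dataset")) {
    geno <- data$genotypes
    status <- data$status
    ids <- data$snp_ids
  } else {
    geno <- as.matrix(data)
    if (is.null(status)) abort("supply a 0/1 `status` vector with a genotype matrix")
    ids <- colnames(geno)
    if (is.null(ids)) ids <- sprintf("snp_%04d", seq_len(ncol(geno)))
  }
  check_genotypes(geno, status)
  rows <- lapply(seq_len(ncol(geno)), function(j) {
    fit_snp_counts(geno[, j], status, ids[j], min_maf)
  })
  out <- bind_rows(rows)
  n_bad <- sum(!out$valid)
  if (n_bad > 0) {
    warn(sprintf(
      "%d SNP(s) monomorphic or below min_maf = %g; flagged invalid and excluded downstream",
      n_bad, min_maf
    ))
  }
  out
}

#' Fit the univariate logistic model for one SNP
#'
#' Single-SNP version of [association_summaries()]; returns a one-row
#' tibble.
#'
#' @inheritParams association_summaries
#' @param snp_index Column index of the SNP to fit.
#' @export
fit_univariate_logistic <- function(data, snp_index, status = NULL) {
  if (inherits(data, "genotype_dataset")) {
    geno <- data$genotypes
    status <- data$status
    ids <- data$snp_ids
  } else {
    geno <- as.matrix(data)
    if (is.null(status)) abort("supply a 0/1 `status` vector with a genotype matrix")
    ids <- colnames(geno)
    if (is.null(ids)) ids <- sprintf("snp_%04d", seq_len(ncol(geno)))
  }
  check_genotypes(geno, status)
  fit_snp_counts(geno[, snp_index], status, ids[snp_index], min_maf = 0)
}

check_genotypes <- function(geno, status) {
  if (!all(geno %in% c(0, 1, 2))) {
    abort("genotypes must be minor-allele counts in {0, 1, 2}")
  }
  if (!all(status %in% c(0, 1)) || length(status) != nrow(geno)) {
    abort("status must be a 0/1 vector with one entry per subject row")
  }
  if (sum(status == 1) < 1 || sum(status == 0) < 1) {
    abort("need at least one case and one control")
  }
}

# Core fit on the aggregated 2 x 3 genotype-by-status table.
fit_snp_counts <- function(g, status, snp_id, min_maf) {
  maf <- mean(g) / 2
  flipped <- FALSE
  if (maf > 0.5) { # orient to the minor allele
    g <- 2 - g
    maf <- 1 - maf
    flipped <- TRUE
  }
  invalid <- tibble(snp_id = snp_id, beta = NA_real_, se = NA_real_,
                    v = NA_real_, maf = maf, valid = FALSE)
  lev <- sort(unique(g))
  if (maf == 0 || maf < min_maf || length(lev) < 2) {
    return(invalid)
  }
  n_case <- vapply(lev, function(x) sum(g == x & status == 1), numeric(1))
  n_ctrl <- vapply(lev, function(x) sum(g == x & status == 0), numeric(1))
  fit <- suppressWarnings(
    glm(cbind(n_case, n_ctrl) ~ lev, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  beta <- unname(coef(fit)[2])
  if (!fit$converged || is.na(beta) || abs(beta) > 15) {
    abort(sprintf(
      "logistic fit for SNP '%s' did not converge (likely separation)", snp_id
    ))
  }
  se <- sqrt(vcov(fit)[2, 2])
  tibble(snp_id = snp_id, beta = beta, se = se, v = se^2,
         maf = maf, valid = TRUE)
}

#' Wakefield approximate Bayes factor
#'
#' Computes `sqrt(V / (V + W)) * exp(beta^2 * W / (2 V (V + W)))`, the
#' approximate Bayes factor for a single SNP under a `N(0, W)` prior on the
#' log odds ratio, using the asymptotic normality of the MLE. This is
#' oriented so that values greater than 1 favour association (the
#' reciprocal of Wakefield's original convention).
#'
#' @param beta MLE of the per-allele log odds ratio.
#' @param v Asymptotic variance of `beta` (squared standard error), `> 0`.
#' @param w Prior variance of the log odds ratio, `> 0`.
#' @return Bayes factor(s), vectorized over the inputs.
#' @examples
#' wakefield_bf(beta = 0.1, v = 0.003, w = 0.1)
#' @export
wakefield_bf <- function(beta, v, w) {
  exp(log_wakefield_bf(beta, v, w))
}

#' @rdname wakefield_bf
#' @export
log_wakefield_bf <- function(beta, v, w) {
  if (any(w <= 0)) abort("prior variance w must be > 0")
  if (any(v <= 0)) abort("asymptotic variance v must be > 0")
  0.5 * (log(v) - log(v + w)) + beta^2 * w / (2 * v * (v + w))
}

#' Update prior odds of association with a Bayes factor
#'
#' Posterior odds = `(delta / (1 - delta)) * bf`, where `delta` is the
#' prior probability that the SNP is truly (causally) associated.
#'
#' @param prior_prob Prior probability `delta` of association, in (0, 1).
#' @param bf Bayes factor, `> 0`.
#' @return Posterior odds of association.
#' @examples
#' posterior_odds(0.01, 100)
#' @export
posterior_odds <- function(prior_prob, bf) {
  if (any(prior_prob <= 0 | prior_prob >= 1)) {
    abort("prior_prob must lie strictly inside (0, 1)")
  }
  if (any(bf <= 0)) abort("bf must be > 0")
  prior_prob / (1 - prior_prob) * bf
}

#' Read and write per-SNP summary-statistics tables
#'
#' The on-disk format is tab-separated with a header and columns `snp_id`,
#' `beta`, `se`, `maf`; `v` is derived as `se^2` on read.
#'
#' @param path File path.
#' @return `read_summary_stats()` returns a tibble with columns `snp_id`,
#'   `beta`, `se`, `v`, `maf`, `valid`.
#' @export
read_summary_stats <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_id", "beta", "se", "maf")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("summary table %s lacks column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  n_drop <- sum(is.na(df$beta) | is.na(df$se))
  if (n_drop > 0) {
    warn(sprintf("dropping %d row(s) with missing beta/se", n_drop))
    df <- df[!(is.na(df$beta) | is.na(df$se)), ]
  }
  tibble(snp_id = as.character(df$snp_id), beta = df$beta, se = df$se,
         v = df$se^2, maf = df$maf, valid = TRUE)
}

#' @rdname read_summary_stats
#' @param data A summary tibble (columns `snp_id`, `beta`, `se`, `maf`).
#' @export
write_summary_stats <- function(data, path) {
  write.table(data[, c("snp_id", "beta", "se", "maf")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
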