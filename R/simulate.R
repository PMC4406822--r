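#' Define a case-control simulation scenario
#'
#' Describes an LD-structured fine-mapping region with a single causal SNP,
#' mirroring the simulation design used to study Bayes-factor filtering: a
#' dense SNP panel, causal MAF 0.08, per-allele odds ratios around
#' 1.10-1.18, and equal numbers of cases and controls. Haplotypes are
#' generated by a first-order Markov chain along the SNPs, so adjacent-SNP
#' correlation decays geometrically with distance (parametric stand-in for
#' reference-panel LD).
#'
#' @param n_snps Number of SNPs in the region (default 2,871).
#' @param n_cases,n_controls Case and control quotas (default 2,000 each,
#'   i.e. a total sample of 4,000).
#' @param causal_index Position of the causal SNP (default: middle of the
#'   region).
#' @param causal_maf Minor allele frequency of the causal SNP (default
#'   0.08).
#' @param odds_ratio Per-allele odds ratio at the causal SNP (default
#'   1.14).
#' @param ld_decay Correlation between adjacent SNPs' haplotype alleles,
#'   in `[0, 1)` (default 0.9); correlation at lag `L` decays like
#'   `ld_decay^L`.
#' @param maf_range Range from which non-causal SNP allele frequencies are
#'   drawn uniformly (default `c(0.05, 0.5)`).
#' @param baseline_prob Disease probability for a subject with zero copies
#'   of the causal minor allele (default 0.1); sets the logistic
#'   intercept.
#' @param n_haplotypes Size of the simulated haplotype pool that diploid
#'   genotypes are drawn from (default 10,000).
#' @param seed Optional integer seed stored with the scenario; all
#'   simulation randomness flows from it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_snps = 2871, n_cases = 2000, n_controls = 2000,
                         causal_index = ceiling(n_snps / 2),
                         causal_maf = 0.08, odds_ratio = 1.14,
                         ld_decay = 0.9, maf_range = c(0.05, 0.5),
                         baseline_prob = 0.1, n_haplotypes = 10000,
                         seed = NULL) {
  stopifnot(n_snps >= 1, n_cases >= 1, n_controls >= 1,
            causal_index >= 1, causal_index <= n_snps,
            odds_ratio > 0, causal_maf > 0, causal_maf <= 0.5,
            ld_decay >= 0, ld_decay < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            baseline_prob > 0, baseline_prob < 1, n_haplotypes >= 2)
  structure(
    list(n_snps = n_snps, n_cases = n_cases, n_controls = n_controls,
         causal_index = as.integer(causal_index), causal_maf = causal_maf,
         odds_ratio = odds_ratio, ld_decay = ld_decay,
         maf_range = maf_range, baseline_prob = baseline_prob,
         n_haplotypes = n_haplotypes, seed = seed),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %d SNPs, %d cases / %d controls\n  causal SNP %d: MAF %.3g, OR %.3g\n  LD decay %.2g, pool %d haplotypes, baseline risk %.2g\n",
    x$n_snps, x$n_cases, x$n_controls, x$causal_index, x$causal_maf,
    x$odds_ratio, x$ld_decay, x$n_haplotypes, x$baseline_prob
  ))
  invisible(x)
}

#' Simulate an LD-structured haplotype pool
#'
#' Builds binary haplotypes by a first-order Markov chain along SNPs:
#' stationary allele frequencies are drawn from `maf_range` (the causal
#' SNP's frequency is forced to `causal_maf`) and each SNP's allele is
#' correlated `ld_decay` with its left neighbour, producing geometric
#' decay of r^2 with lag. Transition probabilities are clamped to `[0, 1]`
#' when the target correlation is infeasible for a frequency pair.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Optional seed overriding `scenario$seed`.
#' @return A list with `haplotypes` (`n_haplotypes` x `n_snps` 0/1
#'   matrix) and `freqs` (target allele frequencies).
#' @export
simulate_haplotype_pool <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  m <- scenario$n_snps
  n <- scenario$n_haplotypes
  f <- runif(m, scenario$maf_range[1], scenario$maf_range[2])
  f[scenario$causal_index] <- scenario$causal_maf
  rho <- scenario$ld_decay
  H <- matrix(0L, n, m)
  H[, 1] <- rbinom(n, 1, f[1])
  if (m > 1) {
    for (j in 2:m) {
      # conditional mean preserving marginal f[j] and corr rho with SNP j-1;
      # rho is capped at the feasibility bound for the frequency pair so the
      # transition probabilities stay in [0, 1] and marginals stay exact
      # (binary variables with unequal frequencies cannot be arbitrarily
      # correlated)
      sd_prev <- sqrt(f[j - 1] * (1 - f[j - 1]))
      sd_cur <- sqrt(f[j] * (1 - f[j]))
      rho_j <- min(rho,
                   f[j] * sd_prev / (sd_cur * f[j - 1]),
                   (1 - f[j]) * sd_prev / (sd_cur * (1 - f[j - 1])))
      pj <- f[j] + rho_j * sd_cur / sd_prev * (H[, j - 1] - f[j - 1])
      H[, j] <- rbinom(n, 1, pmin(pmax(pj, 0), 1))
    }
  }
  list(haplotypes = H, freqs = f)
}

#' Simulate a case-control genotype dataset
#'
#' Draws diploid genotypes as sums of two haplotypes sampled with
#' replacement from a [simulate_haplotype_pool()], assigns case status
#' from the logistic disease model at the causal SNP
#' (`logit P(case) = qlogis(baseline_prob) + ln(odds_ratio) * x`), and
#' rejection-samples subjects until the exact case and control quotas are
#' met.
#'
#' @inheritParams simulate_haplotype_pool
#' @param pool Optionally a precomputed haplotype pool (to share one pool
#'   across replicate datasets).
#' @param max_batches Safety cap on rejection-sampling rounds.
#' @return An object of class `genotype_dataset`: list with `genotypes`
#'   (subjects x SNPs matrix of 0/1/2 counts, cases first), `status`,
#'   `snp_ids`, `causal_index` and the generating `scenario`.
#' @examples
#' dat <- simulate_case_control(sim_scenario(n_snps = 10, n_cases = 100,
#'                                           n_controls = 100, seed = 7))
#' dim(dat$genotypes)
#' @export
simulate_case_control <- function(scenario, seed = scenario$seed,
                                  pool = NULL, max_batches = 500L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- simulate_haplotype_pool(scenario, seed = NULL)
  H <- pool$haplotypes
  n_pool <- nrow(H)
  beta0 <- qlogis(scenario$baseline_prob)
  beta1 <- log(scenario$odds_ratio)
  need_case <- scenario$n_cases
  need_ctrl <- scenario$n_controls
  batch <- 2L * (need_case + need_ctrl)
  cases <- list()
  ctrls <- list()
  got_case <- 0L
  got_ctrl <- 0L
  for (iter in seq_len(max_batches)) {
    if (got_case >= need_case && got_ctrl >= need_ctrl) break
    i1 <- sample.int(n_pool, batch, replace = TRUE)
    i2 <- sample.int(n_pool, batch, replace = TRUE)
    g <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
    p <- plogis(beta0 + beta1 * g[, scenario$causal_index])
    y <- rbinom(batch, 1, p)
    if (got_case < need_case && any(y == 1)) {
      take <- which(y == 1)[seq_len(min(sum(y == 1), need_case - got_case))]
      cases[[length(cases) + 1]] <- g[take, , drop = FALSE]
      got_case <- got_case + length(take)
    }
    if (got_ctrl < need_ctrl && any(y == 0)) {
      take <- which(y == 0)[seq_len(min(sum(y == 0), need_ctrl - got_ctrl))]
      ctrls[[length(ctrls) + 1]] <- g[take, , drop = FALSE]
      got_ctrl <- got_ctrl + length(take)
    }
  }
  if (got_case < need_case || got_ctrl < need_ctrl) {
    abort(sprintf(
      "case/control quota not met after %d batches (disease probability pathologically extreme?)",
      max_batches
    ))
  }
  geno <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
  storage.mode(geno) <- "integer"
  colnames(geno) <- sprintf("snp_%04d", seq_len(scenario$n_snps))
  structure(
    list(genotypes = geno,
         status = rep(c(1L, 0L), c(need_case, need_ctrl)),
         snp_ids = colnames(geno),
         causal_index = scenario$causal_index,
         scenario = scenario),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d subjects (%d cases) x %d SNPs; causal SNP %d\n",
    nrow(x$genotypes), sum(x$status), ncol(x$genotypes), x$causal_index
  ))
  invisible(x)
}

#' Read and write genotype datasets
#'
#' Tab-separated subjects x SNPs matrix of 0/1/2 minor-allele counts with
#' a leading `status` column of 0/1 case indicators. `write_genotypes()`
#' also emits a `<path>.truth` sidecar with the causal index and true OR
#' when the dataset came from a simulation.
#'
#' @param path File path.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, sep = "\t")
  if (!"status" %in% names(df)) {
    abort(sprintf("genotype file %s lacks the `status` column", path))
  }
  status <- as.integer(df$status)
  geno <- as.matrix(df[, setdiff(names(df), "status"), drop = FALSE])
  storage.mode(geno) <- "integer"
  check_genotypes(geno, status)
  structure(
    list(genotypes = geno, status = status, snp_ids = colnames(geno),
         causal_index = NA_integer_, scenario = NULL),
    class = "genotype_dataset"
  )
}

#' @rdname read_genotypes
#' @param status Per-subject 0/1 case indicators, in the sample order of
#'   the VCF columns (VCF carries no phenotype).
#' @export
read_genotypes_vcf <- function(path, status) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # hard genotypes only: count ALT alleles from GT strings like 0/1, 1|1
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  geno <- t(counts)
  if (anyNA(geno)) abort("missing or non-hard GT calls in VCF")
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  status <- as.integer(status)
  check_genotypes(geno, status)
  structure(
    list(genotypes = geno, status = status, snp_ids = colnames(geno),
         causal_index = NA_integer_, scenario = NULL),
    class = "genotype_dataset"
  )
}

#' @rdname read_genotypes
#' @param data A `genotype_dataset`.
#' @export
write_genotypes <- function(data, path) {
  stopifnot(inherits(data, "genotype_dataset"))
  df <- data.frame(status = data$status, data$genotypes)
  names(df) <- c("status", data$snp_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.na(data$causal_index)) {
    truth <- data.frame(
      causal_index = data$causal_index,
      causal_snp = data$snp_ids[data$causal_index],
      odds_ratio = if (is.null(data$scenario)) NA_real_ else data$scenario$odds_ratio
    )
    write.table(truth, paste0(path, ".truth"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
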