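# Config-driven workflows and their serialization contracts.

write_yaml_config <- function(cfg) {
  tf <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  yaml::write_yaml(cfg, tf)
  tf
}

icogs_config <- function(out_dir) {
  list(
    prior = list(elicitation = list(
      ref_percentile = 0.8, pi_u_min = 1.05, pi_u_max = 1.3, v = 0.00017,
      quantiles = list(list(z = 95, pi_u = 1.43),
                       list(z = 75, pi_u = 1.21),
                       list(z = 50, pi_u = 1.14))
    )),
    output = out_dir
  )
}

test_that("configs load from both JSON and YAML", {
  cfg <- list(seed = 7, prior = list(family = "power", a = 0.003, b = 0.1,
                                     k = -1.66, v = 0.00017))
  tj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tj, auto_unbox = TRUE, digits = NA)
  ty <- write_yaml_config(cfg)
  expect_equal(read_run_config(tj), read_run_config(ty))
  expect_error(read_run_config(withr::local_tempfile(fileext = ".txt")),
               "not found")
})

test_that("the elicitation workflow reports the expected family and spec", {
  out <- withr::local_tempdir()
  sel <- run_elicitation_workflow(icogs_config(out), verbose = FALSE)
  expect_identical(sel$best$family, "power")
  expect_true(file.exists(file.path(out, "prior_fits.tsv")))
  spec <- as_prior_spec(jsonlite::read_json(
    file.path(out, "selected_prior.json"), simplifyVector = TRUE))
  expect_identical(spec$family, "power")
  fits <- utils::read.delim(file.path(out, "prior_fits.tsv"))
  expect_identical(nrow(fits), 4L)
  # missing ref-percentile bounds demand explicit support inputs
  bad <- icogs_config(withr::local_tempdir())
  bad$prior$elicitation$pi_u_min <- NULL
  expect_error(run_elicitation_workflow(bad, verbose = FALSE), "pi_u_min")
})

test_that("the BF workflow ranks a toy table like hand-computed Wakefield BFs", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(snp_id = c("s1", "s2", "s3"),
                        beta = c(0.02, 0.10, 0.05),
                        se = c(0.02, 0.02, 0.02),
                        maf = c(0.3, 0.2, 0.1))
  write_summary_stats(tab, tf)
  out <- withr::local_tempfile(fileext = ".tsv")
  cfg <- list(input = tf,
              prior = list(family = "power", a = 0.003, b = 0.1, k = -5,
                           v = 4e-4),
              output = out)
  res <- run_bf_workflow(cfg, verbose = FALSE)
  # with mass near W = a the ordering must match hand-computed WBF(a)
  hand <- wbf_oracle(tab$beta, tab$se^2, 0.003)
  expect_identical(res$snp_id, tab$snp_id[order(-hand)])
  written <- utils::read.delim(out)
  expect_identical(written$snp_id, res$snp_id)
  expect_true(all(c("wbf_at_a", "wbf_at_b", "bf_display") %in% names(written)))
  # an empty prior block is an error, not a default prior
  expect_error(run_bf_workflow(list(input = tf, prior = list()),
                               verbose = FALSE), "prior block")
  # overwrite guard
  expect_error(run_bf_workflow(cfg, verbose = FALSE), "exists")
  # byte-identical rerun under force
  before <- readLines(out)
  run_bf_workflow(cfg, force = TRUE, verbose = FALSE)
  expect_identical(readLines(out), before)
})

test_that("a serialized prior reloaded by the BF workflow gives identical BFs", {
  out <- withr::local_tempdir()
  sel <- run_elicitation_workflow(icogs_config(out), verbose = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tibble::tibble(snp_id = c("s1", "s2"),
                                     beta = c(0.047, 0.02),
                                     se = c(0.011, 0.02),
                                     maf = c(0.29, 0.1)), tf)
  res1 <- run_bf_workflow(list(input = tf,
                               prior = file.path(out, "selected_prior.json")),
                          verbose = FALSE)
  res2 <- novel_bf(read_summary_stats(tf), sel$best$spec) |>
    dplyr::arrange(rank)
  # identical up to the JSON text representation of the spec (15
  # significant digits)
  expect_equal(res1$bf, res2$bf, tolerance = 1e-12)
})

test_that("simulate and evaluate workflows connect end to end", {
  gdir <- withr::local_tempdir()
  gpath <- file.path(gdir, "geno.tsv")
  cfg <- list(scenario = list(n_snps = 12, n_cases = 60, n_controls = 60,
                              causal_index = 6),
              seed = 17, output = gpath)
  dat <- run_simulate_workflow(cfg, verbose = FALSE)
  expect_true(file.exists(gpath) && file.exists(paste0(gpath, ".truth")))
  dat2 <- run_simulate_workflow(c(cfg, force = TRUE), verbose = FALSE)
  expect_identical(dat$genotypes, dat2$genotypes)

  sdir <- withr::local_tempdir()
  set.seed(3)
  for (r in 1:4) {
    sc <- tibble::tibble(snp_id = sprintf("snp_%04d", 1:12),
                         score = runif(12))
    sc$score[6] <- 2 # causal SNP on top
    write.table(sc, file.path(sdir, sprintf("rep%d.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(causal_index = 6, causal_snp = "snp_0006"),
                file.path(sdir, sprintf("rep%d.tsv.truth", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  odir <- withr::local_tempdir()
  ev <- run_evaluate_workflow(list(scores_dir = sdir, output = odir,
                                   fpr_levels = c(0.2, 0.5)),
                              verbose = FALSE)
  expect_equal(ev$tpr$tpr, c(1, 1))
  expect_true(file.exists(file.path(odir, "tpr_at_fpr.tsv")))
  expect_true(file.exists(file.path(odir, "roc_points.tsv")))
})

test_that("the command-line entry point script is shipped", {
  cli <- system.file("cli", "priorbf.R", package = "priorbf")
  expect_true(nzchar(cli) && file.exists(cli))
})
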