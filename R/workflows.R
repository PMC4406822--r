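#' Read a workflow configuration file
#'
#' A single JSON or YAML file (chosen by extension) driving the
#' command-line workflows. Recognized blocks: `prior` (either a serialized
#' [prior_spec()] or an `elicitation` block with `ref_percentile`,
#' `pi_u_min`, `pi_u_max` and a list of `{z, pi_u}` quantiles), `scenario`
#' (see [sim_scenario()]), input/output paths, `seed` and `force`.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    abort(sprintf("unsupported config extension '%s' (use json or yaml)", ext))
  )
  cfg
}

check_outfile <- function(path, force = FALSE) {
  if (file.exists(path) && !isTRUE(force)) {
    abort(sprintf("output %s exists; pass force = TRUE (or --force) to overwrite", path))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  path
}

workflow_log <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

# md5 of the canonical JSON form of a config, so reruns are attributable
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

log_run_header <- function(verbose, config, what) {
  workflow_log(verbose, "%s workflow | priorbf %s | config %s", what,
               as.character(utils::packageVersion("priorbf")),
               config_hash(config))
}

#' Run the elicitation workflow
#'
#' Reads the elicitation block of a config, fits all four prior families,
#' writes the per-family sum-of-squares table, the selected serialized
#' [prior_spec()] (reusable by the Bayes-factor workflow) and feedback
#' quantiles.
#'
#' The variance anchor is taken from `config$prior$elicitation$v`, or
#' computed as the median per-SNP `V` from `config$input` (a summary-stats
#' table) when present; one of the two must be available.
#'
#' @param config A config list ([read_run_config()]) or a path to one.
#' @param out_dir Output directory (default `config$output` or `"."`).
#' @param force Overwrite existing outputs.
#' @param verbose Log progress messages.
#' @return The [select_prior_family()] result, invisibly.
#' @export
run_elicitation_workflow <- function(config, out_dir = NULL, force = FALSE,
                                     verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  force <- isTRUE(force) || isTRUE(config$force)
  log_run_header(verbose, config, "fit-prior")
  el <- config$prior$elicitation
  if (is.null(el)) abort("config lacks a prior$elicitation block")
  if (is.null(el$pi_u_min) || is.null(el$pi_u_max)) {
    abort("elicitation block must give ref-percentile OR bounds pi_u_min and pi_u_max (they define a and b)")
  }
  q <- as.data.frame(do.call(rbind, lapply(el$quantiles, as.data.frame)))
  eq <- elicited_quantiles(
    z = q$z, pi_u = q$pi_u,
    pi_u_min = el$pi_u_min, pi_u_max = el$pi_u_max,
    ref_percentile = el$ref_percentile %||% 0.8
  )
  v <- el$v
  if (is.null(v)) {
    if (is.null(config$input)) {
      abort("supply elicitation$v or an input summary table to derive the median V")
    }
    summ <- read_summary_stats(config$input)
    v <- stats::median(summ$v)
    workflow_log(verbose, "anchor V = median per-SNP V = %g from %s", v, config$input)
  }
  sel <- select_prior_family(eq, v = v)
  out_dir <- out_dir %||% config$output %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab_path <- check_outfile(file.path(out_dir, "prior_fits.tsv"), force)
  write.table(tidy(sel), tab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  spec_path <- check_outfile(file.path(out_dir, "selected_prior.json"), force)
  jsonlite::write_json(prior_spec_to_list(sel$best$spec), spec_path,
                       auto_unbox = TRUE, digits = NA)
  fb_path <- check_outfile(file.path(out_dir, "feedback_quantiles.tsv"), force)
  write.table(feedback_quantiles(sel$best$spec, c(0.05, 0.25, 0.5, 0.75, 0.95)),
              fb_path, sep = "\t", quote = FALSE, row.names = FALSE)
  workflow_log(verbose, "selected %s prior (ssq = %.3g); spec written to %s",
               sel$best$family, sel$best$ssq, spec_path)
  invisible(sel)
}

#' Run the Bayes-factor ranking workflow
#'
#' Loads per-SNP summaries (or computes them from a genotype matrix,
#' logging the median `V`), constructs the prior from the config's prior
#' block (a serialized spec, a path to one, or an elicitation block — an
#' empty prior block is an error, never a silent default), computes the
#' prior-averaged Bayes factors, and writes a ranked table that also
#' carries fixed-W Wakefield BFs at `W = a` and `W = b` for comparison.
#'
#' @param config Config list or path. Keys: `input` (summary TSV) or
#'   `genotypes` (genotype TSV), `prior`, `output` (file path), `force`,
#'   `seed`.
#' @param force,verbose See [run_elicitation_workflow()].
#' @return The ranked tibble, invisibly.
#' @export
run_bf_workflow <- function(config, force = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  force <- isTRUE(force) || isTRUE(config$force)
  log_run_header(verbose, config, "bf")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(config$input)) {
    summ <- read_summary_stats(config$input)
  } else if (!is.null(config$genotypes)) {
    dat <- read_genotypes(config$genotypes)
    summ <- association_summaries(dat)
    workflow_log(verbose, "median per-SNP V = %g over %d SNPs",
                 stats::median(summ$v, na.rm = TRUE), nrow(summ))
  } else {
    abort("config needs an `input` summary table or a `genotypes` matrix")
  }
  pr <- config$prior
  if (is.null(pr) || length(pr) == 0) {
    abort("prior block is empty: specify a prior (there is no default)")
  }
  spec <- if (is.character(pr)) {
    as_prior_spec(jsonlite::read_json(pr, simplifyVector = TRUE))
  } else if (!is.null(pr$elicitation)) {
    run_elicitation_workflow(config, out_dir = tempfile("elic"),
                             force = TRUE, verbose = verbose)$best$spec
  } else {
    as_prior_spec(pr)
  }
  res <- novel_bf(summ, spec)
  res$wbf_at_a <- ifelse(res$valid, wakefield_bf(res$beta, res$v, spec$a), NA_real_)
  res$wbf_at_b <- ifelse(res$valid, wakefield_bf(res$beta, res$v, spec$b), NA_real_)
  res <- arrange(res, .data$rank)
  # display-rounded column alongside full precision, so printed-precision
  # comparisons are explicit
  res$bf_display <- signif(res$bf, 4)
  if (!is.null(config$output)) {
    out <- check_outfile(config$output, force)
    if (!"se" %in% names(res)) res$se <- sqrt(res$v)
    if (!"maf" %in% names(res)) res$maf <- NA_real_
    write.table(
      res[, c("snp_id", "beta", "se", "maf", "bf", "log10_bf", "rank",
              "method", "wbf_at_a", "wbf_at_b", "bf_display")],
      out, sep = "\t", quote = FALSE, row.names = FALSE
    )
    workflow_log(verbose, "ranked BF table for %d SNPs written to %s",
                 nrow(res), out)
  }
  invisible(res)
}

#' Run the simulation workflow
#'
#' Builds a [sim_scenario()] from the config's scenario block, simulates a
#' case-control dataset, and writes the genotype matrix plus a truth
#' sidecar (causal index and true OR).
#'
#' @param config Config list or path. Keys: `scenario` (fields of
#'   [sim_scenario()]), `output` (genotype TSV path), `seed`, `force`.
#' @param force,verbose See [run_elicitation_workflow()].
#' @return The `genotype_dataset`, invisibly.
#' @export
run_simulate_workflow <- function(config, force = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  force <- isTRUE(force) || isTRUE(config$force)
  log_run_header(verbose, config, "simulate")
  sc <- do.call(sim_scenario, c(config$scenario,
                                if (!is.null(config$seed)) list(seed = config$seed)))
  dat <- simulate_case_control(sc)
  if (!is.null(config$output)) {
    check_outfile(config$output, force)
    write_genotypes(dat, config$output)
    workflow_log(verbose, "simulated %d x %d genotypes written to %s (+ .truth)",
                 nrow(dat$genotypes), ncol(dat$genotypes), config$output)
  }
  invisible(dat)
}

#' Run the filter-evaluation workflow
#'
#' Reads a directory of replicate score tables (tab-separated `snp_id`,
#' `score`) with `.truth` sidecars naming each replicate's causal SNP,
#' then writes a TPR-at-FPR table and threshold-averaged ROC points.
#'
#' @param config Config list or path. Keys: `scores_dir`, `fpr_levels`,
#'   `output` (directory), `force`.
#' @param force,verbose See [run_elicitation_workflow()].
#' @return A list with `tpr` and `roc` tibbles, invisibly.
#' @export
run_evaluate_workflow <- function(config, force = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  force <- isTRUE(force) || isTRUE(config$force)
  log_run_header(verbose, config, "evaluate")
  if (is.null(config$scores_dir)) abort("config needs scores_dir")
  files <- list.files(config$scores_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no .tsv score tables in %s", config$scores_dir))
  long <- bind_rows(lapply(seq_along(files), function(i) {
    df <- read.delim(files[i])
    truth_path <- paste0(files[i], ".truth")
    if (!file.exists(truth_path)) {
      abort(sprintf("missing truth sidecar for %s", files[i]))
    }
    truth <- read.delim(truth_path)
    tibble(replicate = i, snp_id = as.character(df$snp_id),
           score = df$score,
           is_causal = df$snp_id %in% truth$causal_snp)
  }))
  fprs <- config$fpr_levels %||% c(0.01, 0.05, 0.10, 0.15, 0.20)
  tpr <- tpr_at_fpr(long, score, is_causal, replicate, fpr_levels = fprs)
  roc <- threshold_averaged_roc(long, score, is_causal, replicate)
  out_dir <- config$output %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(tpr, check_outfile(file.path(out_dir, "tpr_at_fpr.tsv"), force),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(roc[, c("fpr", "tpr")],
              check_outfile(file.path(out_dir, "roc_points.tsv"), force),
              sep = "\t", quote = FALSE, row.names = FALSE)
  workflow_log(verbose, "evaluated %d replicates; outputs in %s",
               length(files), out_dir)
  invisible(list(tpr = tpr, roc = roc))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
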