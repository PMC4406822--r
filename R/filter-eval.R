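#' Rank SNPs by a filtering statistic
#'
#' Stable ranking for SNP filtering: rank 1 is the best SNP. Bayes factors
#' rank high-to-low (`higher_is_better = TRUE`); P-values rank low-to-high.
#' Tied values share the mean rank. Non-finite statistics are excluded
#' with a warning.
#'
#' @param data A data frame with one row per SNP.
#' @param score Column (tidy-evaluated) holding the statistic.
#' @param higher_is_better `TRUE` for Bayes factors, `FALSE` for P-values.
#' @return The input rows with finite scores, ordered best-first, with a
#'   `rank` column (average ties).
#' @examples
#' rank_snps(tibble::tibble(snp_id = c("a", "b", "c"),
#'                          p = c(0.2, 0.001, 0.2)),
#'           p, higher_is_better = FALSE)
#' @export
rank_snps <- function(data, score, higher_is_better = TRUE) {
  sc <- eval_tidy(enquo(score), data)
  bad <- !is.finite(sc)
  if (any(bad)) {
    warn(sprintf("excluding %d SNP(s) with non-finite statistics", sum(bad)))
    data <- data[!bad, , drop = FALSE]
    sc <- sc[!bad]
  }
  key <- if (higher_is_better) -sc else sc
  data$rank <- rank(key, ties.method = "average")
  data[order(key), , drop = FALSE]
}

# Resolve the long-format replicate columns shared by tpr_at_fpr() and
# threshold_averaged_roc().
eval_replicate_cols <- function(data, score, truth, replicate) {
  sc <- eval_tidy(enquo(score), data)
  tr <- eval_tidy(enquo(truth), data)
  rep_id <- eval_tidy(enquo(replicate), data)
  stopifnot(length(sc) == nrow(data), length(tr) == nrow(data))
  if (is.null(rep_id)) rep_id <- rep(1L, nrow(data))
  keep <- is.finite(sc)
  if (any(!keep)) {
    warn(sprintf("excluding %d row(s) with non-finite scores", sum(!keep)))
  }
  list(score = sc[keep], truth = as.logical(tr)[keep],
       replicate = rep_id[keep])
}

#' True-positive rate at fixed false-positive rates across replicates
#'
#' For each FPR level, each replicate's admission threshold is the most
#' permissive one that still admits at most that fraction of null SNPs
#' (i.e. `floor(level * n_null)` of them, a conservative convention); the
#' TPR at that level is the fraction of true causal SNPs admitted,
#' averaged over replicates. With the single-causal-SNP design this is the
#' fraction of replicates whose causal SNP survives the filter.
#'
#' @param data Long-format results: one row per SNP per replicate.
#' @param score Column with the filtering statistic (higher = stronger
#'   evidence; negate or transform P-values first).
#' @param truth Logical column flagging the true causal SNP(s).
#' @param replicate Column identifying the replicate dataset.
#' @param fpr_levels False-positive rates to evaluate (default
#'   `c(0.01, 0.05, 0.10, 0.15, 0.20)`, the range relevant to
#'   fine-mapping filters).
#' @return A tibble of class `filter_evaluation` with columns `fpr`
#'   (requested level), `achieved_fpr` (mean admitted null fraction, which
#'   can sit below the request when `floor` bites), `tpr`, and
#'   `n_replicates`. A `fpr_unreachable` attribute flags levels where no
#'   threshold admits a nonzero null fraction at or below the request.
#' @export
tpr_at_fpr <- function(data, score, truth, replicate = NULL,
                       fpr_levels = c(0.01, 0.05, 0.10, 0.15, 0.20)) {
  cols <- eval_replicate_cols(data, {{ score }}, {{ truth }}, {{ replicate }})
  stopifnot(all(fpr_levels >= 0 & fpr_levels <= 1))
  reps <- split(seq_along(cols$score), cols$replicate)
  per_level <- lapply(fpr_levels, function(f) {
    stats_r <- vapply(reps, function(ix) {
      s <- cols$score[ix]
      is_pos <- cols$truth[ix]
      null_s <- sort(s[!is_pos], decreasing = TRUE)
      n_null <- length(null_s)
      m <- floor(f * n_null)
      cutoff <- if (m >= n_null) -Inf else null_s[m + 1]
      # admit scores strictly above the first rejected null
      c(tpr = mean(s[is_pos] > cutoff), fpr = if (n_null == 0) 0 else m / n_null)
    }, numeric(2))
    c(tpr = mean(stats_r["tpr", ]), achieved = mean(stats_r["fpr", ]))
  })
  out <- tibble(
    fpr = fpr_levels,
    achieved_fpr = vapply(per_level, `[[`, numeric(1), "achieved"),
    tpr = vapply(per_level, `[[`, numeric(1), "tpr"),
    n_replicates = length(reps)
  )
  unreachable <- fpr_levels > 0 & out$achieved_fpr == 0
  if (any(unreachable)) {
    warn(sprintf(
      "FPR level(s) %s unreachable with this SNP count; nearest achievable level (0) used",
      paste(fpr_levels[unreachable], collapse = ", ")
    ))
  }
  attr(out, "fpr_unreachable") <- fpr_levels[unreachable]
  class(out) <- c("filter_evaluation", class(out))
  out
}

#' Threshold-averaged ROC curve across replicate analyses
#'
#' Pools score thresholds across replicates; at each threshold the
#' per-replicate (FPR, TPR) pairs are averaged, summarising many replicate
#' ROC curves as one (Fawcett's threshold averaging). Endpoints (0, 0) and
#' (1, 1) are always included, and the averaged curve is monotone by
#' construction.
#'
#' @inheritParams tpr_at_fpr
#' @param n_thresholds Maximum number of pooled thresholds; all distinct
#'   scores are used up to this cap, then subsampled evenly by rank
#'   (default 512).
#' @return A tibble of class `roc_points` with columns `threshold`, `fpr`,
#'   `tpr` sorted by FPR.
#' @export
threshold_averaged_roc <- function(data, score, truth, replicate = NULL,
                                   n_thresholds = 512) {
  cols <- eval_replicate_cols(data, {{ score }}, {{ truth }}, {{ replicate }})
  reps <- split(seq_along(cols$score), cols$replicate)
  thr <- sort(unique(cols$score), decreasing = TRUE)
  if (length(thr) > n_thresholds) {
    thr <- thr[unique(round(seq(1, length(thr), length.out = n_thresholds)))]
  }
  fpr_mat <- vapply(reps, function(ix) {
    s <- cols$score[ix]
    null_s <- s[!cols$truth[ix]]
    vapply(thr, function(t) mean(null_s >= t), numeric(1))
  }, numeric(length(thr)))
  tpr_mat <- vapply(reps, function(ix) {
    s <- cols$score[ix]
    pos_s <- s[cols$truth[ix]]
    vapply(thr, function(t) mean(pos_s >= t), numeric(1))
  }, numeric(length(thr)))
  fpr_mat <- matrix(fpr_mat, nrow = length(thr))
  tpr_mat <- matrix(tpr_mat, nrow = length(thr))
  out <- tibble(threshold = c(Inf, thr, -Inf),
                fpr = c(0, rowMeans(fpr_mat), 1),
                tpr = c(0, rowMeans(tpr_mat), 1)) |>
    arrange(.data$fpr, .data$tpr)
  class(out) <- c("roc_points", class(out))
  out
}

#' Area under a threshold-averaged ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) points.
#'
#' @param roc A `roc_points` tibble from [threshold_averaged_roc()].
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Largest vertical gap between two ROC curves
#'
#' Interpolates both curves onto a common FPR grid and returns the sup of
#' `|TPR_1 - TPR_2|`; used to check that a prior-averaged BF "tracks" the
#' fixed-W Wakefield BF whose `W` its prior concentrates on.
#'
#' @param roc1,roc2 `roc_points` tibbles.
#' @param grid_n Number of FPR grid points (default 201).
#' @return Scalar sup distance in `[0, 1]`.
#' @export
roc_sup_distance <- function(roc1, roc2, grid_n = 201) {
  g <- seq(0, 1, length.out = grid_n)
  t1 <- approx(roc1$fpr, roc1$tpr, xout = g, ties = max, rule = 2)$y
  t2 <- approx(roc2$fpr, roc2$tpr, xout = g, ties = max, rule = 2)$y
  max(abs(t1 - t2))
}
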