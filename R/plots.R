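#' Plot a prior density on W
#'
#' Density curve of a [prior_spec()] over its support.
#'
#' @param object A `prior_spec`.
#' @param n Number of grid points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prior_spec <- function(object, n = 400, ...) {
  w <- seq(object$a, object$b, length.out = n)
  df <- tibble(w = w, density = prior_density(object, w))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "W (prior variance of the log odds ratio)",
      y = "density",
      title = sprintf("%s prior on W, support [%g, %g]",
                      object$family, object$a, object$b)
    )
}

#' Compare the four fitted prior families
#'
#' Overlays the fitted distribution functions from a
#' [select_prior_family()] result together with the elicited quantile
#' points, the visual check an elicitor relays back to the expert.
#'
#' @param object A `prior_selection`.
#' @param n Number of grid points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prior_selection <- function(object, n = 300, ...) {
  a <- object$best$spec$a
  b <- object$best$spec$b
  w <- seq(a, b, length.out = n)
  curves <- bind_rows(lapply(names(object$fits), function(f) {
    tibble(family = f, w = w, cdf = prior_cdf(object$fits[[f]]$spec, w))
  }))
  pts <- object$elicited$quantiles
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$w, y = .data$cdf,
                                       colour = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$w, y = .data$p),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::labs(x = "W", y = "F(W)",
                  title = "Fitted prior distribution functions vs elicited quantiles")
}

#' Plot a threshold-averaged ROC curve
#'
#' @param object A `roc_points` tibble from [threshold_averaged_roc()],
#'   or a named list of them (one curve per method).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_points <- function(object, ...) {
  plot_roc(list(roc = object))
}

#' @rdname autoplot.roc_points
#' @param rocs A named list of `roc_points` tibbles.
#' @export
plot_roc <- function(rocs) {
  df <- bind_rows(lapply(names(rocs), function(m) {
    tibble(method = m, fpr = rocs[[m]]$fpr, tpr = rocs[[m]]$tpr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = "Threshold-averaged ROC")
}
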