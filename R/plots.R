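#' Plot a benchmark scan
#'
#' One panel per metric: per-condition mean with +/- SEM error bars over the
#' condition axis (bias-to-variation ratio or reference precision). For the
#' closeness proportion a dashed line marks 0.5, the equal-performance
#' level.
#'
#' @param object An `ng_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ng_benchmark <- function(object, ...) {
  axis <- attr(object, "axis")
  xlab <- if (axis == "ratio") {
    "bias-to-variation ratio"
  } else {
    "reference-to-target variation ratio"
  }
  ref <- tibble(
    metric = "closeness_proportion", level = 0.5
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[axis]], y = .data$mean)) +
    ggplot2::geom_hline(
      data = ref, ggplot2::aes(yintercept = .data$level), linetype = "dashed"
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = xlab, y = sprintf("mean ± SEM over resamplings"))
}

#' Plot the gene-count stability curve
#'
#' Theoretical `1 / sqrt(k)` stability of the fitted bias against the
#' empirical across-subset sd from gene subsampling (rescaled to its own
#' first point so both curves are relative).
#'
#' @param object An `ng_stability` from [subsample_stability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ng_stability <- function(object, ...) {
  d <- as_tibble(object)
  d$empirical_rel <- d$empirical_sd /
    (d$empirical_sd[1] / d$theoretical_rel_sd[1])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theoretical_rel_sd)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$empirical_rel)) +
    ggplot2::labs(
      x = "genes used for normalization",
      y = "relative sd of fitted bias"
    )
}

#' Plot fitted replicate factors with uncertainty
#'
#' Per-replicate linear normalization factors `a` with first-order error
#' bars (reduced-form sd of `b`, propagated to the linear scale), faceted by
#' treatment. Factors near 1 indicate little replicate bias.
#'
#' @param object An `ng_norm` from [ng_normalize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ng_norm <- function(object, ...) {
  d <- tidy(object)
  base <- object$fit$base
  d$lo <- base^(d$b - d$sd_b_reduced)
  d$hi <- base^(d$b + d$sd_b_reduced)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$replicate, y = .data$a)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      width = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$treatment)) +
    ggplot2::labs(y = "normalization factor a")
}
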