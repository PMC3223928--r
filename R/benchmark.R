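#' Within-treatment variance reduction achieved by normalization
#'
#' For each treatment, one minus the ratio of the residual sum of squares of
#' log values around their per-gene means after normalization to the same
#' quantity before. Data-driven least-squares normalization can only shrink
#' this residual (the value is >= 0 by the least-squares property);
#' reference-factor normalization carries no such guarantee and the value
#' may be negative. Present cells of `raw` and `normalized` must match.
#'
#' @param raw Long expression table before normalization.
#' @param normalized The same table after normalization.
#' @return A tibble with columns `treatment`, `variance_reduction`.
#' @export
variance_reduction <- function(raw, normalized) {
  raw <- ng_data(raw)
  normalized <- ng_data(normalized)
  key <- function(d) paste(d$treatment, d$replicate, d$gene, sep = "\r")
  raw_p <- raw[!is.na(raw$value), ]
  norm_p <- normalized[!is.na(normalized$value), ]
  if (!setequal(key(raw_p), key(norm_p))) {
    abort("`raw` and `normalized` must cover the same present cells.")
  }
  norm_p <- norm_p[match(key(raw_p), key(norm_p)), ]

  rss <- function(logv, tr, gene) {
    mu <- tapply(logv, paste(tr, gene, sep = "\r"), mean)
    tapply(
      (logv - mu[paste(tr, gene, sep = "\r")])^2, tr,
      sum
    )
  }
  rss_raw <- rss(log(raw_p$value), raw_p$treatment, raw_p$gene)
  rss_norm <- rss(log(norm_p$value), norm_p$treatment, norm_p$gene)
  if (any(rss_raw == 0)) {
    abort(sprintf(
      "Raw residual variance is zero in treatment(s) %s; reduction undefined.",
      paste(names(rss_raw)[rss_raw == 0], collapse = ", ")
    ))
  }
  tibble(
    treatment = names(rss_raw),
    variance_reduction = as.vector(1 - rss_norm[names(rss_raw)] / rss_raw)
  )
}

#' Proportion of normalized points closer to the true mean
#'
#' Head-to-head accuracy of two normalizations of the same cells against
#' known truth: the fraction of cells where method A's normalized log value
#' lies strictly nearer the true mean than method B's; exact ties score 0.5.
#' A value of 0.5 means equal performance. Comparison is on the natural-log
#' scale.
#'
#' @param norm_a,norm_b Two normalized long expression tables covering the
#'   same present cells.
#' @param truth True mean log value(s): a single number applied to every
#'   cell, or a tibble (treatment, replicate, gene, true_log) for cell-wise
#'   truth.
#' @return Scalar proportion in \[0, 1\].
#' @export
closeness_proportion <- function(norm_a, norm_b, truth) {
  norm_a <- ng_data(norm_a)
  norm_b <- ng_data(norm_b)
  a <- norm_a[!is.na(norm_a$value), ]
  b <- norm_b[!is.na(norm_b$value), ]
  key <- function(d) paste(d$treatment, d$replicate, d$gene, sep = "\r")
  if (!setequal(key(a), key(b))) {
    abort("`norm_a` and `norm_b` must cover the same present cells.")
  }
  b <- b[match(key(a), key(b)), ]
  true_log <- if (is.data.frame(truth)) {
    tk <- paste(truth$treatment, truth$replicate, truth$gene, sep = "\r")
    idx <- match(key(a), tk)
    if (anyNA(idx)) abort("`truth` does not cover every present cell.")
    truth$true_log[idx]
  } else {
    stopifnot(is.numeric(truth), length(truth) == 1)
    truth
  }
  da <- abs(log(a$value) - true_log)
  db <- abs(log(b$value) - true_log)
  mean((da < db) + 0.5 * (da == db))
}

#' Benchmark scan over bias-to-variation ratios
#'
#' The central benchmark: for each bias-to-variation ratio, repeatedly (i)
#' simulate an artificial data-set with known truth, (ii) normalize its
#' target genes data-driven (least-squares replicate bias) and by the
#' reference factor, and (iii) score the variance reduction of the
#' data-driven fit and the proportion of its points closer to the true mean
#' than the reference-normalized ones. Per-condition means and standard
#' errors over the re-samplings are returned; the full per-resample records
#' are kept in `attr(, "resamples")` so every summary is recomputable.
#'
#' @param ratios Bias-to-variation ratios to scan (sd of replicate bias over
#'   sd of gene-level noise, natural-log scale).
#' @param config Base simulation design (see [sim_config()]); its `bias_sd`
#'   is overridden per condition, and `n_resamples` sets the re-samplings.
#' @param seed Master seed; per-(condition, resample) seeds are derived from
#'   it, so a scan is fully reproducible.
#' @return A tibble of class `ng_benchmark` with columns `ratio`, `metric`
#'   (`"variance_reduction"` or `"closeness_proportion"`), `mean`, `sem`,
#'   `n`.
#' @examples
#' \donttest{
#' scan <- run_bias_scan(c(0.5, 2), sim_config(n_resamples = 10), seed = 1)
#' }
#' @export
run_bias_scan <- function(ratios = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4),
                          config = sim_config(), seed = 1) {
  stopifnot(all(ratios > 0))
  run_scan(
    axis = "ratio", values = ratios, config = config, seed = seed,
    config_for = function(cfg, v) {
      cfg$bias_sd <- bias_sd_for_ratio(v, cfg$target_cv)
      cfg
    }
  )
}

#' Benchmark scan over reference-factor precision
#'
#' As [run_bias_scan()], but the condition axis is the reference-to-target
#' variation ratio (1 = the reference channel is measured as noisily as a
#' target gene; 0.25 = four-fold more precisely) at a fixed bias level. The
#' default fixed bias-to-variation ratio is 0.75, the midpoint of the range
#' typical of real qPCR data-sets.
#'
#' @param ref_ratios Reference-to-target variation ratios in (0, 1].
#' @param config Base simulation design.
#' @param bias_ratio Fixed bias-to-variation ratio of the scan.
#' @param seed Master seed.
#' @return A tibble of class `ng_benchmark` with condition column
#'   `ref_ratio`.
#' @export
run_precision_scan <- function(ref_ratios = c(1, 0.75, 0.5, 0.33, 0.25, 0.175),
                               config = sim_config(), bias_ratio = 0.75,
                               seed = 1) {
  stopifnot(all(ref_ratios > 0), all(ref_ratios <= 1), bias_ratio > 0)
  config$bias_sd <- bias_sd_for_ratio(bias_ratio, config$target_cv)
  run_scan(
    axis = "ref_ratio", values = ref_ratios, config = config, seed = seed,
    config_for = function(cfg, v) {
      cfg$ref_cv_ratio <- v
      cfg
    }
  )
}

run_scan <- function(axis, values, config, seed, config_for) {
  stopifnot(inherits(config, "ng_simconfig"))
  if (config$n_reference < 1) {
    abort("Benchmark scans need at least one reference channel.")
  }
  records <- purrr::map_dfr(seq_along(values), function(ci) {
    cfg <- config_for(config, values[ci])
    purrr::map_dfr(seq_len(cfg$n_resamples), function(k) {
      sim <- simulate_qpcr(cfg, seed = substream_seed(seed, ci * 1000003 + k))
      sc <- score_resample(sim)
      tibble(
        !!axis := values[ci], resample = k,
        variance_reduction = sc$variance_reduction,
        closeness_proportion = sc$closeness_proportion
      )
    })
  })
  out <- records |>
    tidyr::pivot_longer(
      c("variance_reduction", "closeness_proportion"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data[[axis]], .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "resamples") <- records
  attr(out, "axis") <- axis
  class(out) <- c("ng_benchmark", class(out))
  out
}

# One resample: data-driven vs reference normalization of the target genes.
score_resample <- function(sim) {
  targets <- sim$data[sim$data$gene %in% target_genes(sim), ]
  norm_ng <- apply_normalization(
    targets,
    estimate_bias(build_log_matrix(targets, "T1", min_genes = 1))
  )
  rf <- reference_factor(sim$data, reference_genes(sim))
  norm_ref <- apply_reference_normalization(targets, rf)
  list(
    variance_reduction =
      variance_reduction(targets, norm_ng)$variance_reduction,
    closeness_proportion =
      closeness_proportion(norm_ng, norm_ref, sim$true_mean_log)
  )
}

#' Interpolated crossing of a benchmark metric
#'
#' Scans the per-condition means of one metric along the condition axis and
#' linearly interpolates where they cross `level`. Used to locate the
#' bias-to-variation ratio (or reference precision) at which the two
#' normalization strategies perform equally (closeness proportion 0.5).
#'
#' @param result An `ng_benchmark`.
#' @param level Level to cross (default 0.5).
#' @param metric Metric to scan (default `"closeness_proportion"`).
#' @return Scalar position on the condition axis, or `NA` (with a warning)
#'   if no adjacent pair of conditions brackets `level`.
#' @export
find_crossover <- function(result, level = 0.5,
                           metric = "closeness_proportion") {
  stopifnot(inherits(result, "ng_benchmark"))
  axis <- attr(result, "axis")
  d <- result[result$metric == metric, ]
  d <- d[order(d[[axis]]), ]
  if (nrow(d) < 2) {
    abort("Need at least two conditions to locate a crossing.")
  }
  x <- d[[axis]]
  y <- d$mean
  for (i in seq_len(length(x) - 1)) {
    if ((y[i] - level) * (y[i + 1] - level) <= 0 && y[i] != y[i + 1]) {
      return(x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i]))
    }
  }
  warn(sprintf("No adjacent conditions bracket level %g.", level))
  NA_real_
}

#' Paired signed-rank comparison of two methods
#'
#' Wilcoxon's signed-rank test for paired observations, used to compare the
#' per-replicate (or per-dataset) variance reductions achieved by two
#' normalization strategies. The exact null distribution is used for up to
#' 25 pairs, the continuity-corrected normal approximation above. If every
#' pair is tied the comparison is degenerate: the test statistic carries no
#' information and p = 1 is returned with a warning.
#'
#' @param x,y Equal-length paired samples (at least 5 pairs).
#' @return A tibble with columns `statistic`, `p_value`, `n`, `method`.
#' @export
wilcoxon_compare <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    abort("`x` and `y` must be paired samples of equal length.")
  }
  n <- length(x)
  if (n < 5) abort("Need at least 5 pairs.")
  if (all(x == y)) {
    warn("All paired differences are zero; the comparison is degenerate.")
    return(tibble(
      statistic = 0, p_value = 1, n = n,
      method = "Wilcoxon signed rank (degenerate)"
    ))
  }
  exact <- n <= 25
  ht <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
    method = ht$method
  )
}
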