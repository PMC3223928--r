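#' Per-gene mean log expression
#'
#' The estimated mean log value of each gene across the replicates of one
#' treatment, using present cells only. These means are the anchor from which
#' replicate bias is measured.
#'
#' @param logmat An `ng_logmat` (see [build_log_matrix()]).
#' @return Named numeric vector of per-gene mean log values.
#' @export
gene_means <- function(logmat) {
  stopifnot(inherits(logmat, "ng_logmat"))
  if (any(logmat$M == 0)) {
    abort(sprintf(
      "Gene(s) with no present replicate in treatment '%s': %s.",
      logmat$treatment,
      paste(logmat$genes[logmat$M == 0], collapse = ", ")
    ))
  }
  rowMeans(logmat$logx, na.rm = TRUE)
}

#' Estimate replicate-level bias within one treatment
#'
#' Fits the additive two-way model `log x[i, j] = mu[i] + b[j] + eps` by the
#' closed-form estimator
#' `b[j] = (1 / N[j]) * sum_i (log x[i, j] - mhat[i])`,
#' the mean deviation of replicate `j`'s present genes from their per-gene
#' means. With complete data this is exactly the least-squares solution under
#' the sum-to-zero constraint on `b`; with unbalanced missingness it is the
#' same closed form evaluated over present cells (the gap to the exact
#' unbalanced least-squares fit is small and vanishes for balanced data).
#' The linear-scale normalization factor is `a[j] = base^b[j]`, close to
#' unity unless replicate bias is large.
#'
#' The returned object also carries the pooled residual standard deviation
#' (see [pooled_sigma()]) and the first-order standard deviation of each
#' fitted bias in both the full and the reduced `sigma / sqrt(N[j])` form
#' (see [bias_sd()]); these are `NA` when residual degrees of freedom are
#' exhausted.
#'
#' @param logmat An `ng_logmat`.
#' @return An object of class `ng_bias` with elements `treatment`,
#'   `replicates`, `b` (log-scale bias), `a` (linear factors, `base^b`),
#'   `gene_means`, `sigma_log`, `sd_b_full`, `sd_b_reduced`, `N`, `M`,
#'   `base`, `df`.
#' @examples
#' m <- as_log_matrix(matrix(c(1, 1.2, 1.5, 1.7), 2, 2), base = 10)
#' estimate_bias(m)
#' @export
estimate_bias <- function(logmat) {
  stopifnot(inherits(logmat, "ng_logmat"))
  if (any(logmat$N == 0)) {
    abort(sprintf(
      "Replicate(s) with no present gene in treatment '%s': %s.",
      logmat$treatment,
      paste(logmat$replicates[logmat$N == 0], collapse = ", ")
    ))
  }
  if (any(logmat$low_n)) {
    warn(sprintf(
      paste0(
        "Treatment '%s': replicate(s) %s have fewer than %d present genes; ",
        "the fitted bias is defined but not stable."
      ),
      logmat$treatment,
      paste(logmat$replicates[logmat$low_n], collapse = ", "),
      logmat$min_genes
    ))
  }
  mhat <- gene_means(logmat)
  dev <- logmat$logx - mhat # recycles mhat down columns
  b <- colMeans(dev, na.rm = TRUE)
  est <- structure(
    list(
      treatment = logmat$treatment,
      replicates = logmat$replicates,
      b = b,
      a = logmat$base^b,
      gene_means = mhat,
      sigma_log = NA_real_,
      sd_b_full = setNames(rep(NA_real_, length(b)), names(b)),
      sd_b_reduced = setNames(rep(NA_real_, length(b)), names(b)),
      N = logmat$N,
      M = logmat$M,
      base = logmat$base,
      df = residual_df(logmat)
    ),
    class = "ng_bias"
  )
  if (est$df > 0) {
    est$sigma_log <- pooled_sigma(logmat, est)
    present <- !is.na(logmat$logx)
    est$sd_b_full <- vapply(
      seq_along(b),
      function(j) {
        bias_sd(logmat$N[j], logmat$M[present[, j]], est$sigma_log, mode = "full")
      },
      numeric(1)
    )
    est$sd_b_reduced <- vapply(
      seq_along(b),
      function(j) bias_sd(logmat$N[j], sigma = est$sigma_log, mode = "reduced"),
      numeric(1)
    )
    names(est$sd_b_full) <- names(est$sd_b_reduced) <- names(b)
  }
  est
}

residual_df <- function(logmat) {
  sum(!is.na(logmat$logx)) - length(logmat$genes) - length(logmat$replicates) + 1L
}

#' Pooled residual standard deviation of the bias fit
#'
#' Residual standard deviation of `r[i, j] = log x[i, j] - mhat[i] - b[j]`
#' pooled over all present cells of a treatment, assuming variance
#' homogeneity on the log scale (equal relative error of the measurements).
#' Degrees of freedom are `present cells - n - m + 1`, the residual df of
#' the additive two-way model.
#'
#' @param logmat An `ng_logmat`.
#' @param est The matching `ng_bias` from [estimate_bias()].
#' @return Scalar residual sd in `base`-log units.
#' @export
pooled_sigma <- function(logmat, est) {
  stopifnot(inherits(logmat, "ng_logmat"), inherits(est, "ng_bias"))
  df <- residual_df(logmat)
  if (df <= 0) {
    abort(sprintf(
      paste0(
        "Treatment '%s': %d present cells cannot support the %d model ",
        "parameters; residual sd is undefined (df = %d)."
      ),
      logmat$treatment, sum(!is.na(logmat$logx)),
      length(logmat$genes) + length(logmat$replicates) - 1L, df
    ))
  }
  resid <- sweep(logmat$logx - est$gene_means, 2, est$b)
  sqrt(sum(resid^2, na.rm = TRUE) / df)
}

#' First-order standard deviation of a fitted replicate bias
#'
#' Uncertainty of the fitted log-scale bias `b[j]` of a replicate with
#' `n_genes` present genes. The reduced form is `sigma / sqrt(n_genes)`,
#' valid when each gene is observed in many replicates (the product
#' `N[j] * M[i]` dominates `N[j]`). The full form,
#' `sigma * sqrt((1 / n_genes) * (1 - 1 / Mbar))` with `Mbar` the harmonic
#' mean of the per-gene replicate counts `M[i]` over the genes present in the
#' replicate, is the exact least-squares variance in the balanced case and
#' converges to the reduced form as `Mbar` grows. The full form is never
#' larger than the reduced form.
#'
#' @param n_genes Number of genes present in the replicate (`N[j]`).
#' @param m_counts Per-gene replicate counts `M[i]` for the genes present in
#'   the replicate (required for `mode = "full"`).
#' @param sigma Pooled residual sd from [pooled_sigma()].
#' @param mode `"reduced"` (canonical reported form) or `"full"`.
#' @return Scalar sd of `b[j]`, same log units as `sigma`.
#' @examples
#' bias_sd(4, sigma = 0.05) # 0.025: four genes halve the single-gene sd
#' bias_sd(8, m_counts = rep(4, 8), sigma = 0.05, mode = "full")
#' @export
bias_sd <- function(n_genes, m_counts = NULL, sigma,
                    mode = c("reduced", "full")) {
  mode <- match.arg(mode)
  stopifnot(length(n_genes) == 1, length(sigma) == 1)
  if (is.na(n_genes) || n_genes < 1) {
    abort("`n_genes` must be at least 1 (degenerate replicate).")
  }
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (mode == "reduced") {
    return(sigma / sqrt(n_genes))
  }
  if (is.null(m_counts) || length(m_counts) == 0) {
    abort("`mode = \"full\"` needs the per-gene replicate counts `m_counts`.")
  }
  if (any(m_counts < 1)) abort("All `m_counts` must be at least 1.")
  mbar <- length(m_counts) / sum(1 / m_counts)
  sigma * sqrt((1 / n_genes) * (1 - 1 / mbar))
}

#' Divide out fitted replicate bias
#'
#' Applies per-replicate normalization factors to a dataset:
#' `value' = value / a[j]` within each (treatment, replicate), equivalently
#' `log value' = log value - b[j]`. Because the factor is replicate-specific
#' it applies to every gene of the replicate, so no replicate is lost to a
#' single missing cell; missing cells stay missing.
#'
#' @param data A long expression table (see [ng_data()]).
#' @param estimates An `ng_fit` (from [ng_normalize()]), a single `ng_bias`,
#'   or a list of `ng_bias` objects covering every treatment in `data`.
#' @return Normalized long tibble of the same shape as `data`.
#' @export
apply_normalization <- function(data, estimates) {
  data <- ng_data(data)
  ests <- as_bias_list(estimates)
  key_a <- unlist(unname(lapply(ests, function(e) {
    setNames(e$a, paste(e$treatment, e$replicates, sep = "\r"))
  })))
  key <- paste(data$treatment, data$replicate, sep = "\r")
  idx <- match(key, names(key_a))
  no_est <- !is.na(data$value) & is.na(idx)
  if (any(no_est)) {
    i <- which(no_est)[1]
    abort(sprintf(
      "No bias estimate for treatment '%s', replicate '%s'.",
      data$treatment[i], data$replicate[i]
    ))
  }
  data$value <- data$value / unname(key_a[idx])
  data
}

as_bias_list <- function(estimates) {
  if (inherits(estimates, "ng_bias")) {
    estimates <- list(estimates)
  } else if (inherits(estimates, "ng_fit")) {
    estimates <- estimates$estimates
  }
  if (!is.list(estimates) || !all(vapply(estimates, inherits, TRUE, "ng_bias"))) {
    abort("`estimates` must be an ng_fit, an ng_bias, or a list of ng_bias.")
  }
  estimates
}

#' Data-driven normalization of a qPCR dataset
#'
#' The main entry point: for every treatment independently (no between
#' treatment relations are used, so differential expression is untouched),
#' builds the log grid, estimates the replicate bias by least squares with
#' its first-order uncertainty, and divides the fitted linear factors out of
#' the data. Treatments are processed in order of first appearance.
#'
#' @inheritParams build_log_matrix
#' @return An object of class `ng_norm` with elements:
#'   * `data` — the normalized long tibble;
#'   * `fit` — an `ng_fit` holding one `ng_bias` per treatment; inspect it
#'     with [tidy()] (per-replicate factors and sds) and [glance()]
#'     (per-treatment pooled sd and dimensions).
#' @examples
#' d <- ng_data(expand.grid(
#'   treatment = "ctrl", replicate = c("r1", "r2"),
#'   gene = paste0("g", 1:2), value = 10, stringsAsFactors = FALSE
#' ))
#' fitted <- ng_normalize(d)
#' tidy(fitted)
#' @export
ng_normalize <- function(data, base = 10, min_genes = 5) {
  data <- ng_data(data)
  if (nrow(data) == 0 || all(is.na(data$value))) {
    abort("Cannot normalize an empty dataset.")
  }
  treatments <- unique(data$treatment)
  estimates <- lapply(treatments, function(tr) {
    tryCatch(
      estimate_bias(build_log_matrix(data, tr, base = base, min_genes = min_genes)),
      error = function(e) {
        abort(sprintf("Treatment '%s': %s", tr, conditionMessage(e)))
      }
    )
  })
  names(estimates) <- treatments
  fit <- structure(list(estimates = estimates, base = base), class = "ng_fit")
  structure(
    list(data = apply_normalization(data, fit), fit = fit),
    class = "ng_norm"
  )
}

#' @export
print.ng_bias <- function(x, ...) {
  cat(sprintf(
    "<ng_bias> treatment '%s' (log base %g, sigma_log = %s, df = %d)\n",
    x$treatment, x$base,
    if (is.na(x$sigma_log)) "NA" else format(x$sigma_log, digits = 4), x$df
  ))
  print(tibble(
    replicate = x$replicates, N = unname(x$N), b = unname(x$b),
    a = unname(x$a), sd_b = unname(x$sd_b_reduced)
  ))
  invisible(x)
}

#' @export
print.ng_norm <- function(x, ...) {
  cat(sprintf(
    "<ng_norm> %d treatment(s), %d records normalized\n",
    length(x$fit$estimates), nrow(x$data)
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy per-replicate bias report
#'
#' One row per (treatment, replicate): present-gene count, log-scale bias
#' `b`, linear factor `a`, and the reduced and full first-order sds of `b`.
#' This is the canonical normalization report.
#'
#' @param x An `ng_norm` or `ng_fit`.
#' @param ... Unused.
#' @return A tibble with columns `treatment`, `replicate`, `n_genes`, `b`,
#'   `a`, `sd_b_reduced`, `sd_b_full`.
#' @export
tidy.ng_fit <- function(x, ...) {
  purrr::map_dfr(x$estimates, function(e) {
    tibble(
      treatment = e$treatment,
      replicate = e$replicates,
      n_genes = unname(e$N),
      b = unname(e$b),
      a = unname(e$a),
      sd_b_reduced = unname(e$sd_b_reduced),
      sd_b_full = unname(e$sd_b_full)
    )
  })
}

#' @rdname tidy.ng_fit
#' @export
tidy.ng_norm <- function(x, ...) tidy(x$fit, ...)

#' Per-treatment fit summary
#'
#' One row per treatment: panel dimensions, present-cell count, pooled
#' residual sd on the log scale, and its degrees of freedom.
#'
#' @param x An `ng_norm` or `ng_fit`.
#' @param ... Unused.
#' @return A tibble with columns `treatment`, `n_genes`, `n_replicates`,
#'   `n_present`, `sigma_log`, `df`.
#' @export
glance.ng_fit <- function(x, ...) {
  purrr::map_dfr(x$estimates, function(e) {
    tibble(
      treatment = e$treatment,
      n_genes = length(e$gene_means),
      n_replicates = length(e$replicates),
      n_present = sum(e$N),
      sigma_log = e$sigma_log,
      df = e$df
    )
  })
}

#' @rdname glance.ng_fit
#' @export
glance.ng_norm <- function(x, ...) glance(x$fit, ...)
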