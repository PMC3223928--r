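#' Theoretical stability of the fitted bias versus panel size
#'
#' Relative standard deviation of the fitted replicate bias when `n_genes`
#' genes contribute, normalized to the single-gene case: `1 / sqrt(n_genes)`
#' (the reduced first-order form). The curve halves just past four genes —
#' the basis for recommending panels of five or more target genes.
#'
#' @param n_genes Integer vector of gene counts, all at least 1.
#' @return Numeric vector of relative sds (1 at `n_genes = 1`).
#' @examples
#' theoretical_rel_sd(c(1, 4, 5))
#' @export
theoretical_rel_sd <- function(n_genes) {
  if (length(n_genes) == 0 || any(is.na(n_genes)) ||
    any(n_genes < 1) || any(n_genes != floor(n_genes))) {
    abort("`n_genes` must be whole numbers >= 1.")
  }
  1 / sqrt(n_genes)
}

#' Smallest panel size reaching a stability threshold
#'
#' The smallest number of genes for which the theoretical relative sd of the
#' fitted bias drops strictly below `threshold` times its single-gene value.
#' At the default threshold of one half the answer is five genes.
#'
#' @param threshold Relative-sd threshold in (0, Inf); default 0.5.
#' @return Integer gene count.
#' @examples
#' min_genes_for_halving() # 5
#' @export
min_genes_for_halving <- function(threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  as.integer(floor(1 / threshold^2)) + 1L
}

#' Theoretical stability curve over a range of panel sizes
#'
#' @param gene_counts Integer vector of panel sizes.
#' @return A tibble with columns `k` and `rel_sd`.
#' @export
stability_curve <- function(gene_counts = 1:12) {
  tibble(k = as.integer(gene_counts), rel_sd = theoretical_rel_sd(gene_counts))
}

#' Empirical stability of normalization under gene subsampling
#'
#' Re-estimates the replicate bias of one treatment on random `k`-gene
#' subsets (drawn uniformly without replacement) and summarizes, per `k`,
#' how stable the fitted bias is across subsets. For data conforming to the
#' additive model the across-subset sd shrinks like `sqrt(1/k - 1/n)` —
#' the `1 / sqrt(k)` law of [theoretical_rel_sd()] carrying the
#' finite-panel correction of sampling from a fixed set of `n` genes, so it
#' vanishes exactly when every gene is used. Per-replicate means and sds
#' are computed first and then averaged across replicates.
#'
#' @param data A long expression table.
#' @param k Integer vector of subset sizes, each at most the number of genes.
#' @param draws Number of random subsets per `k` (default 3).
#' @param treatment Treatment to analyze; defaults to the only one present.
#' @param seed Optional integer seed for reproducible subset draws.
#' @param base Log base for the bias estimates.
#' @return A tibble of class `ng_stability` with one row per `k`:
#'   `k`, `theoretical_rel_sd`, `empirical_mean`, `empirical_sd`, `draws`.
#'   The across-subset statistics of each replicate's fitted `b` are kept in
#'   `attr(, "by_replicate")`.
#' @export
subsample_stability <- function(data, k, draws = 3, treatment = NULL,
                                seed = NULL, base = 10) {
  data <- ng_data(data)
  if (is.null(treatment)) {
    treatments <- unique(data$treatment)
    if (length(treatments) != 1) {
      abort("`treatment` must be given when the dataset has several treatments.")
    }
    treatment <- treatments
  }
  stopifnot(draws >= 1)
  lm_full <- build_log_matrix(data, treatment, base = base, min_genes = 1)
  n_total <- length(lm_full$genes)
  if (any(k < 1) || any(k > n_total)) {
    abort(sprintf("`k` must lie in 1..%d (the number of genes).", n_total))
  }
  if (!is.null(seed)) set.seed(seed)

  detail <- purrr::map_dfr(sort(unique(as.integer(k))), function(kk) {
    bs <- vapply(seq_len(draws), function(d) {
      idx <- sample.int(n_total, kk)
      sub <- new_log_matrix(
        lm_full$logx[idx, , drop = FALSE],
        base = base, treatment = treatment, min_genes = 1
      )
      estimate_bias(sub)$b
    }, numeric(length(lm_full$replicates)))
    bs <- matrix(bs, nrow = length(lm_full$replicates)) # replicates x draws
    tibble(
      k = kk,
      replicate = lm_full$replicates,
      mean_b = rowMeans(bs),
      sd_b = apply(bs, 1, sd)
    )
  })

  out <- detail |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      empirical_mean = mean(.data$mean_b),
      empirical_sd = mean(.data$sd_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      theoretical_rel_sd = theoretical_rel_sd(.data$k),
      draws = as.integer(draws),
      .after = "k"
    )
  attr(out, "by_replicate") <- detail
  class(out) <- c("ng_stability", class(out))
  out
}
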