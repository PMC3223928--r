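#' Build one treatment's log-expression grid
#'
#' Normalization operates per treatment on the genes-by-replicates grid of
#' log-transformed expression. The grid carries a missing-data mask and the
#' two bookkeeping counts the estimator needs: `N[j]`, the number of genes
#' recorded for replicate `j`, and `M[i]`, the number of replicates with data
#' for gene `i`. Replicates with fewer than `min_genes` present genes are
#' flagged (`low_n`): the fit is still defined there, but its precision
#' degrades as sigma/sqrt(N).
#'
#' @param data A long expression table (see [ng_data()]).
#' @param treatment Label of the treatment to extract.
#' @param base Logarithm base for the transform (default 10, the qPCR
#'   convention). Normalized output is base-invariant; only the scale of the
#'   reported log-bias depends on it.
#' @param min_genes Minimum number of present genes per replicate below which
#'   the replicate is flagged as unstable (default 5).
#' @return An object of class `ng_logmat`: list with `treatment`, `genes`,
#'   `replicates`, `logx` (genes x replicates matrix, `NA` = missing), `N`,
#'   `M`, `base`, `min_genes`, `low_n`.
#' @examples
#' d <- ng_data(expand.grid(
#'   treatment = "ctrl", replicate = c("r1", "r2"),
#'   gene = c("g1", "g2"), value = 10, stringsAsFactors = FALSE
#' ))
#' build_log_matrix(d, "ctrl")
#' @export
build_log_matrix <- function(data, treatment, base = 10, min_genes = 5) {
  data <- ng_data(data)
  stopifnot(is.character(treatment) || is.factor(treatment), length(treatment) == 1)
  treatment <- as.character(treatment)
  if (!treatment %in% data$treatment) {
    abort(sprintf("Treatment '%s' not found in the dataset.", treatment))
  }
  d <- data[data$treatment == treatment & !is.na(data$value), , drop = FALSE]
  genes <- unique(data$gene[data$treatment == treatment])
  replicates <- unique(data$replicate[data$treatment == treatment])
  logx <- matrix(
    NA_real_, length(genes), length(replicates),
    dimnames = list(genes, replicates)
  )
  logx[cbind(match(d$gene, genes), match(d$replicate, replicates))] <-
    log(d$value, base = base)
  new_log_matrix(logx, base = base, treatment = treatment, min_genes = min_genes)
}

#' Wrap an existing log-expression matrix
#'
#' Convenience constructor for users who already hold one treatment's data as
#' a genes-by-replicates matrix of log values (`NA` = missing cell).
#'
#' @param logx Numeric matrix, genes in rows, replicates in columns.
#' @inheritParams build_log_matrix
#' @return An `ng_logmat` (see [build_log_matrix()]).
#' @export
as_log_matrix <- function(logx, base = 10, treatment = "T1", min_genes = 5) {
  stopifnot(is.matrix(logx), is.numeric(logx))
  if (is.null(rownames(logx))) {
    rownames(logx) <- paste0("g", seq_len(nrow(logx)))
  }
  if (is.null(colnames(logx))) {
    colnames(logx) <- paste0("r", seq_len(ncol(logx)))
  }
  new_log_matrix(logx, base = base, treatment = treatment, min_genes = min_genes)
}

new_log_matrix <- function(logx, base, treatment, min_genes) {
  stopifnot(base > 0, base != 1, min_genes >= 1)
  present <- !is.na(logx)
  N <- colSums(present)
  M <- rowSums(present)
  structure(
    list(
      treatment = treatment,
      genes = rownames(logx),
      replicates = colnames(logx),
      logx = logx,
      N = N,
      M = M,
      base = base,
      min_genes = min_genes,
      low_n = N < min_genes
    ),
    class = "ng_logmat"
  )
}

#' @export
print.ng_logmat <- function(x, ...) {
  cat(sprintf(
    "<ng_logmat> treatment '%s': %d genes x %d replicates (base %g), %d missing cell(s)\n",
    x$treatment, length(x$genes), length(x$replicates), x$base,
    sum(is.na(x$logx))
  ))
  cat("  N (genes per replicate):", paste(x$N, collapse = ", "), "\n")
  if (any(x$low_n)) {
    cat(
      "  replicates below the", x$min_genes, "gene stability minimum:",
      paste(x$replicates[x$low_n], collapse = ", "), "\n"
    )
  }
  invisible(x)
}
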