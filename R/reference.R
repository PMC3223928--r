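#' Reference-gene normalization factor
#'
#' The classical baseline: per (treatment, replicate), the geometric mean of
#' the present reference-gene values (a single reference gene reduces to its
#' own value). A replicate with no present reference value cannot be
#' normalized this way at all — it is flagged `lost` rather than silently
#' dropped, because losing whole biological replicates to one missing
#' reference well is the structural weakness of this strategy.
#'
#' @param data A long expression table (see [ng_data()]).
#' @param ref_genes Character vector of reference gene labels.
#' @return A tibble of class `ng_ref` with one row per (treatment,
#'   replicate): `factor` (linear scale), `n_ref` (reference values used),
#'   `lost` (no reference data). Reference gene labels are kept in
#'   `attr(, "ref_genes")`.
#' @examples
#' d <- ng_data(data.frame(
#'   treatment = "ctrl", replicate = "r1",
#'   gene = c("ref1", "ref2", "tg1"), value = c(1, 100, 5)
#' ))
#' reference_factor(d, c("ref1", "ref2")) # geometric mean 10
#' @export
reference_factor <- function(data, ref_genes) {
  data <- ng_data(data)
  stopifnot(is.character(ref_genes), length(ref_genes) >= 1)
  unknown <- setdiff(ref_genes, unique(data$gene))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Reference gene(s) not in the dataset: %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  out <- data |>
    dplyr::mutate(is_ref = .data$gene %in% ref_genes & !is.na(.data$value)) |>
    dplyr::group_by(.data$treatment, .data$replicate) |>
    dplyr::summarise(
      factor = exp(mean(log(.data$value[.data$is_ref]))),
      n_ref = sum(.data$is_ref),
      .groups = "drop"
    ) |>
    dplyr::mutate(lost = .data$n_ref == 0)
  out$factor[out$lost] <- NA_real_
  attr(out, "ref_genes") <- ref_genes
  class(out) <- c("ng_ref", class(out))
  out
}

#' Normalize by a reference factor
#'
#' Divides every value of a replicate by that replicate's reference factor.
#' Replicates flagged `lost` (no reference measurement) are removed from the
#' output with a warning, faithfully reproducing how reference-gene
#' normalization discards whole replicates — the data-driven alternative
#' ([ng_normalize()]) keeps them.
#'
#' @param data A long expression table.
#' @param rf An `ng_ref` from [reference_factor()].
#' @return Normalized long tibble; lost replicates are absent.
#' @export
apply_reference_normalization <- function(data, rf) {
  data <- ng_data(data)
  if (!inherits(rf, "ng_ref")) {
    abort("`rf` must come from reference_factor().")
  }
  key_rf <- setNames(rf$factor, paste(rf$treatment, rf$replicate, sep = "\r"))
  key <- paste(data$treatment, data$replicate, sep = "\r")
  idx <- match(key, names(key_rf))
  no_factor <- !is.na(data$value) & is.na(idx)
  if (any(no_factor)) {
    i <- which(no_factor)[1]
    abort(sprintf(
      "No reference factor for treatment '%s', replicate '%s'.",
      data$treatment[i], data$replicate[i]
    ))
  }
  f <- unname(key_rf[idx])
  lost <- !is.na(idx) & is.na(f)
  if (any(lost)) {
    lost_labs <- unique(paste0(data$treatment[lost], "/", data$replicate[lost]))
    warn(sprintf(
      "Dropping %d replicate(s) with no reference measurement: %s.",
      length(lost_labs), paste(lost_labs, collapse = ", ")
    ))
  }
  data$value <- data$value / f
  data[!lost, , drop = FALSE]
}
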