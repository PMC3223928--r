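# Builders for in-code fixtures; no data files are shipped.

# Long tibble from a genes x replicates matrix of linear-scale values
# (NA = missing cell).
long_from_matrix <- function(values, treatment = "A") {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("r", seq_len(ncol(values)))
  }
  tibble::tibble(
    treatment = treatment,
    replicate = rep(colnames(values), each = nrow(values)),
    gene = rep(rownames(values), times = ncol(values)),
    value = as.vector(values)
  )
}

long_from_log <- function(logx, base = 10, treatment = "A") {
  long_from_matrix(base^logx, treatment = treatment)
}

# Two replicates one decade apart on the linear scale: the fitted factors
# must be 10^(-1/2) and 10^(+1/2).
decade_data <- function() {
  long_from_matrix(cbind(r1 = c(10, 20), r2 = c(100, 200)))
}

# Exact least-squares replicate effects of the additive two-way model under
# the sum-to-zero constraint, via lm() with sum contrasts (independent of
# the package's closed form).
ls_bias_oracle <- function(logx) {
  d <- data.frame(
    y = as.vector(logx),
    gene = factor(rep(seq_len(nrow(logx)), times = ncol(logx))),
    rep = factor(rep(seq_len(ncol(logx)), each = nrow(logx)))
  )
  d <- d[!is.na(d$y), ]
  fit <- stats::lm(y ~ gene + rep, data = d, contrasts = list(rep = "contr.sum"))
  co <- stats::coef(fit)
  head_effects <- unname(co[grep("^rep", names(co))])
  c(head_effects, -sum(head_effects))
}

# Random log matrix mu_i + b_j + noise, optionally with missing cells.
random_logmat <- function(n, m, noise_sd = 0.05, bias_sd = 0.1,
                          n_missing = 0, seed = 1) {
  set.seed(seed)
  mu <- rnorm(n, 1, 0.5)
  b <- rnorm(m, 0, bias_sd)
  x <- outer(mu, rep(1, m)) + rep(b, each = n) +
    matrix(rnorm(n * m, 0, noise_sd), n, m)
  if (n_missing > 0) {
    x[sample.int(n * m, n_missing)] <- NA
  }
  x
}
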