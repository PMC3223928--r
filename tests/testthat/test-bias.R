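test_that("gene means average the present log values", {
  x <- rbind(c(1.0, 1.2, NA, 1.4), c(2, 2, 2, 2))
  lmat <- as_log_matrix(x, min_genes = 1)
  expect_equal(unname(gene_means(lmat)), c(1.2, 2))

  # brute-force oracle on a random masked grid
  x <- random_logmat(5, 4, n_missing = 3, seed = 3)
  lmat <- as_log_matrix(x, min_genes = 1)
  oracle <- apply(x, 1, function(row) mean(row[!is.na(row)]))
  expect_equal(unname(gene_means(lmat)), unname(oracle))

  x[2, ] <- NA
  expect_error(gene_means(as_log_matrix(x, min_genes = 1)), "no present replicate")
})

test_that("no bias is fitted to a constant matrix", {
  est <- estimate_bias(as_log_matrix(matrix(1.5, 6, 3), base = 10))
  expect_equal(unname(est$b), rep(0, 3))
  expect_equal(unname(est$a), rep(1, 3))
  expect_equal(est$sigma_log, 0)
})

test_that("a one-decade replicate offset is split symmetrically", {
  lmat <- build_log_matrix(decade_data(), "A", base = 10, min_genes = 2)
  est <- estimate_bias(lmat)
  expect_equal(unname(est$b), c(-0.5, 0.5))
  expect_equal(unname(est$a), c(10^-0.5, 10^0.5))
})

test_that("the closed form is the constrained least-squares fit on complete data", {
  for (seed in 1:5) {
    x <- random_logmat(6, 4, seed = seed)
    b <- estimate_bias(as_log_matrix(x))$b
    expect_equal(unname(b), ls_bias_oracle(x), tolerance = 1e-8)
    expect_equal(sum(b), 0, tolerance = 1e-12)
  }
})

test_that("unbalanced missingness opens a small gap to the exact LS fit", {
  x <- random_logmat(6, 4, n_missing = 2, seed = 7)
  b_closed <- estimate_bias(as_log_matrix(x, min_genes = 1))$b
  b_exact <- ls_bias_oracle(x)
  # compare up to the additive location the constraint pins down
  gap <- max(abs((b_closed - mean(b_closed)) - (b_exact - mean(b_exact))))
  expect_lt(gap, 0.02) # small relative to the noise scale, but real
  expect_gt(gap, 1e-12) # the two estimators genuinely differ here

  # and the gap closes for the balanced version of the same data
  x_bal <- random_logmat(6, 4, seed = 7)
  gap_bal <- max(abs(
    estimate_bias(as_log_matrix(x_bal))$b - ls_bias_oracle(x_bal)
  ))
  expect_lt(gap_bal, 1e-8)
})

test_that("pooled sigma is the residual sd of the additive fit", {
  # exact additive data: perfect fit
  x <- outer(rnorm(5), rep(1, 3)) + rep(c(-0.1, 0, 0.1), each = 5)
  lmat <- as_log_matrix(x)
  est <- estimate_bias(lmat)
  expect_equal(pooled_sigma(lmat, est), 0, tolerance = 1e-12)

  # 2 x 2 complete grid has one residual degree of freedom
  x <- matrix(c(1.0, 2.0, 1.3, 2.2), 2, 2)
  lmat <- as_log_matrix(x, min_genes = 1)
  est <- suppressWarnings(estimate_bias(lmat))
  interaction_contrast <- abs(x[1, 1] - x[1, 2] - x[2, 1] + x[2, 2])
  expect_equal(pooled_sigma(lmat, est), interaction_contrast / 2)

  # insufficient data
  one_gene <- as_log_matrix(matrix(1:3, 1, 3), min_genes = 1)
  est1 <- suppressWarnings(estimate_bias(one_gene))
  expect_error(pooled_sigma(one_gene, est1), "undefined")
})

test_that("pooled sigma recovers the simulated noise level", {
  set.seed(11)
  sigmas <- replicate(1000, {
    x <- matrix(rnorm(32, 2, 0.05), 8, 4)
    lmat <- as_log_matrix(x)
    pooled_sigma(lmat, estimate_bias(lmat))
  })
  expect_equal(mean(sigmas), 0.05, tolerance = 0.05)
})

test_that("bias sd follows the reduced and full first-order forms", {
  expect_equal(bias_sd(1, sigma = 0.07), 0.07)
  expect_equal(bias_sd(4, sigma = 0.07), 0.035) # exactly halved at four genes
  expect_equal(bias_sd(5, sigma = 1), 1 / sqrt(5))
  expect_lt(bias_sd(5, sigma = 1), 0.5)

  full <- bias_sd(8, m_counts = rep(4, 8), sigma = 0.05, mode = "full")
  expect_equal(full, 0.05 * sqrt((1 / 8) * (1 - 1 / 4)))

  # full <= reduced, equality in the many-replicate limit
  for (seed in 1:5) {
    set.seed(seed)
    m_counts <- sample(2:6, 8, replace = TRUE)
    expect_lte(
      bias_sd(8, m_counts, sigma = 0.05, mode = "full"),
      bias_sd(8, sigma = 0.05)
    )
  }
  expect_equal(
    bias_sd(8, m_counts = rep(1e9, 8), sigma = 0.05, mode = "full"),
    bias_sd(8, sigma = 0.05),
    tolerance = 1e-6
  )

  expect_error(bias_sd(0, sigma = 0.05), "at least 1")
  expect_error(bias_sd(4, sigma = 0.05, mode = "full"), "m_counts")
})

test_that("the full-form sd matches simulation for the balanced design", {
  set.seed(21)
  sigma <- 0.05
  b_hats <- replicate(4000, {
    x <- matrix(rnorm(32, 0, sigma), 8, 4) # noise only, no true bias
    estimate_bias(as_log_matrix(x))$b[1]
  })
  expect_equal(
    sd(b_hats),
    bias_sd(8, m_counts = rep(4, 8), sigma = sigma, mode = "full"),
    tolerance = 0.05
  )
})

test_that("normalization divides the fitted factors out", {
  d <- decade_data()
  res <- suppressWarnings(ng_normalize(d, min_genes = 2))
  wide <- tidyr::pivot_wider(
    res$data,
    names_from = "replicate", values_from = "value"
  )
  expect_equal(wide$r1, wide$r2) # exact bias removal
  # identity factors leave data untouched
  est <- res$fit$estimates$A
  est$a[] <- 1
  expect_equal(apply_normalization(d, est)$value, d$value)
})

test_that("per-gene log means are preserved under complete data", {
  x <- random_logmat(8, 4, seed = 9)
  d <- long_from_log(x)
  res <- ng_normalize(d)
  before <- tapply(log(d$value), d$gene, mean)
  after <- tapply(log(res$data$value), res$data$gene, mean)
  expect_equal(after, before, tolerance = 1e-10)
})

test_that("treatments are normalized independently", {
  x <- random_logmat(8, 4, seed = 13)
  d <- rbind(
    long_from_log(x, treatment = "A"),
    long_from_log(x + 0.7, treatment = "B") # constant-fold shift
  )
  res <- ng_normalize(d)
  ta <- tidy(res)
  expect_equal(
    ta$b[ta$treatment == "A"],
    ta$b[ta$treatment == "B"],
    tolerance = 1e-10
  )
  diff_log <- mean(log(res$data$value[res$data$treatment == "B"], 10)) -
    mean(log(res$data$value[res$data$treatment == "A"], 10))
  expect_equal(diff_log, 0.7, tolerance = 1e-10)
})

test_that("a replicate missing one gene keeps all its other genes", {
  x <- random_logmat(9, 4, seed = 4)
  x[9, 2] <- NA # e.g. the would-be reference gene of replicate 2
  d <- long_from_log(x)
  res <- ng_normalize(d)
  r2 <- res$data[res$data$replicate == "r2" & !is.na(res$data$value), ]
  expect_equal(nrow(r2), 8) # everything else survives
  expect_error(ng_normalize(d[0, ]), "empty")
})

test_that("normalization never increases the within-treatment residual", {
  for (seed in 1:5) {
    x <- random_logmat(7, 4, bias_sd = 0.2, n_missing = 3, seed = seed)
    d <- long_from_log(x)
    res <- suppressWarnings(ng_normalize(d))
    rss <- function(dd) {
      dd <- dd[!is.na(dd$value), ]
      lv <- log(dd$value)
      mu <- tapply(lv, dd$gene, mean)
      sum((lv - mu[dd$gene])^2)
    }
    expect_lte(rss(res$data), rss(d) + 1e-12)
  }
})

test_that("normalized output does not depend on the log base", {
  x <- random_logmat(6, 4, n_missing = 2, seed = 15)
  d <- long_from_log(x)
  v10 <- suppressWarnings(ng_normalize(d, base = 10))$data$value
  v2 <- suppressWarnings(ng_normalize(d, base = 2))$data$value
  ve <- suppressWarnings(ng_normalize(d, base = exp(1)))$data$value
  expect_equal(v10, v2, tolerance = 1e-12)
  expect_equal(v10, ve, tolerance = 1e-12)
})

test_that("normalizing twice fits zero bias the second time", {
  x <- random_logmat(8, 4, bias_sd = 0.3, seed = 17)
  once <- ng_normalize(long_from_log(x))
  twice <- ng_normalize(once$data)
  expect_equal(unname(twice$fit$estimates$A$b), rep(0, 4), tolerance = 1e-12)
})

test_that("fitted bias tracks the true simulated bias", {
  set.seed(23)
  sigma <- 0.05
  truth <- fitted <- c()
  for (k in 1:40) {
    beta <- rnorm(4, 0, 2 * sigma) # bias-to-variation ratio 2
    x <- matrix(rnorm(32, 1, sigma), 8, 4) + rep(beta, each = 8)
    fitted <- c(fitted, estimate_bias(as_log_matrix(x))$b)
    truth <- c(truth, beta - mean(beta)) # the estimable part of the bias
  }
  expect_gt(cor(fitted, truth), 0.95)
  # RMSE of the fit error matches the theoretical first-order sd
  rmse <- sqrt(mean((fitted - truth)^2))
  expect_equal(
    rmse,
    bias_sd(8, m_counts = rep(4, 8), sigma = sigma, mode = "full"),
    tolerance = 0.15
  )
})

test_that("missing estimates and empty replicates raise errors", {
  d <- decade_data()
  est <- suppressWarnings(estimate_bias(build_log_matrix(d, "A")))
  extra <- d
  extra$replicate[1] <- "r9"
  expect_error(apply_normalization(extra, est), "r9")

  x <- random_logmat(4, 3, seed = 1)
  x[, 2] <- NA
  expect_error(
    estimate_bias(as_log_matrix(x, min_genes = 1)),
    "no present gene"
  )
})
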