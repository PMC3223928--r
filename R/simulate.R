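#' Convert a linear-scale coefficient of variation to a log-scale sd
#'
#' For a lognormal measurement whose linear-scale coefficient of variation is
#' `cv`, the sd of its logarithm is `sqrt(log(1 + cv^2)) / log(base)`. This
#' anchors the simulator's "percent variation" knobs (e.g. the 10% target
#' gene variation) on the log scale where the model lives; at qPCR-typical
#' magnitudes the two readings are nearly interchangeable.
#'
#' @param cv Linear-scale coefficient of variation, in (0, 1).
#' @param base Log base of the result (default natural log).
#' @return Scalar log-scale sd.
#' @examples
#' cv_to_log_sd(0.10) # ~0.0998 natural-log units
#' @export
cv_to_log_sd <- function(cv, base = exp(1)) {
  stopifnot(length(cv) == 1, is.numeric(cv))
  if (is.na(cv) || cv <= 0 || cv >= 1) {
    abort("`cv` must lie strictly between 0 and 1.")
  }
  sqrt(log(1 + cv^2)) / log(base)
}

#' Configuration of the artificial qPCR data generator
#'
#' Defaults reproduce the benchmark design for artificial data-sets: a
#' single treatment of four replicates, eight target genes measured with 10%
#' relative variation, one reference factor of tunable precision, a true log
#' mean of zero (relative expression 1), an experiment-dependent replicate
#' bias drawn fresh for every re-sampling, and 40 re-samplings per
#' condition.
#'
#' @param n_replicates Replicates per treatment (default 4).
#' @param n_target_genes Target genes (default 8).
#' @param n_reference Reference channels (default 1).
#' @param true_mean_log True mean on the natural-log scale (default 0).
#' @param bias_sd Natural-log sd of the replicate-level bias. The default
#'   equals the gene-level noise sd (bias-to-variation ratio 1); see
#'   [bias_sd_for_ratio()].
#' @param target_cv Linear-scale coefficient of variation of target-gene
#'   measurements (default 0.10).
#' @param ref_cv_ratio Reference-to-target variation ratio in (0, 1]
#'   (default 1: the reference is measured no more precisely than a target).
#' @param n_resamples Re-samplings per benchmark condition (default 40).
#' @param seed Optional master seed recorded with the config.
#' @return A validated list of class `ng_simconfig`.
#' @export
sim_config <- function(n_replicates = 4, n_target_genes = 8, n_reference = 1,
                       true_mean_log = 0, bias_sd = NULL, target_cv = 0.10,
                       ref_cv_ratio = 1, n_resamples = 40, seed = NULL) {
  bias_sd <- bias_sd %||% cv_to_log_sd(target_cv)
  stopifnot(
    n_replicates >= 1, n_target_genes >= 1, n_reference >= 0,
    bias_sd >= 0, ref_cv_ratio > 0, n_resamples >= 1
  )
  if (target_cv <= 0 || target_cv >= 1) {
    abort("`target_cv` must lie strictly between 0 and 1.")
  }
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      n_target_genes = as.integer(n_target_genes),
      n_reference = as.integer(n_reference),
      true_mean_log = true_mean_log,
      bias_sd = bias_sd,
      target_cv = target_cv,
      ref_cv_ratio = ref_cv_ratio,
      n_resamples = as.integer(n_resamples),
      seed = seed
    ),
    class = "ng_simconfig"
  )
}

#' Replicate-bias sd giving a requested bias-to-variation ratio
#'
#' The benchmark's condition axis is the ratio of replicate-level bias sd to
#' gene-level noise sd, both on the natural-log scale. This helper converts
#' a requested ratio into the `bias_sd` knob of [sim_config()] given the
#' target-gene coefficient of variation.
#'
#' @param ratio Bias-to-variation ratio, > 0.
#' @param target_cv Linear-scale CV of target genes (default 0.10).
#' @return Natural-log sd of the replicate bias.
#' @export
bias_sd_for_ratio <- function(ratio, target_cv = 0.10) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  ratio * cv_to_log_sd(target_cv)
}

#' Simulate one artificial qPCR data-set with known truth
#'
#' Generation follows two independent steps. Step one draws a replicate-level
#' bias `beta[j] ~ Normal(0, bias_sd)` on the natural-log scale — the
#' experiment-dependent handling/RT bias shared by every gene of a
#' replicate. Step two adds independent gene-level measurement noise: each
#' target cell is `exp(true_mean_log + beta[j] + eps)`,
#' `eps ~ Normal(0, cv_to_log_sd(target_cv))`, and each reference cell uses
#' noise sd scaled by `ref_cv_ratio`. The reference channel is a "perfect"
#' reference — its true mean never varies — so only its measurement
#' precision distinguishes it from a target gene. The two steps consume
#' separate seeded RNG streams derived from `seed`.
#'
#' @param config An `ng_simconfig` (see [sim_config()]).
#' @param seed Integer seed for this draw; falls back to `config$seed`.
#' @return An object of class `ng_sim`: list with
#'   * `data` — long tibble (treatment `"T1"`, replicates `"r1"...`, target
#'     genes `"tg1"...`, reference channels `"ref1"...`);
#'   * `true_bias` — tibble (replicate, true_bias) of the drawn log biases;
#'   * `true_mean_log`, `config`, `seed`.
#' @examples
#' sim <- simulate_qpcr(sim_config(), seed = 1)
#' nrow(sim$data) # 4 replicates x (8 targets + 1 reference) = 36 cells
#' @export
simulate_qpcr <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "ng_simconfig"))
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    abort("A `seed` is required (directly or via the config).")
  }
  m <- config$n_replicates
  nt <- config$n_target_genes
  nr <- config$n_reference
  noise_sd <- cv_to_log_sd(config$target_cv)

  # step 1: experiment-dependent replicate bias (own stream)
  set.seed(substream_seed(seed, 1L))
  beta <- rnorm(m, 0, config$bias_sd)

  # step 2: gene-level measurement variation (own stream)
  set.seed(substream_seed(seed, 2L))
  target_log <- config$true_mean_log + rep(beta, each = nt) +
    rnorm(nt * m, 0, noise_sd)
  ref_log <- if (nr > 0) {
    config$true_mean_log + rep(beta, each = nr) +
      rnorm(nr * m, 0, config$ref_cv_ratio * noise_sd)
  } else {
    numeric(0)
  }

  replicates <- paste0("r", seq_len(m))
  genes <- c(paste0("tg", seq_len(nt)), if (nr > 0) paste0("ref", seq_len(nr)))
  data <- tibble(
    treatment = "T1",
    replicate = rep(replicates, each = nt + nr),
    gene = rep(genes, times = m),
    value = exp(as.numeric(rbind(
      matrix(target_log, nrow = nt),
      matrix(ref_log, nrow = nr)
    )))
  )
  structure(
    list(
      data = data,
      true_bias = tibble(replicate = replicates, true_bias = beta),
      true_mean_log = config$true_mean_log,
      config = config,
      seed = seed
    ),
    class = "ng_sim"
  )
}

# Deterministic 32-bit substream seeds from (master seed, stream index).
substream_seed <- function(seed, stream) {
  (abs(as.numeric(seed)) * 48271 + stream * 16807) %% 2147483647
}

#' Target and reference gene labels of a simulated dataset
#'
#' @param sim An `ng_sim`.
#' @return Character vector of labels.
#' @export
target_genes <- function(sim) {
  stopifnot(inherits(sim, "ng_sim"))
  paste0("tg", seq_len(sim$config$n_target_genes))
}

#' @rdname target_genes
#' @export
reference_genes <- function(sim) {
  stopifnot(inherits(sim, "ng_sim"))
  if (sim$config$n_reference == 0) {
    return(character(0))
  }
  paste0("ref", seq_len(sim$config$n_reference))
}
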