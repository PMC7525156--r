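#' Configuration for the two-sample summary-statistic generator
#'
#' Defines the generative model for synthetic exposure/outcome GWAS summary
#' panels with a known causal effect: per variant `k`, a true exposure
#' effect `x_k` is drawn uniformly from `exposure_effect_range` with random
#' sign; the true outcome effect is `beta_causal * x_k + alpha_k` with
#' pleiotropic shift `alpha_k ~ N(pleiotropy_mean, pleiotropy_sd^2)`
#' expressed per exposure-increasing allele (entering the outcome effect as
#' `sign(x_k) * alpha_k`, so "directional" keeps its meaning regardless of
#' which allele each panel happens to report); observed effects add Gaussian
#' sampling noise with the panel-reported standard errors. All effects live directly on the summary-statistic
#' scales the estimators assume (exposure units; outcome log-odds) — no
#' individual-level simulation.
#'
#' Defaults mirror the magnitudes of the packaged study fixture: exposure
#' effects of 0.015–0.075 trait units per allele (the MAGIC glycemic range)
#' against a large outcome GWAS with per-allele log-odds SEs of 0.005–0.015
#' (OncoArray-like), no exposure measurement error (the NOME regime the IVW
#' weights assume) and no pleiotropy.
#'
#' @param K number of instruments (>= 1).
#' @param beta_causal true causal effect, log-odds per exposure unit.
#' @param exposure_effect_range interval for `|x_k|`; positive.
#' @param se_X_scale exposure-panel standard error (>= 0; 0 = no
#'   measurement error in the exposure associations).
#' @param se_Y_range interval for outcome SEs; strictly positive.
#' @param pleiotropy_mean mean directional pleiotropic effect (log-odds per
#'   allele); nonzero values violate the exclusion restriction on average
#'   and are what the MR-Egger intercept targets.
#' @param pleiotropy_sd spread of balanced pleiotropy around the mean.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(K = 50L, beta_causal = 0,
                       exposure_effect_range = c(0.015, 0.075),
                       se_X_scale = 0, se_Y_range = c(0.005, 0.015),
                       pleiotropy_mean = 0, pleiotropy_sd = 0, seed = 1L) {
  if (K < 1L) stop("configuration error: K must be >= 1", call. = FALSE)
  if (length(exposure_effect_range) != 2L ||
      any(exposure_effect_range <= 0) || diff(exposure_effect_range) < 0)
    stop("configuration error: exposure_effect_range must be a positive interval",
         call. = FALSE)
  if (length(se_Y_range) != 2L || any(se_Y_range <= 0) || diff(se_Y_range) < 0)
    stop("configuration error: se_Y_range must be strictly positive", call. = FALSE)
  if (se_X_scale < 0 || pleiotropy_sd < 0)
    stop("configuration error: scales must be >= 0", call. = FALSE)
  structure(list(K = as.integer(K), beta_causal = beta_causal,
                 exposure_effect_range = exposure_effect_range,
                 se_X_scale = se_X_scale, se_Y_range = se_Y_range,
                 pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.rand_alleles <- function(K) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, K, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a two-sample summary-statistic study
#'
#' Draws one synthetic exposure/outcome panel pair under a [sim_config()]
#' model. Fully reproducible: the same config (including seed) yields an
#' identical study.
#'
#' @param config a [sim_config()].
#' @return list of class `simulated_study`: `exposure` and `outcome`
#'   [assoc_panel()] objects sharing rsids and allele encodings, plus
#'   `truth` (`beta_causal`, `pleiotropy_mean`, per-variant `alpha` on the
#'   exposure-increasing-allele scale, latent `x_true`, `y_true`) and the
#'   `config`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$K
  x_true <- stats::runif(K, config$exposure_effect_range[1],
                         config$exposure_effect_range[2]) *
    sample(c(-1, 1), K, replace = TRUE)
  X_obs <- x_true + if (config$se_X_scale > 0)
    stats::rnorm(K, 0, config$se_X_scale) else 0
  alpha <- config$pleiotropy_mean + if (config$pleiotropy_sd > 0)
    stats::rnorm(K, 0, config$pleiotropy_sd) else 0
  alpha <- rep_len(alpha, K)
  se_Y <- stats::runif(K, config$se_Y_range[1], config$se_Y_range[2])
  # pleiotropy acts per exposure-increasing allele: joint (X, Y) reorientation
  # (as in the Egger fit) must preserve its direction
  y_true <- config$beta_causal * x_true + sign(x_true) * alpha
  Y_obs <- y_true + stats::rnorm(K, 0, se_Y)
  al <- .rand_alleles(K)
  eaf <- stats::runif(K, 0.05, 0.95)
  rsid <- sprintf("rs%07d", seq_len(K))
  chrom <- sample(1:22, K, replace = TRUE)
  pos <- sample.int(1e8, K)
  pval_x <- if (config$se_X_scale > 0)
    2 * stats::pnorm(-abs(X_obs) / config$se_X_scale)
  else rep(.Machine$double.xmin, K)
  exposure <- assoc_panel(data.frame(
    rsid = rsid, chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
    eaf = eaf, beta = X_obs, se = config$se_X_scale, pval = pmax(pval_x, .Machine$double.xmin),
    stringsAsFactors = FALSE), trait = "FG", dataset = "sim-exposure")
  outcome <- assoc_panel(data.frame(
    rsid = rsid, chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
    eaf = eaf, beta = Y_obs, se = se_Y,
    pval = pmax(2 * stats::pnorm(-abs(Y_obs) / se_Y), .Machine$double.xmin),
    stringsAsFactors = FALSE), trait = "BC", dataset = "sim-outcome")
  structure(list(exposure = exposure, outcome = outcome,
                 truth = list(beta_causal = config$beta_causal,
                              pleiotropy_mean = config$pleiotropy_mean,
                              alpha = alpha, x_true = x_true, y_true = y_true),
                 config = config),
            class = "simulated_study")
}

#' Monte-Carlo calibration of the MR estimators
#'
#' Repeatedly simulates studies under one [sim_config()], pushes each
#' through the full harmonize-then-estimate path ([match_instruments()],
#' [mr_ivw()], [mr_egger()], [cochran_q()]) and aggregates estimator
#' performance. Per-replicate seeds are derived from the config seed by one
#' draw of `sample.int(2^31 - 1, n_reps)` under that seed, so any replicate
#' can be regenerated independently.
#'
#' @param config a [sim_config()]; its `seed` is the master seed.
#' @param n_reps number of replicates (>= 100).
#' @param alpha test level for the rejection-rate summaries.
#' @param egger_orient orientation for [mr_egger()] (default TRUE; with
#'   random-sign exposure effects this exercises the orientation step).
#' @return list of class `calibration_summary`: `ivw_bias`, `ivw_rmse`,
#'   `ivw_ci_coverage`, `egger_intercept_rejection_rate`,
#'   `q_rejection_rate`, `median_ivw_se`, plus `n_reps`, `alpha`, `config`.
#'   Under the no-pleiotropy null the two rejection rates are type-I
#'   errors; with `pleiotropy_mean != 0` the Egger rate is power.
#' @export
calibration_experiment <- function(config, n_reps, alpha = 0.05,
                                   egger_orient = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 100L) stop("n_reps must be >= 100", call. = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2147483647L, n_reps)
  est <- se <- numeric(n_reps)
  cover <- egger_rej <- q_rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulate_two_sample(cfg)
    instr <- match_instruments(sim$exposure, sim$outcome,
                               palindrome_policy = "keep")
    fit <- mr_ivw(instr)
    est[i] <- fit$beta
    se[i] <- fit$se
    cover[i] <- fit$ci_low <= config$beta_causal &&
      config$beta_causal <= fit$ci_high
    q_rej[i] <- cochran_q(instr, beta = fit$beta)$pvalue < alpha
    egger_rej[i] <- if (config$K >= 3L)
      mr_egger(instr, orient = egger_orient)$intercept_p < alpha else NA
  }
  structure(list(
    ivw_bias = mean(est) - config$beta_causal,
    ivw_rmse = sqrt(mean((est - config$beta_causal)^2)),
    ivw_ci_coverage = mean(cover),
    egger_intercept_rejection_rate = mean(egger_rej),
    q_rejection_rate = mean(q_rej),
    median_ivw_se = stats::median(se),
    n_reps = n_reps, alpha = alpha, config = config
  ), class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat(sprintf("Calibration over %d replicates (K=%d, beta=%.3g, mu_alpha=%.3g)\n",
              x$n_reps, x$config$K, x$config$beta_causal, x$config$pleiotropy_mean))
  cat(sprintf("  IVW bias %.4g, rmse %.4g, %.0f%% CI coverage %.3f\n",
              x$ivw_bias, x$ivw_rmse, 95, x$ivw_ci_coverage))
  cat(sprintf("  rejection at alpha=%.2f: Egger intercept %.3f, Cochran Q %.3f\n",
              x$alpha, x$egger_intercept_rejection_rate, x$q_rejection_rate))
  invisible(x)
}
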