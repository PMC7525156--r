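.as_instruments <- function(instruments) {
  if (!is.data.frame(instruments) ||
      !all(c("X", "Y", "se_Y") %in% names(instruments)))
    stop("usage error: expected an mr_instruments data frame with columns X, Y, se_Y",
         call. = FALSE)
  if (nrow(instruments) == 0L)
    stop("usage error: empty instrument set", call. = FALSE)
  if (any(instruments$se_Y <= 0))
    stop("usage error: all se_Y must be > 0", call. = FALSE)
  instruments
}

.n_unique_snps <- function(instruments) {
  if ("rsid" %in% names(instruments)) length(unique(instruments$rsid))
  else nrow(instruments)
}

#' Per-variant Wald ratio causal estimate
#'
#' The ratio estimate for one genetic instrument: `theta = Y/X`, with
#' first-order standard error `se_Y/|X|`. Exposure uncertainty is ignored
#' (the no-measurement-error assumption used by the fixed-effect IVW
#' weights). Vectorized.
#'
#' @param X exposure effect(s) per effect allele; must be nonzero.
#' @param Y outcome log-odds effect(s) per effect allele.
#' @param se_Y standard error(s) of `Y`, > 0.
#' @return list with `theta` and `se`.
#' @export
wald_ratio <- function(X, Y, se_Y) {
  if (any(X == 0)) stop("undefined ratio: X = 0", call. = FALSE)
  if (any(se_Y <= 0)) stop("se_Y must be > 0", call. = FALSE)
  list(theta = Y / X, se = se_Y / abs(X))
}

#' Fixed-effect inverse-variance weighted MR estimate
#'
#' Combines per-variant Wald ratios in a fixed-effect meta-analysis:
#' \deqn{\hat\beta_{IVW} = \frac{\sum_k X_k Y_k \sigma_{Yk}^{-2}}
#'                               {\sum_k X_k^2 \sigma_{Yk}^{-2}},\qquad
#'       se(\hat\beta_{IVW}) = \frac{1}{\sqrt{\sum_k X_k^2 \sigma_{Yk}^{-2}}}}
#' equivalently the weighted mean of ratios `Y_k/X_k` with weights
#' `X_k^2 / se_Yk^2`. The p-value is a two-sided normal test of beta = 0.
#'
#' @param instruments an `mr_instruments` data frame (see
#'   [match_instruments()]) or any data frame with columns `X`, `Y`, `se_Y`.
#' @param level confidence level for the interval (default 0.95).
#' @return object of class `mr_result`: log-scale `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, instrument counts, and the exponentiated
#'   (odds-ratio scale) triple under `$or_scale`.
#' @export
mr_ivw <- function(instruments, level = 0.95) {
  s <- .as_instruments(instruments)
  w <- s$X^2 / s$se_Y^2
  beta <- sum(s$X * s$Y / s$se_Y^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(
    beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    n_snps = .n_unique_snps(s), n_rows = nrow(s), level = level,
    or_scale = log_to_or(beta, se, level)
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("IVW MR estimate (%d SNP%s%s)\n", x$n_snps,
              if (x$n_snps > 1) "s" else "",
              if (x$n_rows != x$n_snps) sprintf(", %d rows", x$n_rows) else ""))
  cat(sprintf("  log-odds beta = %.4f (se %.4f), p = %.3g\n", x$beta, x$se, x$pvalue))
  cat(sprintf("  OR = %.3f (%d%% CI %.3f-%.3f)\n", x$or_scale$or_value,
              round(100 * x$level), x$or_scale$ci_low, x$or_scale$ci_high))
  invisible(x)
}

#' Cochran's Q heterogeneity test for MR instruments
#'
#' With per-variant ratios `theta_k = Y_k/X_k` and weights
#' `w_k = X_k^2 / se_Yk^2`, the statistic is
#' `Q = sum_k w_k (theta_k - beta)^2`, referred to a chi-square with K - 1
#' degrees of freedom. Large Q flags heterogeneous instrument-specific
#' effects — a symptom of pleiotropy.
#'
#' @param instruments instrument data frame, K >= 2 rows.
#' @param beta pooled estimate to test against; defaults to the IVW estimate
#'   of `instruments`.
#' @return object of class `mr_het` with `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(instruments, beta = NULL) {
  s <- .as_instruments(instruments)
  if (nrow(s) < 2L) stop("usage error: Cochran's Q needs K >= 2", call. = FALSE)
  if (is.null(beta)) beta <- mr_ivw(s)$beta
  th <- s$Y / s$X
  w <- s$X^2 / s$se_Y^2
  Q <- sum(w * (th - beta)^2)
  df <- nrow(s) - 1L
  structure(list(Q = Q, df = df,
                 pvalue = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "mr_het")
}

#' @export
print.mr_het <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n", x$Q, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects `Y_k` on exposure effects `X_k`
#' with an unconstrained intercept and weights `1/se_Yk^2`. The slope is a
#' pleiotropy-robust causal estimate (under the InSIDE assumption); a
#' nonzero intercept indicates directional horizontal pleiotropy — the
#' average per-allele outcome effect not mediated by the exposure.
#'
#' @param instruments instrument data frame, K >= 3 rows.
#' @param level confidence level.
#' @param orient when TRUE, instruments with negative exposure effect have
#'   `(X, Y)` jointly negated before the fit, so all exposure effects are
#'   positive — the conventional orientation that makes the intercept's sign
#'   interpretable. Joint negation leaves IVW invariant but not Egger.
#' @param intercept_dist reference distribution for intercept (and slope)
#'   tests: `"t"` (default, K - 2 df — materially different from normal at
#'   the small K typical of instrument sets) or `"normal"`.
#' @return object of class `mr_egger_result`: `intercept`, `intercept_se`,
#'   `intercept_ci_low/high`, `intercept_p`, `slope`, `slope_se`, `slope_p`,
#'   `n_snps`, and the exponentiated intercept triple under
#'   `$intercept_or_scale` (per-allele odds-ratio scale).
#' @export
mr_egger <- function(instruments, level = 0.95, orient = TRUE,
                     intercept_dist = c("t", "normal")) {
  intercept_dist <- match.arg(intercept_dist)
  s <- .as_instruments(instruments)
  K <- nrow(s)
  if (K < 3L) stop("usage error: MR-Egger needs K >= 3", call. = FALSE)
  X <- s$X
  Y <- s$Y
  if (orient) {
    neg <- X < 0
    X[neg] <- -X[neg]
    Y[neg] <- -Y[neg]
  }
  if (stats::sd(X) == 0)
    stop("singular design: all exposure effects identical", call. = FALSE)
  fit <- stats::lm(Y ~ X, weights = 1 / s$se_Y^2)
  est <- stats::coef(fit)
  secoef <- sqrt(diag(stats::vcov(fit)))
  tq <- if (intercept_dist == "t") stats::qt((1 + level) / 2, df = K - 2L)
        else stats::qnorm((1 + level) / 2)
  pfun <- function(stat) {
    if (intercept_dist == "t") 2 * stats::pt(-abs(stat), df = K - 2L)
    else 2 * stats::pnorm(-abs(stat))
  }
  ic <- est[[1]]; ic_se <- secoef[[1]]
  sl <- est[[2]]; sl_se <- secoef[[2]]
  structure(list(
    intercept = ic, intercept_se = ic_se,
    intercept_ci_low = ic - tq * ic_se, intercept_ci_high = ic + tq * ic_se,
    intercept_p = pfun(ic / ic_se),
    slope = sl, slope_se = sl_se,
    slope_ci_low = sl - tq * sl_se, slope_ci_high = sl + tq * sl_se,
    slope_p = pfun(sl / sl_se),
    n_snps = .n_unique_snps(s), level = level, orient = orient,
    intercept_dist = intercept_dist,
    intercept_or_scale = list(or_value = exp(ic),
                              ci_low = exp(ic - tq * ic_se),
                              ci_high = exp(ic + tq * ic_se))
  ), class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger regression (%d SNPs, %s intercept test)\n",
              x$n_snps, x$intercept_dist))
  cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g; exp(intercept) = %.3f (%.3f-%.3f)\n",
              x$intercept, x$intercept_se, x$intercept_p,
              x$intercept_or_scale$or_value, x$intercept_or_scale$ci_low,
              x$intercept_or_scale$ci_high))
  cat(sprintf("  slope = %.4f (se %.4f), p = %.3g\n", x$slope, x$slope_se, x$slope_p))
  invisible(x)
}

#' Pool instrument sets across outcome datasets into one IVW estimate
#'
#' Concatenates per-dataset harmonized instrument sets and runs a single
#' fixed-effect IVW. Deduplication policies:
#' \describe{
#'   \item{per_dataset_rows}{every dataset-specific row enters the IVW; an
#'     rsid instrumented in several datasets contributes one row per dataset
#'     (the reported SNP count is unique rsids);}
#'   \item{first_dataset}{an rsid contributes only its first occurrence, in
#'     the order the sets are given;}
#'   \item{none}{plain concatenation, no deduplication.}
#' }
#'
#' @param instrument_sets list of `mr_instruments` data frames (a single
#'   data frame is accepted).
#' @param dedup_policy see above; default `per_dataset_rows`.
#' @param level confidence level.
#' @return an [mr_ivw()] `mr_result`; `n_snps` counts unique rsids.
#' @export
mr_pool <- function(instrument_sets,
                    dedup_policy = c("per_dataset_rows", "first_dataset", "none"),
                    level = 0.95) {
  dedup_policy <- match.arg(dedup_policy)
  if (is.data.frame(instrument_sets)) instrument_sets <- list(instrument_sets)
  if (length(instrument_sets) == 0L ||
      !all(vapply(instrument_sets, function(s) is.data.frame(s) && nrow(s) > 0, logical(1))))
    stop("usage error: need at least one non-empty instrument set", call. = FALSE)
  all_rows <- do.call(rbind, lapply(instrument_sets, as.data.frame))
  rownames(all_rows) <- NULL
  if (dedup_policy == "first_dataset") {
    all_rows <- all_rows[!duplicated(all_rows$rsid), , drop = FALSE]
  } else if (dedup_policy == "per_dataset_rows" &&
             all(c("rsid", "dataset") %in% names(all_rows))) {
    all_rows <- all_rows[!duplicated(all_rows[c("rsid", "dataset")]), , drop = FALSE]
  }
  mr_ivw(all_rows, level = level)
}
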