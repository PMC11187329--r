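# 97.5% normal quantile used for all 95% intervals, fixed so that interval
# arithmetic is reproducible to the precision reported in result tables.
Z975 <- 1.959964

#' Odds-ratio and Wald-p reporting transform
#'
#' Converts a log-odds effect and its standard error into the reporting
#' scale: `OR = exp(beta)`, 95% CI `exp(beta +/- 1.959964*se)`, and the
#' two-sided Wald p-value `2*(1 - pnorm(|beta|/se))`.
#'
#' @param beta effect on the log-odds scale (vectorized).
#' @param se standard error, > 0.
#' @return data.frame with `or_value`, `or_ci_low`, `or_ci_high`, `pval`.
#' @export
to_or <- function(beta, se) {
  stopifnot(all(se > 0))
  data.frame(or_value = exp(beta),
             or_ci_low = exp(beta - Z975 * se),
             or_ci_high = exp(beta + Z975 * se),
             pval = 2 * stats::pnorm(-abs(beta) / se))
}

#' Assemble an MR result row
#'
#' Derives the confidence interval, odds-ratio scale and p-value from the
#' point estimate and its standard error; the p-value uses the standard
#' normal reference unless `df` is given, in which case a t reference with
#' `df` degrees of freedom is used (MR-Egger convention).
#'
#' @param method label, e.g. `"IVW_mre"`.
#' @param n_snps number of instruments behind the estimate.
#' @param beta,se point estimate and standard error.
#' @param df optional degrees of freedom for a t reference.
#' @return one-row data.frame of class `mr_result` with columns `method`,
#'   `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `or_value`, `or_ci_low`,
#'   `or_ci_high`, `pval`.
#' @export
mr_result <- function(method, n_snps, beta, se, df = NULL) {
  stopifnot(se > 0)
  if (is.null(df)) {
    q <- Z975
    pval <- 2 * stats::pnorm(-abs(beta) / se)
  } else {
    q <- stats::qt(0.975, df)
    pval <- 2 * stats::pt(-abs(beta) / se, df)
  }
  ci_low <- beta - q * se
  ci_high <- beta + q * se
  structure(
    data.frame(method = method, n_snps = as.integer(n_snps),
               beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
               or_value = exp(beta), or_ci_low = exp(ci_low),
               or_ci_high = exp(ci_high), pval = pval,
               stringsAsFactors = FALSE),
    class = c("mr_result", "data.frame"))
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect, with the first-order standard error `se_outcome/|beta_exposure|`
#' (exposure-side sampling variance ignored).
#'
#' @param pairs data.frame of harmonized pairs (any number of rows).
#' @return data.frame with `snp_id`, `theta`, `se_theta`.
#' @export
wald_ratio <- function(pairs) {
  if (any(pairs$beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure = 0")
  }
  data.frame(snp_id = pairs$snp_id,
             theta = pairs$beta_outcome / pairs$beta_exposure,
             se_theta = pairs$se_outcome / abs(pairs$beta_exposure),
             stringsAsFactors = FALSE)
}

# IVW internals on raw vectors; no warnings, used by leave-one-out and
# MR-PRESSO where the J = 1 fallback is expected.
ivw_core <- function(bx, by, sy, mode = "mre") {
  theta <- by / bx
  w <- (bx / sy)^2
  beta <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  j <- length(bx)
  if (j >= 2L) {
    q <- sum(w * (theta - beta)^2)
    scale <- if (mode == "mre") sqrt(max(1, q / (j - 1))) else 1
  } else {
    q <- NA_real_
    scale <- 1
  }
  list(beta = beta, se = se_fixed * scale, q = q, j = j)
}

#' Inverse-variance weighted causal estimate
#'
#' Precision-weighted average of per-SNP Wald ratios with first-order
#' weights `1/se_theta^2`. In `"fixed"` mode the standard error is
#' `(sum w)^-1/2`; in `"mre"` (multiplicative random effects, the default)
#' it is inflated by `sqrt(max(1, Q/(J-1)))` where Q is Cochran's Q, so the
#' point estimate is identical between modes and the standard error never
#' shrinks below the fixed-effect one. 95% CI and two-sided p use the
#' standard normal reference.
#'
#' @param pairs data.frame of harmonized pairs (kept/flipped), >= 1 row,
#'   all `beta_exposure` nonzero.
#' @param mode `"mre"` (default) or `"fixed"`. With a single SNP `"mre"`
#'   falls back to the Wald ratio with a warning.
#' @return one-row `mr_result`.
#' @export
ivw <- function(pairs, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  j <- nrow(pairs)
  if (j == 0L) stop("no instruments: cannot run IVW")
  if (any(pairs$beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure = 0")
  }
  if (j == 1L) {
    if (mode == "mre") {
      warning("single instrument: falling back to the Wald ratio",
              call. = FALSE)
    }
    wr <- wald_ratio(pairs)
    return(mr_result("Wald_single", 1L, wr$theta, wr$se_theta))
  }
  fit <- ivw_core(pairs$beta_exposure, pairs$beta_outcome, pairs$se_outcome,
                  mode = mode)
  label <- if (mode == "mre") "IVW_mre" else "IVW_fixed"
  mr_result(label, j, fit$beta, fit$se)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1/se_outcome^2`, after orienting every pair so the
#' exposure beta is non-negative (both betas flipped together, to which the
#' causal estimate is invariant). The slope is the pleiotropy-adjusted
#' causal estimate; the intercept estimates average directional pleiotropy.
#' Standard errors come from the WLS covariance with the residual variance
#' floored at 1 (multiplicative random effects that never deflate below the
#' fixed-effect error); p-values are two-sided from t with J - 2 df.
#'
#' @param pairs data.frame of harmonized pairs, >= 3 rows.
#' @return list with `slope` and `intercept`, each a one-row `mr_result`.
#' @export
mr_egger <- function(pairs) {
  j <- nrow(pairs)
  if (j < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(pairs$beta_exposure)
  flip[flip == 0] <- 1
  bx <- pairs$beta_exposure * flip
  by <- pairs$beta_outcome * flip
  wts <- 1 / pairs$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = wts)
  coefs <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  # se_lm already carries sigma; dividing by min(1, sigma) floors the
  # residual variance at 1
  adj <- 1 / min(1, sigma)
  slope <- mr_result("Egger_slope", j, coefs["bx", "Estimate"],
                     coefs["bx", "Std. Error"] * adj, df = j - 2)
  intercept <- mr_result("Egger_intercept", j, coefs["(Intercept)", "Estimate"],
                         coefs["(Intercept)", "Std. Error"] * adj, df = j - 2)
  list(slope = slope, intercept = intercept)
}
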