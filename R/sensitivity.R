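#' Cochran's Q heterogeneity test across Wald ratios
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` with first-order weights
#' `w_j = 1/se_theta_j^2`, referred to chi-square with J - 1 df. The
#' I-squared statistic, `max(0, (Q - df)/Q) * 100`, is the percentage of
#' variability across ratios attributable to heterogeneity rather than
#' sampling error.
#'
#' @param pairs data.frame of harmonized pairs, >= 2 rows.
#' @return list with `q`, `df`, `pval`, `i2` (percent in [0, 100]).
#' @export
cochran_q <- function(pairs) {
  j <- nrow(pairs)
  if (j < 2L) stop("Cochran's Q requires at least 2 instruments")
  fit <- ivw_core(pairs$beta_exposure, pairs$beta_outcome, pairs$se_outcome)
  q <- fit$q
  df <- j - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, df = df,
       pval = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = i2)
}

#' Egger intercept test for directional pleiotropy
#'
#' The intercept row of [mr_egger()] with a significance flag at
#' `alpha`: a nonzero intercept indicates average directional pleiotropy
#' across the instruments.
#'
#' @param pairs data.frame of harmonized pairs, >= 3 rows.
#' @param alpha significance level for the flag (default 0.05).
#' @return one-row `mr_result` with an extra `significant` column.
#' @export
egger_intercept_test <- function(pairs, alpha = 0.05) {
  res <- mr_egger(pairs)$intercept
  res$significant <- res$pval < alpha
  res
}

# Leave-one-out IVW point estimates for all SNPs at once, from sums.
loo_estimates <- function(bx, by, sy) {
  theta <- by / bx
  w <- (bx / sy)^2
  (sum(w * theta) - w * theta) / (sum(w) - w)
}

#' MR-PRESSO global, outlier, and distortion tests
#'
#' Detects horizontal pleiotropy by comparing the observed weighted residual
#' sum of squares with its parametric-simulation distribution. For each SNP
#' j the leave-one-out IVW estimate gives the residual
#' `r_j = beta_Yj - theta_(-j) * beta_Xj`; `RSS_obs = sum r_j^2 / se_Yj^2`.
#' Each of `n_sim` replicates redraws `beta*_Xj ~ N(beta_Xj, se_Xj)` and
#' `beta*_Yj ~ N(theta_(-j) * beta_Xj, se_Yj)` and recomputes the RSS with
#' fresh leave-one-out estimates; the global p-value is
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`. The outlier test compares each
#' observed squared residual with its simulated counterparts and applies a
#' Bonferroni correction over the J SNPs. When outliers are found, the
#' outlier-corrected IVW estimate is computed on the remaining SNPs and the
#' distortion p-value locates the observed shift `beta_raw - beta_corrected`
#' in the distribution of shifts obtained by removing random subsets of the
#' same size.
#'
#' @param pairs data.frame of harmonized pairs, >= 4 rows.
#' @param n_sim number of parametric simulations (>= 100; default 1000).
#' @param outlier_significance level for the Bonferroni-adjusted per-SNP
#'   outlier test (default 0.05).
#' @param seed optional integer seed for the simulations.
#' @return list with `rss_obs`, `global_pval`, `outlier_pvals` (named,
#'   Bonferroni-adjusted), `outliers` (SNP ids), `beta_raw`,
#'   `beta_corrected` (`NA` when no outliers), `distortion_pval` (`NA` when
#'   no outliers), `n_sim`.
#' @export
mr_presso <- function(pairs, n_sim = 1000L, outlier_significance = 0.05,
                      seed = NULL) {
  j <- nrow(pairs)
  if (j < 4L) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 100L) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  bx <- pairs$beta_exposure; sx <- pairs$se_exposure
  by <- pairs$beta_outcome; sy <- pairs$se_outcome

  theta_loo <- loo_estimates(bx, by, sy)
  r_obs <- by - theta_loo * bx
  rss_obs <- sum((r_obs / sy)^2)

  # parametric simulation, vectorized J x n_sim
  bx_sim <- matrix(stats::rnorm(j * n_sim, mean = bx, sd = sx), nrow = j)
  by_sim <- matrix(stats::rnorm(j * n_sim, mean = theta_loo * bx, sd = sy),
                   nrow = j)
  w_sim <- (bx_sim / sy)^2
  wt_sim <- bx_sim * by_sim / sy^2          # w * theta
  loo_sim <- (rep(colSums(wt_sim), each = j) - wt_sim) /
             (rep(colSums(w_sim), each = j) - w_sim)
  r_sim <- by_sim - loo_sim * bx_sim
  rss_sim <- colSums((r_sim / sy)^2)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_out <- (1 + rowSums(r_sim^2 >= r_obs^2)) / (n_sim + 1)
  p_adj <- pmin(1, p_out * j)
  names(p_adj) <- pairs$snp_id
  outliers <- pairs$snp_id[p_adj < outlier_significance]

  beta_raw <- ivw_core(bx, by, sy)$beta
  beta_corrected <- NA_real_
  distortion_pval <- NA_real_
  n_out <- length(outliers)
  if (n_out > 0L && n_out < j) {
    keep <- !(pairs$snp_id %in% outliers)
    beta_corrected <- ivw_core(bx[keep], by[keep], sy[keep])$beta
    d_obs <- beta_raw - beta_corrected
    d_sim <- vapply(seq_len(n_sim), function(k) {
      drop_k <- sample.int(j, n_out)
      beta_raw - ivw_core(bx[-drop_k], by[-drop_k], sy[-drop_k])$beta
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  list(rss_obs = rss_obs, global_pval = global_pval,
       outlier_pvals = p_adj, outliers = outliers,
       beta_raw = beta_raw, beta_corrected = beta_corrected,
       distortion_pval = distortion_pval, n_sim = as.integer(n_sim))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate J times, dropping one SNP at a time. The
#' analysis is flagged robust when every leave-one-out estimate keeps the
#' sign of the full estimate, i.e. no single instrument drives the result.
#'
#' @param pairs data.frame of harmonized pairs, >= 2 rows.
#' @param mode IVW mode for the leave-one-out fits (`"mre"` default; a
#'   two-SNP input reduces each fit to the other SNP's Wald ratio).
#' @return list with `loo` (data.frame `snp_id`, `beta_without`,
#'   `se_without`, `pval_without`), `all_snp_beta`, `robust`.
#' @export
leave_one_out <- function(pairs, mode = "mre") {
  j <- nrow(pairs)
  if (j < 2L) stop("leave-one-out requires at least 2 instruments")
  full <- ivw_core(pairs$beta_exposure, pairs$beta_outcome,
                   pairs$se_outcome, mode = mode)
  rows <- lapply(seq_len(j), function(i) {
    fit <- ivw_core(pairs$beta_exposure[-i], pairs$beta_outcome[-i],
                    pairs$se_outcome[-i], mode = mode)
    data.frame(snp_id = pairs$snp_id[i], beta_without = fit$beta,
               se_without = fit$se,
               pval_without = 2 * stats::pnorm(-abs(fit$beta) / fit$se),
               stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  list(loo = loo, all_snp_beta = full$beta,
       robust = all(sign(loo$beta_without) == sign(full$beta)))
}

#' Funnel-plot data
#'
#' The per-SNP Wald ratio against its precision `1/se_theta`; asymmetry of
#' this scatter around the IVW estimate suggests directional pleiotropy.
#' Only the data are produced, not a figure.
#'
#' @param pairs data.frame of harmonized pairs, >= 1 row.
#' @return data.frame with `snp_id`, `theta`, `precision`.
#' @export
funnel_data <- function(pairs) {
  if (nrow(pairs) < 1L) stop("funnel data requires at least 1 instrument")
  wr <- wald_ratio(pairs)
  data.frame(snp_id = wr$snp_id, theta = wr$theta,
             precision = 1 / wr$se_theta, stringsAsFactors = FALSE)
}

#' Full sensitivity battery for one instrument set
#'
#' Runs Cochran's Q/I-squared, the Egger intercept test (J >= 3), MR-PRESSO
#' (J >= 4), and leave-one-out, skipping diagnostics whose minimum
#' instrument count is not met (reported as `NA`).
#'
#' @param pairs data.frame of harmonized pairs.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed seed for MR-PRESSO.
#' @return list of class `sensitivity_report` with elements `q`, `egger`,
#'   `presso`, `loo`, and `summary`, a one-row data.frame for export
#'   (columns `n_snps`, `q`, `q_df`, `q_pval`, `i2`, `egger_intercept`,
#'   `egger_intercept_p`, `presso_global_p`, `presso_outliers`,
#'   `loo_robust`).
#' @export
sensitivity_report <- function(pairs, n_sim = 1000L, seed = NULL) {
  j <- nrow(pairs)
  q <- if (j >= 2L) cochran_q(pairs) else NULL
  egger <- if (j >= 3L) egger_intercept_test(pairs) else NULL
  presso <- if (j >= 4L) mr_presso(pairs, n_sim = n_sim, seed = seed) else NULL
  loo <- if (j >= 2L) leave_one_out(pairs) else NULL
  summary <- data.frame(
    n_snps = j,
    q = if (is.null(q)) NA_real_ else q$q,
    q_df = if (is.null(q)) NA_integer_ else q$df,
    q_pval = if (is.null(q)) NA_real_ else q$pval,
    i2 = if (is.null(q)) NA_real_ else q$i2,
    egger_intercept = if (is.null(egger)) NA_real_ else egger$beta,
    egger_intercept_p = if (is.null(egger)) NA_real_ else egger$pval,
    presso_global_p = if (is.null(presso)) NA_real_ else presso$global_pval,
    presso_outliers = if (is.null(presso)) NA_character_ else
      paste(presso$outliers, collapse = ","),
    loo_robust = if (is.null(loo)) NA else loo$robust,
    stringsAsFactors = FALSE)
  structure(list(q = q, egger = egger, presso = presso, loo = loo,
                 summary = summary),
            class = "sensitivity_report")
}
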