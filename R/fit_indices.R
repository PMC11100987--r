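# Conventional SEM fit indices computed from likelihood-ratio statistics of
# nested two-level models. Chi-square isolates misfit to one level (or one
# target structure) because the other level is saturated in both models of
# the comparison.

#' Likelihood-ratio chi-square of nested fits
#'
#' \eqn{\chi^2 = 2(\ell_{H1} - \ell_{H0})}, floored at zero, on degrees of
#' freedom equal to the difference in free-parameter counts; the p-value is
#' the upper tail of the central chi-square.
#'
#' @param fit_h0,fit_h1 `fit_result`s; `fit_h0`'s template must be nested
#'   in `fit_h1`'s (fewer or equal free parameters with `fit_h1` typically
#'   the saturated model).
#' @return List with `chi2`, `df`, `p`, `converged`.
#' @export
chi_square <- function(fit_h0, fit_h1) {
  if (fit_h0$free_params > fit_h1$free_params) {
    stop("`fit_h0` must be nested in `fit_h1`", call. = FALSE)
  }
  df <- fit_h0$df - fit_h1$df
  chi2 <- max(0, 2 * (fit_h1$loglik - fit_h0$loglik))
  list(
    chi2 = chi2,
    df = df,
    p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
    converged = fit_h0$converged && fit_h1$converged
  )
}

#' Root mean square error of approximation
#'
#' \eqn{\sqrt{\max(\chi^2 - df, 0) / (df \cdot N)}} with `n_total` the total
#' individual count. Zero whenever the statistic does not exceed its
#' degrees of freedom.
#'
#' @param chi2 Chi-square statistic.
#' @param df Its degrees of freedom (> 0).
#' @param n_total Total number of individuals.
#' @return A single number.
#' @export
rmsea <- function(chi2, df, n_total) {
  if (df <= 0) stop("RMSEA is undefined at df = 0", call. = FALSE)
  if (n_total <= 0) stop("`n_total` must be positive", call. = FALSE)
  sqrt(max(chi2 - df, 0) / (df * n_total))
}

#' Comparative fit index
#'
#' \eqn{1 - \max(\chi^2 - df, 0) / \max(\chi^2_b - df_b, \chi^2 - df, 0)}
#' against an independence baseline; returns 1 when the denominator
#' vanishes.
#'
#' @param chi2,df Target model statistic and degrees of freedom.
#' @param chi2_base,df_base Baseline model statistic and degrees of freedom.
#' @return A number in [0, 1].
#' @export
cfi <- function(chi2, df, chi2_base, df_base) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_base - df_base, chi2 - df, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Tucker-Lewis index
#'
#' \eqn{((\chi^2_b/df_b) - (\chi^2/df)) / ((\chi^2_b/df_b) - 1)}, stored
#' unclamped: values above 1 occur whenever the target statistic falls
#' below its degrees of freedom.
#'
#' @inheritParams cfi
#' @return A single number (may exceed 1).
#' @export
tli <- function(chi2, df, chi2_base, df_base) {
  if (df <= 0 || df_base <= 0) stop("TLI needs positive df", call. = FALSE)
  r_base <- chi2_base / df_base
  if (r_base == 1) stop("TLI is undefined when the baseline ratio is 1", call. = FALSE)
  (r_base - chi2 / df) / (r_base - 1)
}

#' Standardized root mean square residual at one level
#'
#' Root mean square of the correlation-metric residuals between the
#' saturated covariance estimate at a level and a hypothesized model's
#' implied covariance at that level:
#' \eqn{\sqrt{\frac{2}{T(T+1)}\sum_{i \le j}
#' ((s_{ij} - \hat\sigma_{ij}) / \sqrt{s_{ii} s_{jj}})^2}}.
#' Optionally appends standardized mean residuals
#' \eqn{(\bar y_t - \hat\mu_t)/\sqrt{s_{tt}}} (off by default; the
#' level-specific models keep means saturated so those residuals are
#' identically zero).
#'
#' @param sat_cov Saturated (unrestricted) covariance estimate.
#' @param implied_cov Hypothesized model's implied covariance.
#' @param sat_mean,implied_mean Optional mean vectors for the mean-residual
#'   variant.
#' @return A nonnegative number.
#' @export
srmr_level <- function(sat_cov, implied_cov, sat_mean = NULL, implied_mean = NULL) {
  d <- diag(sat_cov)
  if (any(d <= 0)) stop("saturated covariance needs positive diagonal", call. = FALSE)
  tt <- nrow(sat_cov)
  scale <- sqrt(tcrossprod(d))
  res <- ((sat_cov - implied_cov) / scale)[lower.tri(sat_cov, diag = TRUE)]
  if (!is.null(sat_mean)) {
    res <- c(res, (sat_mean - implied_mean) / sqrt(d))
  }
  sqrt(mean(res^2))
}

#' All twenty fit indices for one dataset
#'
#' Runs [fit_catalog()] and derives, for each comparison (PS_B, PS_W,
#' TS_COV, TS_MEAN), the chi-square against the fully saturated model plus
#' RMSEA, CFI and TLI against the matching baseline (independence baselines
#' for the covariance comparisons, the equal-means baseline for TS_MEAN),
#' and the two level-specific SRMRs. Every RMSEA uses the total individual
#' count.
#'
#' @param dataset A `clustered_dataset` (or `sufficient_stats`; then
#'   `n_total` is taken from the statistics).
#' @param basis Growth basis of the fitted structure.
#' @param control [fit_control()] settings.
#' @param templates Template catalog to fit.
#' @param srmr_mean_residuals If `TRUE`, the TS_MEAN SRMR includes
#'   standardized mean residuals.
#' @return A `fit_index_set` list: the 20 indices (named as in
#'   [index_names()]), `n_total`, `converged_all`, and the `fits`.
#' @export
compute_fit_indices <- function(dataset, basis, control = fit_control(),
                                templates = template_catalog(),
                                srmr_mean_residuals = FALSE) {
  st <- sufficient_stats(dataset)
  fits <- fit_catalog(st, basis, control, templates)
  n <- st$n_total

  block <- function(target, baseline) {
    cs <- chi_square(fits[[target]], fits$H1)
    cb <- chi_square(fits[[baseline]], fits$H1)
    list(
      chi2 = cs$chi2,
      rmsea = rmsea(cs$chi2, cs$df, n),
      cfi = cfi(cs$chi2, cs$df, cb$chi2, cb$df),
      tli = tli(cs$chi2, cs$df, cb$chi2, cb$df)
    )
  }
  ps_b <- block("PS_B", "BASE_B")
  ps_w <- block("PS_W", "BASE_W")
  ts_cov <- block("TS_COV", "BASE_B")
  ts_mean <- block("TS_MEAN", "BASE_MEAN")

  sat_b <- fits$H1$params$sigma_b
  sat_w <- fits$H1$params$sigma_w
  # Heywood-type saturated solutions (negative between variance) leave the
  # standardized residuals undefined; flag instead of failing
  safe_srmr <- function(...) tryCatch(srmr_level(...), error = function(e) NA_real_)
  idx <- list(
    chi2_ps_b = ps_b$chi2, chi2_ps_w = ps_w$chi2,
    chi2_ts_cov = ts_cov$chi2, chi2_ts_mean = ts_mean$chi2,
    rmsea_ps_b = ps_b$rmsea, rmsea_ps_w = ps_w$rmsea,
    rmsea_ts_cov = ts_cov$rmsea, rmsea_ts_mean = ts_mean$rmsea,
    cfi_ps_b = ps_b$cfi, cfi_ps_w = ps_w$cfi,
    cfi_ts_cov = ts_cov$cfi, cfi_ts_mean = ts_mean$cfi,
    tli_ps_b = ps_b$tli, tli_ps_w = ps_w$tli,
    tli_ts_cov = ts_cov$tli, tli_ts_mean = ts_mean$tli,
    srmr_b = safe_srmr(sat_b, fits$PS_B$params$sigma_b),
    srmr_w = safe_srmr(sat_w, fits$PS_W$params$sigma_w),
    srmr_ts_cov = safe_srmr(sat_b, fits$TS_COV$params$sigma_b),
    srmr_ts_mean = if (srmr_mean_residuals) {
      safe_srmr(sat_b, fits$TS_MEAN$params$sigma_b,
                fits$H1$params$mu, fits$TS_MEAN$params$mu)
    } else {
      safe_srmr(sat_b, fits$TS_MEAN$params$sigma_b)
    }
  )
  structure(
    list(indices = idx, n_total = n,
         converged_all = all(vapply(fits, `[[`, TRUE, "converged")) &&
           !anyNA(unlist(idx)),
         fits = fits),
    class = "fit_index_set"
  )
}

#' Canonical index column order
#'
#' @return Character vector of the 20 per-replication index column names.
#' @export
index_names <- function() {
  c("chi2_ps_b", "chi2_ps_w", "chi2_ts_cov", "chi2_ts_mean",
    "rmsea_ps_b", "rmsea_ps_w", "rmsea_ts_cov", "rmsea_ts_mean",
    "cfi_ps_b", "cfi_ps_w", "cfi_ts_cov", "cfi_ts_mean",
    "tli_ps_b", "tli_ps_w", "tli_ts_cov", "tli_ts_mean",
    "srmr_b", "srmr_w", "srmr_ts_cov", "srmr_ts_mean")
}
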