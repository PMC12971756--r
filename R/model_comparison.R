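#' Arcsine square-root transformation
#'
#' Variance-stabilising transform for proportions: `asin(sqrt(x))`, mapping
#' `[0, 1]` onto `[0, pi/2]` radians. Applied to the proportion of
#' high-mobility hummingbirds and to haplotype diversity before
#' standardisation.
#'
#' @param x Proportions in `[0, 1]`.
#' @return Values in radians.
#' @export
arcsine_sqrt <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("`x` must lie in [0, 1]", call. = FALSE)
  asin(sqrt(x))
}

#' Standardise a variable
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), so that slopes of regressions on standardised variables
#' are beta coefficients.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardised vector.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardise a constant vector", call. = FALSE)
  (x - mean(x)) / s
}

#' Fit a simple linear regression
#'
#' Ordinary least squares of `y` on `x` with an intercept. The
#' log-likelihood is the Gaussian likelihood at the maximum-likelihood
#' variance estimate (RSS/n) including the full normal constant, so the
#' resulting AICc values are comparable with standard implementations.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @return List with `beta` (slope), `se` (slope standard error),
#'   `intercept`, `r2` (unadjusted), `loglik`, `n`.
#' @export
fit_simple_ols <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("at least 4 observations required", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(beta = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       loglik = as.numeric(stats::logLik(fit)),
       n = n)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * loglik + 2k + 2k(k+1)/(n-k-1)`. For the simple linear
#' regression used here, `k = 3` (intercept, slope, residual variance).
#'
#' @param loglik Maximised log-likelihood.
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of estimated parameters (default 3).
#' @return AICc value.
#' @export
aicc <- function(loglik, n, k = 3) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights of a model set
#'
#' `w_m = exp(-dAICc_m / 2) / sum_n exp(-dAICc_n / 2)` where
#' `dAICc_m = AICc_m - min(AICc)`. Weights are non-negative, sum to one,
#' and are invariant to adding a constant to every AICc.
#'
#' @param aicc_values Numeric vector of finite AICc values.
#' @return Vector of weights.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0)
    stop("empty model set", call. = FALSE)
  if (any(!is.finite(aicc_values)))
    stop("AICc values must be finite", call. = FALSE)
  rel <- exp(-(aicc_values - min(aicc_values)) / 2)
  rel / sum(rel)
}

#' Summed Akaike weights per factor level
#'
#' For the 12-model local landscape set of one response, sums the Akaike
#' weights of all models sharing each level of one design factor. Within a
#' factor the level sums partition the total weight, so they add to one.
#'
#' @param rows Data frame of the 12 local models for one response, with
#'   columns `habitat_def`, `weighting`, `gap_mode`, `weight`.
#' @param factor One of `"habitat_def"`, `"weighting"`, `"gap_mode"`.
#' @return Named numeric vector of per-level weight sums.
#' @export
summed_factor_weights <- function(rows,
                                  factor = c("habitat_def", "weighting",
                                             "gap_mode")) {
  factor <- match.arg(factor)
  combos <- table(rows$habitat_def, rows$weighting, rows$gap_mode)
  if (length(combos) != 12 || any(combos != 1))
    stop("`rows` must contain exactly the 2 x 2 x 3 factorial of local ",
         "models", call. = FALSE)
  s <- tapply(rows$weight, rows[[factor]], sum)
  stats::setNames(as.numeric(s), names(s))
}

# transform + standardise one response column by its conventions
prepare_response <- function(values, response) {
  if (response %in% c("prop_high_mobility", "h"))
    values <- arcsine_sqrt(values)
  standardize(values)
}

#' Compare all connectivity metrics for all responses
#'
#' For every response variable and every connectivity metric, fits a
#' simple linear regression of the (transformed, standardised) response on
#' the standardised metric and ranks the models by AICc within each
#' (response, scale) set: the 3 intra-patch models and the 12 local models
#' form separate sets, mirroring their treatment as alternative
#' explanations.
#'
#' @param responses Site-level response table from
#'   [build_response_table()] (columns `site_id`, `prop_high_mobility`,
#'   `h`, `tm_minus_ts`; NAs drop a site from that response's models).
#' @param metrics Long-format metric table from [compute_metric_suite()]
#'   stacked over sites.
#' @param k AICc parameter count (default 3).
#' @return Data frame with one row per (response, metric): `response`,
#'   `scale`, `metric`, `habitat_def`, `weighting`, `gap_mode`, `n`,
#'   `beta`, `se`, `r2`, `aicc`, `delta_aicc`, `weight`.
#' @export
compare_all <- function(responses, metrics, k = 3) {
  metrics$key <- metric_key(metrics)
  out <- NULL
  for (resp in c("prop_high_mobility", "h", "tm_minus_ts")) {
    y_all <- responses[[resp]]
    keep_sites <- responses$site_id[!is.na(y_all)]
    if (length(keep_sites) < 4) next
    for (scl in c("INTRA_PATCH", "LOCAL")) {
      mm <- metrics[metrics$scale == scl, , drop = FALSE]
      if (nrow(mm) == 0) next
      rows <- NULL
      for (key in unique(mm$key)) {
        mk <- mm[mm$key == key, , drop = FALSE]
        m <- match(keep_sites, mk$site_id)
        if (anyNA(m))
          stop("metric '", key, "' missing for site(s): ",
               paste(keep_sites[is.na(m)], collapse = ", "), call. = FALSE)
        x <- standardize(mk$transformed[m])
        y <- prepare_response(y_all[match(keep_sites, responses$site_id)],
                              resp)
        fit <- fit_simple_ols(x, y)
        rows <- rbind(rows, data.frame(
          response = resp, scale = scl, metric = mk$metric[1],
          habitat_def = mk$habitat_def[1], weighting = mk$weighting[1],
          gap_mode = mk$gap_mode[1], n = fit$n, beta = fit$beta,
          se = fit$se, r2 = fit$r2,
          aicc = aicc(fit$loglik, fit$n, k),
          stringsAsFactors = FALSE))
      }
      rows$delta_aicc <- rows$aicc - min(rows$aicc)
      rows$weight <- akaike_weights(rows$aicc)
      out <- rbind(out, rows)
    }
  }
  rownames(out) <- NULL
  out
}
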