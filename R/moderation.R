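# Newton solve of trigamma(x) = y; monotone decreasing, so the iteration
# x <- x + trigamma(x) * (1 - trigamma(x)/y) / psigamma(x, 2) converges from
# the asymptotic start 0.5 + 1/y.
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderation of per-protein residual variances
#'
#' Shrinks each protein's residual variance towards a common prior by
#' treating the sample variances as draws from a scaled F distribution:
#' `s^2_j ~ s0^2 F(d_j, d0)`. The prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by matching the first two moments of
#' `log s^2_j` (whose mean and variance involve digamma/trigamma functions
#' of the degrees of freedom), and the posterior (moderated) variances are
#' the standard squeeze
#' `s~^2_j = (d0 s0^2 + d_j s^2_j) / (d0 + d_j)`.
#'
#' When the observed log-variances are no more dispersed than sampling alone
#' explains, `d0` is infinite and all moderated variances equal `s0^2`.
#' With `df_prior = 0` (see `run_differential_abundance(moderation =
#' FALSE)`) the squeeze is the identity and ordinary per-protein t-tests are
#' recovered.
#'
#' @param s2 Per-protein residual variances (>= 10 finite positive values).
#' @param df Residual degrees of freedom, scalar or per-protein vector.
#' @return List with `df_prior` (d0, possibly `Inf`), `var_prior` (s0^2) and
#'   `var_post` (moderated variances, same length as `s2`; proteins with
#'   non-positive or missing `s2` keep `NA` and are excluded from
#'   estimation with a warning).
#' @export
moderate_variances <- function(s2, df) {
  n <- length(s2)
  df <- rep_len(df, n)
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 10) {
    stop("need at least 10 proteins with positive finite variances")
  }
  if (any(!ok)) {
    warning(sprintf("%d proteins with non-positive or missing variance %s",
                    sum(!ok), "excluded from moderation"))
  }
  z <- log(s2[ok])
  d <- df[ok]
  if (diff(range(z)) < 1e-12) {
    # exact ties carry no sampling dispersion to moment-match against:
    # infinitely strong prior located at the common value
    var_post <- rep(NA_real_, n)
    var_post[ok] <- exp(mean(z))
    return(list(df_prior = Inf, var_prior = exp(mean(z)),
                var_post = var_post))
  }
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  var_post <- rep(NA_real_, n)
  var_post[ok] <- if (is.infinite(df_prior)) {
    var_prior
  } else {
    (df_prior * var_prior + df[ok] * s2[ok]) / (df_prior + df[ok])
  }
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

#' Moderated t-statistics and p-values for selected coefficients
#'
#' Divides each fitted coefficient by its moderated standard error
#' `sqrt(var_post) * stdev_unscaled` and refers the statistic to a t
#' distribution with `df_residual + df_prior` degrees of freedom (a normal
#' reference in the infinite-prior limit).
#'
#' @param coefficients Numeric vector (one protein per element) of fitted
#'   coefficients for one model column.
#' @param stdev_unscaled Design-based unscaled coefficient SDs (sqrt of the
#'   relevant diagonal entry of `(X'X)^-1`), recycled if scalar.
#' @param var_post Moderated variances from [moderate_variances()] (or raw
#'   `s^2` with `df_prior = 0` for classical tests).
#' @param df_residual Residual degrees of freedom (scalar or vector).
#' @param df_prior Prior degrees of freedom (0 = no moderation).
#' @return Data frame with `t_stat`, `p_value` and `df_total`.
#' @export
moderated_tests <- function(coefficients, stdev_unscaled, var_post,
                            df_residual, df_prior = 0) {
  n <- length(coefficients)
  stdev_unscaled <- rep_len(stdev_unscaled, n)
  df_total <- rep_len(df_residual, n) + df_prior
  se <- sqrt(var_post) * stdev_unscaled
  t_stat <- ifelse(se > 0, coefficients / se,
                   ifelse(coefficients == 0, 0, sign(coefficients) * Inf))
  # cap df so pt() stays defined in the infinite-prior (normal) limit
  p <- 2 * pt(-abs(t_stat), df = pmin(df_total, 1e7))
  data.frame(t_stat = t_stat, p_value = p, df_total = df_total)
}
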