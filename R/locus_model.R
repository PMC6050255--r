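# Per-feature linear models against the continuous exposure score, with
# empirical-Bayes variance moderation and p -> signed-z transformation.
# Shared between the methylation (M-value) and expression (normalized
# log-count) arms of the pipeline.

# Design matrix: intercept, LSI score, age, batch indicator(s).
build_design <- function(samples) {
  need <- c("lsi_score", "age", "batch")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop_value("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  }
  samples$batch <- factor(samples$batch)
  X <- stats::model.matrix(~ lsi_score + age + batch, data = samples)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_pipeline("design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", "))
  }
  X
}

#' Fit per-feature linear models against the exposure score
#'
#' Ordinary least squares of each matrix row on the design intercept +
#' lsi_score + age + batch. Returns the LSI-score coefficient with its
#' standard error, residual degrees of freedom, raw t and two-sided p.
#' Features with zero residual variance get `p = NA` (with one warning
#' summarizing how many) and are excluded by downstream stages.
#'
#' @param y features x samples numeric matrix (M-values or normalized
#'   log-counts); rownames are feature ids
#' @param samples sample sheet with lsi_score, age, batch
#' @return data.frame of class `locus_stats`: id, coef, se, df, t, p, plus
#'   the raw residual variance `sigma2` and unscaled coefficient SD
#'   `stdev_unscaled` used by [moderate_variances()]
#' @export
fit_locus_models <- function(y, samples) {
  X <- build_design(samples)
  if (ncol(y) != nrow(X)) stop_value("matrix columns do not match sample sheet")
  qrX <- qr(X)
  coefs <- qr.coef(qrX, t(y))            # p x features
  fitted <- X %*% coefs
  res <- t(y) - fitted
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match("lsi_score", colnames(X))
  c_lsi <- sqrt(xtx_inv[j, j])           # unscaled SD of the LSI coefficient
  b <- coefs["lsi_score", ]
  se <- sqrt(sigma2) * c_lsi
  tval <- b / se
  p <- 2 * pt(-abs(tval), df)
  zero_var <- sigma2 <= .Machine$double.eps * max(1, mean(sigma2, na.rm = TRUE))
  if (any(zero_var)) {
    warning(sprintf("%d feature(s) with zero residual variance; p set to NA",
                    sum(zero_var)), call. = FALSE)
    p[zero_var] <- NA_real_
    tval[zero_var] <- NA_real_
    se[zero_var] <- NA_real_
  }
  out <- data.frame(id = rownames(y), coef = b, se = se, df = df,
                    t = tval, p = p, sigma2 = sigma2,
                    stdev_unscaled = c_lsi, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("locus_stats", "data.frame")
  out
}

# Invert the trigamma function by Newton's method (monotone decreasing,
# convex target; started from the asymptotic 1/y approximation).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (it in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of a scaled inverse-chi-square prior to the sample
# variances: E[log s^2] and Var[log s^2] identify (d0, s0^2) through
# digamma/trigamma relations.
fit_variance_prior <- function(sigma2, df) {
  ok <- is.finite(sigma2) & sigma2 > 0
  if (sum(ok) < 10) {
    stop_pipeline("fewer than 10 features with finite positive variance (%d); variance-prior moments are unstable", sum(ok))
  }
  s2 <- sigma2[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s0_2)
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks each feature's residual variance toward a common prior variance
#' estimated by method of moments on the log sample variances
#' (digamma/trigamma inversion), then recomputes t and p with the
#' augmented degrees of freedom: posterior variance
#' `(d0*s0^2 + df*s^2) / (d0 + df)`, moderated `t = b / (c * s_post)`,
#' p from the t distribution on `d0 + df` df. When the moment estimate of
#' the prior df is infinite every posterior variance equals the prior
#' variance.
#'
#' @param stats a `locus_stats` data.frame from [fit_locus_models()]
#' @param prior_df optional override of the prior degrees of freedom
#'   (0 reproduces the raw t exactly; Inf equalizes all variances)
#' @return `stats` with columns replaced/added: moderated_t, p (moderated),
#'   raw_t, raw_p, posterior_var, and attributes `prior_df`, `prior_var`
#' @export
moderate_variances <- function(stats, prior_df = NULL) {
  pr <- fit_variance_prior(stats$sigma2, stats$df[1])
  d0 <- prior_df %||% pr$prior_df
  s0_2 <- pr$prior_var
  df <- stats$df
  post <- if (is.infinite(d0)) rep(s0_2, nrow(stats)) else {
    (d0 * s0_2 + df * stats$sigma2) / (d0 + df)
  }
  mod_t <- stats$coef / (stats$stdev_unscaled * sqrt(post))
  total_df <- df + d0
  mod_p <- 2 * pt(-abs(mod_t), total_df)
  bad <- !is.finite(stats$p)
  mod_t[bad] <- NA_real_
  mod_p[bad] <- NA_real_
  stats$raw_t <- stats$t
  stats$raw_p <- stats$p
  stats$moderated_t <- mod_t
  stats$t <- mod_t
  stats$p <- mod_p
  stats$posterior_var <- post
  attr(stats, "prior_df") <- d0
  attr(stats, "prior_var") <- s0_2
  stats
}

#' Transform two-sided p-values to signed z-scores
#'
#' `z = sign(b) * qnorm(1 - p/2)`; p is clamped below at 1e-300 so z stays
#' finite. Carrying the coefficient sign keeps hyper- and hypo-methylation
#' distinguishable to the HMM's alternative mixture.
#'
#' @param p two-sided p-values in (0, 1]
#' @param coefficient_sign numeric; only its sign is used (0 maps to +)
#' @return signed z-scores
#' @export
p_to_z <- function(p, coefficient_sign) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop_value("p-values must lie in (0, 1]")
  }
  pc <- pmax(p, 1e-300)
  s <- ifelse(coefficient_sign < 0, -1, 1)
  s * qnorm(pc / 2, lower.tail = FALSE)
}
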