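# Two-state hidden-Markov local-index-of-significance machinery.
#
# State 0 ("null") emits N(0, 1) — the distribution of signed z-scores for
# unaffected probes. State 1 ("alternative") emits a free K = 2 normal
# mixture, capturing hyper- and hypo-methylated effects at once. Chains
# restart at every chromosome boundary. LIS_i is the posterior probability
# of the null state at probe i; thresholding the running mean of the sorted
# LIS values (aLIS) controls the FDR for dependent tests.

default_hmm_init <- function() {
  list(pi_null = 0.95,
       A = matrix(c(0.95, 0.05, 0.3, 0.7), 2, 2, byrow = TRUE),
       mix_w = c(0.5, 0.5), mix_mu = c(-2, 2), mix_sd = c(1, 1))
}

# log density of the alternative emission (K-component normal mixture)
log_mix_density <- function(z, w, mu, sd) {
  comp <- vapply(seq_along(w), function(k) {
    log(w[k]) + dnorm(z, mu[k], sd[k], log = TRUE)
  }, numeric(length(z)))
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
  m <- apply(comp, 1, max)
  m + log(rowSums(exp(comp - m)))
}

hmm_log_emissions <- function(z, model) {
  cbind(dnorm(z, 0, 1, log = TRUE),
        log_mix_density(z, model$mix_w, model$mix_mu, model$mix_sd))
}

# One E-step over all chains; returns summed statistics and posteriors.
hmm_e_step <- function(z, seg, model) {
  logem <- hmm_log_emissions(z, model)
  logpi <- log(c(model$pi_null, 1 - model$pi_null))
  logA <- log(model$A)
  gamma <- matrix(0, length(z), 2)
  xi <- matrix(0, 2, 2)
  start_gamma <- c(0, 0)
  ll <- 0
  for (s in seq_len(nrow(seg))) {
    idx <- seg$start[s]:seg$end[s]
    fb <- hmm_forward_backward(logem[idx, , drop = FALSE], logpi, logA)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi
    start_gamma <- start_gamma + fb$gamma[1, ]
    ll <- ll + fb$loglik
  }
  list(gamma = gamma, xi = xi, start_gamma = start_gamma, loglik = ll)
}

# min_alt_mean: identifiability constraint keeping the alternative mixture
# separated from the N(0,1) null. Without it, data with no (or weak) signal
# admit near-equal-likelihood solutions in which the "alternative" mimics
# the null and absorbs arbitrary occupancy. The constrained M-step clamps
# each component mean to the nearest boundary of {|mu| >= min_alt_mean},
# which is the exact constrained maximizer of the (quadratic) Q function,
# so EM monotonicity is preserved.
hmm_m_step <- function(z, es, model, n_chains, sd_floor = 0.1,
                       min_alt_mean = 1) {
  model$pi_null <- min(max(es$start_gamma[1] / n_chains, 1e-6), 1 - 1e-6)
  A <- es$xi / rowSums(es$xi)
  A <- pmin(pmax(A, 1e-8), 1 - 1e-8)
  model$A <- A / rowSums(A)
  # mixture responsibilities within the alternative state
  K <- length(model$mix_w)
  comp <- vapply(seq_len(K), function(k) {
    log(model$mix_w[k]) + dnorm(z, model$mix_mu[k], model$mix_sd[k],
                                log = TRUE)
  }, numeric(length(z)))
  m <- apply(comp, 1, max)
  r <- exp(comp - m)
  r <- r / rowSums(r)
  r <- r * es$gamma[, 2]
  tot <- colSums(r)
  alt_mass <- sum(es$gamma[, 2])
  if (alt_mass > 1e-8 && all(tot > 1e-8)) {
    model$mix_w <- tot / alt_mass
    mu <- colSums(r * z) / tot
    small <- abs(mu) < min_alt_mean
    mu[small] <- ifelse(mu[small] < 0, -min_alt_mean, min_alt_mean)
    model$mix_mu <- mu
    model$mix_sd <- pmax(sqrt(colSums(r * (outer(z, model$mix_mu, "-"))^2) /
                                tot), sd_floor)
  }
  model
}

chain_segments <- function(chromosome, n) {
  if (is.null(chromosome)) {
    data.frame(start = 1L, end = n)
  } else {
    r <- rle(as.character(chromosome))
    end <- cumsum(r$lengths)
    data.frame(start = end - r$lengths + 1L, end = end)
  }
}

#' Fit the two-state HMM and compute the local index of significance
#'
#' Fits the HMM by EM with log-space forward–backward (null emission fixed
#' at N(0,1); free initial-state probability, homogeneous 2x2 transitions,
#' K = 2 alternative normal mixture). Chains restart independently at each
#' chromosome boundary. EM stops when the relative log-likelihood change
#' falls below `tol` or after `max_iter` iterations; the default fit plus
#' `restarts` randomly perturbed initializations are run and the best
#' likelihood wins.
#'
#' @param z signed z-scores, ordered by (chromosome, position)
#' @param chromosome chromosome label per z (NULL = one chain)
#' @param restarts number of random restarts in addition to the default
#'   initialization (default 3)
#' @param seed integer seed controlling restart perturbations
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations per start
#' @param min_probes minimum number of probes required (default 100)
#' @param min_alt_mean identifiability constraint: minimal |mean| of each
#'   alternative mixture component, in null-SD units (default 1); keeps the
#'   alternative separated from the N(0,1) null so signal-free data do not
#'   drift into a label-swapped solution
#' @return list of class `hmm_lis`: `model` (pi_null, A, mix_w, mix_mu,
#'   mix_sd, loglik_trace), `lis` (posterior null probability per probe),
#'   `restart_logliks`
#' @export
fit_hmm_lis <- function(z, chromosome = NULL, restarts = 3, seed = 1,
                        tol = 1e-8, max_iter = 1000, min_probes = 100,
                        min_alt_mean = 1) {
  if (any(!is.finite(z))) stop_value("z contains non-finite values")
  n <- length(z)
  if (n < min_probes) {
    stop_pipeline("need at least %d probes for HMM fitting, got %d",
                  min_probes, n)
  }
  seg <- chain_segments(chromosome, n)
  inits <- list(default_hmm_init())
  if (restarts > 0) {
    inits <- c(inits, with_seed(seed, {
      lapply(seq_len(restarts), function(r) {
        ini <- default_hmm_init()
        mu <- sort(ini$mix_mu + rnorm(2, 0, 1))
        mu[abs(mu) < min_alt_mean] <-
          ifelse(mu[abs(mu) < min_alt_mean] < 0, -min_alt_mean, min_alt_mean)
        ini$mix_mu <- mu
        ini$mix_sd <- runif(2, 0.5, 2)
        ini$pi_null <- runif(1, 0.8, 0.99)
        ini
      })
    }))
  }
  run_em <- function(model) {
    trace <- numeric(0)
    es <- hmm_e_step(z, seg, model)
    trace <- es$loglik
    for (it in seq_len(max_iter)) {
      model <- hmm_m_step(z, es, model, n_chains = nrow(seg),
                          min_alt_mean = min_alt_mean)
      es <- hmm_e_step(z, seg, model)
      trace <- c(trace, es$loglik)
      d <- trace[length(trace)] - trace[length(trace) - 1]
      if (abs(d) / (abs(trace[length(trace)]) + 1) < tol) break
    }
    model$loglik_trace <- trace
    list(model = model, es = es, loglik = trace[length(trace)])
  }
  fits <- lapply(inits, run_em)
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls))) {
    stop_pipeline("EM failed to produce a finite likelihood in any restart")
  }
  best <- fits[[which.max(lls)]]
  structure(list(model = best$model, lis = best$es$gamma[, 1],
                 restart_logliks = lls), class = "hmm_lis")
}

#' Adjust LIS values and call differentially methylated loci
#'
#' Sorts LIS ascending; the adjusted LIS at rank k is the running mean of
#' the k smallest LIS values, mapped back to probe order. A probe is called
#' when its aLIS is below `alpha`; the called set is always a prefix of the
#' ascending-LIS ranking.
#'
#' @param lis LIS values in \[0, 1\]
#' @param alpha call threshold (default 0.05)
#' @return data.frame: lis, alis, called
#' @export
adjust_lis <- function(lis, alpha = 0.05) {
  if (any(lis < 0 | lis > 1)) stop_value("LIS values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  ord <- order(lis)  # stable: ties broken by original (genomic) order
  alis_sorted <- cumsum(lis[ord]) / seq_along(lis)
  alis <- numeric(length(lis))
  alis[ord] <- alis_sorted
  data.frame(lis = lis, alis = alis, called = alis < alpha)
}

#' Posterior null probabilities under a fixed HMM
#'
#' Computes LIS values for given z-scores under a fully specified model
#' without fitting — useful for inspecting a fit or for forcing parameter
#' values.
#'
#' @param model list with pi_null, A, mix_w, mix_mu, mix_sd
#' @param z signed z-scores
#' @param chromosome chain labels (NULL = one chain)
#' @return numeric vector of posterior null probabilities
#' @export
hmm_lis_posteriors <- function(model, z, chromosome = NULL) {
  es <- hmm_e_step(z, chain_segments(chromosome, length(z)), model)
  es$gamma[, 1]
}
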