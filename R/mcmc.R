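# Markov chain Monte Carlo for the two hierarchical rate models.
#
# Both models pool species within one size class. They are small enough
# (one scalar parameter pair per species plus two hyperparameters) that a
# purpose-built vectorized Gibbs / Metropolis-within-Gibbs sampler mixes in
# seconds for hundreds of species; sufficient statistics are computed once,
# so cost per sweep is O(n_species), independent of the number of raw
# observations.

#' Split-chain potential scale reduction factor
#'
#' Split-Rhat: each chain is halved, and the usual between/within variance
#' ratio is computed over the resulting sequences. Values near 1 indicate
#' the chains have mixed; the pipeline requires < 1.01.
#'
#' @param draws iterations x chains matrix of posterior draws of one scalar.
#' @return the split-Rhat statistic (NA for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_total <- function(draws) {
  # effective sample size summed over chains
  sum(apply(as.matrix(draws), 2L, function(x) {
    as.numeric(coda::effectiveSize(coda::mcmc(x)))
  }))
}

adapt_step <- function(step, accepted, window) {
  step * exp((accepted / window - 0.44) * 0.6)
}

#' Fit the hierarchical growth model for one size class
#'
#' Transformed growth observations of individual i of species j are modelled
#' as Normal(g_j, sigma_j), with species means pooled as
#' g_j ~ Normal(g_class, 1) and species standard deviations as
#' sigma_j ~ Lognormal(sigma_class, 1). The class-level location parameters
#' carry wide proper uniform priors (g_class in \[-100, 100\], sigma_class in
#' \[-20, 20\] on the log scale) so posteriors are proper while remaining
#' effectively flat. Species means get conjugate Gibbs updates; log species
#' SDs use an adaptive random-walk Metropolis step vectorized over species.
#'
#' Species with fewer than `config$min_obs` observations are excluded from
#' the fit (their rates stay missing downstream). Point estimates are
#' posterior means. Convergence requires split-Rhat < 1.01 and total
#' effective sample size > 400 for every reported quantity; fits failing the
#' contract are returned with `converged = FALSE`.
#'
#' @param obs data frame with columns `species` and `y`, the
#'   modulus-transformed annual increments of one size class.
#' @param config a [pipeline_config()]; uses `min_obs`, `n_chains`,
#'   `n_iter`, `n_burnin`.
#' @param seed integer seed.
#' @return object of class `growth_fit`: `species_estimates` (species,
#'   n_obs, raw_mean, g_mean, g_sd, sigma_mean, rhat, ess), `hyper`
#'   (posterior means and diagnostics of g_class and sigma_class),
#'   `converged`, `excluded`.
#' @export
fit_growth_model <- function(obs, config = pipeline_config(), seed = 1L) {
  stopifnot(all(c("species", "y") %in% names(obs)))
  counts <- table(obs$species)
  keep_sp <- sort(names(counts)[counts >= config$min_obs])
  excluded <- sort(names(counts)[counts < config$min_obs])
  if (length(keep_sp) == 0L) stop("no species with at least ",
                                  config$min_obs, " growth observations")
  obs <- obs[obs$species %in% keep_sp, , drop = FALSE]
  sp <- factor(obs$species, levels = keep_sp)
  J <- length(keep_sp)
  n_j <- as.numeric(table(sp))
  ybar <- as.numeric(tapply(obs$y, sp, mean))
  ss <- as.numeric(tapply(obs$y, sp, function(v) sum((v - mean(v))^2)))
  sd0 <- sqrt(pmax(ss / pmax(n_j - 1, 1), 1e-4))

  n_chains <- config$n_chains; n_iter <- config$n_iter; n_burnin <- config$n_burnin
  total <- n_iter + n_burnin
  g_draws <- array(NA_real_, c(n_iter, n_chains, J))
  cm_draws <- array(NA_real_, c(n_iter, n_chains, J))  # Rao-Blackwellized
  l_draws <- array(NA_real_, c(n_iter, n_chains, J))
  hyper_draws <- array(NA_real_, c(n_iter, n_chains, 2L),
                       dimnames = list(NULL, NULL, c("g_class", "sigma_class")))
  set.seed(as.integer(seed))
  for (ch in seq_len(n_chains)) {
    g <- ybar + stats::rnorm(J, 0, 0.1 * (1 + sd0 / sqrt(n_j)))
    l <- log(sd0) + stats::rnorm(J, 0, 0.1)
    g_class <- mean(g); sigma_class <- mean(l)
    step <- rep(0.5, J); acc <- rep(0, J); window <- 50L
    for (it in seq_len(total)) {
      sig2 <- exp(2 * l)
      prec <- n_j / sig2 + 1
      g <- stats::rnorm(J, (n_j * ybar / sig2 + g_class) / prec, sqrt(1 / prec))
      S <- ss + n_j * (ybar - g)^2
      lp <- stats::rnorm(J, l, step)
      logpost <- function(ell) {
        -n_j * ell - S / (2 * exp(2 * ell)) - (ell - sigma_class)^2 / 2
      }
      ratio <- logpost(lp) - logpost(l)
      ok <- log(stats::runif(J)) < ratio
      l[ok] <- lp[ok]
      acc <- acc + ok
      if (it <= n_burnin && it %% window == 0L) {
        step <- adapt_step(step, acc, window); acc <- rep(0, J)
      }
      g_class <- min(100, max(-100, stats::rnorm(1L, mean(g), sqrt(1 / J))))
      sigma_class <- min(20, max(-20, stats::rnorm(1L, mean(l), sqrt(1 / J))))
      if (it > n_burnin) {
        g_draws[it - n_burnin, ch, ] <- g
        # conditional posterior mean of g_j given (sigma_j, g_class): a convex
        # combination of the species raw mean and the class mean, so its
        # average preserves the pooling direction exactly
        sig2_cur <- exp(2 * l)
        prec_cur <- n_j / sig2_cur + 1
        cm_draws[it - n_burnin, ch, ] <-
          (n_j * ybar / sig2_cur + g_class) / prec_cur
        l_draws[it - n_burnin, ch, ] <- l
        hyper_draws[it - n_burnin, ch, ] <- c(g_class, sigma_class)
      }
    }
  }
  diag_g <- vapply(seq_len(J), function(j) {
    c(split_rhat(g_draws[, , j]), ess_total(g_draws[, , j]))
  }, numeric(2L))
  diag_h <- vapply(1:2, function(k) {
    c(split_rhat(hyper_draws[, , k]), ess_total(hyper_draws[, , k]))
  }, numeric(2L))
  species_estimates <- data.frame(
    species = keep_sp, n_obs = n_j, raw_mean = ybar,
    g_mean = apply(cm_draws, 3L, mean),
    g_sd = apply(g_draws, 3L, stats::sd),
    sigma_mean = apply(exp(l_draws), 3L, mean),
    rhat = diag_g[1L, ], ess = diag_g[2L, ],
    stringsAsFactors = FALSE
  )
  hyper <- data.frame(
    parameter = c("g_class", "sigma_class"),
    mean = apply(hyper_draws, 3L, mean),
    rhat = diag_h[1L, ], ess = diag_h[2L, ],
    stringsAsFactors = FALSE
  )
  converged <- all(c(diag_g[1L, ], diag_h[1L, ]) < 1.01, na.rm = TRUE) &&
    all(c(diag_g[2L, ], diag_h[2L, ]) > 400, na.rm = TRUE)
  structure(list(species_estimates = species_estimates, hyper = hyper,
                 converged = converged, excluded = excluded),
            class = "growth_fit")
}

#' Fit the hierarchical survival model for one size class
#'
#' An individual of species j alive at the start of an interval of t years
#' is still alive at its end with probability `s_j^t`, where s_j is the
#' annual survival probability; observations are Bernoulli with that
#' interval-censored success probability. Species survival rates are pooled
#' through a class-level Beta(alpha, beta) distribution whose parameters are
#' estimated jointly (uniform priors on (0, 1000\]). Species rates use an
#' adaptive random-walk Metropolis step on the logit scale, vectorized over
#' species via per-species sufficient statistics (total survived years and
#' death counts per distinct interval length); the Beta parameters use a
#' joint random walk on the log scale.
#'
#' @param obs data frame with columns `species`, `alive` (0/1) and `t`
#'   (interval years) for one size class.
#' @inheritParams fit_growth_model
#' @return object of class `survival_fit`: `species_estimates` (species,
#'   n_obs, raw_annual, s_mean, s_sd, lifespan, rhat, ess), `hyper`
#'   (alpha, beta posterior means and diagnostics), `converged`, `excluded`.
#' @export
fit_survival_model <- function(obs, config = pipeline_config(), seed = 1L) {
  stopifnot(all(c("species", "alive", "t") %in% names(obs)))
  if (any(obs$t <= 0)) stop("interval lengths must be positive")
  counts <- table(obs$species)
  keep_sp <- sort(names(counts)[counts >= config$min_obs])
  excluded <- sort(names(counts)[counts < config$min_obs])
  if (length(keep_sp) == 0L) stop("no species with at least ",
                                  config$min_obs, " survival observations")
  obs <- obs[obs$species %in% keep_sp, , drop = FALSE]
  sp <- factor(obs$species, levels = keep_sp)
  J <- length(keep_sp)
  n_j <- as.numeric(table(sp))
  # sufficient statistics: years survived, deaths per distinct interval length
  A <- as.numeric(tapply(obs$t * obs$alive, sp, sum))
  tv <- sort(unique(obs$t[obs$alive == 0L]))
  D <- matrix(0, J, max(1L, length(tv)))
  if (length(tv)) {
    dead <- obs[obs$alive == 0L, , drop = FALSE]
    tab <- table(factor(dead$species, levels = keep_sp),
                 factor(dead$t, levels = tv))
    D <- matrix(as.numeric(tab), nrow = J)
  } else tv <- 1
  mean_t <- as.numeric(tapply(obs$t, sp, mean))
  raw <- pmin(pmax(as.numeric(tapply(obs$alive, sp, mean)), 1 / (n_j + 2)),
              1 - 1 / (n_j + 2))^(1 / mean_t)

  loglik <- function(theta, alpha, beta) {
    log_s <- stats::plogis(theta, log.p = TRUE)
    log_1ms <- stats::plogis(-theta, log.p = TRUE)
    lt <- outer(log_s, tv)           # J x M matrix of t * log(s)
    A * log_s + rowSums(D * log(-expm1(pmin(lt, -1e-300)))) +
      alpha * log_s + beta * log_1ms # Beta prior plus logit Jacobian
  }
  n_chains <- config$n_chains; n_iter <- config$n_iter; n_burnin <- config$n_burnin
  total <- n_iter + n_burnin
  s_draws <- array(NA_real_, c(n_iter, n_chains, J))
  hyper_draws <- array(NA_real_, c(n_iter, n_chains, 2L),
                       dimnames = list(NULL, NULL, c("alpha", "beta")))
  # hyperparameters move on (logit mean, log concentration): mu = a/(a+b),
  # kappa = a+b; the posterior is far less correlated on this scale than on
  # (log a, log b). Uniform prior on (0, 1000]^2 for (a, b); the Jacobian of
  # the reparametrization is kappa^2 mu (1 - mu).
  hyper_logpost <- function(lm, lk, s) {
    mu <- stats::plogis(lm); kappa <- exp(lk)
    a <- mu * kappa; b <- (1 - mu) * kappa
    if (a > 1000 || b > 1000 || a <= 0 || b <= 0) return(-Inf)
    sum(stats::dbeta(s, a, b, log = TRUE)) +
      2 * lk + log(mu) + log1p(-mu)
  }
  set.seed(as.integer(seed))
  for (ch in seq_len(n_chains)) {
    theta <- stats::qlogis(raw) + stats::rnorm(J, 0, 0.2)
    lm <- stats::qlogis(mean(raw)) + stats::rnorm(1L, 0, 0.2)
    lk <- log(4) + stats::rnorm(1L, 0, 0.2)
    step <- rep(0.4, J); acc <- rep(0, J)
    mstep <- 0.3; kstep <- 0.3; macc <- 0; kacc <- 0; window <- 50L
    for (it in seq_len(total)) {
      mu <- stats::plogis(lm); kappa <- exp(lk)
      alpha <- mu * kappa; beta <- (1 - mu) * kappa
      tp <- theta + stats::rnorm(J, 0, step)
      ratio <- loglik(tp, alpha, beta) - loglik(theta, alpha, beta)
      ok <- log(stats::runif(J)) < ratio
      theta[ok] <- tp[ok]
      acc <- acc + ok
      s <- stats::plogis(theta)
      cur <- hyper_logpost(lm, lk, s)
      lmp <- lm + stats::rnorm(1L, 0, mstep)
      prop <- hyper_logpost(lmp, lk, s)
      if (log(stats::runif(1L)) < prop - cur) { lm <- lmp; cur <- prop; macc <- macc + 1 }
      lkp <- lk + stats::rnorm(1L, 0, kstep)
      prop <- hyper_logpost(lm, lkp, s)
      if (log(stats::runif(1L)) < prop - cur) { lk <- lkp; kacc <- kacc + 1 }
      if (it <= n_burnin && it %% window == 0L) {
        step <- adapt_step(step, acc, window); acc <- rep(0, J)
        mstep <- adapt_step(mstep, macc, window); macc <- 0
        kstep <- adapt_step(kstep, kacc, window); kacc <- 0
      }
      if (it > n_burnin) {
        mu <- stats::plogis(lm); kappa <- exp(lk)
        s_draws[it - n_burnin, ch, ] <- stats::plogis(theta)
        hyper_draws[it - n_burnin, ch, ] <- c(mu * kappa, (1 - mu) * kappa)
      }
    }
  }
  diag_s <- vapply(seq_len(J), function(j) {
    c(split_rhat(s_draws[, , j]), ess_total(s_draws[, , j]))
  }, numeric(2L))
  diag_h <- vapply(1:2, function(k) {
    c(split_rhat(hyper_draws[, , k]), ess_total(hyper_draws[, , k]))
  }, numeric(2L))
  s_mean <- apply(s_draws, 3L, mean)
  species_estimates <- data.frame(
    species = keep_sp, n_obs = n_j, raw_annual = raw,
    s_mean = s_mean, s_sd = apply(s_draws, 3L, stats::sd),
    lifespan = lifespan_transform(s_mean),
    rhat = diag_s[1L, ], ess = diag_s[2L, ],
    stringsAsFactors = FALSE
  )
  hyper <- data.frame(
    parameter = c("alpha", "beta"),
    mean = apply(hyper_draws, 3L, mean),
    rhat = diag_h[1L, ], ess = diag_h[2L, ],
    stringsAsFactors = FALSE
  )
  converged <- all(c(diag_s[1L, ], diag_h[1L, ]) < 1.01, na.rm = TRUE) &&
    all(c(diag_s[2L, ], diag_h[2L, ]) > 400, na.rm = TRUE)
  structure(list(species_estimates = species_estimates, hyper = hyper,
                 converged = converged, excluded = excluded),
            class = "survival_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("hierarchical growth fit: %d species (%d excluded), %s\n",
              nrow(x$species_estimates), length(x$excluded),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("hierarchical survival fit: %d species (%d excluded), %s\n",
              nrow(x$species_estimates), length(x$excluded),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
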