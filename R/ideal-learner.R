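# Conjugate Bayesian ideal learner over log-ratio-of-INI series.
#
# Model: r_i ~ Normal(mu, sigma^2) with a Normal-Inverse-Chi-Squared
# conjugate prior. The uninformative setting kappa0 = 0, nu0 = -1,
# scale0 = 0 (mu0 arbitrary) makes the posterior depend on the data
# alone, MAP estimates coincide with maximum likelihood, and the
# posterior predictive for a new interval is a Student t.

#' Uninformative conjugate prior for the ideal learner
#'
#' @param mu0 prior location (irrelevant under `kappa0 = 0`).
#' @param kappa0 prior pseudo-count for the mean.
#' @param nu0 prior degrees of freedom for the variance.
#' @param scale0 prior scale for the variance.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu0 = 0, kappa0 = 0, nu0 = -1, scale0 = 0) {
  structure(list(mu0 = mu0, kappa0 = kappa0, nu0 = nu0, scale0 = scale0),
            class = "prior_spec")
}

#' Fit the conjugate posterior to a log-ratio series
#'
#' Normal-Inverse-Chi-Squared update: `kappa_n = kappa0 + n`,
#' `nu_n = nu0 + n`, `mu_n = (kappa0 mu0 + n rbar) / kappa_n`,
#' `nu_n scale_n = nu0 scale0 + ssd + kappa0 n (rbar - mu0)^2 / kappa_n`
#' with `ssd = sum (r_i - rbar)^2`. Under the default prior this gives
#' `mu_n = rbar`, `kappa_n = n`, `nu_n = n - 1`, and the point
#' estimates equal maximum likelihood: `mu_hat = rbar`,
#' `sigma2_hat = ssd / n` (the unbiased `ssd / (n - 1)` is also kept).
#'
#' @param r a `log_ratio_series` or numeric vector (`NA` dropped).
#' @param prior a [prior_spec()].
#' @return An object of class `learner_posterior` with fields `n`,
#'   `rbar`, `ssd`, `mu_n`, `kappa_n`, `nu_n`, `scale_n`, `mu_hat`,
#'   `sigma2_hat` (ML), `sigma2_unbiased`, `degenerate` flag.
#' @export
fit_posterior <- function(r, prior = prior_spec()) {
  if (inherits(r, "log_ratio_series")) r <- r$r
  r <- r[!is.na(r)]
  n <- length(r)
  if (n < 2L) stop("need at least 2 observed log-ratios (got ", n, ")")
  rbar <- mean(r)
  ssd <- sum((r - rbar)^2)
  kappa_n <- prior$kappa0 + n
  nu_n <- prior$nu0 + n
  mu_n <- (prior$kappa0 * prior$mu0 + n * rbar) / kappa_n
  scale_n <- (prior$nu0 * prior$scale0 + ssd +
                prior$kappa0 * n * (rbar - prior$mu0)^2 / kappa_n) / nu_n
  structure(list(n = n, rbar = rbar, ssd = ssd,
                 mu_n = mu_n, kappa_n = kappa_n, nu_n = nu_n,
                 scale_n = scale_n,
                 mu_hat = mu_n, sigma2_hat = ssd / n,
                 sigma2_unbiased = ssd / (n - 1),
                 # log-ratios are dimensionless; sd below 1e-10 is time-axis
                 # round-off, not linguistic variation
                 degenerate = ssd / n < 1e-20),
            class = "learner_posterior")
}

#' Posterior-predictive Student t for the next log-ratio
#'
#' Under the default prior the predictive for a new interval is
#' `t_{n-1}(rbar, s)` with squared scale
#' `s^2 = (1 + n) ssd / (n (n - 1))`, i.e. the sampling variance
#' inflated by the learner's remaining uncertainty about mu and sigma.
#'
#' @param p a `learner_posterior`.
#' @return An object of class `predictive_t`: list with `df`, `loc`,
#'   `scale2`.
#' @export
posterior_predictive <- function(p) {
  if (p$degenerate) stop("degenerate posterior (zero sum of squares)")
  structure(list(df = p$nu_n,
                 loc = p$mu_n,
                 scale2 = (1 + 1 / p$kappa_n) * p$scale_n),
            class = "predictive_t")
}

#' Predictive density
#' @param t a `predictive_t`.
#' @param x evaluation points.
#' @return density values.
#' @export
dpredictive <- function(t, x) {
  stats::dt((x - t$loc) / sqrt(t$scale2), df = t$df) / sqrt(t$scale2)
}

#' Predictive CDF
#' @param t a `predictive_t`.
#' @param x evaluation points.
#' @return probabilities.
#' @export
ppredictive <- function(t, x) {
  stats::pt((x - t$loc) / sqrt(t$scale2), df = t$df)
}

#' Differential entropy of the posterior predictive (nats)
#'
#' `h = -integral p ln p` of the location-scale Student t: for scale
#' `s` and nu degrees of freedom,
#' `h = ln(sqrt(nu) B(nu/2, 1/2)) + (nu+1)/2 (psi((nu+1)/2) - psi(nu/2))
#'  + ln s`. Lower entropy means the ideal learner predicts the next
#' relative duration more reliably; as nu grows it approaches the
#' Gaussian value `0.5 ln(2 pi e s^2)`.
#'
#' @param t a `predictive_t`.
#' @return entropy in nats.
#' @export
differential_entropy <- function(t) {
  if (!is.finite(t$scale2) || t$scale2 <= 0) stop("nonpositive squared scale")
  nu <- t$df
  h_std <- (nu + 1) / 2 * (digamma((nu + 1) / 2) - digamma(nu / 2)) +
    0.5 * log(nu) + lbeta(nu / 2, 0.5)
  h_std + 0.5 * log(t$scale2)
}

#' Sample the learner's predictions
#'
#' Simulates the generative account of prediction: draw (mu, sigma^2)
#' from the posterior — `sigma^2 = nu_n scale_n / chisq(nu_n)`,
#' `mu ~ Normal(mu_n, sigma^2 / kappa_n)` — then draw
#' `r_new ~ Normal(mu, sigma^2)`. Marginally the draws follow the
#' closed-form [posterior_predictive()] t distribution.
#'
#' @param p a `learner_posterior`.
#' @param n_draws number of predictions.
#' @param seed integer seed (reproducible; caller's RNG state is
#'   restored).
#' @return numeric vector of `r_new` draws.
#' @export
sample_predictions <- function(p, n_draws, seed = 1L) {
  if (p$degenerate) stop("degenerate posterior (zero sum of squares)")
  if (n_draws <= 0) stop("n_draws must be positive")
  with_preserved_seed(seed, {
    sigma2 <- p$nu_n * p$scale_n / stats::rchisq(n_draws, df = p$nu_n)
    mu <- stats::rnorm(n_draws, p$mu_n, sqrt(sigma2 / p$kappa_n))
    stats::rnorm(n_draws, mu, sqrt(sigma2))
  })
}

# evaluate expr under set.seed(seed), restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
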