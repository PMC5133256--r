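test_that("conjugate update under the uninformative prior", {
  p <- fit_posterior(c(-1, 0, 1))
  expect_equal(p$rbar, 0)
  expect_equal(p$ssd, 2)
  expect_equal(p$sigma2_hat, 2 / 3)
  expect_equal(p$sigma2_unbiased, 1)
  expect_equal(p$kappa_n, 3)
  expect_equal(p$nu_n, 2)
  expect_equal(p$mu_n, 0)
  expect_false(p$degenerate)

  expect_true(fit_posterior(rep(0.4, 5))$degenerate)
  expect_error(fit_posterior(c(0.1)), "at least 2")
  # NA are dropped (break-masked ratios)
  expect_equal(fit_posterior(c(-1, NA, 0, 1))$n, 3)
})

test_that("point estimates are consistent on simulated data", {
  set.seed(31)
  r <- rnorm(150, 0.02, 0.5)
  p <- fit_posterior(r)
  expect_lt(abs(p$mu_hat - 0.02), 3 * 0.5 / sqrt(150))
  se_var <- 0.25 * sqrt(2 / 149)
  expect_lt(abs(p$sigma2_hat - 0.25), 3 * se_var)
})

test_that("posterior predictive is the printed Student t", {
  p <- fit_posterior(c(-1, 0, 1))
  t <- posterior_predictive(p)
  expect_equal(t$df, 2)
  expect_equal(t$loc, 0)
  expect_equal(t$scale2, 4 / 3)  # (1+n) ssd / (n (n-1)) = 8/6

  # density at loc matches Monte-Carlo integration over the posterior
  set.seed(77)
  n_mc <- 2e5
  sigma2 <- p$nu_n * p$scale_n / rchisq(n_mc, p$nu_n)
  mu <- rnorm(n_mc, p$mu_n, sqrt(sigma2 / p$kappa_n))
  dens_mc <- mean(dnorm(0, mu, sqrt(sigma2)))
  expect_equal(dpredictive(t, 0), dens_mc, tolerance = 0.01)

  # large-n limit: t converges to Normal(rbar, ssd/n)
  set.seed(78)
  r <- rnorm(5e4, 0.1, 0.4)
  tb <- posterior_predictive(fit_posterior(r))
  xs <- seq(-1.5, 1.5, length.out = 41)
  expect_equal(dpredictive(tb, xs),
               dnorm(xs, mean(r), sd(r)), tolerance = 1e-3)
  expect_error(posterior_predictive(fit_posterior(rep(1, 4))), "degenerate")
})

test_that("differential entropy: quadrature oracle, limits, invariances", {
  # closed form vs adaptive quadrature of -int p ln p
  for (case in list(list(df = 5, scale2 = 1), list(df = 2, scale2 = 4 / 3),
                    list(df = 17, scale2 = 0.3))) {
    t <- structure(list(df = case$df, loc = 0.2, scale2 = case$scale2),
                   class = "predictive_t")
    h_num <- integrate(function(x) {
      p <- dpredictive(t, x)
      ifelse(p > 0, -p * log(p), 0)
    }, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(differential_entropy(t), h_num, tolerance = 1e-8)
  }
  # Gaussian limit
  tg <- structure(list(df = 1e7, loc = 0, scale2 = 0.25),
                  class = "predictive_t")
  expect_equal(differential_entropy(tg), 0.5 * log(2 * pi * exp(1) * 0.25),
               tolerance = 1e-6)
  # monotone in scale2; location-shift invariant
  t1 <- structure(list(df = 6, loc = 0, scale2 = 0.2), class = "predictive_t")
  t2 <- structure(list(df = 6, loc = 0, scale2 = 0.5), class = "predictive_t")
  expect_lt(differential_entropy(t1), differential_entropy(t2))
  p <- fit_posterior(c(-1, 0, 1)); ps <- fit_posterior(c(-1, 0, 1) + 5)
  expect_equal(differential_entropy(posterior_predictive(p)),
               differential_entropy(posterior_predictive(ps)))
  expect_equal(posterior_predictive(ps)$loc, 5)
})

test_that("sampled predictions match the closed-form predictive", {
  p <- fit_posterior(c(0.3, -0.2, 0.5, 0.1, -0.4, 0.2, 0.0, 0.6))
  expect_identical(sample_predictions(p, 100, seed = 9),
                   sample_predictions(p, 100, seed = 9))
  draws <- sample_predictions(p, 1e5, seed = 10)
  t <- posterior_predictive(p)
  ks <- suppressWarnings(ks.test(draws, function(x) ppredictive(t, x)))
  expect_lt(unname(ks$statistic), 0.01)
  se_mean <- sqrt(t$scale2 * t$df / (t$df - 2) / length(draws))
  expect_lt(abs(mean(draws) - p$rbar), 3 * se_mean)
  expect_error(sample_predictions(p, 0), "positive")
})

test_that("entropy recovers the configured generator variance as n grows", {
  g <- generate_language(synth_config(n_nuclei = 4000L, n_phrases = 4L,
                                      sdlog = sqrt(0.25 / 2), seed = 99L))
  lr <- log_ratio(extract_ini(g$seq))
  h <- differential_entropy(posterior_predictive(fit_posterior(lr)))
  expect_equal(h, 0.5 * log(2 * pi * exp(1) * 0.25), tolerance = 0.03)
})
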