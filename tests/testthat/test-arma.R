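test_that("AICc and Akaike weights match hand evaluation", {
  f <- list(loglik = -100, k = 2, n_eff = 50)
  expect_equal(aicc(f), 204 + 12 / 47)
  # limit: AICc -> AIC as n grows
  f$n_eff <- 1e9
  expect_equal(aicc(f), 204, tolerance = 1e-6)
  # monotone penalty in k at equal loglik
  expect_lt(aicc(list(loglik = -100, k = 2, n_eff = 50)),
            aicc(list(loglik = -100, k = 3, n_eff = 50)))
  # exclusion when n_eff <= k + 1
  expect_equal(aicc(list(loglik = -1, k = 5, n_eff = 6)), Inf)

  expect_equal(akaike_weights(100), 1)
  expect_equal(akaike_weights(c(7, 7, 7)), rep(1 / 3, 3))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(sum(akaike_weights(c(10, 12, Inf, 11))), 1)
  expect_equal(akaike_weights(c(10, Inf))[2], 0)
  expect_error(akaike_weights(c(Inf, Inf)), "no finite")
  # weights invariant to a constant shift of all AICc
  expect_equal(akaike_weights(c(3, 5, 9) + 1234), akaike_weights(c(3, 5, 9)))
})

test_that("Akaike set is the minimal cumulative-weight prefix", {
  expect_equal(akaike_set(1), 1L)
  expect_equal(sort(akaike_set(c(0.5, 0.3, 0.16, 0.04))), 1:3)
  u <- rep(1 / 72, 72)
  expect_length(akaike_set(u), ceiling(0.95 * 72))
  # cumulative-sum oracle on random weights
  set.seed(12)
  for (i in 1:5) {
    w <- akaike_weights(runif(20, 0, 30))
    idx <- akaike_set(w)
    expect_gte(sum(w[idx]), 0.95 - 1e-12)
    expect_lt(sum(w[idx]) - max(w[idx]), 0.95)  # minimality
  }
})

test_that("ARMA(0,0) without exog is the mean model", {
  set.seed(41)
  y <- rnorm(80, 2, 1)
  f <- fit_arma(y, spec = arma_spec(0, 0, 0, with_exog = FALSE))
  expect_equal(unname(f$coefficients["intercept"]), mean(y), tolerance = 0.01)
  expect_equal(f$innovation_var, var(y) * 79 / 80, tolerance = 0.05)
  expect_equal(f$k, 2)  # intercept + innovation variance
  expect_equal(f$n_eff, 80)
})

test_that("AR(1) coefficient recovery within 3 SE", {
  set.seed(42)
  y <- as.numeric(arima.sim(list(ar = 0.6), n = 300))
  f <- fit_arma(y, spec = arma_spec(1, 0, 0, with_exog = FALSE))
  se <- sqrt((1 - 0.6^2) / 300)
  expect_lt(abs(unname(f$coefficients["ar1"]) - 0.6), 3 * se)
})

test_that("missing values reduce n_eff, never raise it; exog masking", {
  set.seed(43)
  y <- rnorm(100)
  x <- rnorm(100)
  f_full <- fit_arma(y, x, arma_spec(0, 0, 0))
  y2 <- y; y2[seq(5, 95, by = 10)] <- NA
  f_miss <- fit_arma(y2, x, arma_spec(0, 0, 0))
  expect_equal(f_full$n_eff, 100)
  expect_equal(f_miss$n_eff, 90)
  expect_equal(f_full$k, 3)  # intercept + exog + variance
  # missing regressor masks the observation
  x2 <- x; x2[1:4] <- NA
  expect_equal(fit_arma(y, x2, arma_spec(0, 0, 0))$n_eff, 96)
  expect_error(fit_arma(y[1:10], x[1:10], arma_spec(0, 0, 0)), "too few")
})

test_that("exog regressor is recovered and not differenced under d = 1", {
  set.seed(44)
  n <- 400
  x <- rnorm(n, 0, 3)
  # construct y with diff(y)[t] = 0.12 x[t+1] + noise: the regressor
  # enters the differenced series undifferenced
  y <- c(0, cumsum(0.12 * x[-1] + rnorm(n - 1, 0, 0.2)))
  f <- fit_arma(y, x, arma_spec(0, 1, 0))
  expect_lt(abs(unname(f$coefficients["intensity_diff"]) - 0.12), 0.03)
  expect_equal(f$k, 2)  # exog + variance (no drift under d = 1)
})

test_that("grid enumeration and marginal weights", {
  set.seed(45)
  g <- generate_language(synth_config(n_nuclei = 120L, n_phrases = 8L,
                                      seed = 45L))
  ini <- extract_ini(g$seq)
  y <- log_ini(ini)
  x <- c(NA, ini$i[-length(ini$i)])
  mt <- grid_search(y, x, max_order = 1L)   # 2x2x2 = 8 variants
  expect_equal(nrow(mt$table), 8L)
  expect_equal(sum(mt$table$weight), 1)
  expect_equal(d1_weight_share(mt),
               100 - 100 * sum(mt$table$weight[mt$table$d == 0]))
  mw <- marginal_weights_by_p(mt)
  expect_equal(sum(mw), 1)
  # group-by oracle
  expect_equal(unname(mw["0"]), sum(mt$table$weight[mt$table$p == 0]))
  expect_equal(sort(unique(paste(mt$table$p, mt$table$d, mt$table$q))),
               sort(apply(expand.grid(0:1, 0:1, 0:1), 1,
                          function(v) paste(v[2], v[3], v[1]))))
  # serialization
  f <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(mt, f)
  back <- read.delim(f)
  expect_equal(back$aicc, mt$table$aicc)
  expect_equal(sum(back$in_akaike_set), length(mt$akaike_set))
})

test_that("best fitted model beats the white-noise baseline on structured data", {
  set.seed(46)
  cfg <- synth_config(n_nuclei = 150L, n_phrases = 3L, process = "arima",
                      arima_order = c(1L, 0L, 0L), ar = 0.7,
                      innovation_sd = 0.3, seed = 46L)
  g <- generate_language(cfg)
  ini <- extract_ini(g$seq)
  y <- log_ini(ini)
  mt <- grid_search(y, max_order = 2L, with_exog = FALSE)
  baseline <- fit_arma(y, spec = arma_spec(0, 0, 0, with_exog = FALSE))
  expect_lte(min(mt$table$aicc), baseline$aicc)
  # the generating order is inside the Akaike set
  aset <- mt$table[mt$akaike_set, ]
  expect_true(any(aset$p >= 1 & aset$d == 0))
})
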