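# ARMA(p,d,q) multi-model inference over log-INI series.
#
# The series y is the log-INI vector with NA at break-masked positions;
# x is the intensity-difference vector aligned so that x[t] is the
# intensity difference preceding y[t] (i.e. i_{t-1}). d = 1 models the
# series of relative durations (log-ratios); d = 0 absolute log
# durations. Likelihoods are exact Gaussian, computed by a Kalman
# state-space recursion that skips missing observations
# (stats::arima, method = "ML") — the engine differencing, regressor
# alignment, parameter counting, AICc and weight machinery are owned
# here.

#' ARMA model specification
#'
#' @param p AR order (0-5).
#' @param d differencing order (0 = absolute log durations, 1 =
#'   relative durations / log-ratios).
#' @param q MA order (0-5).
#' @param with_exog include the preceding intensity difference as an
#'   external regressor.
#' @return An object of class `arma_spec`.
#' @export
arma_spec <- function(p, d, q, with_exog = TRUE) {
  stopifnot(p %in% 0:5, q %in% 0:5, d %in% 0:1)
  structure(list(p = as.integer(p), d = as.integer(d), q = as.integer(q),
                 with_exog = isTRUE(with_exog)),
            class = "arma_spec")
}

#' Fit one ARMA variant to a log-INI series
#'
#' Differencing is applied to the series here (NA propagates through
#' the difference); the exogenous regressor is NOT differenced — it is
#' already a first-order intensity difference. Under `d = 1` no drift
#' term is fit by default (relative durations are mean-zero); under
#' `d = 0` an intercept is included. Observations whose regressor value
#' is missing are masked. The fit is deterministic.
#'
#' @param y numeric log-INI vector with `NA` missing marker.
#' @param x numeric intensity-difference regressor aligned with `y`
#'   (`x[t]` predicts `y[t]`), or `NULL`.
#' @param spec an [arma_spec()].
#' @param include_drift fit an intercept under `d = 1`.
#' @param min_obs minimum present observations after differencing.
#' @return An object of class `arma_fit`: `spec`, `loglik`, `k`,
#'   `n_eff`, `aicc`, `coefficients`, `innovation_var`, `converged`.
#' @export
fit_arma <- function(y, x = NULL, spec, include_drift = FALSE, min_obs = 20L) {
  stopifnot(inherits(spec, "arma_spec"))
  if (spec$with_exog && is.null(x))
    stop("spec requests the exogenous regressor but x is NULL")
  if (!is.null(x) && length(x) != length(y))
    stop("x must be aligned with y")
  if (spec$d == 1L) {
    yd <- diff(y)                       # NA propagates
    xd <- if (spec$with_exog) x[-1L] else NULL
    use_mean <- include_drift
  } else {
    yd <- y
    xd <- if (spec$with_exog) x else NULL
    use_mean <- TRUE
  }
  if (!is.null(xd)) {
    yd[is.na(xd)] <- NA                 # regressor missing -> skip obs
    xd[is.na(xd)] <- 0                  # value irrelevant once y is NA
  }
  n_eff <- sum(!is.na(yd))
  if (n_eff < min_obs)
    stop("too few present observations after differencing (", n_eff,
         " < ", min_obs, ")")
  xreg <- if (!is.null(xd)) matrix(xd, ncol = 1,
                                   dimnames = list(NULL, "intensity_diff"))
  fit <- tryCatch(
    suppressWarnings(           # optimizer excursions log NaNs; handled below
      stats::arima(yd, order = c(spec$p, 0L, spec$q), xreg = xreg,
                   include.mean = use_mean, method = "ML",
                   optim.control = list(maxit = 500))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(spec = spec, loglik = NA_real_, k = NA_integer_,
                          n_eff = n_eff, aicc = Inf, coefficients = NULL,
                          innovation_var = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "arma_fit"))
  }
  k <- spec$p + spec$q + as.integer(use_mean) +
    as.integer(spec$with_exog) + 1L     # + innovation variance
  out <- structure(list(spec = spec, loglik = as.numeric(fit$loglik), k = k,
                        n_eff = n_eff, aicc = NA_real_,
                        coefficients = stats::coef(fit),
                        innovation_var = fit$sigma2,
                        converged = fit$code == 0,
                        message = NULL),
                   class = "arma_fit")
  out$aicc <- aicc(out)
  out
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AIC = -2 loglik + 2k`; `AICc = AIC + 2k(k+1)/(n_eff - k - 1)`.
#' Returns `Inf` when `n_eff <= k + 1` (model excluded from ranking).
#'
#' @param fit an `arma_fit`, or a list with `loglik`, `k`, `n_eff`.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  if (is.na(fit$loglik)) return(Inf)
  if (fit$n_eff <= fit$k + 1L) return(Inf)
  -2 * fit$loglik + 2 * fit$k + 2 * fit$k * (fit$k + 1) / (fit$n_eff - fit$k - 1)
}

#' Akaike weights from AICc scores
#'
#' `w_hat_i = exp(-(AICc_i - min_j AICc_j)/2)`, normalized to sum to 1.
#' Infinite AICc (excluded models) get weight 0.
#'
#' @param aiccs numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  fin <- is.finite(aiccs)
  if (!any(fin)) stop("no finite AICc value")
  w <- numeric(length(aiccs))
  w[fin] <- exp(-0.5 * (aiccs[fin] - min(aiccs[fin])))
  w / sum(w)
}

#' The Akaike set: minimal top-weight models reaching cumulative 0.95
#'
#' Models are ranked by decreasing weight; ties broken by smaller
#' parameter count `k`, then smaller `p + d + q`, then lexicographic
#' `(p, d, q)`. Returns indices (into `weights`) of the minimal prefix
#' whose cumulative weight reaches the threshold.
#'
#' @param weights Akaike weights (sum 1).
#' @param threshold cumulative-weight threshold.
#' @param specs optional data.frame with columns `p`, `d`, `q`, `k` for
#'   tie-breaking; without it ties keep input order.
#' @return integer vector of model indices.
#' @export
akaike_set <- function(weights, threshold = 0.95, specs = NULL) {
  if (is.null(specs)) {
    ord <- order(-weights)
  } else {
    ord <- order(-weights, specs$k, specs$p + specs$d + specs$q,
                 specs$p, specs$d, specs$q)
  }
  cum <- cumsum(weights[ord])
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) m <- length(ord)       # numerical slack: take all
  ord[seq_len(m)]
}

#' Fit the full 72-variant ARMA grid to one language
#'
#' Enumerates p in 0..max_order, q in 0..max_order, d in 0..d_max
#' (6 x 6 x 2 = 72 variants at the defaults), all with the intensity
#' regressor when `with_exog`. Non-converged fits are kept in the table
#' with infinite AICc and weight 0, and excluded from the weight
#' normalization.
#'
#' @param y log-INI vector with `NA` marker.
#' @param x aligned intensity-difference regressor (or `NULL` with
#'   `with_exog = FALSE`).
#' @param max_order maximum AR and MA order.
#' @param d_max maximum differencing order.
#' @param with_exog include the regressor.
#' @param threshold Akaike-set cumulative threshold.
#' @param include_drift drift under d = 1 (off by default).
#' @param min_obs observation floor per fit.
#' @return An object of class `model_table`: `fits` (list of
#'   `arma_fit`), `table` (data.frame: p, d, q, loglik, k, n_eff, aicc,
#'   weight, in_akaike_set, converged), `akaike_set` (row indices),
#'   `best` (row index of min AICc), `d1_weight_percent`.
#' @export
grid_search <- function(y, x = NULL, max_order = 5L, d_max = 1L,
                        with_exog = !is.null(x), threshold = 0.95,
                        include_drift = FALSE, min_obs = 20L) {
  grid <- expand.grid(q = 0:max_order, p = 0:max_order, d = 0:d_max)
  grid <- grid[order(grid$d, grid$p, grid$q), c("p", "d", "q")]
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    fit_arma(y, x, arma_spec(grid$p[i], grid$d[i], grid$q[i],
                             with_exog = with_exog),
             include_drift = include_drift, min_obs = min_obs)
  })
  tab <- data.frame(
    p = grid$p, d = grid$d, q = grid$q,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    k = vapply(fits, function(f) as.numeric(f$k), 0),
    n_eff = vapply(fits, function(f) as.numeric(f$n_eff), 0),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    converged = vapply(fits, `[[`, TRUE, "converged")
  )
  n_bad <- sum(!tab$converged)
  if (n_bad > 0)
    message(n_bad, " of ", nrow(tab),
            " model variants did not converge and carry zero weight")
  tab$aicc[!tab$converged] <- Inf   # excluded from weight normalization
  tab$weight <- akaike_weights(tab$aicc)
  aset <- akaike_set(tab$weight, threshold, specs = tab)
  tab$in_akaike_set <- seq_len(nrow(tab)) %in% aset
  structure(list(fits = fits, table = tab, akaike_set = aset,
                 best = which.min(tab$aicc),
                 threshold = threshold),
            class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  b <- x$table[x$best, ]
  cat(sprintf("<model_table> %d variants; best (p,q)=(%d,%d), d=%d, AICc=%.2f; Akaike set size %d; d=1 share %.2f%%\n",
              nrow(x$table), b$p, b$q, b$d, b$aicc,
              length(x$akaike_set), d1_weight_share(x)))
  invisible(x)
}

#' Percentage of Akaike weight on d = 1 models
#' @param t a `model_table`.
#' @return percentage in `[0, 100]`.
#' @export
d1_weight_share <- function(t) {
  100 * sum(t$table$weight[t$table$d == 1L])
}

#' Akaike weights marginalized over d and q, by AR order p
#' @param t a `model_table`.
#' @return named vector, one entry per p value (sums to 1).
#' @export
marginal_weights_by_p <- function(t) {
  ps <- sort(unique(t$table$p))
  out <- vapply(ps, function(p) sum(t$table$weight[t$table$p == p]), 0)
  names(out) <- ps
  out
}

#' Serialize a model table to tidy TSV
#' @param t a `model_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(t, path) {
  utils::write.table(t$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
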