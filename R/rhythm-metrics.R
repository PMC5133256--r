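# Order-0/1 distributional metrics on INI series.

#' Normalized pairwise variability index over INIs
#'
#' nPVI = 100/m * sum |d_t - d_{t+1}| / (0.5 (d_t + d_{t+1})) over the m
#' adjacent pairs where both durations are present (a pair never spans a
#' break). Computed on inter-nucleus-interval durations, not syllable
#' lengths. 0 for a metronomic series; at most 100 for positive data
#' (strictly below 200 in general).
#'
#' @param d an `ini_series` or a numeric duration vector (`NA` = masked).
#' @return nPVI score.
#' @export
npvi <- function(d) {
  if (inherits(d, "ini_series")) d <- d$d
  if (length(d) < 2L) stop("need at least 2 INIs")
  a <- d[-length(d)]; b <- d[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("nPVI undefined: no valid adjacent INI pair")
  100 * mean(abs(a[ok] - b[ok]) / (0.5 * (a[ok] + b[ok])))
}

#' Kolmogorov-Smirnov distance to a moment-matched normal
#'
#' Sup-distance between the empirical CDF of `x` and the CDF of
#' Normal(mean(x), sd(x)), evaluated at both one-sided ECDF limits at
#' every sample point. Used as a descriptive non-normality measure (no
#' Lilliefors correction, no p-value).
#'
#' @param x numeric vector (durations or log-durations); `NA` dropped.
#' @param ddof degrees-of-freedom correction for the matched sd:
#'   1 (default) is the sample sd, 0 the population sd.
#' @return D in `[0, 1]`.
#' @export
ks_normality_d <- function(x, ddof = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 values")
  m <- mean(x)
  s2 <- sum((x - m)^2) / (n - ddof)
  # float round-off on a time axis leaves ~1e-16 jitter in "equal" INIs
  if (s2 <= 0 || sqrt(s2) <= 1e-10 * max(abs(m), 1))
    stop("degenerate input: zero variance")
  xs <- sort(x)
  cdf <- stats::pnorm(xs, m, sqrt(s2))
  max(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness z-score (D'Agostino's transformed sqrt(b1))
#' and the kurtosis z-score (Anscombe-Glynn) into K2 = z_s^2 + z_k^2,
#' chi-squared with 2 df under normality. Requires n >= 8 for the
#' skewness transformation to be defined.
#'
#' @param x numeric vector; `NA` dropped.
#' @return list with `statistic` (K2) and `p.value` (two-sided).
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test needs n >= 8 (got ", n, ")")
  if (stats::sd(x) <= 1e-10 * max(abs(mean(x)), 1))
    stop("degenerate input: zero variance")
  zs <- dp_skew_z(x)
  zk <- dp_kurt_z(x)
  k2 <- zs^2 + zk^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

# skewness z (D'Agostino 1970 transformation of g1)
dp_skew_z <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  delta * asinh(y / alpha)  # log(u + sqrt(u^2+1)); continuous 0 at y = 0
}

# kurtosis z (Anscombe & Glynn 1983)
dp_kurt_z <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  z1 <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  t1 <- 1 - 2 / (9 * a)
  denom <- 1 + z1 * sqrt(2 / (a - 4))
  t2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  (t1 - t2) / sqrt(2 / (9 * a))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with any `NA`
#'   are dropped.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}
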