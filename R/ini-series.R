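# Inter-nucleus-interval (INI) series: the duration vector D and
# intensity-difference vector I of one language, with intervals spanning
# an annotated break (or an audio-part boundary) replaced by NA rather
# than dropped, so the series keeps its temporal alignment.

#' Extract the INI series from an annotation sequence
#'
#' For nuclei s = 1..n, `d[s] = time(s+1) - time(s)` (seconds) and
#' `i[s] = intensity(s+1) - intensity(s)` (dB). Any interval that
#' contains a phrase/sentence break, or whose endpoints lie in different
#' audio parts, is masked `NA` in both vectors — the break interrupts the
#' rhythm, but positions are kept so downstream time-series models see
#' the gap. A rhythmic phrase is a maximal run of nuclei with no break
#' between them; singleton phrases contribute no INIs but are counted.
#'
#' @param seq an [annotation_seq()].
#' @return An object of class `ini_series`: list with `d`, `i` (length
#'   `n_nuclei - 1`), `n_nuclei`, `n_phrases`.
#' @export
extract_ini <- function(seq) {
  ev <- seq$events
  nuc <- which(ev$kind == "nucleus")
  if (length(nuc) < 2L)
    stop("need at least 2 nuclei to form an INI series (got ", length(nuc), ")")
  n <- length(nuc)
  d <- i <- rep(NA_real_, n - 1L)
  # phrase bookkeeping: a new phrase starts at the first nucleus and after
  # every masked interval
  masked <- logical(n - 1L)
  for (s in seq_len(n - 1L)) {
    a <- nuc[s]; b <- nuc[s + 1L]
    cross_part <- ev$part[a] != ev$part[b]
    has_break <- b > a + 1L && any(ev$kind[(a + 1L):(b - 1L)] != "nucleus")
    if (cross_part || has_break) {
      masked[s] <- TRUE
    } else {
      d[s] <- ev$time[b] - ev$time[a]
      i[s] <- ev$intensity[b] - ev$intensity[a]
      if (d[s] <= 0) stop("nonpositive INI at nucleus ", s)
    }
  }
  structure(list(d = d, i = i, n_nuclei = n,
                 n_phrases = 1L + sum(masked)),
            class = "ini_series")
}

#' @export
print.ini_series <- function(x, ...) {
  cat(sprintf("<ini_series> %d nuclei, %d phrases, %d/%d INIs present (median %.0f ms)\n",
              x$n_nuclei, x$n_phrases, sum(!is.na(x$d)), length(x$d),
              1000 * stats::median(x$d, na.rm = TRUE)))
  invisible(x)
}

#' Natural-log INI durations
#'
#' Log duration is the working scale of the analysis: differences of
#' logs are ratios of durations, which abstracts over speaking rate.
#' Missing values propagate.
#'
#' @param s an `ini_series`.
#' @return numeric vector of `log(d)` with `NA` preserved.
#' @export
log_ini <- function(s) {
  d <- s$d
  if (any(!is.na(d) & d <= 0)) stop("nonpositive INI duration")
  log(d)
}

#' Log-ratios of adjacent INIs
#'
#' `r[s] = log d[s+1] - log d[s]`, defined only where both neighbours
#' are present (no pair spans a break). Equal adjacent INIs give 0; the
#' series is invariant to uniform time rescaling.
#'
#' @param s an `ini_series`.
#' @return An object of class `log_ratio_series`: list with `r`
#'   (length `length(d) - 1`) and `n_obs` (present values).
#' @export
log_ratio <- function(s) {
  ld <- log_ini(s)
  r <- if (length(ld) >= 2L) diff(ld) else numeric()
  structure(list(r = r, n_obs = sum(!is.na(r))), class = "log_ratio_series")
}

#' Median INI in milliseconds
#'
#' Computed over present durations only, linear-interpolation quantile
#' convention (R type 7).
#'
#' @param s an `ini_series`.
#' @return median INI in ms.
#' @export
median_ini_ms <- function(s) {
  1000 * unname(stats::quantile(s$d, 0.5, na.rm = TRUE, type = 7))
}
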