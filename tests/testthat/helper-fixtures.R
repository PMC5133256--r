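# Builders for tiny in-code fixtures.

# sequence from nucleus times (+ optional break times) in one part
make_seq <- function(times, intensities = NULL, breaks = numeric(),
                     break_kind = "phrase_break", iso = "xxx", ann = "tt") {
  if (is.null(intensities)) intensities <- seq(70, by = 0.5,
                                               length.out = length(times))
  ev <- rbind(
    data.frame(part = 1L, time = times, kind = "nucleus",
               intensity = intensities),
    if (length(breaks))
      data.frame(part = 1L, time = breaks, kind = break_kind,
                 intensity = NA_real_)
  )
  ev <- ev[order(ev$time), ]
  annotation_seq(ev, iso, ann)
}

# independent brute-force DTW over all monotone step paths (tiny inputs)
brute_dtw <- function(a, b) {
  best <- list(cost = Inf, sse = NA_real_)
  recurse <- function(i, j, cost, sse) {
    cost <- cost + abs(a[i] - b[j])
    sse <- sse + (a[i] - b[j])^2
    if (cost >= best$cost) return()
    if (i == length(a) && j == length(b)) {
      best <<- list(cost = cost, sse = sse)
      return()
    }
    if (i < length(a) && j < length(b)) recurse(i + 1, j + 1, cost, sse)
    if (i < length(a)) recurse(i + 1, j, cost, sse)
    if (j < length(b)) recurse(i, j + 1, cost, sse)
  }
  recurse(1, 1, 0, 0)
  best
}

# exhaustive ECDF-vs-CDF KS oracle
brute_ks <- function(x, ddof = 1) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - ddof))
  xs <- sort(x)
  dmax <- 0
  for (i in seq_len(n)) {
    f <- pnorm(xs[i], m, s)
    dmax <- max(dmax, abs(i / n - f), abs((i - 1) / n - f))
  }
  dmax
}

quick_cfg <- function(...) pipeline_config(arma_max_order = 1L, ...)
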