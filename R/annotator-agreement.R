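# Inter-annotator agreement: dynamic-time-warping alignment of two
# annotators' nucleus timing sequences, scored by the sum of squared
# time differences over matched pairs, with the 10x separation check
# between same-language and cross-language pairs.

#' Dynamic-time-warping alignment of two nucleus time sequences
#'
#' Classic DP over the `|t_a - t_b|` cost matrix with steps (1,0),
#' (0,1), (1,1) and matched endpoints. The optimal path minimizes
#' total absolute time difference; the agreement statistic `sse` is
#' the sum of squared differences over the matched pairs of that path.
#' Break events should be excluded before calling (only nuclei are
#' aligned); [nucleus_times()] does this.
#'
#' @param a,b numeric vectors of nucleus times (seconds), nonempty.
#' @return An object of class `dtw_alignment`: `path` (two-column
#'   matrix of matched indices into `a` and `b`), `cost` (total
#'   absolute-difference path cost), `sse` (seconds^2).
#' @export
dtw_align <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("empty nucleus sequence")
  cost <- abs(outer(a, b, "-"))
  acc <- matrix(Inf, n + 1L, m + 1L)
  acc[1L, 1L] <- 0
  for (i in seq_len(n)) {
    row <- acc[i + 1L, ]
    prev <- acc[i, ]
    for (j in seq_len(m)) {
      row[j + 1L] <- cost[i, j] + min(prev[j], prev[j + 1L], row[j])
    }
    acc[i + 1L, ] <- row
  }
  # backtrack (prefer diagonal on ties, then the (1,0) step)
  path <- matrix(0L, n + m, 2L)
  i <- n; j <- m; s <- 0L
  while (i >= 1L && j >= 1L) {
    s <- s + 1L
    path[s, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    cand <- c(diag = acc[i, j], up = acc[i, j + 1L], left = acc[i + 1L, j])
    if (i == 1L) step <- "left" else if (j == 1L) step <- "up"
    else step <- names(cand)[which.min(cand)]
    if (step == "diag") { i <- i - 1L; j <- j - 1L }
    else if (step == "up") i <- i - 1L
    else j <- j - 1L
  }
  path <- path[s:1, , drop = FALSE]
  structure(list(path = path,
                 cost = acc[n + 1L, m + 1L],
                 sse = sum((a[path[, 1L]] - b[path[, 2L]])^2)),
            class = "dtw_alignment")
}

#' Nucleus times of an annotation sequence
#'
#' Concatenates nucleus event times across parts, offsetting each part
#' so parts do not overlap (parts are separate recordings; the offset
#' keeps times monotone for alignment).
#'
#' @param seq an [annotation_seq()].
#' @return numeric vector of times in seconds.
#' @export
nucleus_times <- function(seq) {
  ev <- seq$events[seq$events$kind == "nucleus", ]
  if (!nrow(ev)) return(numeric())
  offset <- 0
  out <- numeric(0)
  for (p in unique(ev$part)) {
    tt <- ev$time[ev$part == p]
    out <- c(out, tt + offset)
    offset <- offset + max(tt) + 1
  }
  out
}

#' Same- vs cross-group DTW agreement summary
#'
#' Computes the DTW sum of squared errors for each pair and reports
#' `ratio = min(cross-group sse) / max(same-group sse)`. The
#' separation check passes when the ratio is at least `min_ratio`
#' (cross-language or random alignments must be at least 10 times
#' worse than two annotators on the same recording).
#'
#' @param same_pairs,cross_pairs lists of pairs; each pair is a list
#'   of two nucleus time vectors (or two `annotation_seq` objects).
#' @param min_ratio required separation factor.
#' @return list with `same_sse`, `cross_sse`, `ratio`, `pass`.
#' @export
agreement_report <- function(same_pairs, cross_pairs, min_ratio = 10) {
  if (!length(same_pairs) || !length(cross_pairs))
    stop("need at least one pair per group")
  sse_of <- function(pair) {
    v <- lapply(pair, function(x)
      if (inherits(x, "annotation_seq")) nucleus_times(x) else x)
    dtw_align(v[[1L]], v[[2L]])$sse
  }
  same <- vapply(same_pairs, sse_of, 0)
  cross <- vapply(cross_pairs, sse_of, 0)
  ratio <- if (max(same) == 0) Inf else min(cross) / max(same)
  list(same_sse = same, cross_sse = cross, ratio = ratio,
       pass = ratio >= min_ratio)
}
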