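# Per-language and corpus analysis pipeline: runs the INI extraction,
# order-0 metrics, ideal-learner and ARMA stages, and assembles the
# per-language report row and corpus aggregates.

#' Default pipeline configuration
#'
#' @param arma_max_order maximum AR/MA order for the grid (5 gives the
#'   full 72-variant grid; lower it for quick runs).
#' @param arma_d_max maximum differencing order.
#' @param akaike_threshold cumulative weight threshold of the Akaike
#'   set.
#' @param arma_min_obs observation floor for an ARMA fit.
#' @param with_exog use the intensity-difference regressor.
#' @param ks_on_log compute the KS non-normality D on log-INIs instead
#'   of raw INIs.
#' @param run_arma set `FALSE` to skip the (slow) ARMA stage.
#' @return named list.
#' @export
pipeline_config <- function(arma_max_order = 5L, arma_d_max = 1L,
                            akaike_threshold = 0.95, arma_min_obs = 20L,
                            with_exog = TRUE, ks_on_log = FALSE,
                            run_arma = TRUE) {
  list(arma_max_order = arma_max_order, arma_d_max = arma_d_max,
       akaike_threshold = akaike_threshold, arma_min_obs = arma_min_obs,
       with_exog = with_exog, ks_on_log = ks_on_log, run_arma = run_arma)
}

#' Analyze one language
#'
#' Runs the full per-language pipeline: INI extraction, median INI,
#' KS non-normality D, nPVI, D'Agostino-Pearson normality p of the
#' log-ratios, ideal-learner posterior and differential entropy, and
#' the ARMA multi-model grid. A stage that cannot run (too few
#' observations, degenerate data) leaves its fields `NA` and logs the
#' reason; the pipeline continues.
#'
#' @param seq an [annotation_seq()].
#' @param config a [pipeline_config()].
#' @return one-row data.frame (`language_report`): language_iso,
#'   n_nuclei, n_phrases, median_ini_ms, ks_d, npvi, normality_p,
#'   lr_ini_mean, lr_ini_variance, lr_ini_variance_unbiased,
#'   differential_entropy, best_p, best_q, best_d, akaike_set_size,
#'   d1_weight_percent. Stage messages in attribute `"log"`; the full
#'   `model_table` in attribute `"model_table"`.
#' @export
analyze_language <- function(seq, config = pipeline_config()) {
  log_msgs <- character()
  note <- function(field, e) {
    log_msgs <<- c(log_msgs, paste0(field, ": ", conditionMessage(e)))
    NA_real_
  }
  row <- data.frame(
    language_iso = seq$language_iso, n_nuclei = n_nuclei(seq),
    n_phrases = NA_integer_, median_ini_ms = NA_real_, ks_d = NA_real_,
    npvi = NA_real_, normality_p = NA_real_, lr_ini_mean = NA_real_,
    lr_ini_variance = NA_real_, lr_ini_variance_unbiased = NA_real_,
    differential_entropy = NA_real_, best_p = NA_integer_,
    best_q = NA_integer_, best_d = NA_integer_,
    akaike_set_size = NA_integer_, d1_weight_percent = NA_real_,
    stringsAsFactors = FALSE)
  mt <- NULL
  ini <- tryCatch(extract_ini(seq), error = function(e) { note("ini", e); NULL })
  if (!is.null(ini)) {
    row$n_phrases <- ini$n_phrases
    row$median_ini_ms <- tryCatch(median_ini_ms(ini),
                                  error = function(e) note("median", e))
    ks_input <- if (config$ks_on_log) log_ini(ini) else ini$d
    row$ks_d <- tryCatch(ks_normality_d(ks_input),
                         error = function(e) note("ks_d", e))
    row$npvi <- tryCatch(npvi(ini), error = function(e) note("npvi", e))
    lr <- log_ratio(ini)
    row$normality_p <- tryCatch(dagostino_pearson(lr$r)$p.value,
                                error = function(e) note("normality_p", e))
    post <- tryCatch(fit_posterior(lr),
                     error = function(e) { note("posterior", e); NULL })
    if (!is.null(post)) {
      row$lr_ini_mean <- post$mu_hat
      row$lr_ini_variance <- post$sigma2_hat
      row$lr_ini_variance_unbiased <- post$sigma2_unbiased
      row$differential_entropy <- tryCatch(
        differential_entropy(posterior_predictive(post)),
        error = function(e) note("entropy", e))
    }
    if (isTRUE(config$run_arma)) {
      y <- log_ini(ini)
      x <- if (config$with_exog) c(NA, ini$i[-length(ini$i)]) else NULL
      mt <- tryCatch(
        grid_search(y, x, max_order = config$arma_max_order,
                    d_max = config$arma_d_max,
                    with_exog = config$with_exog,
                    threshold = config$akaike_threshold,
                    min_obs = config$arma_min_obs),
        error = function(e) { note("arma", e); NULL })
      if (!is.null(mt)) {
        b <- mt$table[mt$best, ]
        row$best_p <- b$p; row$best_q <- b$q; row$best_d <- b$d
        row$akaike_set_size <- length(mt$akaike_set)
        row$d1_weight_percent <- d1_weight_share(mt)
      }
    }
  }
  structure(row, log = log_msgs, model_table = mt,
            class = c("language_report", "data.frame"))
}

#' Analyze a corpus of languages
#'
#' @param seqs list of [annotation_seq()] objects (>= 2 for the
#'   correlation aggregates).
#' @param config a [pipeline_config()].
#' @return An object of class `corpus_report`: list with `rows`
#'   (stacked per-language data.frame) and `aggregates`: Spearman rho
#'   of (ks_d, npvi), mean entropy, counts below the mean and below
#'   0.9, mean log-ratio variance, and nucleus-count median/Q1/Q3
#'   (linear-interpolation quantiles).
#' @export
analyze_corpus <- function(seqs, config = pipeline_config()) {
  rows <- do.call(rbind, lapply(seqs, function(s) {
    r <- analyze_language(s, config)
    attributes(r)[c("log", "model_table")] <- NULL
    class(r) <- "data.frame"
    r
  }))
  rownames(rows) <- NULL
  corpus_report(rows)
}

#' Assemble a corpus report from per-language rows
#'
#' Aggregates are recomputable from the rows; this constructor is also
#' the recomputation path used to check published summary claims
#' against a printed per-language table.
#'
#' @param rows data.frame with at least `ks_d`, `npvi`,
#'   `differential_entropy`, `lr_ini_variance`, `n_nuclei` columns.
#' @return a `corpus_report`.
#' @export
corpus_report <- function(rows) {
  ent <- rows$differential_entropy
  agg <- list(
    spearman_d_npvi = if (sum(stats::complete.cases(rows[c("ks_d", "npvi")])) >= 3)
      spearman_rho(rows$ks_d, rows$npvi) else NA_real_,
    mean_entropy = mean(ent, na.rm = TRUE),
    max_entropy = if (all(is.na(ent))) NA_real_ else max(ent, na.rm = TRUE),
    n_below_mean_entropy = sum(ent < mean(ent, na.rm = TRUE), na.rm = TRUE),
    n_below_0_9 = sum(ent < 0.9, na.rm = TRUE),
    mean_variance = mean(rows$lr_ini_variance, na.rm = TRUE),
    nuclei_median_q1_q3 = unname(stats::quantile(
      rows$n_nuclei, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7))
  )
  structure(list(rows = rows, aggregates = agg), class = "corpus_report")
}

#' @export
print.corpus_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<corpus_report> %d languages\n", nrow(x$rows)))
  cat(sprintf("  Spearman(KS-D, nPVI) = %.2f\n", a$spearman_d_npvi))
  cat(sprintf("  entropy: mean %.2f, max %.2f, %d below mean, %d below 0.9\n",
              a$mean_entropy, a$max_entropy, a$n_below_mean_entropy,
              a$n_below_0_9))
  cat(sprintf("  mean LR-INI variance %.2f; nuclei median/Q1/Q3 = %.0f/%.0f/%.0f\n",
              a$mean_variance, a$nuclei_median_q1_q3[1],
              a$nuclei_median_q1_q3[2], a$nuclei_median_q1_q3[3]))
  invisible(x)
}

#' Write a corpus report
#'
#' Emits a human-readable TSV at table precision (values rounded at
#' serialization only) and, alongside it, a full-precision JSON
#' (`<path>.json`) from which [read_report()] reproduces the in-memory
#' report exactly.
#'
#' @param report a `corpus_report`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  rows <- report$rows
  disp <- rows
  num3 <- c("ks_d", "lr_ini_mean", "lr_ini_variance",
            "lr_ini_variance_unbiased", "differential_entropy")
  for (cn in intersect(num3, names(disp))) disp[[cn]] <- round(disp[[cn]], 3)
  for (cn in intersect(c("npvi", "d1_weight_percent", "normality_p"),
                       names(disp))) disp[[cn]] <- round(disp[[cn]], 2)
  if ("median_ini_ms" %in% names(disp))
    disp$median_ini_ms <- round(disp$median_ini_ms)
  utils::write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rows = rows, aggregates = report$aggregates),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a corpus report written by [write_report()]
#' @param path the TSV path passed to [write_report()] (the JSON
#'   companion `<path>.json` is the authoritative source).
#' @return a `corpus_report`.
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rep <- corpus_report(as.data.frame(j$rows))
  rep
}
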