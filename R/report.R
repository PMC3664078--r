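#' Analyse one recording across parameters
#'
#' Runs [analyze_parameter()] for each requested parameter and summarises
#' the inter-extrema frequencies and amplitudes with [summarize_group()].
#'
#' @param series A [beat_series].
#' @param parameters Character vector of parameter names
#'   (default: all of [beat_parameters()]).
#' @return An object of class `analysis_report`: list with `summary` (data
#'   frame, one row per parameter: `n_extrema`, `n_pairs`, and
#'   median/quartiles/mean/SD of frequency and amplitude; `NA` when fewer
#'   than 2 pairs), `metrics` (named list of `extrema_metrics`), and
#'   `meta` (subject, phase, group, beat count, duration).
#' @export
analyze_series <- function(series, parameters = beat_parameters()) {
  stopifnot(inherits(series, "beat_series"))
  parameters <- vapply(parameters, check_parameter, character(1))
  metrics <- lapply(parameters, function(p) analyze_parameter(series, p))
  names(metrics) <- parameters
  summary <- do.call(rbind, lapply(parameters, function(p) {
    m <- metrics[[p]]
    row <- data.frame(parameter = p,
                      n_extrema = nrow(m$extrema),
                      n_pairs = length(m$intervals))
    for (metric in c("frequency", "amplitude")) {
      v <- if (metric == "frequency") m$frequencies else m$amplitudes
      if (length(v) >= 2) {
        s <- summarize_group(v)
        vals <- c(s$median, s$q1, s$q3, s$mean, s$sd)
      } else vals <- rep(NA_real_, 5)
      names(vals) <- paste0(metric, "_", c("median", "q1", "q3", "mean", "sd"))
      row <- cbind(row, as.data.frame(as.list(vals)))
    }
    row
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, metrics = metrics,
                 meta = list(subject_id = attr(series, "subject_id"),
                             phase = attr(series, "phase"),
                             group = attr(series, "group"),
                             n_beats = nrow(series),
                             duration_s = if (nrow(series) > 0)
                               diff(range(series$time_s)) else 0)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<analysis_report> subject=%s phase=%s: %d beats over %.0f s\n",
              m$subject_id, m$phase, m$n_beats, m$duration_s))
  print(x$summary, digits = 3)
  invisible(x)
}

# internal: "median (q1-q3)" cell with 3 significant figures
format_cell <- function(median, q1, q3) {
  ifelse(is.na(median), "NC",
         sprintf("%s (%s-%s)", signif(median, 3), signif(q1, 3),
                 signif(q3, 3)))
}

#' Compare two recordings parameter by parameter
#'
#' For each parameter, the inter-extrema frequency sequences of the two
#' recordings are compared with [compare_groups()], and likewise the
#' amplitude sequences — mirroring the frequency/amplitude rows of a
#' two-subject haemodynamic comparison table. A parameter with fewer than 2
#' extrema pairs on either side is marked not computable (`NC`) and the run
#' continues.
#'
#' @param series_a,series_b Two [beat_series] objects.
#' @param parameters Parameters to compare (default all).
#' @param alpha Significance level.
#' @return An object of class `comparison_report`: list with `table` (data
#'   frame: `parameter`, `metric`, group medians/quartiles, formatted
#'   `a_cell`/`b_cell`, `test`, `statistic`, `p_value`, `significant`),
#'   `comparisons` (nested list of `comparison_result`), and `meta`.
#' @export
compare_series <- function(series_a, series_b,
                           parameters = beat_parameters(), alpha = 0.05) {
  stopifnot(inherits(series_a, "beat_series"),
            inherits(series_b, "beat_series"))
  parameters <- vapply(parameters, check_parameter, character(1))
  rep_a <- analyze_series(series_a, parameters)
  rep_b <- analyze_series(series_b, parameters)
  comparisons <- list()
  rows <- list()
  for (p in parameters) {
    ma <- rep_a$metrics[[p]]; mb <- rep_b$metrics[[p]]
    for (metric in c("frequency", "amplitude")) {
      va <- if (metric == "frequency") ma$frequencies else ma$amplitudes
      vb <- if (metric == "frequency") mb$frequencies else mb$amplitudes
      if (length(va) >= 2 && length(vb) >= 2) {
        cmp <- compare_groups(va, vb, alpha = alpha)
        comparisons[[p]][[metric]] <- cmp
        rows[[paste(p, metric)]] <- data.frame(
          parameter = p, metric = metric,
          a_median = cmp$group_a$median, a_q1 = cmp$group_a$q1,
          a_q3 = cmp$group_a$q3,
          b_median = cmp$group_b$median, b_q1 = cmp$group_b$q1,
          b_q3 = cmp$group_b$q3,
          a_cell = format_cell(cmp$group_a$median, cmp$group_a$q1,
                               cmp$group_a$q3),
          b_cell = format_cell(cmp$group_b$median, cmp$group_b$q1,
                               cmp$group_b$q3),
          test = cmp$test_name, statistic = cmp$statistic,
          p_value = cmp$p_value, significant = cmp$significant)
      } else {
        rows[[paste(p, metric)]] <- data.frame(
          parameter = p, metric = metric,
          a_median = NA_real_, a_q1 = NA_real_, a_q3 = NA_real_,
          b_median = NA_real_, b_q1 = NA_real_, b_q3 = NA_real_,
          a_cell = "NC", b_cell = "NC", test = "NC",
          statistic = NA_real_, p_value = NA_real_, significant = NA)
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, comparisons = comparisons,
                 meta = list(a = rep_a$meta, b = rep_b$meta, alpha = alpha)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> A: %s (%d beats) vs B: %s (%d beats)\n",
              x$meta$a$subject_id, x$meta$a$n_beats,
              x$meta$b$subject_id, x$meta$b$n_beats))
  print(x$table[c("parameter", "metric", "a_cell", "b_cell", "test",
                  "p_value")], digits = 3)
  invisible(x)
}

#' Write an analysis or comparison report (plus per-pair values) to CSV
#'
#' The summary table goes to `path`; for an `analysis_report`, the raw
#' per-pair metrics (full precision) go to a companion file
#' `<path-sans-ext>_pairs.csv`.
#'
#' @param report An `analysis_report` or `comparison_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "analysis_report")) {
    utils::write.csv(report$summary, path, row.names = FALSE)
    pairs <- do.call(rbind, lapply(report$metrics, metrics_table))
    utils::write.csv(pairs,
                     paste0(tools::file_path_sans_ext(path), "_pairs.csv"),
                     row.names = FALSE)
  } else if (inherits(report, "comparison_report")) {
    utils::write.csv(report$table, path, row.names = FALSE)
  } else stop("unsupported report object", call. = FALSE)
  invisible(path)
}
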