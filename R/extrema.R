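#' Detect strict local extrema in a beat-indexed sequence
#'
#' An interior point is a local maximum when it is strictly greater than both
#' neighbours, and a local minimum when strictly smaller than both. Equality
#' with either neighbour disqualifies a point, so flat plateaus produce no
#' extrema; comparisons are exact floating-point comparisons (no tolerance).
#' The first and last points have a single neighbour and never qualify.
#'
#' @param values Numeric sequence of per-beat parameter values, length >= 3.
#' @param times Strictly increasing beat times in seconds, same length as
#'   `values`.
#' @return A data frame of class `extrema_points` with columns `index`
#'   (1-based position in `values`, always in `2:(n-1)`), `time`, `value` and
#'   `kind` (`"maximum"` or `"minimum"`), ordered by index.
#' @examples
#' find_extrema(c(2, 5, 3, 4, 1), 0:4)
#' @export
find_extrema <- function(values, times) {
  if (length(values) != length(times))
    stop("`values` and `times` must have equal length", call. = FALSE)
  if (!all(is.finite(values)) || !all(is.finite(times)))
    stop("`values` and `times` must be finite", call. = FALSE)
  check_times(times)
  values <- as.numeric(values)
  times <- as.numeric(times)
  n <- length(values)
  if (n < 3) {
    warning("sequence shorter than 3 points: no extrema can be detected",
            call. = FALSE)
    return(empty_extrema())
  }
  mid <- values[2:(n - 1)]
  lo <- values[1:(n - 2)]
  hi <- values[3:n]
  is_max <- mid > lo & mid > hi
  is_min <- mid < lo & mid < hi
  idx <- which(is_max | is_min) + 1L
  if (length(idx) == 0) return(empty_extrema())
  structure(data.frame(index = idx,
                       time = times[idx],
                       value = values[idx],
                       kind = ifelse(is_max[idx - 1L], "maximum", "minimum")),
            class = c("extrema_points", "data.frame"))
}

empty_extrema <- function() {
  structure(data.frame(index = integer(0), time = numeric(0),
                       value = numeric(0), kind = character(0)),
            class = c("extrema_points", "data.frame"))
}

#' Time elapsed between consecutive extrema
#'
#' @param extrema An `extrema_points` data frame ordered by time (as returned
#'   by [find_extrema()]).
#' @return Numeric vector of length `nrow(extrema) - 1` (empty when fewer
#'   than 2 extrema); element i is `time[i+1] - time[i]`, always positive.
#' @export
inter_extrema_intervals <- function(extrema) {
  if (nrow(extrema) < 2) return(numeric(0))
  if (is.unsorted(extrema$time, strictly = TRUE))
    stop("extrema must be strictly ordered by time", call. = FALSE)
  as.numeric(diff(extrema$time))
}

#' Inter-extrema frequencies
#'
#' The frequency of change between consecutive extrema: F = 1 / t, in Hz,
#' where t is the elapsed time between the pair in seconds.
#'
#' @param intervals Positive inter-extrema intervals in seconds.
#' @return Numeric vector of frequencies in Hz, same length.
#' @export
extrema_frequencies <- function(intervals) {
  bad <- which(!is.finite(intervals) | intervals <= 0)
  if (length(bad) > 0)
    stop("non-positive interval at pair ", bad[1],
         " (duplicate beat times upstream?)", call. = FALSE)
  1 / intervals
}

#' Inter-extrema amplitudes
#'
#' Absolute value difference between consecutive extrema. Reported as
#' absolute values for consistency with summary tables; the signed change is
#' recoverable from the extrema kinds.
#'
#' @inheritParams inter_extrema_intervals
#' @return Numeric vector of length `nrow(extrema) - 1`, all >= 0.
#' @export
extrema_amplitudes <- function(extrema) {
  if (nrow(extrema) < 2) return(numeric(0))
  as.numeric(abs(diff(extrema$value)))
}

#' Extrema-points metrics for one haemodynamic parameter
#'
#' Composes [find_extrema()], [inter_extrema_intervals()],
#' [extrema_frequencies()] and [extrema_amplitudes()] on one parameter of a
#' beat series. Intervals are computed between all consecutive extrema
#' regardless of kind (maximum-to-minimum and minimum-to-maximum transitions
#' both count), using actual beat times so frequencies are in true Hz.
#'
#' @param series A [beat_series].
#' @param parameter One of [beat_parameters()].
#' @return An object of class `extrema_metrics`: list with elements
#'   `parameter`, `extrema` (the `extrema_points` data frame), `intervals`
#'   (s), `frequencies` (Hz) and `amplitudes` (parameter units), the last
#'   three of common length `nrow(extrema) - 1` (0 when fewer than 2 extrema).
#' @export
analyze_parameter <- function(series, parameter) {
  stopifnot(inherits(series, "beat_series"))
  parameter <- check_parameter(parameter)
  values <- beat_values(series, parameter)
  ex <- find_extrema(values, series$time_s)
  intervals <- inter_extrema_intervals(ex)
  structure(list(parameter = parameter,
                 extrema = ex,
                 intervals = intervals,
                 frequencies = if (length(intervals))
                   extrema_frequencies(intervals) else numeric(0),
                 amplitudes = extrema_amplitudes(ex)),
            class = "extrema_metrics")
}

#' @export
print.extrema_metrics <- function(x, ...) {
  cat(sprintf("<extrema_metrics> parameter=%s: %d extrema, %d pairs\n",
              x$parameter, nrow(x$extrema), length(x$intervals)))
  if (length(x$frequencies) > 0)
    cat(sprintf("  median frequency %.3f Hz, median amplitude %.3g\n",
                stats::median(x$frequencies), stats::median(x$amplitudes)))
  invisible(x)
}

#' Per-pair metrics table
#'
#' Long-format table of every consecutive extrema pair, suitable for export.
#'
#' @param metrics An `extrema_metrics` object.
#' @return Data frame with columns `parameter`, `pair_index`, `t_start_s`,
#'   `t_end_s`, `interval_s`, `frequency_hz`, `amplitude`.
#' @export
metrics_table <- function(metrics) {
  stopifnot(inherits(metrics, "extrema_metrics"))
  k <- length(metrics$intervals)
  data.frame(parameter = rep(metrics$parameter, k),
             pair_index = seq_len(k),
             t_start_s = metrics$extrema$time[seq_len(k)],
             t_end_s = metrics$extrema$time[seq_len(k) + 1L],
             interval_s = metrics$intervals,
             frequency_hz = metrics$frequencies,
             amplitude = metrics$amplitudes)
}

#' Ohm's-law flow variation
#'
#' Blood flow as pressure gradient over resistance, Q = (p1 - p2) / R, with
#' the venous pressure `p2` defaulting to 0 (constant-venous-pressure
#' assumption). Illustrates how high pressure variation combined with low
#' resistance variation implies high flow variation.
#'
#' @param delta_p Pressure gradient in mmHg (or `p1` when `p2` is given).
#' @param resistance Vascular resistance, > 0 (MU).
#' @param p2 Optional venous pressure subtracted from `delta_p`.
#' @return Flow in mmHg/MU units.
#' @export
flow_variation <- function(delta_p, resistance, p2 = 0) {
  if (any(!is.finite(resistance) | resistance <= 0))
    stop("`resistance` must be > 0", call. = FALSE)
  (delta_p - p2) / resistance
}
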