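#' Canonical beat-by-beat CSV columns
#'
#' Column order and names of the beat-by-beat CSV dialect: one row per heart
#' beat, units encoded in the header. `time_s`, `sbp_mmhg` and `dbp_mmhg` are
#' required on input; the remaining columns are derived when absent.
#'
#' @format Character vector of the eight canonical column names.
#' @export
beat_columns <- c("time_s", "hr_bpm", "sbp_mmhg", "dbp_mmhg",
                  "map_mmhg", "sv_ml", "co_lmin", "tpr_mu")

# internal: map short parameter names to CSV columns
.param_columns <- c(hr = "hr_bpm", sbp = "sbp_mmhg", dbp = "dbp_mmhg",
                    map = "map_mmhg", sv = "sv_ml", co = "co_lmin",
                    tpr = "tpr_mu")

#' Supported haemodynamic parameter names
#'
#' @return Character vector: `"map"`, `"sbp"`, `"dbp"`, `"tpr"`, `"sv"`,
#'   `"co"`, `"hr"`.
#' @export
beat_parameters <- function() c("map", "sbp", "dbp", "tpr", "sv", "co", "hr")

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' The clinical formula MAP = DBP + (SBP - DBP) / 3, i.e. diastolic pressure
#' plus one third of the pulse pressure. Vectorised.
#'
#' @param sbp Systolic blood pressure, mmHg.
#' @param dbp Diastolic blood pressure, mmHg. Must satisfy `sbp > dbp > 0`
#'   element-wise.
#' @return Mean arterial pressure, mmHg.
#' @examples
#' compute_map(121, 75)   # 90.33
#' compute_map(118, 78)   # 91.33
#' @export
compute_map <- function(sbp, dbp) {
  if (length(sbp) != length(dbp))
    stop("`sbp` and `dbp` must have equal length", call. = FALSE)
  bad <- which(!is.finite(sbp) | !is.finite(dbp) | sbp <= dbp | dbp <= 0)
  if (length(bad) > 0)
    stop("invalid record(s) at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": require sbp > dbp > 0", call. = FALSE)
  dbp + (sbp - dbp) / 3
}

#' Construct a beat series
#'
#' A `beat_series` is a data frame with one row per heart beat and the eight
#' canonical columns (see [beat_columns]), carrying subject metadata as
#' attributes. Record invariants (`sbp > dbp > 0`, `dbp <= map <= sbp`,
#' positive `hr`, `sv`, `co`, `tpr`, strictly increasing non-negative times)
#' are enforced at construction.
#'
#' @param records Data frame with the canonical columns.
#' @param subject_id Subject identifier.
#' @param phase One of `"rest"`, `"stress"`.
#' @param group One of `"HD"`, `"NC"`, `"other"`.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(records, subject_id = "unknown",
                        phase = c("rest", "stress"),
                        group = c("other", "HD", "NC")) {
  phase <- match.arg(phase)
  group <- match.arg(group)
  if (!is.data.frame(records))
    stop("`records` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(beat_columns, names(records))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[beat_columns]
  for (cl in beat_columns) records[[cl]] <- as.numeric(records[[cl]])
  bad <- which(!record_valid(records))
  if (length(bad) > 0)
    stop("invalid record(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  check_times(records$time_s)
  rownames(records) <- NULL
  structure(records,
            subject_id = subject_id, phase = phase, group = group,
            class = c("beat_series", "data.frame"))
}

# internal: per-row invariant check, returns logical vector
record_valid <- function(records) {
  with(records,
       is.finite(time_s) & time_s >= 0 &
         is.finite(sbp_mmhg) & is.finite(dbp_mmhg) & is.finite(map_mmhg) &
         is.finite(hr_bpm) & is.finite(sv_ml) & is.finite(co_lmin) &
         is.finite(tpr_mu) &
         sbp_mmhg > dbp_mmhg & dbp_mmhg > 0 &
         dbp_mmhg <= map_mmhg & map_mmhg <= sbp_mmhg &
         hr_bpm > 0 & sv_ml > 0 & co_lmin > 0 & tpr_mu > 0)
}

# internal: strict monotonicity of beat times; reports first offending row
check_times <- function(time_s) {
  if (length(time_s) > 1) {
    nonmono <- which(diff(time_s) <= 0)
    if (length(nonmono) > 0)
      stop("beat times not strictly increasing: first offence at row ",
           nonmono[1] + 1L, " (time ", time_s[nonmono[1] + 1L], ")",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> subject=%s phase=%s group=%s: %d beats over %.1f s\n",
              attr(x, "subject_id"), attr(x, "phase"), attr(x, "group"),
              nrow(x), if (nrow(x) > 0) diff(range(x$time_s)) else 0))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 4L), ...)
  if (nrow(x) > 4L) cat("  ... ", nrow(x) - 4L, " more beats\n", sep = "")
  invisible(x)
}

#' Extract one parameter's beat values
#'
#' @param series A [beat_series].
#' @param parameter One of [beat_parameters()].
#' @return Numeric vector of per-beat values.
#' @export
beat_values <- function(series, parameter) {
  parameter <- check_parameter(parameter)
  series[[.param_columns[[parameter]]]]
}

# internal
check_parameter <- function(parameter) {
  if (length(parameter) != 1 || !parameter %in% beat_parameters())
    stop("unknown parameter ", deparse(parameter), "; valid names: ",
         paste(beat_parameters(), collapse = ", "), call. = FALSE)
  parameter
}

#' Read a beat-by-beat CSV recording
#'
#' Reads the canonical dialect (comma-separated, one header row, `.` decimal
#' separator, UTF-8). Required columns: `time_s`, `sbp_mmhg`, `dbp_mmhg`.
#' Missing derived columns are filled in order: `map_mmhg` via
#' [compute_map()], `co_lmin` as `sv_ml * hr_bpm / 1000`, `tpr_mu` as
#' `map_mmhg / co_lmin`. Rows violating record invariants are dropped; the
#' per-row diagnostics are attached as the `"rejected"` attribute (data frame
#' with `row` and `reason`) and reported via a warning.
#'
#' @param path Path to a CSV file.
#' @param subject_id,phase,group Metadata for the resulting series.
#' @return A [beat_series]; attribute `"rejected"` lists dropped input rows.
#' @export
read_beats <- function(path, subject_id = basename(path),
                       phase = c("rest", "stress"),
                       group = c("other", "HD", "NC")) {
  phase <- match.arg(phase)
  group <- match.arg(group)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "sbp_mmhg", "dbp_mmhg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("format error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- fill_derived(raw)
  raw <- raw[beat_columns]
  for (cl in beat_columns) raw[[cl]] <- as.numeric(raw[[cl]])

  ok <- record_valid(raw)
  rejected <- data.frame(row = which(!ok),
                         reason = vapply(which(!ok), reject_reason,
                                         character(1), records = raw))
  if (nrow(rejected) > 0)
    warning("dropped ", nrow(rejected), " invalid row(s) from ", path,
            call. = FALSE)
  kept <- raw[ok, , drop = FALSE]
  check_times(kept$time_s)
  out <- beat_series(kept, subject_id = subject_id, phase = phase,
                     group = group)
  attr(out, "rejected") <- rejected
  out
}

# internal: fill map -> co -> tpr, each only when the column is absent
fill_derived <- function(raw) {
  n <- nrow(raw)
  if (is.null(raw$hr_bpm)) raw$hr_bpm <- rep(NA_real_, n)
  if (is.null(raw$sv_ml)) raw$sv_ml <- rep(NA_real_, n)
  if (is.null(raw$map_mmhg)) {
    bad <- which(!(raw$sbp_mmhg > raw$dbp_mmhg & raw$dbp_mmhg > 0))
    raw$map_mmhg <- rep(NA_real_, n)
    good <- setdiff(seq_len(n), bad)
    if (length(good) > 0)
      raw$map_mmhg[good] <- compute_map(raw$sbp_mmhg[good], raw$dbp_mmhg[good])
  }
  if (is.null(raw$co_lmin)) raw$co_lmin <- raw$sv_ml * raw$hr_bpm / 1000
  if (is.null(raw$tpr_mu)) raw$tpr_mu <- raw$map_mmhg / raw$co_lmin
  raw
}

# internal: human-readable reason for dropping a row
reject_reason <- function(i, records) {
  r <- records[i, ]
  if (anyNA(r)) return("missing or non-numeric value")
  if (!(r$sbp_mmhg > r$dbp_mmhg && r$dbp_mmhg > 0))
    return("requires sbp > dbp > 0")
  if (!(r$dbp_mmhg <= r$map_mmhg && r$map_mmhg <= r$sbp_mmhg))
    return("map outside [dbp, sbp]")
  if (r$time_s < 0) return("negative time")
  "non-positive hr, sv, co or tpr"
}

#' Write a beat series to the canonical CSV dialect
#'
#' Values are written with 17 significant digits so that
#' `read_beats(write_beats(s))` reproduces `s` exactly.
#'
#' @param series A [beat_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(beat_columns, collapse = ","), con)
  if (nrow(series) > 0) {
    cols <- lapply(beat_columns, function(cl) sprintf("%.17g", series[[cl]]))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}
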