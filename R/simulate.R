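#' Oscillation component specification
#'
#' One slow sinusoidal component added to a haemodynamic parameter:
#' `amplitude * sin(2 * pi * frequency * t + phase)`.
#'
#' @param frequency Oscillation frequency in Hz, > 0. Must stay resolvable
#'   at the beat rate: validated against `0.45 / mean_rr` when attached to a
#'   profile.
#' @param amplitude Half peak-to-trough excursion, parameter units, >= 0.
#' @param phase Phase offset in radians.
#' @return A list of class `oscillation`.
#' @export
oscillation <- function(frequency, amplitude, phase = 0) {
  stopifnot(is.numeric(frequency), frequency > 0,
            is.numeric(amplitude), amplitude >= 0,
            is.numeric(phase))
  structure(list(frequency = frequency, amplitude = amplitude, phase = phase),
            class = "oscillation")
}

#' Subject simulation profile
#'
#' Defines a synthetic beat-to-beat recording: RR-interval process
#' (truncated normal, lower clip 0.25 s), per-parameter baselines, slow
#' sinusoidal oscillations and additive Gaussian measurement noise.
#' Oscillations and noise can target `"map"` (common-mode, added to both
#' systolic and diastolic pressure), `"sbp"`, `"dbp"`, `"sv"` and `"tpr"`.
#' When `tpr_baseline` is `NULL`, total peripheral resistance is derived as
#' `map / co` (self-consistent physiology); when set, TPR oscillates
#' independently, which lets resistance variability be decoupled from
#' pressure variability.
#'
#' @param subject_id,group,phase Metadata carried into the series.
#' @param mean_rr Mean RR interval, seconds.
#' @param rr_sd RR-interval standard deviation, seconds; must satisfy
#'   `mean_rr > 3 * rr_sd`.
#' @param sbp_baseline,dbp_baseline Baseline pressures, mmHg
#'   (`sbp_baseline > dbp_baseline > 0`).
#' @param sv_baseline Baseline stroke volume, ml.
#' @param tpr_baseline Optional baseline resistance, MU; `NULL` derives TPR.
#' @param oscillations Named list (`map`, `sbp`, `dbp`, `sv`, `tpr`) of
#'   lists of [oscillation()] components.
#' @param noise_sd Named numeric vector of per-parameter noise SDs
#'   (`sbp`, `dbp`, `sv`, `tpr`), parameter units.
#' @param duration Recording duration, seconds.
#' @param seed Integer RNG seed; same profile (incl. seed) reproduces the
#'   same series exactly.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "synthetic",
                            group = c("other", "HD", "NC"),
                            phase = c("rest", "stress"),
                            mean_rr = 1.0, rr_sd = 0.05,
                            sbp_baseline = 120, dbp_baseline = 80,
                            sv_baseline = 70, tpr_baseline = NULL,
                            oscillations = list(),
                            noise_sd = c(sbp = 0.3, dbp = 0.3,
                                         sv = 0.3, tpr = 0),
                            duration = 1800, seed = 1L) {
  group <- match.arg(group)
  phase <- match.arg(phase)
  stopifnot(mean_rr > 0, rr_sd >= 0, duration > 0,
            sbp_baseline > dbp_baseline, dbp_baseline > 0, sv_baseline > 0)
  if (rr_sd > 0 && mean_rr <= 3 * rr_sd)
    stop("require mean_rr > 3 * rr_sd", call. = FALSE)
  if (!is.null(tpr_baseline)) stopifnot(tpr_baseline > 0)
  targets <- c("map", "sbp", "dbp", "sv", "tpr")
  if (length(oscillations) > 0) {
    if (is.null(names(oscillations)) ||
        !all(names(oscillations) %in% targets))
      stop("oscillations must be named with targets among: ",
           paste(targets, collapse = ", "), call. = FALSE)
    fmax <- 0.45 / mean_rr
    for (osc_list in oscillations) for (osc in osc_list) {
      stopifnot(inherits(osc, "oscillation"))
      if (osc$frequency > fmax)
        stop(sprintf(
          "oscillation frequency %.3g Hz exceeds 0.45 x mean beat rate (%.3g Hz)",
          osc$frequency, fmax), call. = FALSE)
    }
  }
  ns <- c(sbp = 0, dbp = 0, sv = 0, tpr = 0)
  ns[names(noise_sd)] <- noise_sd
  structure(list(subject_id = subject_id, group = group, phase = phase,
                 mean_rr = mean_rr, rr_sd = rr_sd,
                 sbp_baseline = sbp_baseline, dbp_baseline = dbp_baseline,
                 sv_baseline = sv_baseline, tpr_baseline = tpr_baseline,
                 oscillations = oscillations, noise_sd = ns,
                 duration = duration, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Simulate irregular beat times
#'
#' Beat times start at 0; successive RR intervals are drawn from a normal
#' distribution truncated below at 0.25 s (240 bpm ceiling, avoiding
#' degenerate beats), by redrawing sub-threshold values. Deterministic for a
#' given seed.
#'
#' @param mean_rr Mean RR interval, s (> 0).
#' @param rr_sd RR standard deviation, s (>= 0).
#' @param duration Recording length, s (> 0).
#' @param seed Integer seed.
#' @return Strictly increasing numeric vector of beat times in `[0, duration]`.
#' @export
simulate_beat_times <- function(mean_rr, rr_sd, duration, seed = 1L) {
  stopifnot(mean_rr > 0, rr_sd >= 0, duration > 0)
  set.seed(as.integer(seed))
  n_beats <- ceiling(duration / mean_rr * 1.25) + 10L
  rr <- stats::rnorm(n_beats, mean_rr, rr_sd)
  for (i in 1:100) {
    low <- rr < 0.25
    if (!any(low)) break
    rr[low] <- stats::rnorm(sum(low), mean_rr, rr_sd)
  }
  rr <- pmax(rr, 0.25)
  times <- cumsum(c(0, rr))
  while (times[length(times)] < duration) {
    extra <- max(abs(stats::rnorm(1, mean_rr, rr_sd)), 0.25)
    times <- c(times, times[length(times)] + extra)
  }
  times[times <= duration]
}

# internal: sum of oscillation components evaluated at times t
osc_sum <- function(osc_list, t) {
  if (is.null(osc_list) || length(osc_list) == 0) return(rep(0, length(t)))
  Reduce(`+`, lapply(osc_list, function(o)
    o$amplitude * sin(2 * pi * o$frequency * t + o$phase)))
}

#' Simulate a beat-to-beat haemodynamic recording
#'
#' Generates a [beat_series] from a [subject_profile()]: irregular beat
#' times, pressures as baseline + oscillations + Gaussian noise, MAP from
#' the clinical formula, HR from the current RR interval, CO as
#' `sv * hr / 1000`, and TPR either derived (`map / co`) or independently
#' oscillated. Noise draws that would violate `sbp > dbp` (or non-positive
#' SV/TPR) are redrawn up to 100 times; an unavoidable violation (oscillation
#' amplitudes incompatible with the baselines) is an error.
#'
#' @param profile A [subject_profile()].
#' @return A [beat_series] whose every record satisfies the record
#'   invariants by construction.
#' @export
simulate_subject <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  times <- simulate_beat_times(profile$mean_rr, profile$rr_sd,
                               profile$duration, profile$seed)
  n <- length(times)
  if (n < 3) stop("duration too short: fewer than 3 beats", call. = FALSE)
  osc <- profile$oscillations
  ns <- profile$noise_sd

  sbp_det <- profile$sbp_baseline + osc_sum(osc$map, times) +
    osc_sum(osc$sbp, times)
  dbp_det <- profile$dbp_baseline + osc_sum(osc$map, times) +
    osc_sum(osc$dbp, times)
  sbp <- sbp_det + stats::rnorm(n, 0, ns[["sbp"]])
  dbp <- dbp_det + stats::rnorm(n, 0, ns[["dbp"]])
  for (i in 1:100) {
    bad <- which(!(sbp > dbp & dbp > 0))
    if (length(bad) == 0) break
    sbp[bad] <- sbp_det[bad] + stats::rnorm(length(bad), 0, ns[["sbp"]])
    dbp[bad] <- dbp_det[bad] + stats::rnorm(length(bad), 0, ns[["dbp"]])
  }
  if (any(!(sbp > dbp & dbp > 0)))
    stop("generation error: sbp > dbp > 0 unattainable with this profile",
         call. = FALSE)

  sv_det <- profile$sv_baseline + osc_sum(osc$sv, times)
  sv <- sv_det + stats::rnorm(n, 0, ns[["sv"]])
  for (i in 1:100) {
    bad <- which(sv <= 0)
    if (length(bad) == 0) break
    sv[bad] <- sv_det[bad] + stats::rnorm(length(bad), 0, ns[["sv"]])
  }
  if (any(sv <= 0))
    stop("generation error: positive stroke volume unattainable", call. = FALSE)

  rr <- c(times[2] - times[1], diff(times))
  hr <- 60 / rr
  map <- compute_map(sbp, dbp)
  co <- sv * hr / 1000
  if (is.null(profile$tpr_baseline)) {
    tpr <- map / co
  } else {
    tpr_det <- profile$tpr_baseline + osc_sum(osc$tpr, times)
    tpr <- tpr_det + stats::rnorm(n, 0, ns[["tpr"]])
    for (i in 1:100) {
      bad <- which(tpr <= 0)
      if (length(bad) == 0) break
      tpr[bad] <- tpr_det[bad] + stats::rnorm(length(bad), 0, ns[["tpr"]])
    }
    if (any(tpr <= 0))
      stop("generation error: positive resistance unattainable", call. = FALSE)
  }

  beat_series(data.frame(time_s = times, hr_bpm = hr, sbp_mmhg = sbp,
                         dbp_mmhg = dbp, map_mmhg = map, sv_ml = sv,
                         co_lmin = co, tpr_mu = tpr),
              subject_id = profile$subject_id,
              phase = profile$phase, group = profile$group)
}

#' Default haemodialysis-like simulation profiles
#'
#' A rest/stress pair of [subject_profile()]s emulating the haemodynamic
#' signature of a haemodialysis patient: relatively fast mean-arterial-
#' pressure oscillation (rest 0.39 Hz, stress 0.38 Hz, so extrema
#' frequencies near twice those values) and a low-amplitude independent TPR
#' oscillation. Durations: 1500 s at rest, 10800 s under stress (a
#' three-hour dialysis session).
#'
#' @param seed Base integer seed; rest and stress use `seed` and `seed + 1`.
#' @return Named list with elements `rest` and `stress`.
#' @export
hd_profile <- function(seed = 101L) {
  base <- function(phase, duration, seed, map_f, map_a, tpr_f, tpr_a) {
    subject_profile(
      subject_id = "HD-like", group = "HD", phase = phase,
      mean_rr = 0.9, rr_sd = 0.04,
      sbp_baseline = 121, dbp_baseline = 75, sv_baseline = 60,
      tpr_baseline = 1.1,
      oscillations = list(
        map = list(oscillation(map_f, map_a)),
        sbp = list(oscillation(0.33, 1.5)),
        sv = list(oscillation(0.40, 5)),
        tpr = list(oscillation(tpr_f, tpr_a))),
      noise_sd = c(sbp = 0.1, dbp = 0.1, sv = 0.25, tpr = 0.0005),
      duration = duration, seed = seed)
  }
  list(rest = base("rest", 1500, seed, map_f = 0.39, map_a = 2.5,
                   tpr_f = 0.41, tpr_a = 0.009),
       stress = base("stress", 10800, seed + 1L, map_f = 0.38, map_a = 2,
                     tpr_f = 0.42, tpr_a = 0.011))
}

#' Default normal-control-like simulation profiles
#'
#' The contrasting rest/stress pair: slower mean-arterial-pressure
#' oscillation (rest 0.17 Hz, stress 0.20 Hz) and an independent TPR
#' oscillation with five times the haemodialysis-like stress amplitude,
#' emulating intact resistance-mediated pressure buffering. Durations:
#' 1800 s at rest, 10800 s under stress (sustained exercise).
#'
#' @param seed Base integer seed; rest and stress use `seed` and `seed + 1`.
#' @return Named list with elements `rest` and `stress`.
#' @export
nc_profile <- function(seed = 202L) {
  base <- function(phase, duration, seed, map_f, map_a, tpr_f, tpr_a) {
    subject_profile(
      subject_id = "NC-like", group = "NC", phase = phase,
      mean_rr = 0.8, rr_sd = 0.04,
      sbp_baseline = 118, dbp_baseline = 78, sv_baseline = 80,
      tpr_baseline = 1.0,
      oscillations = list(
        map = list(oscillation(map_f, map_a)),
        sbp = list(oscillation(0.27, 2)),
        sv = list(oscillation(0.37, 4)),
        tpr = list(oscillation(tpr_f, tpr_a))),
      noise_sd = c(sbp = 0.1, dbp = 0.1, sv = 0.2, tpr = 0.0005),
      duration = duration, seed = seed)
  }
  list(rest = base("rest", 1800, seed, map_f = 0.17, map_a = 3.5,
                   tpr_f = 0.39, tpr_a = 0.055),
       stress = base("stress", 10800, seed + 1L, map_f = 0.20, map_a = 2.5,
                     tpr_f = 0.47, tpr_a = 0.055))
}

#' Write a paired synthetic dataset
#'
#' Simulates rest and stress recordings for a haemodialysis-like and a
#' normal-control-like subject and writes them in the canonical CSV dialect,
#' together with a JSON manifest recording the full profiles (including
#' seeds), so a dataset is reproducible from its manifest.
#'
#' @param hd,nc Rest/stress profile pairs as returned by [hd_profile()] and
#'   [nc_profile()].
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the four CSV paths
#'   (`hd_rest`, `hd_stress`, `nc_rest`, `nc_stress`) with the manifest path
#'   as attribute `"manifest"`.
#' @export
make_paired_dataset <- function(hd = hd_profile(), nc = nc_profile(),
                                out_dir) {
  stopifnot(is.list(hd), all(c("rest", "stress") %in% names(hd)),
            is.list(nc), all(c("rest", "stress") %in% names(nc)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jobs <- list(hd_rest = hd$rest, hd_stress = hd$stress,
               nc_rest = nc$rest, nc_stress = nc$stress)
  paths <- vapply(names(jobs), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_beats(simulate_subject(jobs[[nm]]), p)
    p
  }, character(1))
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    lapply(jobs, function(pr) unclass_profile(pr)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(paths, "manifest") <- manifest
  paths
}

# internal: plain-list view of a profile for serialisation
unclass_profile <- function(pr) {
  pr <- unclass(pr)
  pr$oscillations <- lapply(pr$oscillations,
                            function(l) lapply(l, unclass))
  pr$noise_sd <- as.list(pr$noise_sd)
  pr
}

#' Build profiles from a configuration list or file
#'
#' Configuration is YAML or JSON with top-level keys `hd` and `nc`, each
#' holding `rest` and `stress` [subject_profile()] field lists
#' (`oscillations` as named lists of `{frequency, amplitude, phase}`
#' records). Missing fields take the [subject_profile()] defaults; a missing
#' subject or phase falls back to the corresponding [hd_profile()] /
#' [nc_profile()] default.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or an equivalent
#'   nested list.
#' @param seed Optional base seed overriding the profiles' seeds
#'   (rest/stress get `seed`/`seed + 1` for hd, `seed + 2`/`seed + 3` for nc).
#' @return List with elements `hd` and `nc`, each a rest/stress profile pair.
#' @export
load_profiles <- function(config = NULL, seed = NULL) {
  cfg <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config, call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
    else if (ext == "json") jsonlite::read_json(config, simplifyVector = FALSE)
    else stop("unsupported config format: .", ext, call. = FALSE)
  } else if (is.list(config)) config
  else stop("`config` must be a path or a list", call. = FALSE)

  build <- function(defaults, cfg_subject, group) {
    lapply(stats::setNames(c("rest", "stress"), c("rest", "stress")),
           function(ph) {
             spec <- cfg_subject[[ph]]
             if (is.null(spec)) return(defaults[[ph]])
             spec$group <- group
             spec$phase <- ph
             if (!is.null(spec$oscillations))
               spec$oscillations <- lapply(spec$oscillations, function(l)
                 lapply(l, function(o)
                   oscillation(o$frequency, o$amplitude,
                               if (is.null(o$phase)) 0 else o$phase)))
             if (!is.null(spec$noise_sd))
               spec$noise_sd <- unlist(spec$noise_sd)
             do.call(subject_profile, spec)
           })
  }
  out <- list(hd = build(hd_profile(), cfg$hd, "HD"),
              nc = build(nc_profile(), cfg$nc, "NC"))
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    out$hd$rest$seed <- seed
    out$hd$stress$seed <- seed + 1L
    out$nc$rest$seed <- seed + 2L
    out$nc$stress$seed <- seed + 3L
  }
  out
}
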