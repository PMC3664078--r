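# Independent oracles and fixture builders used across the suite.

# Naive per-triple extrema scan: the reference the vectorised detector is
# checked against.
naive_extrema <- function(values, times) {
  idx <- integer(0); kind <- character(0)
  n <- length(values)
  if (n >= 3) for (i in 2:(n - 1)) {
    if (values[i] > values[i - 1] && values[i] > values[i + 1]) {
      idx <- c(idx, i); kind <- c(kind, "maximum")
    } else if (values[i] < values[i - 1] && values[i] < values[i + 1]) {
      idx <- c(idx, i); kind <- c(kind, "minimum")
    }
  }
  data.frame(index = idx, time = times[idx], value = values[idx],
             kind = kind)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Beat series whose `map` column carries arbitrary values while all record
# invariants hold.
series_with_map <- function(values, times) {
  shift <- max(0, 11 - min(values))
  v <- values + shift
  beat_series(data.frame(time_s = times, hr_bpm = 60,
                         sbp_mmhg = v + 20, dbp_mmhg = v - 10,
                         map_mmhg = v, sv_ml = 70, co_lmin = 4.2,
                         tpr_mu = v / 4.2),
              subject_id = "fixture")
}

# Random beat-times + valid-record generator for property tests.
random_sequence <- function(n, integer_values = FALSE) {
  if (integer_values) sample(0:9, n, replace = TRUE)
  else stats::rnorm(n)
}

# Small-duration copies of the default rest/stress profile pairs, for tests
# that only need the structure, not 3-hour recordings.
short_profiles <- function(seed = 1L, duration = 120) {
  hd <- hd_profile(seed)
  nc <- nc_profile(seed + 10L)
  for (ph in c("rest", "stress")) {
    hd[[ph]]$duration <- duration
    nc[[ph]]$duration <- duration
  }
  list(hd = hd, nc = nc)
}
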