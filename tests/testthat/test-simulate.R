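test_that("beat times are a deterministic truncated-normal RR process", {
  # zero variance: a perfect 1-s grid
  expect_equal(simulate_beat_times(1, 0, 10, seed = 1), 0:10)
  t1 <- simulate_beat_times(0.8, 0.05, 300, seed = 9)
  t2 <- simulate_beat_times(0.8, 0.05, 300, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_beat_times(0.8, 0.05, 300, seed = 10)))
  expect_true(all(diff(t1) >= 0.25))
  expect_true(t1[1] == 0 && max(t1) <= 300)
  expect_error(simulate_beat_times(-1, 0, 10), "mean_rr")
})

test_that("beat counts track duration / mean RR", {
  counts <- vapply(1:20, function(s)
    length(simulate_beat_times(0.8, 0.05, 1800, seed = s)), numeric(1))
  expect_true(all(abs(counts - 2250) / 2250 < 0.05))
})

test_that("a quiescent profile produces a constant pressure series", {
  pr <- subject_profile(noise_sd = c(sbp = 0, dbp = 0, sv = 0, tpr = 0),
                        rr_sd = 0, duration = 100, seed = 2L)
  s <- simulate_subject(pr)
  m <- analyze_parameter(s, "map")
  expect_equal(nrow(m$extrema), 0)
  expect_equal(length(unique(s$sbp_mmhg)), 1)
})

test_that("every simulated record is physiologically consistent", {
  profs <- short_profiles(seed = 3L, duration = 200)
  for (pr in c(profs$hd, profs$nc)) {
    s <- simulate_subject(pr)
    expect_true(all(s$sbp_mmhg > s$dbp_mmhg & s$dbp_mmhg > 0))
    expect_true(all(s$dbp_mmhg <= s$map_mmhg & s$map_mmhg <= s$sbp_mmhg))
    expect_true(all(s$hr_bpm > 0 & s$sv_ml > 0 & s$co_lmin > 0 & s$tpr_mu > 0))
    expect_true(all(abs(s$map_mmhg -
                          (s$dbp_mmhg + (s$sbp_mmhg - s$dbp_mmhg) / 3)) < 1e-9))
    expect_equal(s$co_lmin, s$sv_ml * s$hr_bpm / 1000)
  }
})

test_that("profile validation rejects unresolvable oscillations and bad RR", {
  expect_error(subject_profile(mean_rr = 1, rr_sd = 0.5), "3 \\* rr_sd")
  expect_error(
    subject_profile(mean_rr = 1,
                    oscillations = list(map = list(oscillation(0.48, 2)))),
    "exceeds 0.45")
  expect_error(oscillation(-0.1, 1), "frequency")
})

test_that("impossible noise/oscillation settings raise a generation error", {
  pr <- subject_profile(sbp_baseline = 100, dbp_baseline = 95,
                        oscillations = list(dbp = list(oscillation(0.1, 20))),
                        noise_sd = c(sbp = 0, dbp = 0, sv = 0, tpr = 0),
                        duration = 60, seed = 1L)
  expect_error(simulate_subject(pr), "generation error")
})

test_that("designed oscillations are recovered at twice their frequency and amplitude", {
  for (f0 in c(0.2, 0.25)) {
    med_f <- med_a <- numeric(20)
    for (s in 1:20) {
      pr <- subject_profile(
        oscillations = list(map = list(oscillation(f0, 6))),
        noise_sd = c(sbp = 0.3, dbp = 0.3, sv = 0, tpr = 0),
        mean_rr = 1, duration = 1800, seed = s)
      m <- analyze_parameter(simulate_subject(pr), "map")
      med_f[s] <- median(m$frequencies)
      med_a[s] <- median(m$amplitudes)
    }
    expect_lt(abs(median(med_f) - 2 * f0) / (2 * f0), 0.15)
    expect_lt(abs(median(med_a) - 12) / 12, 0.15)
  }
})

test_that("added noise raises, and never materially lowers, the median extrema frequency", {
  med_at_noise <- vapply(c(0, 0.3, 1.5, 3), function(ns) {
    meds <- vapply(1:10, function(s) {
      pr <- subject_profile(
        oscillations = list(map = list(oscillation(0.2, 6))),
        noise_sd = c(sbp = ns, dbp = ns, sv = 0, tpr = 0),
        mean_rr = 1, duration = 900, seed = s)
      median(analyze_parameter(simulate_subject(pr), "map")$frequencies)
    }, numeric(1))
    median(meds)
  }, numeric(1))
  # allow sub-2% wiggle from interval quantisation at ~1 s beat spacing
  expect_true(all(diff(med_at_noise) >= -0.02 * med_at_noise[-length(med_at_noise)]))
  expect_gt(med_at_noise[length(med_at_noise)], med_at_noise[1])
})

test_that("paired datasets are reproducible byte for byte", {
  profs <- short_profiles(seed = 21L, duration = 90)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_paired_dataset(profs$hd, profs$nc, d1)
  p2 <- make_paired_dataset(profs$hd, profs$nc, d2)
  expect_setequal(names(p1), c("hd_rest", "hd_stress", "nc_rest", "nc_stress"))
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  expect_true(file.exists(attr(p1, "manifest")))
  manifest <- jsonlite::read_json(attr(p1, "manifest"))
  expect_setequal(names(manifest),
                  c("hd_rest", "hd_stress", "nc_rest", "nc_stress"))
  expect_equal(manifest$hd_rest$seed, profs$hd$rest$seed)
})

test_that("profiles load from YAML and JSON configuration", {
  cfg <- list(hd = list(rest = list(
    mean_rr = 0.75, duration = 60, seed = 5,
    oscillations = list(map = list(list(frequency = 0.2, amplitude = 4))),
    noise_sd = list(sbp = 0.2, dbp = 0.2))))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  pr <- load_profiles(yml)
  expect_equal(pr$hd$rest$mean_rr, 0.75)
  expect_equal(pr$hd$rest$oscillations$map[[1]]$frequency, 0.2)
  expect_identical(pr$hd$rest$group, "HD")
  # unspecified phases fall back to the built-in defaults
  expect_equal(pr$hd$stress$duration, hd_profile()$stress$duration)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, js, auto_unbox = TRUE, digits = NA)
  pr2 <- load_profiles(js, seed = 77)
  expect_equal(pr2$hd$rest$mean_rr, 0.75)
  expect_equal(pr2$hd$rest$seed, 77L)
  expect_equal(pr2$nc$stress$seed, 80L)
  # the bundled example configuration is valid and simulatable
  example <- system.file("extdata", "profiles_example.yaml",
                         package = "extremabeat")
  pr3 <- load_profiles(example)
  expect_equal(pr3$hd$rest$duration, 300)
  expect_s3_class(simulate_subject(pr3$nc$rest), "beat_series")
})
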