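test_that("strict local extrema are detected on the worked five-beat example", {
  ex <- find_extrema(c(2, 5, 3, 4, 1), 0:4)
  expect_equal(ex$index, c(2L, 3L, 4L))
  expect_equal(ex$kind, c("maximum", "minimum", "maximum"))
  expect_equal(ex$time, c(1, 2, 3))
  expect_equal(ex$value, c(5, 3, 4))
})

test_that("monotone runs and plateaus yield no extrema (strict comparisons)", {
  expect_equal(nrow(find_extrema(c(1, 2, 3, 4), 0:3)), 0)
  expect_equal(nrow(find_extrema(c(1, 2, 2, 1), 0:3)), 0)
  expect_equal(nrow(find_extrema(c(4, 3, 2, 1), 0:3)), 0)
})

test_that("degenerate inputs are warned about or rejected", {
  expect_warning(ex <- find_extrema(c(1, 2), c(0, 1)), "shorter than 3")
  expect_equal(nrow(ex), 0)
  expect_error(find_extrema(1:4, 0:4), "equal length")
  expect_error(find_extrema(1:3, c(0, 1, 1)), "strictly increasing")
})

test_that("detector matches the naive per-triple oracle on random sequences", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:120, 1)
    v <- random_sequence(n, integer_values = rep %% 2 == 0)
    t <- cumsum(runif(n, 0.3, 1.5))
    got <- find_extrema(v, t)
    ref <- naive_extrema(v, t)
    expect_equal(got$index, ref$index)
    expect_equal(got$kind, ref$kind)
    expect_equal(got$time, ref$time)
  }
})

test_that("extrema alternate in kind for tie-free sequences", {
  set.seed(7)
  for (rep in 1:50) {
    v <- rnorm(80)                      # continuous: no adjacent ties
    ex <- find_extrema(v, seq_along(v))
    if (nrow(ex) >= 2) {
      expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
      n_max <- sum(ex$kind == "maximum")
      expect_lte(abs(n_max - (nrow(ex) - n_max)), 1)
    }
  }
})

test_that("intervals, frequencies and amplitudes compose as reciprocals and differences", {
  ex <- data.frame(index = c(2L, 5L, 9L), time = c(0.0, 1.5, 2.5),
                   value = c(10, 4, 9), kind = c("maximum", "minimum", "maximum"))
  iv <- inter_extrema_intervals(ex)
  expect_equal(iv, c(1.5, 1.0))
  expect_equal(extrema_frequencies(iv), c(1 / 1.5, 1.0))
  expect_equal(extrema_amplitudes(ex), c(6, 5))
  expect_equal(extrema_frequencies(c(2.0)), 0.5)
  expect_equal(extrema_frequencies(c(1.25, 0.5)), c(0.8, 2.0))
  # fewer than 2 extrema: empty metrics, not an error
  expect_length(inter_extrema_intervals(ex[1, ]), 0)
  expect_length(extrema_amplitudes(ex[1, ]), 0)
  expect_error(extrema_frequencies(c(1, 0)), "pair 2")
})

test_that("frequency times interval is 1 to within round-off", {
  set.seed(9)
  for (rep in 1:20) {
    t <- cumsum(runif(150, 0.4, 1.6))
    ex <- find_extrema(rnorm(150), t)
    iv <- inter_extrema_intervals(ex)
    expect_true(all(abs(extrema_frequencies(iv) * iv - 1) < 1e-12))
  }
})

test_that("a dense aligned sinusoid yields the half-period law exactly", {
  f <- 0.5; A <- 6
  dt <- (1 / f) / 40                    # peaks fall on samples
  t <- seq(0, 20, by = dt)
  ex <- find_extrema(A * sin(2 * pi * f * t), t)
  iv <- inter_extrema_intervals(ex)
  expect_true(all(abs(extrema_frequencies(iv) / (2 * f) - 1) < 1e-6))
  expect_true(all(abs(extrema_amplitudes(ex) / (2 * A) - 1) < 1e-6))
})

test_that("metrics are invariant to time shifts and value offsets", {
  set.seed(13)
  v <- rnorm(100); t <- cumsum(runif(100, 0.5, 1.5))
  base <- find_extrema(v, t)
  shifted <- find_extrema(v, t + 137.5)
  offset <- find_extrema(v + 55, t)
  expect_equal(inter_extrema_intervals(shifted),
               inter_extrema_intervals(base))
  expect_equal(extrema_amplitudes(shifted), extrema_amplitudes(base))
  expect_equal(offset$index, base$index)
  expect_equal(inter_extrema_intervals(offset),
               inter_extrema_intervals(base))
  expect_equal(extrema_amplitudes(offset), extrema_amplitudes(base))
})

test_that("analyze_parameter composes detection and metrics on a beat series", {
  s <- series_with_map(c(2, 5, 3, 4, 1), 0:4)
  m <- analyze_parameter(s, "map")
  expect_s3_class(m, "extrema_metrics")
  expect_equal(m$extrema$kind, c("maximum", "minimum", "maximum"))
  expect_equal(m$intervals, c(1, 1))
  expect_equal(m$frequencies, c(1, 1))
  expect_equal(m$amplitudes, c(2, 1))
  tab <- metrics_table(m)
  expect_equal(tab$t_start_s, c(1, 2))
  expect_equal(tab$t_end_s, c(2, 3))
  expect_equal(tab$frequency_hz, c(1, 1))
  # constant series: no extrema, empty metric sequences
  const <- series_with_map(rep(90, 100), 0:99)
  m0 <- analyze_parameter(const, "map")
  expect_equal(nrow(m0$extrema), 0)
  expect_length(m0$frequencies, 0)
  expect_length(m0$amplitudes, 0)
  expect_error(analyze_parameter(s, "XYZ"), "map, sbp, dbp")
})

test_that("flow variation follows the pressure-over-resistance law", {
  expect_equal(flow_variation(90, 1), 90)
  expect_equal(flow_variation(0, 3.7), 0)
  expect_equal(flow_variation(120, 2), 2 * flow_variation(60, 2))
  expect_equal(flow_variation(100, 2, p2 = 10), 45)
  expect_error(flow_variation(90, 0), "resistance")
})
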