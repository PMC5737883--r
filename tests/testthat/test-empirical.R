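make_trials <- function(conditions = c("a", "b"), bias = 0,
                        amplitude = c(a = 2, b = -1),
                        n_rep = 2, rate = 20, dur = 3.5) {
  time_s <- (seq_len(dur * rate) - 1) / rate
  r <- amplitude
  tidyr::expand_grid(condition = conditions, direction = c(1, -1),
                     rep = seq_len(n_rep)) |>
    dplyr::mutate(trial = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      condition = condition, direction = direction, trial = trial,
      time_s = time_s,
      turning_deg_s = bias + direction * r[[condition]] * (time_s >= 1),
      walking_speed_mm_s = 10
    )
}

test_that("mirror subtraction removes shared bias and recovers the plant", {
  trials <- make_trials(bias = 7)
  ms <- mirror_subtract(trials)
  expect_equal(ms$turning_deg_s[ms$condition == "a"],
               2 * (sort(unique(trials$time_s)) >= 1))
  expect_equal(ms$turning_deg_s[ms$condition == "b"],
               -1 * (sort(unique(trials$time_s)) >= 1))
  # identical traces in both directions cancel to zero
  sym <- trials |> dplyr::mutate(turning_deg_s = 5)
  expect_true(all(mirror_subtract(sym)$turning_deg_s == 0))
  # linearity: adding any direction-independent trace changes nothing
  shared <- trials |>
    dplyr::mutate(turning_deg_s = turning_deg_s + sin(time_s * 3) + 2)
  expect_equal(mirror_subtract(shared)$turning_deg_s, ms$turning_deg_s)
  # a missing direction is reported with its condition
  expect_error(mirror_subtract(trials[trials$direction == 1 |
                                        trials$condition == "a", ]),
               "b")
})

test_that("turning summaries average the stated window", {
  tr <- tibble::tibble(time_s = (0:69) / 20, turning_deg_s = 4)
  expect_equal(summarize_turning(tr)$turning_deg_s, 4)
  ind <- tibble::tibble(time_s = (0:69) / 20,
                        turning_deg_s = as.numeric((0:69) / 20 >= 1.5 &
                                                     (0:69) / 20 < 3))
  expect_equal(summarize_turning(ind)$turning_deg_s, 1)
  expect_error(summarize_turning(tr, window = c(2, 5)), "window")
})

test_that("fly selection applies speed and bias rules with earliest-window ties", {
  slow <- make_trials(n_rep = 12) |>
    dplyr::mutate(fly = "slow", walking_speed_mm_s = 3)
  fast <- make_trials(n_rep = 12) |>
    dplyr::mutate(fly = "fast", walking_speed_mm_s = 10)
  cohort <- dplyr::bind_rows(slow, fast)
  sel <- select_flies(cohort, window_trials = 40, bias_tol = 10)
  expect_equal(sel$fly, "fast")
  expect_equal(sel$window_start, 1)  # ties break to the earliest window
  expect_equal(sel$window_end, 40)
  # a fly whose first 30 trials are too slow gets a later window
  lazy <- make_trials(n_rep = 18) |>
    dplyr::mutate(fly = "lazy",
                  walking_speed_mm_s = ifelse(trial <= 30, 0.1, 12))
  sel2 <- select_flies(lazy, window_trials = 40, bias_tol = 10)
  # oracle: enumerate all contiguous windows by brute force
  per_trial <- lazy |>
    dplyr::group_by(trial) |>
    dplyr::summarise(speed = mean(walking_speed_mm_s), .groups = "drop")
  ok <- vapply(1:33, function(s) {
    mean(per_trial$speed[s:(s + 39)]) > 4
  }, logical(1))
  expect_equal(sel2$window_start, which(ok)[1])
  # retention is monotone in the speed threshold
  for (thr in c(2, 6, 11)) {
    kept <- select_flies(cohort, speed_threshold = thr, bias_tol = 10)$fly
    expect_true(all(kept %in% sel$fly) || thr < 4)
  }
  expect_equal(nrow(select_flies(cohort, speed_threshold = 11,
                                 bias_tol = 10)), 0)
})

test_that("voltage summaries are baseline-referenced and gate inclusion at 6 mV", {
  rate <- 2000
  flat <- physio_trace(rep(-50, 4 * rate), rate, 1, "membrane_mV")
  expect_equal(summarize_voltage(flat), 0)
  t <- (seq_len(4 * rate) - 1) / rate
  square <- physio_trace(-50 + 10 * (t >= 1 & t < 3), rate, 1,
                         "membrane_mV")
  expect_equal(summarize_voltage(square), 10)
  expect_false(cell_included(5.9))
  expect_true(cell_included(6))
  short <- physio_trace(rep(-50, rate), rate, 0.5, "membrane_mV")
  expect_error(summarize_voltage(short), "window")
  ca <- physio_trace(rep(100, 100), 7.51, 1, "fluorescence_au")
  expect_error(summarize_voltage(ca), "membrane")
})

test_that("dF/F has the stated transform properties", {
  rate <- 7.51
  n <- round(60 * rate)
  const <- physio_trace(rep(80, n), rate, 10, "fluorescence_au")
  expect_true(all(delta_f_over_f(const)$value == 0))
  # single transient of height a on baseline b: peak dF/F = a / b
  t <- (seq_len(n) - 1) / rate
  b <- 50; a <- 30
  f <- b + a * exp(-((t - 30) / 1.5)^2)
  tr <- physio_trace(f, rate, 10, "fluorescence_au")
  dff <- delta_f_over_f(tr)
  # the sampled transient peak sits slightly off the 7.51 Hz grid
  expect_equal(max(dff$value), (max(f) - b) / b)
  expect_equal(max(dff$value), a / b, tolerance = 0.01)
  # invariant under multiplicative rescaling
  dff_scaled <- delta_f_over_f(physio_trace(3 * f, rate, 10,
                                            "fluorescence_au"))
  expect_equal(dff_scaled$value, dff$value)
  # additive shift changes dF/F as dictated by the formula
  shift <- delta_f_over_f(physio_trace(f + b, rate, 10,
                                       "fluorescence_au"))
  expect_equal(max(shift$value), (max(f) - b) / (2 * b))
  neg <- physio_trace(f - 50, rate, 10, "fluorescence_au")
  expect_error(delta_f_over_f(neg), "baseline")
})

test_that("imaging summaries subtract null from preferred direction", {
  rate <- 7.51
  n <- round(20 * rate)
  t <- (seq_len(n) - 1) / rate
  mk <- function(level) {
    tr <- physio_trace(rep(1, n), rate, 5, "fluorescence_au")
    tr$value <- level * (t >= 5 & t < 12)
    tr
  }
  expect_equal(summarize_imaging(mk(0.4), mk(0.4)), 0)
  expect_equal(summarize_imaging(mk(0.5), mk(0.2)), 0.3)
  other <- physio_trace(rep(1, n), 10, 5, "fluorescence_au")
  expect_error(summarize_imaging(mk(0.5), other), "timebase")
})

test_that("bootstrap intervals are seeded, ordered, and degenerate on constants", {
  x <- withr::with_seed(10, rnorm(30))
  ci1 <- bootstrap_ci(x, seed = 99)
  ci2 <- bootstrap_ci(x, seed = 99)
  expect_identical(ci1, ci2)
  expect_lt(ci1["low"], ci1["high"])
  expect_true(ci1["low"] < mean(x) && mean(x) < ci1["high"])
  cc <- bootstrap_ci(rep(2, 10), seed = 1)
  expect_equal(unname(cc), c(2, 2))
  expect_error(bootstrap_ci(numeric(0), seed = 1), "empty")
  expect_error(bootstrap_ci(1, seed = 1), "2 samples")
  expect_error(bootstrap_ci(x), "seed")
})

test_that("downsampling block-averages and validates rates", {
  expect_equal(downsample(rep(3, 400), 50, rate_hz = 2000), rep(3, 10))
  x <- 1:80
  expect_equal(downsample(x, 50, rate_hz = 2000), c(20.5, 60.5))
  alt <- rep(c(1, -1), 100)
  expect_equal(downsample(alt, 50, rate_hz = 2000), rep(0, 5))
  expect_error(downsample(x, 300, rate_hz = 2000), "divide")
  tr <- physio_trace(rep(-50, 4000), 2000, 1, "membrane_mV")
  tr50 <- downsample(tr, 50)
  expect_equal(attr(tr50, "rate_hz"), 50)
  expect_equal(nrow(tr50), 100)
})
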