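# Synthetic data generator: populations, events, traces, frames.

test_that("bead_population validates its fields", {
  expect_s3_class(bead_population("6um", 6, 0.07), "bead_population")
  expect_error(bead_population("x", -1, 0.1), "mean_diameter",
               class = "pulsecount_validation_error")
  expect_error(bead_population("x", 6, -0.1), "cv",
               class = "pulsecount_validation_error")
  expect_error(bead_population("x", 6, 1), "cv",
               class = "pulsecount_validation_error")
  expect_error(bead_population("x", 6, 0.1, -2), "event_rate",
               class = "pulsecount_validation_error")
})

test_that("sample_diameters: zero variance, reproducibility, positivity", {
  d <- sample_diameters(bead_population("6um", 6, 0), 5, seed = 1)
  expect_identical(d, rep(6, 5))
  a <- sample_diameters(default_11um(), 100, seed = 42)
  b <- sample_diameters(default_11um(), 100, seed = 42)
  expect_identical(a, b)
  expect_true(all(a > 0))
  # strong-CV population still yields strictly positive diameters
  tiny <- sample_diameters(bead_population("x", 0.5, 0.9), 2000, seed = 3)
  expect_true(all(tiny > 0))
  expect_error(sample_diameters(list(), 5, 1),
               class = "pulsecount_validation_error")
})

test_that("sample_diameters reproduces the population moments", {
  n <- 1e5
  d <- sample_diameters(default_11um(), n, seed = 7)
  se_mean <- 1.98 / sqrt(n)
  se_sd <- 1.98 / sqrt(2 * n)
  expect_lt(abs(mean(d) - 11), 3 * se_mean)
  expect_lt(abs(sd(d) - 1.98), 3 * se_sd)
  # empirical CV converges to the specified CV
  expect_lt(abs(sd(d) / mean(d) - 0.18), 3 * se_sd / 11)
})

test_that("sample_diameters upper tail matches the normal law", {
  # fraction of 6 um (7% CV) diameters above 7 um vs an independent CDF
  n <- 1e5
  d <- sample_diameters(default_6um(), n, seed = 11)
  p <- pnorm(7, mean = 6, sd = 0.42, lower.tail = FALSE)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(d > 7) - p), 3 * se)
})

test_that("ideal_amplitude implements the volumetric law", {
  expect_identical(ideal_amplitude(0), 0)
  expect_equal(ideal_amplitude(6), 1.6)
  # independent arithmetic: cube of the diameter ratio
  a11 <- 1.6 * (11 * 11 * 11) / (6 * 6 * 6)
  expect_equal(ideal_amplitude(11), a11)
  expect_gt(a11, 1.9)   # inside the printed 11 um amplitude range
  expect_lt(a11, 20.7)
  expect_error(ideal_amplitude(-1), class = "pulsecount_validation_error")
  # strictly increasing and scale-invariant: A(alpha d) = alpha^3 A(d)
  d <- seq(0.5, 20, by = 0.25)
  expect_true(all(diff(ideal_amplitude(d)) > 0))
  for (alpha in c(0.3, 2, 11 / 6))
    expect_equal(ideal_amplitude(alpha * d), alpha^3 * ideal_amplitude(d))
})

test_that("generate_events: Poisson arrivals with ground-truth amplitudes", {
  expect_identical(nrow(generate_events(list(default_6um(0)), 10, 100,
                                        seed = 1)), 0L)
  expect_identical(nrow(generate_events(list(), 10, 100, seed = 1)), 0L)
  ev <- generate_events(list(bead_population("6um", 6, 0.07, 0.5)), 600, 110,
                        seed = 5)
  expect_lt(abs(nrow(ev) - 300), 3 * sqrt(300))
  expect_false(is.unsorted(ev$crossing_time_s))
  expect_true(all(ev$crossing_time_s >= 0 & ev$crossing_time_s <= 600))
  expect_equal(ev$true_amplitude_mV, ideal_amplitude(ev$diameter_um))
  # 1:1 mixture gives statistically equal label counts
  mix <- generate_events(list(default_6um(0.5), default_11um(0.5)), 600, 110,
                         seed = 6)
  n1 <- sum(mix$label == "6um")
  n2 <- sum(mix$label == "11um")
  expect_lt(abs(n1 - n2), 4 * sqrt((n1 + n2) / 2))
})

test_that("generate_events: spaced arrivals are dilute and deterministic", {
  specs <- list(default_6um(0.1), default_11um(0.1))
  ev <- generate_events(specs, 1000, 110, seed = 9, arrivals = "spaced")
  expect_identical(nrow(ev), 200L)
  expect_identical(sum(ev$label == "6um"), 100L)
  expect_false(is.unsorted(ev$crossing_time_s))
  # +/-25% jitter on a duration/n grid keeps gaps above half the spacing
  expect_gt(min(diff(ev$crossing_time_s)), 0.5 * 1000 / 200)
  expect_identical(ev, generate_events(specs, 1000, 110, seed = 9,
                                       arrivals = "spaced"))
})

test_that("synthesize_trace: silence, bypass, determinism, validation", {
  acq <- acq_quiet(filter_time_constant = 0)
  empty <- make_events(numeric(0), numeric(0), 110)
  tr <- synthesize_trace(empty, acq, 10, seed = 1)
  expect_identical(unique(tr$values), 0)
  # one pulse, filter bypassed: peak equals the true amplitude up to
  # sampling of the Gaussian maximum
  ev <- make_events(5, 6, 110)
  tr1 <- synthesize_trace(ev, acq, 10, seed = 1)
  expect_lt(abs(max(tr1$values) - 1.6), 1e-4)
  # identical seeds give bit-identical traces
  acqn <- acquisition_config()
  expect_identical(synthesize_trace(ev, acqn, 10, seed = 3)$values,
                   synthesize_trace(ev, acqn, 10, seed = 3)$values)
  expect_error(synthesize_trace(make_events(20, 6, 110), acq, 10, seed = 1),
               "within",
               class = "pulsecount_validation_error")
  # too few samples per FWHM
  slow <- acq_quiet(sample_rate = 20)
  expect_error(synthesize_trace(make_events(5, 6, 110), slow, 10, seed = 1),
               "FWHM")
})

test_that("filter attenuation matches an independent convolution oracle", {
  acq <- acq_quiet()
  peaks <- vapply(c(110, 344), function(v) {
    max(synthesize_trace(make_events(10, 6, v), acq, 20, seed = 1)$values)
  }, numeric(1))
  expect_lt(peaks[2], peaks[1])  # faster transit, stronger attenuation
  for (i in seq_along(c(110, 344))) {
    v <- c(110, 344)[i]
    ref <- oracle_filtered_peak(1.6, acq$sensing_length / v,
                                acq$filter_time_constant)
    expect_lt(abs(peaks[i] - ref) / ref, 0.01)
  }
})

test_that("filter attenuation is monotone non-increasing in velocity", {
  acq <- acq_quiet()
  vel <- seq(50, 600, by = 50)
  peaks <- vapply(vel, function(v)
    max(synthesize_trace(make_events(10, 6, v), acq, 20, seed = 1)$values),
    numeric(1))
  expect_true(all(diff(peaks) <= 0))
})

test_that("trace synthesis conserves event count (noise and drift off)", {
  times <- seq(5, 55, by = 5)   # non-overlapping by construction
  ev <- make_events(times, c(6, 11), 110)
  tr <- synthesize_trace(ev, acq_quiet(), 60, seed = 1)
  v <- tr$values
  maxima <- which(diff(sign(diff(v))) == -2) + 1
  maxima <- maxima[v[maxima] > 1e-6]
  expect_identical(length(maxima), length(times))
})

test_that("render_frames draws reproducible binary disks with ground truth", {
  vconf <- video_config(frame_width = 64, frame_height = 48,
                        electrode_x = 32)
  empty <- make_events(numeric(0), numeric(0), 110)
  out <- render_frames(empty, vconf, 0.1)
  expect_true(all(vapply(out$frames, function(f)
    all(f == vconf$background_intensity), logical(1))))
  expect_identical(nrow(out$truth), 0L)

  # one 11 um bead at 1 um/px: pixel count equals brute-force enumeration
  ev <- make_events(0, 11, 110)     # centred on the electrode at t = 0
  out <- render_frames(ev, vconf, 1 / 60)
  f <- out$frames[[1]]
  area <- sum(f == vconf$bead_intensity)
  ref <- oracle_disk_area(32, 23.5, 5.5, 64, 48)
  expect_identical(area, ref)
  expect_lt(abs(area - pi * 5.5^2) / (pi * 5.5^2), 0.15)
})

test_that("bead centroids advance by velocity / frame_rate pixels", {
  vconf <- video_config()
  ev <- make_events(0.4, 11, 289)
  out <- render_frames(ev, vconf, 0.8)
  cents <- vapply(out$frames, function(f) {
    idx <- which(f == vconf$bead_intensity, arr.ind = TRUE)
    if (nrow(idx)) mean(idx[, 2] - 1) else NA_real_
  }, numeric(1))
  steps <- diff(cents[!is.na(cents)])
  steps <- steps[abs(steps) < 20]   # ignore entry/exit frames
  expect_lt(abs(mean(steps) - 289 / 60), 0.2)
  expect_equal(out$truth$x_px[out$truth$frame == 24],
               (24 / 60 - 0.4) * 289 + 128)
})

test_that("sub-resolution beads are flagged", {
  vconf <- video_config(pixel_scale = 4)   # 6 um -> 1.5 px
  ev <- make_events(0.5, 6, 110)
  expect_warning(out <- render_frames(ev, vconf, 1), "2 px")
  expect_true(all(out$truth$sub_resolution))
})
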