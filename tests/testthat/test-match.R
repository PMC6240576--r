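# Cross-modal matching, rates, conversions, crossover, reports.

mk_tracks <- function(times, classes = "small") {
  cls <- rep_len(classes, length(times))
  data.frame(track_id = seq_along(times),
             n_detections = rep(10L, length(times)),
             velocity_um_s = rep(110, length(times)),
             crossing_time_s = times,
             est_diameter_um = ifelse(cls == "small", 6, 11),
             size_class = cls,
             stringsAsFactors = FALSE)
}

mk_peaks <- function(times, amps = 2) {
  data.frame(time_s = times, amplitude_mV = rep_len(amps, length(times)))
}

test_that("match_events applies the time window one-to-one", {
  empty <- match_events(mk_tracks(numeric(0)), mk_peaks(numeric(0)))
  expect_identical(nrow(empty$pairs), 0L)
  expect_identical(empty$unmatched_peaks, integer(0))

  # window rule: 10.05 matches, 10.40 is a false positive
  mr <- match_events(mk_tracks(10.0), mk_peaks(c(10.05, 10.40)))
  expect_identical(mr$pairs$peak_index, 1L)
  expect_equal(mr$pairs$delta_t_s, 0.05)
  expect_identical(mr$unmatched_peaks, 2L)
  expect_identical(length(mr$unmatched_tracks), 0L)

  # greedy ascending |dt|: nearest pair wins, remaining elements unmatched
  mr2 <- match_events(mk_tracks(c(5.00, 5.06)), mk_peaks(5.02))
  expect_identical(mr2$pairs$track_id, 1L)
  expect_identical(mr2$unmatched_tracks, 2L)
})

test_that("matching conserves and is monotone in the window", {
  ct <- pulsecount:::with_seed(31, sort(runif(40, 0, 120)))
  pt <- pulsecount:::with_seed(32, sort(runif(35, 0, 120)))
  for (w in c(0.05, 0.1, 0.5, 2)) {
    mr <- match_events(mk_tracks(ct), mk_peaks(pt), match_config(w))
    expect_identical(nrow(mr$pairs) + length(mr$unmatched_tracks),
                     length(ct))
    expect_identical(nrow(mr$pairs) + length(mr$unmatched_peaks),
                     length(pt))
    expect_true(all(mr$pairs$delta_t_s <= w))
    expect_identical(anyDuplicated(mr$pairs$track_id), 0L)
    expect_identical(anyDuplicated(mr$pairs$peak_index), 0L)
  }
  sizes <- vapply(c(0.02, 0.05, 0.1, 0.3, 1),
                  function(w) nrow(match_events(mk_tracks(ct), mk_peaks(pt),
                                                match_config(w))$pairs),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("greedy matching equals optimal assignment on sparse fixtures", {
  # 200 events, ~1 s apart, unique small gaps; some missing peaks and some
  # spurious ones
  fix <- pulsecount:::with_seed(55, {
    ct <- cumsum(runif(200, 0.8, 1.4))
    pt <- ct + runif(200, -0.09, 0.09)
    pt <- pt[-sample(200, 12)]             # missed beads
    pt <- sort(c(pt, runif(8, 0, max(ct)))) # false positives
    list(ct = ct, pt = pt)
  })
  mr <- match_events(mk_tracks(fix$ct), mk_peaks(fix$pt))
  ref <- oracle_match(fix$ct, fix$pt, 0.1)
  got <- mr$pairs[order(mr$pairs$track_id), c("track_id", "peak_index")]
  expect_identical(unname(as.matrix(got)),
                   unname(as.matrix(ref)))
})

test_that("detection_rate reproduces the printed worked examples", {
  expect_identical(detection_rate(148, 173), 86)
  expect_identical(detection_rate(27, 84), 32)
  expect_identical(detection_rate(84, 85), 99)
  expect_identical(detection_rate(46, 118), 39)
  expect_identical(detection_rate(46, 46), 100)
  expect_identical(detection_rate(0, 0), NA_real_)
  expect_error(detection_rate(5, 4), class = "pulsecount_validation_error")
})

test_that("amplitude_to_current converts by the trans-impedance gain", {
  expect_identical(amplitude_to_current(1.6, 1e5), 16)
  expect_identical(amplitude_to_current(0), 0)
  # 20.7 mV / (1e5 V/A) = 2.07e-7 A = 207 nA
  expect_equal(amplitude_to_current(20.7), 207)
  expect_error(amplitude_to_current(1, 0),
               class = "pulsecount_validation_error")
})

test_that("size_crossover: equal-variance midpoint and scale equivariance", {
  # Normal(6, 1) vs Normal(10, 1): crossover exactly halfway
  a <- bead_population("a", 6, 1 / 6)
  b <- bead_population("b", 10, 0.1)
  expect_equal(size_crossover(a, b), 8, tolerance = 1e-6)
  # rescaling both means (same cv => sd scales along) moves the root
  # proportionally
  x1 <- size_crossover(default_6um(), default_11um())
  x2 <- size_crossover(bead_population("a", 12, 0.07),
                       bead_population("b", 22, 0.18))
  expect_equal(x2, 2 * x1, tolerance = 1e-5)
  # densities that do not cross between the means
  wide <- bead_population("w", 6, 0.84)
  narrow <- bead_population("n", 7, 1 / 7)
  expect_error(size_crossover(wide, narrow), "cross")
  expect_error(size_crossover(b, a), class = "pulsecount_validation_error")
})

test_that("amplitude_histogram bins half-open and conserves counts", {
  pairs <- data.frame(amplitude_mV = c(0.4, 1.0, 1.2, 1.49, 1.5, 9.9),
                      size_class = c("small", "small", "small", "small",
                                     "small", "large"))
  h <- amplitude_histogram(pairs, bin_width = 0.5)
  expect_identical(sum(h$count), 6L)
  expect_identical(sum(h$count[h$size_class == "small"]), 5L)
  # 1.5 falls in [1.5, 2), not [1, 1.5): 1.0, 1.2, 1.49 share a bin
  expect_identical(h$count[h$size_class == "small" & h$bin_lo == 1.0], 3L)
  expect_identical(h$count[h$size_class == "small" & h$bin_lo == 1.5], 1L)
  expect_identical(nrow(amplitude_histogram(pairs[0, ], 0.5)), 0L)
  expect_error(amplitude_histogram(pairs, 0),
               class = "pulsecount_validation_error")
})

test_that("build_report matches direct counting and is order-invariant", {
  tracks <- mk_tracks(c(1, 3, 5, 7, 9, 11),
                      c("small", "small", "large", "small", "large",
                        "small"))
  peaks <- mk_peaks(c(1.02, 5.01, 7.04, 9.02, 20))
  mr <- match_events(tracks, peaks)
  rep1 <- build_report(mr, tracks, peaks)
  # direct bookkeeping: small 2/4 matched, large 2/2, one stray peak
  expect_identical(rep1$classes$video_count, c(2L, 4L))
  expect_identical(rep1$classes$matched_count, c(2L, 2L))
  expect_identical(rep1$classes$detection_rate_pct, c(100, 50))
  expect_identical(rep1$electrical_peak_count, 5L)
  expect_identical(rep1$false_positive_count, 1L)
  expect_identical(sum(rep1$classes$matched_count) +
                     rep1$false_positive_count,
                   rep1$electrical_peak_count)
  # permuting the input rows changes nothing
  perm_t <- tracks[c(4, 1, 6, 2, 5, 3), ]
  rep2 <- build_report(match_events(perm_t, peaks), perm_t, peaks)
  expect_equal(rep1, rep2)
  no_cls <- tracks
  no_cls$size_class <- NA_character_
  expect_error(build_report(mr, no_cls, peaks),
               class = "pulsecount_validation_error")
})

test_that("perfect conditions give 100% rates and zero false positives", {
  specs <- list(default_6um(0.1), default_11um(0.1))
  cfg <- default_config()
  cfg$populations <- specs
  cfg$acquisition <- acq_quiet()
  cfg$run$velocity <- 110
  cfg$run$duration <- 120
  ev <- generate_events(specs, 120, 110, seed = 17, arrivals = "spaced")
  ev <- ev[ev$crossing_time_s > 2 & ev$crossing_time_s < 118, ]
  ev$bead_id <- seq_len(nrow(ev))
  res <- pulsecount:::run_pipeline_events(ev, cfg, 18)
  expect_true(all(res$report$classes$detection_rate_pct == 100))
  expect_identical(res$report$false_positive_count, 0L)
})

test_that("velocity sweep output shape and binomial stability", {
  specs <- list(default_6um(0.1), default_11um(0.1))
  sw <- velocity_sweep(specs, c(150, 300), acq = acq_quiet(),
                       duration = 120, seed = 23, arrivals = "spaced")
  expect_setequal(names(sw),
                  c("velocity_um_s", "size_class", "video_count",
                    "matched_count", "detection_rate_pct",
                    "false_positive_count"))
  expect_identical(nrow(sw), 4L)
  # noise off: no attenuation below threshold at these speeds
  expect_true(all(sw$detection_rate_pct == 100))
  # doubling the event count (same density, twice the duration) leaves
  # rates unchanged within binomial error (3 sigma, pooled proportion)
  sw2 <- velocity_sweep(specs, c(150, 300), acq = acq_quiet(),
                        duration = 240, seed = 24, arrivals = "spaced")
  key <- function(d) paste(d$velocity_um_s, d$size_class)
  sw2 <- sw2[match(key(sw), key(sw2)), ]
  p_pool <- (sw$matched_count + sw2$matched_count) /
    (sw$video_count + sw2$video_count)
  bound <- 300 * sqrt(pmax(p_pool * (1 - p_pool), 0.25 / sw$video_count) *
                        (1 / sw$video_count + 1 / sw2$video_count))
  expect_true(all(abs(sw2$detection_rate_pct - sw$detection_rate_pct) <=
                    bound))
})
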