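test_that("zero-lag Butterworth filter matches its analytic magnitude response", {
  fs <- 1000
  # DC gain is exactly 1: constants pass through untouched
  expect_equal(butterworth_lowpass(rep(3.7, 500), 15, fs), rep(3.7, 500),
               tolerance = 1e-9)
  # dual-pass 2nd-order Butterworth at its corner: |H|^2 = 1/2
  t <- seq(0, 2, by = 1 / fs)
  for (fc in c(15, 100)) {
    x <- sin(2 * pi * fc * t)
    y <- butterworth_lowpass(x, fc, fs)
    mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    ratio <- sqrt(2 * mean(y[mid]^2))  # RMS amplitude of the steady state
    expect_equal(ratio, 0.5, tolerance = 0.02)
  }
  # a decade above the corner: 4th-order roll-off kills the tone
  x10 <- sin(2 * pi * 150 * t)
  y10 <- butterworth_lowpass(x10, 15, fs)
  expect_lt(max(abs(y10[seq(600, 1400)])), 0.01)
  expect_error(butterworth_lowpass(rnorm(100), 500, 1000), "Nyquist")
  expect_error(butterworth_lowpass(rnorm(5), 15, 1000), "too short")
})

test_that("filtering introduces no phase shift on band-limited input", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 7 * t)
  y <- butterworth_lowpass(x, 15, fs)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # and the passband content is essentially untouched
  expect_lt(max(abs(y - x)), 0.05)
})

test_that("stance detection follows the 10 N threshold semantics", {
  expect_equal(nrow(detect_stances(rep(0, 1000))), 0)
  x <- rep(0, 1000); x[101:400] <- 500
  st <- detect_stances(x)
  expect_equal(st$start, 101)
  expect_equal(st$end, 401)  # half-open: first index after the stance
  # incomplete stances at the record edges are dropped
  y <- rep(0, 300); y[1:50] <- 400; y[120:180] <- 400; y[280:300] <- 400
  st2 <- detect_stances(y)
  expect_equal(nrow(st2), 1)
  expect_equal(c(st2$start, st2$end), c(120, 181))
})

test_that("a generated trial yields exactly the planted number of stances", {
  co <- small_cohort()
  tr <- co$trials[[1]]
  fz <- butterworth_lowpass(tr$grf$fz_N, 100, 1000)
  expect_equal(nrow(detect_stances(fz)), 10)
})

test_that("stance detection tolerates sub-threshold flight noise", {
  x <- rep(0, 2000)
  for (t0 in c(200, 700, 1200)) x[t0:(t0 + 299)] <- 300  # plateaus >> 2x threshold
  clean <- detect_stances(x)
  set.seed(9)
  noisy <- x + runif(length(x), 0, 4.9) * (x == 0)  # < threshold/2, flight only
  expect_equal(detect_stances(noisy), clean)
})

test_that("time normalization preserves endpoints, constants and linearity", {
  expect_equal(time_normalize(rep(2.5, 57)), rep(2.5, 101))
  for (n in c(2, 10, 137)) {
    ramp <- seq(0, 1, length.out = n)
    expect_equal(time_normalize(ramp), (0:100) / 100)
  }
  # analytic half-sine reference
  hs <- sin(pi * seq(0, 1, length.out = 250))
  expect_lt(max(abs(time_normalize(hs) - sin(pi * (0:100) / 100))), 1e-3)
  expect_error(time_normalize(1), "at least 2")
})

test_that("averaging identical steps reproduces the single-step waveform", {
  tr <- identical_steps_trial()
  ws <- build_waveform_set(tr, "id1", n_steps = 10)
  expect_s3_class(ws, "waveform_set")
  expect_equal(dim(ws$waveforms), c(10, 101))
  expect_identical(rownames(ws$waveforms), waveform_channels())
  # single mid-trial stance, processed the same way
  fz <- butterworth_lowpass(tr$grf$fz_N, 100, 1000)
  st <- detect_stances(fz)
  expect_gte(nrow(st), 12)
  k <- 5
  t0 <- tr$grf$time_s[st$start[k]]; t1 <- tr$grf$time_s[st$end[k] - 1]
  kin <- butterworth_lowpass(tr$kinematics$ankle_sagittal, 15, 200)
  single <- stats::approx(tr$kinematics$time_s, kin,
                          xout = seq(t0, t1, length.out = 101))$y
  # stance boundaries are quantized to the 1 kHz grid, so individual
  # stances can differ by one sample in length; the averaged curve must
  # agree with a single stance to within that boundary tolerance
  expect_lt(max(abs(ws$waveforms["ankle_sagittal", ] - single)), 0.25)
})

test_that("a 12-stance trial uses the first 10 stances and ignores the rest", {
  tr <- identical_steps_trial(n_steps = 12)
  ws10 <- build_waveform_set(tr, "x", n_steps = 10)
  expect_equal(ws10$n_steps_averaged, 10)
  # corrupt stances 11-12 heavily: the first-10 average must not care
  bad <- tr
  late <- bad$kinematics$time_s > 10 * 0.42 + 0.06  # past the end of stance 10
  bad$kinematics$ankle_sagittal[late] <- bad$kinematics$ankle_sagittal[late] + 50
  ws10b <- build_waveform_set(bad, "x", n_steps = 10)
  expect_equal(ws10b$waveforms["ankle_sagittal", ],
               ws10$waveforms["ankle_sagittal", ], tolerance = 1e-2)
  ws12b <- build_waveform_set(bad, "x", n_steps = 12)
  expect_gt(mean(ws12b$waveforms["ankle_sagittal", ] -
                   ws10$waveforms["ankle_sagittal", ]), 4)
  expect_error(build_waveform_set(tr, "x", n_steps = 13), "only 12 complete stances")
})

test_that("pointwise step-to-step variability matches the planted SD", {
  cfg <- cohort_config(group_sizes = c(2, 2, 2), subject_sd_deg = 0,
                       step_sd_deg = 2, grf_noise_bw = 0, seed = 77)
  co <- generate_cohort(cfg)
  sds <- vapply(co$trials, function(tr) {
    fz <- butterworth_lowpass(tr$grf$fz_N, 100, 1000)
    st <- detect_stances(fz)
    kin <- butterworth_lowpass(tr$kinematics$methal_sagittal, 15, 200)
    steps <- vapply(seq_len(10), function(k) {
      t0 <- tr$grf$time_s[st$start[k]]; t1 <- tr$grf$time_s[st$end[k] - 1]
      stats::approx(tr$kinematics$time_s, kin, xout = seq(t0, t1, length.out = 101))$y
    }, numeric(101))
    mean(apply(steps, 1, sd))
  }, numeric(1))
  expect_equal(mean(sds), 2, tolerance = 0.25)
})
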