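# analytic one-stance fixtures on a dense clock
analytic_stance <- function(dur = 0.30, rate = 1000) {
  t <- seq(0, dur, by = 1 / rate)
  s <- t / dur
  vz <- 2.2 * exp(-((s - 0.5) / 0.22)^2) + 0.95 * exp(-((s - 0.15) / 0.05)^2)
  vz <- vz - (vz[1] * (1 - s) + vz[length(vz)] * s)
  list(t = t, s = s, vz = pmax(vz, 0), ap = -0.23 * sin(2 * pi * s))
}

test_that("body-weight normalization is the definitional division", {
  expect_equal(normalize_bw(686.7, 70), 1.0)
  expect_equal(normalize_bw(0, 70), 0)
  x <- rnorm(10)
  expect_equal(normalize_bw(2 * x, 80), 2 * normalize_bw(x, 80))
  expect_error(normalize_bw(100, 0), "positive")
})

test_that("vertical landmarks find the impact transient, valley and active peak", {
  st <- analytic_stance()
  lm <- find_vertical_landmarks(st$vz, st$t)
  expect_false(lm$degenerate)
  expect_equal(lm$first_peak$value, 1.12, tolerance = 0.02)
  expect_equal(lm$first_peak$time / 0.30, 0.15, tolerance = 0.03)
  expect_equal(lm$second_peak$value, 2.2, tolerance = 0.01)
  expect_equal(lm$second_peak$time / 0.30, 0.5, tolerance = 0.03)
  expect_lt(lm$first_peak$value, lm$second_peak$value)
  expect_gt(lm$valley$time, lm$first_peak$time)
  expect_lt(lm$valley$time, lm$second_peak$time)
  # single-hump stance: degeneracy branch
  t <- seq(0, 0.3, by = 1e-3)
  hump <- 2.2 * sin(pi * t / 0.3)
  lm2 <- find_vertical_landmarks(hump, t)
  expect_true(lm2$degenerate)
  expect_equal(lm2$valley$index, lm2$first_peak$index)
  expect_error(find_vertical_landmarks(seq(0, 1, 0.01), seq(0, 1, 0.01)), "monotone")
})

test_that("loading rate is the 20-80% secant slope of the rising limb", {
  # pure linear rise at 10 BW/s
  t <- seq(0, 0.2, by = 1e-3)
  f <- ifelse(t <= 0.1, 10 * t, 1 - 5 * (t - 0.1))
  lm <- find_vertical_landmarks(f, t)
  expect_equal(loading_rate(f, t, lm$first_peak), 10, tolerance = 1e-6)
  # piecewise slope 5 then 20: secant strictly between
  f2 <- ifelse(t <= 0.1, 5 * t, pmin(0.5 + 20 * (t - 0.1), 1.2))
  f2[t > 0.15] <- 1.2 - 3 * (t[t > 0.15] - 0.15)
  lm2 <- list(value = max(f2), index = which.max(f2))
  lr2 <- loading_rate(f2, t, lm2)
  expect_gt(lr2, 5); expect_lt(lr2, 20)
  # dense-grid oracle on the generator's stance template
  st1 <- analytic_stance(rate = 1000)
  st10 <- analytic_stance(rate = 10000)
  l1 <- loading_rate(st1$vz, st1$t, find_vertical_landmarks(st1$vz, st1$t)$first_peak)
  l10 <- loading_rate(st10$vz, st10$t, find_vertical_landmarks(st10$vz, st10$t)$first_peak)
  expect_equal(l1, l10, tolerance = 0.01)
})

test_that("impulse integrals match rectangle areas and a refined oracle", {
  # constant 1 BW over 0.30 s split at 0.10 s
  t <- seq(0, 0.30, by = 1e-3)
  v <- rep(1, length(t))
  lm <- list(valley = list(time = 0.10), second_peak = list(time = 0.20))
  ap <- c(rep(-0.2, 150), rep(0.2, 151))
  imp <- grf_impulses(v, ap, t, lm, split = "valley")
  expect_equal(imp$v_impulse_1, 0.10, tolerance = 1e-3)
  expect_equal(imp$v_impulse_2, 0.20, tolerance = 1e-3)
  expect_equal(imp$ap_impulse_brake, -0.03, tolerance = 0.02)
  expect_equal(imp$ap_impulse_prop, 0.03, tolerance = 0.02)
  # refinement oracle: 1 kHz trapezoid within 0.5% of 10 kHz integration
  s1 <- analytic_stance(rate = 1000); s10 <- analytic_stance(rate = 10000)
  lm1 <- find_vertical_landmarks(s1$vz, s1$t)
  lm10 <- find_vertical_landmarks(s10$vz, s10$t)
  i1 <- grf_impulses(s1$vz, s1$ap, s1$t, lm1)
  i10 <- grf_impulses(s10$vz, s10$ap, s10$t, lm10)
  for (f in names(i1))
    expect_equal(i1[[f]], i10[[f]], tolerance = 5e-3)
})

test_that("impulses conserve the totals and are time-shift invariant", {
  s <- analytic_stance()
  lm <- find_vertical_landmarks(s$vz, s$t)
  imp <- grf_impulses(s$vz, s$ap, s$t, lm)
  expect_equal(imp$v_impulse_1 + imp$v_impulse_2, pracma::trapz(s$t, s$vz),
               tolerance = 1e-9)
  expect_equal(imp$ap_impulse_brake + imp$ap_impulse_prop,
               pracma::trapz(s$t, s$ap), tolerance = 1e-9)
  lm2 <- find_vertical_landmarks(s$vz, s$t + 3.7)
  imp2 <- grf_impulses(s$vz, s$ap, s$t + 3.7, lm2)
  expect_equal(unlist(imp2), unlist(imp), tolerance = 1e-9)
})

test_that("extract_discrete returns nine averaged variables with correct signs", {
  tr <- identical_steps_trial()
  d <- extract_discrete(tr)
  expect_length(d, 9)
  expect_named(d, c("v_first_peak", "v_second_peak", "loading_rate",
                    "v_impulse_1", "v_impulse_2", "ap_negative_peak",
                    "ap_positive_peak", "ap_impulse_brake", "ap_impulse_prop"))
  expect_true(d["v_first_peak"] >= 0 && d["v_second_peak"] >= 0)
  expect_lt(d["v_first_peak"], d["v_second_peak"])
  expect_true(d["ap_negative_peak"] <= 0 && d["ap_positive_peak"] >= 0)
  expect_true(d["ap_impulse_brake"] <= 0 && d["ap_impulse_prop"] >= 0)
  # identical stances: per-stance extraction equals the mean-curve mode
  dm <- extract_discrete(tr, aggregation = "mean_curve")
  expect_equal(d, dm, tolerance = 0.05)
  expect_error(extract_discrete(tr, n_steps = 20), "only 12 complete stances")
})

test_that("flipping the AP sign convention swaps and negates the impulses", {
  tr <- identical_steps_trial()
  d <- extract_discrete(tr)
  tr_flipped <- tr
  tr_flipped$grf$fy_N <- -tr_flipped$grf$fy_N
  df <- extract_discrete(tr_flipped)
  expect_equal(unname(df["ap_impulse_brake"]), unname(-d["ap_impulse_prop"]),
               tolerance = 1e-9)
  expect_equal(unname(df["ap_impulse_prop"]), unname(-d["ap_impulse_brake"]),
               tolerance = 1e-9)
  expect_equal(unname(df["ap_negative_peak"]), unname(-d["ap_positive_peak"]),
               tolerance = 1e-9)
})

test_that("the impulse split landmark is configurable", {
  s <- analytic_stance()
  lm <- find_vertical_landmarks(s$vz, s$t)
  iv <- grf_impulses(s$vz, s$ap, s$t, lm, split = "valley")
  ip <- grf_impulses(s$vz, s$ap, s$t, lm, split = "second_peak")
  # the valley precedes the second peak, so impulse 1 grows with the split
  expect_lt(iv$v_impulse_1, ip$v_impulse_1)
  expect_equal(iv$v_impulse_1 + iv$v_impulse_2, ip$v_impulse_1 + ip$v_impulse_2,
               tolerance = 1e-9)
})
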