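#' Normalize a force series to body weights
#'
#' @param force_N Force series in newtons.
#' @param body_mass_kg Body mass in kg (> 0).
#' @param g Gravitational acceleration, default 9.81 m/s^2.
#' @return Series in body weights (BW).
#' @export
normalize_bw <- function(force_N, body_mass_kg, g = 9.81) {
  if (!is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("body mass must be positive")
  force_N / (body_mass_kg * g)
}

grf_variable_names <- function() {
  c("v_first_peak", "v_second_peak", "loading_rate",
    "v_impulse_1", "v_impulse_2",
    "ap_negative_peak", "ap_positive_peak",
    "ap_impulse_brake", "ap_impulse_prop")
}

#' Locate the vertical-force landmarks of one stance
#'
#' Finds the impact transient (first local maximum within the first 40%
#' of stance), the valley after it, and the active second peak (global
#' maximum after the first peak). When the stance has no distinct
#' impact transient, both the first peak and the valley degenerate to
#' the point of maximum curvature of the rising limb and the
#' `degenerate` flag is set.
#'
#' @param vgrf_bw Vertical force over one stance, in BW.
#' @param time_s Matching time vector.
#' @return List with `first_peak`, `valley`, `second_peak` (each a list
#'   `value`, `time`, `index`) and logical `degenerate`.
#' @export
find_vertical_landmarks <- function(vgrf_bw, time_s) {
  n <- length(vgrf_bw)
  if (n < 5) stop("stance too short for landmark detection")
  if (all(diff(vgrf_bw) >= 0) || all(diff(vgrf_bw) <= 0))
    stop("stance series is monotone; no landmarks")
  i_max <- which.max(vgrf_bw)
  # interior local maxima (plateau-tolerant) in the first 40% of stance
  lim <- max(3, floor(0.4 * n))
  locmax <- which(diff(sign(diff(vgrf_bw))) < 0) + 1
  locmax <- locmax[locmax <= lim & locmax < i_max]
  degenerate <- length(locmax) == 0
  if (!degenerate) {
    i1 <- locmax[1]
    iv <- i1 - 1 + which.min(vgrf_bw[i1:i_max])
  } else {
    # no impact transient: use the most concave-down point of the
    # rising limb up to the single peak
    rise <- 2:(i_max - 1)
    curv <- diff(vgrf_bw, differences = 2)[rise - 1]
    i1 <- rise[which.min(curv)]
    iv <- i1
  }
  mk <- function(i) list(value = vgrf_bw[i], time = time_s[i], index = i)
  list(first_peak = mk(i1), valley = mk(iv), second_peak = mk(i_max),
       degenerate = degenerate)
}

#' Vertical loading rate
#'
#' Secant slope of the rising vertical force between the first times it
#' crosses 20% and 80% of the first-peak magnitude, with the crossing
#' times linearly interpolated between samples.
#'
#' @param vgrf_bw Vertical stance force in BW.
#' @param time_s Matching time vector.
#' @param first_peak The `first_peak` element of
#'   [find_vertical_landmarks()] (or any list with `value` and `index`).
#' @return Loading rate in BW/s.
#' @export
loading_rate <- function(vgrf_bw, time_s, first_peak) {
  cross_time <- function(level) {
    seg <- seq_len(first_peak$index)
    i <- which(vgrf_bw[seg] >= level)[1]
    if (is.na(i)) stop("loading-rate crossing not found on the rising limb")
    if (i == 1) return(time_s[1])
    frac <- (level - vgrf_bw[i - 1]) / (vgrf_bw[i] - vgrf_bw[i - 1])
    time_s[i - 1] + frac * (time_s[i] - time_s[i - 1])
  }
  t20 <- cross_time(0.2 * first_peak$value)
  t80 <- cross_time(0.8 * first_peak$value)
  if (t80 <= t20) stop("degenerate rising limb: 80% crossing not after 20% crossing")
  0.6 * first_peak$value / (t80 - t20)
}

# first braking-to-propulsion zero crossing, linearly interpolated.
# In the canonical convention (braking negative first) this is the first
# negative-to-positive crossing; a sign-flipped input is handled
# symmetrically so the braking/propulsion phases keep their identities.
ap_zero_crossing <- function(ap_bw, time_s) {
  s <- sign(ap_bw)
  s0 <- s[s != 0][1]
  if (is.na(s0)) stop("anteroposterior force is identically zero")
  idx <- if (s0 < 0) which(s[-length(s)] < 0 & s[-1] >= 0)
         else        which(s[-length(s)] > 0 & s[-1] <= 0)
  if (!length(idx)) stop("anteroposterior force never crosses from braking to propulsion")
  i <- idx[1]
  frac <- -ap_bw[i] / (ap_bw[i + 1] - ap_bw[i])
  list(time = time_s[i] + frac * (time_s[i + 1] - time_s[i]), index = i)
}

trapz_between <- function(t, y, t0, t1) {
  # trapezoidal integral of y(t) over [t0, t1] with interpolated endpoints
  inner <- which(t > t0 & t < t1)
  tt <- c(t0, t[inner], t1)
  yy <- c(stats::approx(t, y, t0)$y, y[inner], stats::approx(t, y, t1)$y)
  pracma::trapz(tt, yy)
}

#' Stance impulses of the vertical and anteroposterior force
#'
#' Trapezoidal integration of the BW-normalized forces over the four
#' sub-intervals: vertical from stance start to the split landmark and
#' from the split to stance end; anteroposterior over the braking phase
#' (start to the first negative-to-positive zero crossing) and the
#' propulsion phase (crossing to end).
#'
#' @param vgrf_bw,ap_bw Vertical and anteroposterior stance series (BW).
#' @param time_s Matching time vector.
#' @param landmarks Result of [find_vertical_landmarks()].
#' @param split Where to split the vertical impulses: `"valley"`
#'   (default; the valley after the first peak) or `"second_peak"`.
#' @return Named list `v_impulse_1`, `v_impulse_2`, `ap_impulse_brake`,
#'   `ap_impulse_prop` (BW.s).
#' @export
grf_impulses <- function(vgrf_bw, ap_bw, time_s, landmarks,
                         split = c("valley", "second_peak")) {
  split <- match.arg(split)
  t_split <- if (split == "valley") landmarks$valley$time else landmarks$second_peak$time
  t0 <- time_s[1]; t1 <- time_s[length(time_s)]
  zc <- ap_zero_crossing(ap_bw, time_s)
  i_a <- trapz_between(time_s, ap_bw, t0, zc$time)
  i_b <- trapz_between(time_s, ap_bw, zc$time, t1)
  # braking is the decelerating (negative-impulse) phase regardless of
  # the input's sign convention
  list(v_impulse_1 = trapz_between(time_s, vgrf_bw, t0, t_split),
       v_impulse_2 = trapz_between(time_s, vgrf_bw, t_split, t1),
       ap_impulse_brake = min(i_a, i_b),
       ap_impulse_prop  = max(i_a, i_b))
}

extract_discrete_one <- function(vgrf_bw, ap_bw, time_s, split = "valley") {
  lm <- find_vertical_landmarks(vgrf_bw, time_s)
  imp <- grf_impulses(vgrf_bw, ap_bw, time_s, lm, split)
  c(v_first_peak = lm$first_peak$value,
    v_second_peak = lm$second_peak$value,
    loading_rate = loading_rate(vgrf_bw, time_s, lm$first_peak),
    v_impulse_1 = imp$v_impulse_1,
    v_impulse_2 = imp$v_impulse_2,
    ap_negative_peak = min(ap_bw),
    ap_positive_peak = max(ap_bw),
    ap_impulse_brake = imp$ap_impulse_brake,
    ap_impulse_prop = imp$ap_impulse_prop)
}

#' Extract the nine discrete GRF variables of a trial
#'
#' Filters the two force channels (100 Hz corner), normalizes to body
#' weight, detects stances, extracts the nine discrete variables
#' per stance (vertical first/second peaks, loading rate, two vertical
#' impulses, anteroposterior peaks and braking/propulsion impulses) and
#' averages them over the first `n_steps` stances. Alternatively the
#' variables can be computed once on the point-wise averaged stance.
#'
#' @param trial A [raw_trial()].
#' @param n_steps Number of stances to use (default 10).
#' @param aggregation `"per_stance"` (default: extract per stance, then
#'   average the nine values) or `"mean_curve"` (average the
#'   time-normalized stances first, then extract once).
#' @param split Vertical impulse split landmark, see [grf_impulses()].
#' @param grf_cutoff_hz,threshold_N Filter corner and stance threshold.
#' @return Named numeric vector of the nine variables (BW, BW/s, BW.s).
#' @export
extract_discrete <- function(trial, n_steps = 10,
                             aggregation = c("per_stance", "mean_curve"),
                             split = c("valley", "second_peak"),
                             grf_cutoff_hz = 100, threshold_N = 10) {
  aggregation <- match.arg(aggregation); split <- match.arg(split)
  stopifnot(inherits(trial, "raw_trial"))
  rate <- 1 / diff(trial$grf$time_s[1:2])
  fz <- butterworth_lowpass(trial$grf$fz_N, grf_cutoff_hz, rate)
  fy <- butterworth_lowpass(trial$grf$fy_N, grf_cutoff_hz, rate)
  stances <- detect_stances(fz, threshold_N)
  if (nrow(stances) < n_steps)
    stop("trial contains only ", nrow(stances), " complete stances; ",
         n_steps, " required")
  stances <- stances[seq_len(n_steps), , drop = FALSE]
  fz_bw <- normalize_bw(fz, trial$body_mass_kg)
  fy_bw <- normalize_bw(fy, trial$body_mass_kg)
  if (aggregation == "per_stance") {
    per <- lapply(seq_len(n_steps), function(k) {
      idx <- stances$start[k]:(stances$end[k] - 1)
      tryCatch(extract_discrete_one(fz_bw[idx], fy_bw[idx], trial$grf$time_s[idx], split),
               error = function(e) stop("stance ", k, ": ", conditionMessage(e)))
    })
    return(colMeans(do.call(rbind, per)))
  }
  # mean_curve: time-normalize each stance, average, rebuild a time axis
  # with the mean stance duration
  npt <- 101
  vz <- rowMeans(vapply(seq_len(n_steps), function(k) {
    idx <- stances$start[k]:(stances$end[k] - 1)
    time_normalize(fz_bw[idx], npt)
  }, numeric(npt)))
  ap <- rowMeans(vapply(seq_len(n_steps), function(k) {
    idx <- stances$start[k]:(stances$end[k] - 1)
    time_normalize(fy_bw[idx], npt)
  }, numeric(npt)))
  mean_dur <- mean((stances$end - stances$start) / rate)
  tt <- seq(0, mean_dur, length.out = npt)
  extract_discrete_one(vz, ap, tt, split)
}

#' Discrete GRF table for a whole cohort
#'
#' @param cohort A `runner_cohort`.
#' @param ... Passed to [extract_discrete()].
#' @return Data frame: `subject_id` plus the nine variables.
#' @export
grf_table <- function(cohort, ...) {
  rows <- lapply(names(cohort$trials), function(id)
    c(list(subject_id = id),
      as.list(extract_discrete(cohort$trials[[id]], ...))))
  do.call(rbind, lapply(rows, as.data.frame))
}
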