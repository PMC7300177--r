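#' Zero-lag fourth-order Butterworth low-pass filter
#'
#' Forward-backward pass of a 2nd-order Butterworth filter, the
#' dominant biomechanics convention for a "zero-lag fourth-order"
#' filter: the dual pass doubles the effective order to 4 and cancels
#' the phase, leaving the amplitude response |H|^2 of the underlying
#' 2nd-order design (gain 1/2 at the corner frequency). The signal is
#' extended by odd reflection at both ends before filtering so that the
#' dual pass is free of the start-up transients a zero-padded filter
#' would introduce.
#'
#' @param x Uniformly sampled numeric series.
#' @param cutoff_hz Corner frequency in Hz (must be below Nyquist).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Filtered series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, cutoff_hz, sample_rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  n <- length(x)
  pad <- ceiling(10 * sample_rate_hz / cutoff_hz)
  if (n < 12 || n - 1 < 9)
    stop("series too short to filter (need at least 12 samples)")
  pad <- min(pad, n - 1)
  bf <- signal::butter(2, cutoff_hz / (sample_rate_hz / 2), type = "low")
  # odd (point-mirrored) reflection: continuous in value and slope
  left  <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}

#' Detect stance phases from the vertical ground reaction force
#'
#' A stance begins at the first sample at or above the force threshold
#' following a sub-threshold sample and ends before the first subsequent
#' sample back below the threshold. Intervals are half-open
#' `[start, end)` in 1-based sample indices: `end` is the first index
#' after the stance. Incomplete leading/trailing stances (already in
#' contact at the start of the record, or still in contact at the end)
#' are discarded.
#'
#' @param vertical_grf Vertical force series in newtons (filtered).
#' @param threshold_N Contact threshold, default 10 N.
#' @return Data frame with columns `start`, `end`; zero rows when no
#'   complete stance exists (this is a valid empty result, not an
#'   error).
#' @export
detect_stances <- function(vertical_grf, threshold_N = 10) {
  if (threshold_N <= 0) stop("threshold must be positive")
  above <- vertical_grf >= threshold_N
  n <- length(above)
  if (n == 0 || !any(above)) return(data.frame(start = integer(), end = integer()))
  d <- diff(c(FALSE, above, FALSE))  # +1 at rises, -1 one past falls
  starts <- which(d == 1)
  ends <- which(d == -1)
  # drop a stance already in progress at sample 1 or unfinished at n
  if (length(starts) && starts[1] == 1 && above[1]) {
    starts <- starts[-1]; ends <- ends[-1]
  }
  if (length(ends) && ends[length(ends)] == n + 1 && above[n]) {
    starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
  }
  data.frame(start = starts, end = ends)
}

#' Time-normalize a stance segment to a fixed number of points
#'
#' Linear interpolation of the segment onto `n_points` equally spaced
#' positions spanning it inclusively (the canonical 0-100% stance grid
#' with the default 101 points). The first and last samples are
#' preserved exactly.
#'
#' @param segment Numeric series of length >= 2.
#' @param n_points Output length, default 101.
#' @return Numeric vector of `n_points` values.
#' @export
time_normalize <- function(segment, n_points = 101) {
  if (length(segment) < 2) stop("segment must contain at least 2 samples")
  stats::approx(seq(0, 1, length.out = length(segment)), segment,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Stance waveform set container
#'
#' @param subject_id Subject identifier.
#' @param waveforms Numeric matrix 10 x 101: rows named by
#'   [waveform_channels()], columns the 0-100% stance grid.
#' @param n_steps_averaged Number of stances averaged.
#' @return An object of class `waveform_set`.
#' @export
waveform_set <- function(subject_id, waveforms, n_steps_averaged) {
  if (!is.matrix(waveforms) || nrow(waveforms) != 10 || ncol(waveforms) != 101)
    stop("waveforms must be a 10 x 101 matrix")
  if (!identical(rownames(waveforms), waveform_channels()))
    stop("waveform rows must be the canonical channel vocabulary, in order")
  structure(list(subject_id = subject_id, waveforms = waveforms,
                 n_steps_averaged = n_steps_averaged),
            class = "waveform_set")
}

#' Build a subject's averaged stance waveform set from a raw trial
#'
#' The full preprocessing chain for one subject: low-pass filter the
#' vertical force (100 Hz cutoff) and the kinematic/kinetic channels
#' (15 Hz cutoff), detect stances with the 10 N threshold on the
#' filtered vertical force, map each stance window from the force-plate
#' clock to the kinematic clock (simultaneous acquisition start, with an
#' optional constant offset), resample each channel within each stance
#' onto the 101-point stance grid, and average pointwise over the first
#' `n_steps` consecutive stances.
#'
#' @param trial A [raw_trial()].
#' @param subject_id Identifier stored in the result.
#' @param n_steps Number of consecutive stances to average (default 10).
#' @param kin_cutoff_hz,grf_cutoff_hz Filter corner frequencies
#'   (defaults 15 and 100 Hz).
#' @param threshold_N Stance-detection threshold (default 10 N).
#' @param n_points Stance grid size (default 101).
#' @param clock_offset_s Constant offset added to stance times when
#'   reading the kinematic clock (default 0: clocks are synchronous).
#' @return A [waveform_set()].
#' @export
build_waveform_set <- function(trial, subject_id = "subject",
                               n_steps = 10,
                               kin_cutoff_hz = 15, grf_cutoff_hz = 100,
                               threshold_N = 10, n_points = 101,
                               clock_offset_s = 0) {
  stopifnot(inherits(trial, "raw_trial"))
  grf_rate <- 1 / diff(trial$grf$time_s[1:2])
  kin_rate <- 1 / diff(trial$kinematics$time_s[1:2])
  fz <- butterworth_lowpass(trial$grf$fz_N, grf_cutoff_hz, grf_rate)
  stances <- detect_stances(fz, threshold_N)
  if (nrow(stances) < n_steps)
    stop("trial contains only ", nrow(stances), " complete stances; ",
         n_steps, " required")
  stances <- stances[seq_len(n_steps), , drop = FALSE]
  channels <- waveform_channels()
  kin <- vapply(channels, function(ch)
    butterworth_lowpass(trial$kinematics[[ch]], kin_cutoff_hz, kin_rate),
    numeric(nrow(trial$kinematics)))
  acc <- matrix(0, nrow = length(channels), ncol = n_points,
                dimnames = list(channels, NULL))
  for (k in seq_len(n_steps)) {
    t0 <- trial$grf$time_s[stances$start[k]] + clock_offset_s
    t1 <- trial$grf$time_s[stances$end[k] - 1] + clock_offset_s
    tt <- seq(t0, t1, length.out = n_points)
    for (ch in channels)
      acc[ch, ] <- acc[ch, ] + stats::approx(trial$kinematics$time_s, kin[, ch],
                                             xout = tt, rule = 2)$y
  }
  waveform_set(subject_id, acc / n_steps, n_steps)
}

#' Preprocess every subject of a cohort
#'
#' @param cohort A `runner_cohort`.
#' @param ... Passed to [build_waveform_set()].
#' @return Named list of [waveform_set()] objects.
#' @export
preprocess_cohort <- function(cohort, ...) {
  sets <- lapply(names(cohort$trials), function(id)
    build_waveform_set(cohort$trials[[id]], subject_id = id, ...))
  names(sets) <- names(cohort$trials)
  sets
}

#' Write waveform sets to a long-format CSV
#'
#' Schema: `subject_id`, `waveform_name`, `t000` ... `t100`.
#' @param sets List of [waveform_set()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(ws) {
    df <- as.data.frame(ws$waveforms)
    names(df) <- sprintf("t%03d", 0:100)
    cbind(data.frame(subject_id = ws$subject_id,
                     waveform_name = rownames(ws$waveforms)), df)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
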