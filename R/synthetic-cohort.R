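#' Configuration for a synthetic runner cohort
#'
#' Controls the group sizes, planted group effects, and noise levels of
#' the synthetic cohort generator. Defaults reproduce the reference
#' study conditions the pipeline was designed around: three experience groups
#' of 24/23/31 runners, 10 stance phases per subject, a two-peaked
#' vertical ground reaction force (first peak near 1.1 BW at ~15% of
#' stance, second near 2.2 BW at mid-stance) and a biphasic
#' anteroposterior force peaking near +/-0.23 BW.
#'
#' The planted experience effect is an additive stance-wide shift of the
#' first-metatarsophalangeal (Met-Hal) and calcaneus-metatarsal
#' (Cal-Met) sagittal angles: the less-experienced group gets
#' `+met_hal_offset_deg` extra toe dorsiflexion and
#' `-cal_met_offset_deg` extra arch plantarflexion, the experienced
#' group the sign-flipped shifts, the moderate group none. The moderate
#' group instead carries a low-amplitude mid-stance shape deviation
#' (`moderate_shape_deg`) on the ankle frontal and Cal-Met transverse
#' channels, emulating the subtle, high-order-component pattern that
#' distinguishes intermediate runners.
#'
#' @param group_sizes Integer triple `c(less, moderate, experienced)`,
#'   each >= 2.
#' @param met_hal_offset_deg Stance-wide Met-Hal sagittal shift (deg).
#' @param cal_met_offset_deg Stance-wide Cal-Met sagittal shift (deg).
#' @param moderate_shape_deg Amplitude (deg) of the moderate group's
#'   mid-stance shape deviation.
#' @param subject_sd_deg Between-subject waveform SD (deg; pointwise).
#' @param step_sd_deg Within-subject step-to-step SD (deg; pointwise).
#' @param grf_noise_bw Additive GRF noise SD in body weights; also used
#'   as the relative SD of per-step peak-amplitude jitter.
#' @param n_steps Stance phases generated per subject (>= 1).
#' @param seed Integer random seed.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(group_sizes = c(less = 24, moderate = 23, experienced = 31),
                          met_hal_offset_deg = 5,
                          cal_met_offset_deg = 4,
                          moderate_shape_deg = 2.5,
                          subject_sd_deg = 3,
                          step_sd_deg = 1.5,
                          grf_noise_bw = 0.03,
                          n_steps = 10,
                          seed = 1) {
  cfg <- list(group_sizes = group_sizes,
              met_hal_offset_deg = met_hal_offset_deg,
              cal_met_offset_deg = cal_met_offset_deg,
              moderate_shape_deg = moderate_shape_deg,
              subject_sd_deg = subject_sd_deg,
              step_sd_deg = step_sd_deg,
              grf_noise_bw = grf_noise_bw,
              n_steps = n_steps, seed = seed)
  if (length(group_sizes) != 3 || any(group_sizes < 2) ||
      any(group_sizes != round(group_sizes)))
    stop("invalid cohort config field 'group_sizes': need three integer sizes >= 2")
  for (f in c("subject_sd_deg", "step_sd_deg", "grf_noise_bw"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop("invalid cohort config field '", f, "': must be a non-negative number")
  for (f in c("met_hal_offset_deg", "cal_met_offset_deg", "moderate_shape_deg"))
    if (!is.finite(cfg[[f]]))
      stop("invalid cohort config field '", f, "': must be finite")
  if (!is.finite(n_steps) || n_steps < 1 || n_steps != round(n_steps))
    stop("invalid cohort config field 'n_steps': must be an integer >= 1")
  if (!is.finite(seed) || seed != round(seed))
    stop("invalid cohort config field 'seed': must be an integer")
  names(cfg$group_sizes) <- experience_levels()
  structure(cfg, class = "cohort_config")
}

#' The ten stance waveform channel names, in canonical order
#'
#' Eight joint angles (ankle in three planes, medial longitudinal arch
#' sagittal, Met-Hal sagittal, Cal-Met in three planes) plus the ankle
#' sagittal moment and power.
#' @return Character vector of length 10.
#' @export
waveform_channels <- function() {
  c("ankle_sagittal", "ankle_frontal", "ankle_transverse",
    "mla_sagittal", "methal_sagittal",
    "calmet_sagittal", "calmet_frontal", "calmet_transverse",
    "ankle_moment", "ankle_power")
}

# per-channel noise scale: angle channels in degrees, moment (N*m/kg)
# and power (W/kg) scaled to a comparable relative variability
channel_noise_scale <- function() {
  c(ankle_sagittal = 1, ankle_frontal = 1, ankle_transverse = 1,
    mla_sagittal = 1, methal_sagittal = 1,
    calmet_sagittal = 1, calmet_frontal = 1, calmet_transverse = 1,
    ankle_moment = 0.12, ankle_power = 0.8)
}

# smooth stance templates; s is stance fraction in [0, 1]
channel_template <- function(channel, s) {
  g <- function(mu, sg) exp(-((s - mu) / sg)^2)
  switch(channel,
    ankle_sagittal    = -8 + 20 * sin(pi * s) - 10 * g(0.9, 0.08),
    ankle_frontal     = 2 - 6 * sin(pi * s),
    ankle_transverse  = -3 - 4 * sin(2 * pi * s),
    mla_sagittal      = 131 - 8 * sin(pi * s),
    methal_sagittal   = 10 + 5 * sin(pi * s) + 25 * g(0.8, 0.12),
    calmet_sagittal   = -15 - 8 * sin(pi * s),
    calmet_frontal    = 3 + 4 * sin(pi * s),
    calmet_transverse = -2 + 3 * sin(2 * pi * s),
    ankle_moment      = 2.5 * sin(pi * s)^2,
    ankle_power       = -6 * g(0.35, 0.12) + 10 * g(0.85, 0.07),
    stop("unknown waveform channel: ", channel))
}

# mid-stance bump carried by the moderate group
moderate_bump <- function(s) exp(-((s - 0.5) / 0.1)^2)

# smooth random curve with exactly unit pointwise SD at every s:
# sqrt(.5)*z0 + sqrt(.5)*(z1 sin(pi s) + z2 cos(pi s)) has variance
# .5 + .5 (sin^2 + cos^2) = 1 for iid standard normal z
random_smooth_curve <- function(s) {
  z <- stats::rnorm(3)
  sqrt(0.5) * z[1] + sqrt(0.5) * (z[2] * sin(pi * s) + z[3] * cos(pi * s))
}

#' Draw a training history consistent with one experience group
#'
#' Samples training frequency, weekly volume, years of practice and race
#' count from truncated normal distributions whose means follow the
#' group-level characteristics the generator emulates and whose spreads
#' are tight enough that the fuzzy scorer reproduces the intended label
#' for at least 90% of draws. Physiologic bounds are enforced
#' (frequency 1-7 sessions/week, volume 5-120 km/week).
#'
#' @param group_label One of `"less"`, `"moderate"`, `"experienced"`.
#' @param seed Optional integer seed (for standalone reproducibility).
#' @param sd_scale Multiplier on the sampling SDs; 0 returns the group
#'   means exactly.
#' @return A [training_history()].
#' @export
generate_training_history <- function(group_label, seed = NULL, sd_scale = 1) {
  pars <- list(
    less        = list(f = c(3.1, 0.5), v = c(20, 4),    y = c(2.8, 1.2), r = c(19, 10)),
    moderate    = list(f = c(3.9, 0.4), v = c(29.5, 3.5), y = c(7.9, 1.4), r = c(32, 8)),
    experienced = list(f = c(4.5, 0.6), v = c(58, 9),    y = c(10, 2),    r = c(58, 14)))
  if (!group_label %in% names(pars))
    stop("unknown experience group label: '", group_label, "'")
  if (!is.null(seed)) set.seed(seed)
  p <- pars[[group_label]]
  rtn <- function(m, s, lo, hi) min(max(stats::rnorm(1, m, s * sd_scale), lo), hi)
  training_history(
    training_frequency = rtn(p$f[1], p$f[2], 1, 7),
    training_volume    = rtn(p$v[1], p$v[2], 5, 120),
    practice_time      = rtn(p$y[1], p$y[2], 0.2, 40),
    competitions       = round(rtn(p$r[1], p$r[2], 0, 300)))
}

# one subject's raw trial: GRF at 1000 Hz, kinematics at 200 Hz
generate_subject_trial <- function(group, cfg, body_mass_kg) {
  n_steps <- cfg$n_steps
  stance_dur <- stats::runif(n_steps, 0.25, 0.35)
  flight_dur <- stats::runif(n_steps + 1, 0.10, 0.15)
  # event times: flight, stance, flight, stance, ...
  stance_start <- numeric(n_steps)
  t <- flight_dur[1]
  for (k in seq_len(n_steps)) {
    stance_start[k] <- t
    t <- t + stance_dur[k] + flight_dur[k + 1]
  }
  total_dur <- t

  grf_t <- seq(0, total_dur, by = 1e-3)
  kin_t <- seq(0, total_dur, by = 5e-3)
  fz_bw <- numeric(length(grf_t))
  fy_bw <- numeric(length(grf_t))

  dir <- switch(group, less = 1, moderate = 0, experienced = -1)
  scl <- channel_noise_scale()
  channels <- waveform_channels()
  # frozen per-subject waveform deviation, one smooth curve per channel
  subj_dev <- lapply(channels, function(ch) {
    z <- stats::rnorm(3)
    function(s) cfg$subject_sd_deg * scl[[ch]] *
      (sqrt(0.5) * z[1] + sqrt(0.5) * (z[2] * sin(pi * s) + z[3] * cos(pi * s)))
  })
  names(subj_dev) <- channels

  kin_vals <- matrix(NA_real_, nrow = length(kin_t), ncol = length(channels),
                     dimnames = list(NULL, channels))
  for (k in seq_len(n_steps)) {
    t0 <- stance_start[k]; dur <- stance_dur[k]
    gi <- which(grf_t >= t0 & grf_t <= t0 + dur)
    s <- (grf_t[gi] - t0) / dur
    # vertical force: main support hump + impact transient, per-step jitter
    a_main <- 2.2 * (1 + cfg$grf_noise_bw * stats::rnorm(1))
    a_imp  <- 0.95 * (1 + cfg$grf_noise_bw * stats::rnorm(1))
    vz <- a_main * exp(-((s - 0.5) / 0.22)^2) + a_imp * exp(-((s - 0.15) / 0.05)^2)
    vz <- vz - (vz[1] * (1 - s) + vz[length(vz)] * s)  # pin ends to zero
    zn <- stats::rnorm(2)
    vz <- vz + cfg$grf_noise_bw * sin(pi * s) * (zn[1] * sin(pi * s) + zn[2] * sin(2 * pi * s))
    fz_bw[gi] <- pmax(vz, 0)
    # anteroposterior: braking (negative) then propulsion, one crossing
    a_ap <- 0.23 * (1 + cfg$grf_noise_bw * stats::rnorm(1))
    ap <- -a_ap * sin(2 * pi * s)
    zn <- stats::rnorm(1)
    ap <- ap + 0.5 * cfg$grf_noise_bw * zn * sin(pi * s)^2
    fy_bw[gi] <- ap

    ki <- which(kin_t >= t0 & kin_t <= t0 + dur)
    sk <- (kin_t[ki] - t0) / dur
    for (ch in channels) {
      val <- channel_template(ch, sk) + subj_dev[[ch]](sk)
      if (ch == "methal_sagittal") val <- val + dir * cfg$met_hal_offset_deg
      if (ch == "calmet_sagittal") val <- val - dir * cfg$cal_met_offset_deg
      if (group == "moderate" && ch == "ankle_frontal")
        val <- val + cfg$moderate_shape_deg * moderate_bump(sk)
      if (group == "moderate" && ch == "calmet_transverse")
        val <- val - cfg$moderate_shape_deg * moderate_bump(sk)
      # step-to-step deviation: fresh smooth curve per step and channel
      val <- val + cfg$step_sd_deg * scl[[ch]] * random_smooth_curve(sk)
      kin_vals[ki, ch] <- val
    }
  }
  # bridge flight-phase kinematics by interpolation between stances
  for (ch in channels) {
    known <- which(!is.na(kin_vals[, ch]))
    kin_vals[, ch] <- stats::approx(kin_t[known], kin_vals[known, ch],
                                    xout = kin_t, rule = 2)$y
  }
  bw_N <- body_mass_kg * 9.81
  raw_trial(grf = data.frame(time_s = grf_t, fz_N = fz_bw * bw_N, fy_N = fy_bw * bw_N),
            kinematics = data.frame(time_s = kin_t, kin_vals, check.names = FALSE),
            body_mass_kg = body_mass_kg)
}

#' Raw trial container
#'
#' Holds one subject's synchronously started recordings: ground reaction
#' forces sampled at 1000 Hz (`time_s`, vertical `fz_N`, anteroposterior
#' `fy_N`) and the ten kinematic/kinetic channels sampled at 200 Hz.
#'
#' @param grf Data frame `time_s`, `fz_N`, `fy_N` on a uniform 1 kHz grid.
#' @param kinematics Data frame `time_s` plus the ten
#'   [waveform_channels()] on a uniform 200 Hz grid.
#' @param body_mass_kg Subject body mass (> 0).
#' @return An object of class `raw_trial`.
#' @export
raw_trial <- function(grf, kinematics, body_mass_kg) {
  stopifnot(all(c("time_s", "fz_N", "fy_N") %in% names(grf)),
            all(c("time_s", waveform_channels()) %in% names(kinematics)))
  if (!is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("body_mass_kg must be positive")
  for (tt in list(grf$time_s, kinematics$time_s)) {
    dt <- diff(tt)
    if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-9))
      stop("sampling grid must be strictly increasing and uniform")
  }
  structure(list(grf = grf, kinematics = kinematics,
                 body_mass_kg = body_mass_kg),
            class = "raw_trial")
}

#' Generate a complete synthetic cohort
#'
#' Produces per-subject metadata (training history drawn to match each
#' group's fuzzy score band, body mass) and raw trials (1 kHz ground
#' reaction forces, 200 Hz kinematics) with the planted group effects of
#' the configuration. A single global seed drives a per-subject seed
#' sequence, so the cohort is fully reproducible and individual subjects
#' can be regenerated independently.
#'
#' @param config A [cohort_config()].
#' @return A `runner_cohort`: list with `metadata` (data frame) and
#'   `trials` (named list of [raw_trial()] objects).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(experience_levels(), times = config$group_sizes)
  n <- length(groups)
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max, n)
  mass_mean <- c(less = 71.1, moderate = 74.7, experienced = 67.1)
  meta <- vector("list", n); trials <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    g <- groups[i]
    hist <- generate_training_history(g)
    mass <- min(max(stats::rnorm(1, mass_mean[[g]], 8), 45), 110)
    meta[[i]] <- data.frame(subject_id = ids[i], group = g,
                            training_frequency = hist$training_frequency,
                            training_volume_km = hist$training_volume,
                            years_practice = hist$practice_time,
                            n_races = hist$competitions,
                            body_mass_kg = mass)
    trials[[i]] <- generate_subject_trial(g, config, mass)
  }
  metadata <- do.call(rbind, meta)
  metadata$group <- factor(metadata$group, levels = experience_levels())
  names(trials) <- ids
  structure(list(metadata = metadata, trials = trials, config = config),
            class = "runner_cohort")
}

#' @export
print.runner_cohort <- function(x, ...) {
  cat("Synthetic runner cohort:", nrow(x$metadata), "subjects (",
      paste(table(x$metadata$group), collapse = "/"), "),",
      x$config$n_steps, "stances each\n")
  invisible(x)
}

#' Write a cohort to disk in the raw CSV schema
#'
#' Writes `metadata.csv` plus one directory per subject containing
#' `grf.csv` (`time_s`, `fz_N`, `fy_N`) and `kinematics.csv` (`time_s`
#' plus the ten channels). The same schema is accepted for user-supplied
#' data by [read_cohort()].
#'
#' @param cohort A `runner_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (id in names(cohort$trials)) {
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    utils::write.csv(cohort$trials[[id]]$grf, file.path(sd, "grf.csv"), row.names = FALSE)
    utils::write.csv(cohort$trials[[id]]$kinematics, file.path(sd, "kinematics.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from the raw CSV schema
#'
#' @param dir Directory produced by [write_cohort()] (or user data in
#'   the same layout).
#' @return A `runner_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv under ", dir)
  metadata <- utils::read.csv(meta_path)
  trials <- lapply(metadata$subject_id, function(id) {
    raw_trial(grf = utils::read.csv(file.path(dir, id, "grf.csv")),
              kinematics = utils::read.csv(file.path(dir, id, "kinematics.csv"),
                                           check.names = FALSE),
              body_mass_kg = metadata$body_mass_kg[metadata$subject_id == id])
  })
  names(trials) <- metadata$subject_id
  if ("group" %in% names(metadata))
    metadata$group <- factor(metadata$group, levels = experience_levels())
  structure(list(metadata = metadata, trials = trials, config = NULL),
            class = "runner_cohort")
}
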