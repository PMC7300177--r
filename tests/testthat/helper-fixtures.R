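# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small planted-effect cohort used across preprocessing/PCA tests
small_cohort <- function() fixture("small_cohort", function() {
  generate_cohort(cohort_config(group_sizes = c(less = 5, moderate = 5, experienced = 6),
                                n_steps = 10, seed = 42))
})

small_prepared <- function() fixture("small_prepared", function() {
  co <- small_cohort()
  sets <- preprocess_cohort(co)
  grf <- grf_table(co)
  wm <- assemble_matrix(sets)
  pca <- fit_waveform_pca(wm)
  labels <- stats::setNames(co$metadata$group, co$metadata$subject_id)
  list(cohort = co, sets = sets, grf = grf, wm = wm, pca = pca,
       labels = labels,
       candidates = build_candidates(pca, grf, labels))
})

# deterministic trial with identical stance cycles: fixed 0.30 s stance /
# 0.12 s flight, smooth vertical-force bump, sinusoidal kinematics
identical_steps_trial <- function(n_steps = 12, mass = 70) {
  stance <- 0.30; flight <- 0.12
  total <- flight + n_steps * (stance + flight)
  gt <- seq(0, total, by = 1e-3)
  kt <- seq(0, total, by = 5e-3)
  fz <- numeric(length(gt))
  starts <- flight + (0:(n_steps - 1)) * (stance + flight)
  for (t0 in starts) {
    i <- which(gt >= t0 & gt <= t0 + stance)
    s <- (gt[i] - t0) / stance
    fz[i] <- mass * 9.81 * (2.2 * exp(-((s - 0.5) / 0.22)^2) +
                              0.95 * exp(-((s - 0.15) / 0.05)^2))
    fz[i] <- fz[i] - (fz[i][1] * (1 - s) + fz[i][length(i)] * s)
  }
  fy <- numeric(length(gt))
  for (t0 in starts) {
    i <- which(gt >= t0 & gt <= t0 + stance)
    s <- (gt[i] - t0) / stance
    fy[i] <- -mass * 9.81 * 0.23 * sin(2 * pi * s)
  }
  kin <- sapply(seq_along(waveform_channels()), function(j) {
    v <- numeric(length(kt))
    for (t0 in starts) {
      i <- which(kt >= t0 & kt <= t0 + stance)
      s <- (kt[i] - t0) / stance
      v[i] <- j + 10 * sin(pi * s + j / 3)
    }
    # hold flight values by interpolation between stances
    known <- which(v != 0)
    stats::approx(kt[known], v[known], xout = kt, rule = 2)$y
  })
  colnames(kin) <- waveform_channels()
  raw_trial(grf = data.frame(time_s = gt, fz_N = fz, fy_N = fy),
            kinematics = data.frame(time_s = kt, kin, check.names = FALSE),
            body_mass_kg = mass)
}

# waveform_set built directly from a generator function of (channel, s)
synthetic_set <- function(id, fn) {
  s <- seq(0, 1, length.out = 101)
  w <- t(vapply(waveform_channels(), function(ch) fn(ch, s), numeric(101)))
  rownames(w) <- waveform_channels()
  waveform_set(id, w, 10)
}

# n subjects of pure-noise waveform sets (generic full-rank matrix)
random_sets <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    synthetic_set(sprintf("R%03d", i), function(ch, s) rnorm(length(s))))
}
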