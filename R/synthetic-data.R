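# Seeded synthetic SIT cohorts: actress reference track, participant facial /
# gaze frame tables, and voiced audio with controlled prosody.

# Segment weight profiles shaping where an AU is active. Weights multiply the
# subject's whole-conversation occurrence target and are normalized so the
# duration-weighted mean over analyzed segments is 1.
segment_weights <- function(sched, au) {
  w <- rep(1, nrow(sched))
  pos <- sched$valence == "positive"
  neg <- sched$valence == "negative"
  neu <- sched$valence == "neutral"
  if (au %in% c("AU06", "AU12")) {
    w[pos] <- 2.0; w[neu] <- 0.5; w[neg] <- 0.6
  } else if (au %in% c("AU04", "AU09")) {
    w[neg] <- 2.0; w[neu] <- 0.7; w[pos] <- 0.5
  }
  dur <- sched$end - sched$start
  w / sum(w * dur) * sum(dur)
}

group_effects_paper <- function() {
  nt <- list(
    au_occ = c(AU12 = 0.40, AU06 = 0.12),
    au_int = c(AU12 = 0.52, AU06 = 0.40),
    au4_int_negative = 0.03, au4_int_baseline = 0.056,
    mimicry = c(AU06 = 0.19, AU12 = 0.16, AU04 = 0.10, AU09 = 0.10),
    f0 = c(male = 121.68, female = 209.08),
    f0_sd = c(male = 11.68, female = 17.97),
    hnr = c(male = 10.84, female = 10.32),
    hnr_sd = c(male = 1.42, female = 1.47),
    jitter = 0.01, shimmer = 0.05,
    gaze_mean = c(horizontal = 0.02, vertical = -0.25),
    gaze_sd = c(horizontal = 0.06, vertical = 0.12),
    gaze_speed = c(horizontal = 0.65, vertical = 0.71),
    age_range = c(18, 49)
  )
  asd <- nt
  asd$au_occ <- c(AU12 = 0.09, AU06 = 0.02)
  asd$au_int <- c(AU12 = 0.16, AU06 = 0.35)
  asd$au4_int_negative <- 0.08
  asd$mimicry <- c(AU06 = 0.08, AU12 = 0.07, AU04 = 0.05, AU09 = 0.05)
  asd$f0 <- c(male = 139.67, female = 218.91)
  asd$f0_sd <- c(male = 16.22, female = 16.16)
  asd$hnr <- c(male = 8.50, female = 6.91)  # Table-ordered: NT above ASD
  asd$hnr_sd <- c(male = 1.44, female = 2.12)
  asd$gaze_mean <- c(horizontal = 0.01, vertical = -0.23)
  asd$gaze_sd <- c(horizontal = 0.07, vertical = 0.11)
  asd$gaze_speed <- c(horizontal = 0.67, vertical = 0.64)
  asd$age_range <- c(22, 62)
  list(NT = nt, ASD = asd)
}

#' Synthetic cohort specification
#'
#' Parameters of the synthetic-cohort generator. The `"paper"` preset
#' encodes the published group profiles: whole-conversation AU12/AU6
#' occurrence 0.40/0.12 (NT) vs 0.09/0.02 (ASD), AU4 intensity in the
#' negative part 0.03 vs 0.08, mimicry coupling 0.19 vs 0.08 (AU6),
#' group-by-gender F0 and HNR targets (HNR higher in NT, following the
#' descriptive table), equal jitter/shimmer, and near-null gaze
#' differences. The `"null"` preset gives both groups the NT profile and an
#' uninformative severity score, so every group contrast is exchangeable.
#'
#' @param n_per_group Subjects per group (>= 2; default 40).
#' @param gender_mix Fraction of female subjects per group (default 0.5).
#' @param seed Root seed; identical seeds give identical cohorts.
#' @param fps Video frame rate (default 30 frames/s).
#' @param audio_rate Audio sampling rate in Hz (default 16000).
#' @param voice_duration Synthesized speech duration per participant in
#'   seconds (default 20).
#' @param preset `"paper"` or `"null"`.
#' @param schedule A [segment_schedule()].
#' @param modalities Which modalities to simulate (subset of
#'   `c("face", "gaze", "voice")`); skipping audio speeds up large
#'   replicate runs.
#' @param aus AU channels to give structured activity; others get
#'   group-independent background activity.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 40, gender_mix = 0.5, seed = 1,
                        fps = 30, audio_rate = 16000, voice_duration = 20,
                        preset = c("paper", "null"),
                        schedule = default_schedule(),
                        modalities = c("face", "gaze", "voice"),
                        aus = sit_aus()) {
  preset <- match.arg(preset)
  assert_that(n_per_group >= 2, "n_per_group must be at least 2")
  assert_that(gender_mix >= 0 && gender_mix <= 1,
              "gender_mix must lie in [0, 1]")
  groups <- group_effects_paper()
  if (preset == "null") groups$ASD <- groups$NT
  occ <- unlist(lapply(groups, function(g) g$au_occ))
  assert_that(all(occ > 0 & occ < 1), "occurrence targets must lie in (0, 1)")
  structure(list(
    n_per_group = n_per_group, gender_mix = gender_mix, seed = seed,
    fps = fps, audio_rate = audio_rate, voice_duration = voice_duration,
    preset = preset, schedule = schedule, modalities = modalities,
    aus = aus, groups = groups,
    mimicry_lag = 0.5,       # reactive delay of the participant, seconds
    background_occ = 0.10,   # occurrence of non-structured AUs
    background_int = 0.20,   # intensity of non-structured AUs
    dropout_rate = 0.02,     # low-confidence frame rate
    fail_rate = 0.005        # tracking-failure frame rate
  ), class = "cohort_spec")
}

rectified_mean <- 1 / sqrt(2 * pi)  # E[max(Z, 0)] for Z ~ N(0, 1)

# latent -> presence/intensity channels given per-segment occurrence and
# intensity targets
channels_from_latent <- function(z, t, sched, occ_seg, int_seg) {
  pres <- integer(length(z))
  inten <- numeric(length(z))
  for (i in seq_len(nrow(sched))) {
    in_seg <- t >= sched$start[i] & t < sched$end[i]
    if (!any(in_seg)) next
    occ <- min(max(occ_seg[i], 0.005), 0.95)
    q <- stats::qnorm(1 - occ)
    pres[in_seg] <- as.integer(z[in_seg] > q)
    k <- int_seg[i] / rectified_mean
    inten[in_seg] <- pmin(k * pmax(z[in_seg], 0), 5)
  }
  list(presence = pres, intensity = inten)
}

#' Deterministic actress reference track
#'
#' The shared stimulus: one frame table of the actress's AU activity over
#' the conversation, identical for every participant of a cohort. Smile AUs
#' (AU6/AU12) are elevated in the positive parts and while she listens;
#' disgust AUs (AU4/AU9) in the negative excerpt. Latent activity is a
#' low-pass-filtered Gaussian process (0.5 Hz cutoff) with per-segment mean
#' shifts; intensities are rectified, presence thresholded.
#'
#' @param sched A [segment_schedule()].
#' @param seed Integer seed (same seed, bit-identical table).
#' @param fps Frame rate (default 30).
#' @return A [frame_table()] with an attached `latent` matrix (one
#'   standardized latent column per AU) used for participant coupling.
#' @export
actress_reference <- function(sched, seed = 1, fps = 30) {
  set.seed(child_seed(seed, "actress"))
  t_end <- max(sched$end)
  t <- seq(0, t_end - 1 / fps, by = 1 / fps)
  n <- length(t)
  shift_profile <- function(au) {
    m <- numeric(n)
    for (i in seq_len(nrow(sched))) {
      in_seg <- t >= sched$start[i] & t < sched$end[i]
      listen <- sched$speaker[i] == "participant"  # actress listens
      s <- switch(au,
        AU12 = c(neutral = 0.3, positive = 1.3, negative = 0.5)[sched$valence[i]] +
          if (listen) 0.3 else 0,
        AU06 = c(neutral = 0.2, positive = 1.1, negative = 0.4)[sched$valence[i]] +
          if (listen) 0.25 else 0,
        AU04 = c(neutral = -0.2, positive = -0.6, negative = 1.0)[sched$valence[i]],
        AU09 = c(neutral = -0.3, positive = -0.5, negative = 0.8)[sched$valence[i]],
        0)
      m[in_seg] <- s
    }
    m
  }
  df <- data.frame(frame_index = seq_len(n), timestamp = t,
                   confidence = rep(0.99, n), success = TRUE)
  latent <- matrix(0, n, length(sit_aus()), dimnames = list(NULL, sit_aus()))
  for (au in sit_aus()) {
    z <- smooth_noise(n, fps) + shift_profile(au)
    zs <- (z - mean(z)) / stats::sd(z)
    latent[, au] <- zs
    structured <- au %in% MIMICRY_AUS
    occ <- if (structured) 0.35 else 0.10
    int <- if (structured) 0.8 else 0.2
    occ_seg <- occ * segment_weights(sched, au)
    int_seg <- int * segment_weights(sched, au)
    ch <- channels_from_latent(zs, t, sched, occ_seg, int_seg)
    df[[paste0(au, "_c")]] <- ch$presence
    df[[paste0(au, "_r")]] <- ch$intensity
  }
  df$gaze_x <- 0.01 * smooth_noise(n, fps)
  df$gaze_y <- -0.1 + 0.01 * smooth_noise(n, fps)
  ft <- frame_table(df, person_id = "actress")
  attr(ft, "latent") <- latent
  ft
}

# mean-reverting gaze-angle series hitting a stationary sd and a mean
# absolute frame-to-frame speed target
ou_series <- function(n, fps, mean_angle, sd_target, speed_target) {
  step_sd <- speed_target / fps * sqrt(pi / 2)
  one_minus_phi <- min(max(step_sd^2 / (2 * sd_target^2), 1e-4), 1)
  phi <- 1 - one_minus_phi
  eps_sd <- sd_target * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_target)
  innov <- stats::rnorm(n - 1, 0, eps_sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  mean_angle + x
}

#' Simulate one participant
#'
#' Facial channels: for each AU a latent smooth process — for the
#' emotion-relevant AUs a mixture `c * actress_latent(t - lag) +
#' sqrt(1 - c^2) * noise` with the group's mimicry coupling `c` — is
#' thresholded to hit the subject's per-segment occurrence targets in
#' expectation and rectified/scaled to the intensity targets. Gaze angles
#' are mean-reverting random walks matching the group's stationary SD and
#' mean-speed targets. Audio comes from [synthesize_voice()] with the
#' group-by-gender prosody targets. Confidence is ~0.99 with occasional
#' dropouts.
#'
#' @param spec A [cohort_spec()].
#' @param group `"ASD"` or `"NT"`.
#' @param gender 1 = female, 0 = male.
#' @param actress Frame table from [actress_reference()].
#' @param seed Integer seed.
#' @param person_id Identifier.
#' @param effect_multiplier Scales this subject's deviation from the NT
#'   profile (default 1); drives the synthetic severity score.
#' @return List: `frames` ([frame_table()]), `wave` (numeric or `NULL`),
#'   `rate`, `voice_params` (the injected prosody targets).
#' @export
simulate_participant <- function(spec, group, gender, actress, seed,
                                 person_id = "p000", effect_multiplier = 1) {
  set.seed(child_seed(seed, paste0("participant-", person_id)))
  g_nt <- spec$groups$NT
  g <- spec$groups[[group]]
  m <- effect_multiplier
  blend <- function(a, b) a + m * (b - a)  # NT value -> subject value
  sched <- spec$schedule
  fps <- spec$fps
  t_end <- max(sched$end)
  t <- seq(0, t_end - 1 / fps, by = 1 / fps)
  n <- length(t)
  lag_frames <- round(spec$mimicry_lag * fps)
  latent_a <- attr(actress, "latent")

  df <- data.frame(frame_index = seq_len(n), timestamp = t,
                   confidence = 0.99, success = TRUE)
  sex <- if (gender == 1) "female" else "male"
  for (au in spec$aus) {
    coupling <- 0
    if (au %in% names(g$mimicry)) {
      coupling <- min(max(blend(g_nt$mimicry[[au]], g$mimicry[[au]]), 0), 0.95)
    }
    za <- if (!is.null(latent_a) && au %in% colnames(latent_a)) {
      latent_a[, au]
    } else {
      x <- actress[[paste0(au, "_r")]]
      if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else numeric(n)
    }
    za_shift <- c(rep(0, lag_frames), za)[seq_len(n)]
    z <- coupling * za_shift + sqrt(1 - coupling^2) * smooth_noise(n, fps)
    occ_target <- if (au %in% names(g$au_occ)) {
      min(max(blend(g_nt$au_occ[[au]], g$au_occ[[au]]), 0.005), 0.95)
    } else {
      spec$background_occ
    }
    # subject-level heterogeneity on the occurrence logit
    occ_subj <- stats::plogis(stats::qlogis(occ_target) +
                                stats::rnorm(1, 0, 0.35))
    int_target <- if (au %in% names(g$au_int)) {
      max(blend(g_nt$au_int[[au]], g$au_int[[au]]), 0.01)
    } else {
      spec$background_int
    }
    int_subj <- int_target * exp(stats::rnorm(1, 0, 0.2))
    occ_seg <- occ_subj * segment_weights(sched, au)
    int_seg <- int_subj * segment_weights(sched, au)
    if (au == "AU04") {
      # intensity calibrated per valence: group effect lives in the
      # negative part, the baseline elsewhere
      neg <- sched$valence == "negative"
      int_seg[neg] <- max(blend(g_nt$au4_int_negative, g$au4_int_negative),
                          0.005) * exp(stats::rnorm(1, 0, 0.2))
      int_seg[!neg] <- g$au4_int_baseline * exp(stats::rnorm(1, 0, 0.2))
    }
    ch <- channels_from_latent(z, t, sched, occ_seg, int_seg)
    df[[paste0(au, "_c")]] <- ch$presence
    df[[paste0(au, "_r")]] <- ch$intensity
  }
  for (au in setdiff(sit_aus(), spec$aus)) {
    df[[paste0(au, "_c")]] <- 0L
    df[[paste0(au, "_r")]] <- 0
  }

  if ("gaze" %in% spec$modalities) {
    df$gaze_x <- ou_series(n, fps, blend(g_nt$gaze_mean[["horizontal"]],
                                         g$gaze_mean[["horizontal"]]),
                           blend(g_nt$gaze_sd[["horizontal"]],
                                 g$gaze_sd[["horizontal"]]),
                           blend(g_nt$gaze_speed[["horizontal"]],
                                 g$gaze_speed[["horizontal"]]))
    df$gaze_y <- ou_series(n, fps, blend(g_nt$gaze_mean[["vertical"]],
                                         g$gaze_mean[["vertical"]]),
                           blend(g_nt$gaze_sd[["vertical"]],
                                 g$gaze_sd[["vertical"]]),
                           blend(g_nt$gaze_speed[["vertical"]],
                                 g$gaze_speed[["vertical"]]))
  } else {
    df$gaze_x <- 0
    df$gaze_y <- 0
  }

  # tracking confidence: high with occasional dropouts
  conf <- pmin(0.985 + abs(stats::rnorm(n, 0, 0.005)), 1)
  drop <- stats::runif(n) < spec$dropout_rate
  conf[drop] <- stats::runif(sum(drop), 0.2, 0.7)
  df$confidence <- conf
  df$success <- stats::runif(n) >= spec$fail_rate

  wave <- NULL
  voice_params <- NULL
  if ("voice" %in% spec$modalities) {
    f0 <- stats::rnorm(1, blend(g_nt$f0[[sex]], g$f0[[sex]]),
                       g$f0_sd[[sex]])
    f0 <- min(max(f0, 80), 450)
    hnr <- stats::rnorm(1, blend(g_nt$hnr[[sex]], g$hnr[[sex]]),
                        g$hnr_sd[[sex]])
    hnr <- min(max(hnr, 0), 35)
    jit <- g$jitter * exp(stats::rnorm(1, 0, 0.2))
    shi <- g$shimmer * exp(stats::rnorm(1, 0, 0.2))
    voice_params <- list(f0 = f0, jitter = jit, shimmer = shi, hnr = hnr)
    wave <- synthesize_voice(f0, jit, shi, hnr, spec$voice_duration,
                             spec$audio_rate,
                             seed = child_seed(seed, paste0("voice-", person_id)))
  }
  list(frames = frame_table(df, person_id = person_id), wave = wave,
       rate = spec$audio_rate, voice_params = voice_params)
}

#' Synthesize a voiced test signal with controlled perturbations
#'
#' Pulse-train synthesis of a sustained voiced sound: glottal-cycle
#' analogues with a smooth harmonic-rich pulse shape, per-cycle period
#' perturbation calibrated so the expected local jitter equals
#' `jitter_local`, per-cycle amplitude perturbation calibrated to
#' `shimmer_local`, and additive white noise at the power giving the
#' requested harmonics-to-noise ratio (`P_noise = P_harm * 10^(-hnr/10)`).
#'
#' @param f0 Fundamental frequency in Hz (60-600).
#' @param jitter_local Target local jitter ratio (default 0).
#' @param shimmer_local Target local shimmer ratio (default 0).
#' @param hnr_db Target harmonics-to-noise ratio in dB (default 40:
#'   essentially noiseless).
#' @param duration Signal duration in seconds (>= 0.5).
#' @param rate Sampling rate in Hz (default 16000).
#' @param seed Optional integer seed (same seed, identical wave).
#' @return Numeric waveform in [-1, 1].
#' @export
synthesize_voice <- function(f0, jitter_local = 0, shimmer_local = 0,
                             hnr_db = 40, duration = 1, rate = 16000,
                             seed = NULL) {
  assert_that(f0 >= 60 && f0 <= 600, "f0 must lie in [60, 600] Hz")
  assert_that(duration >= 0.5, "duration must be at least 0.5 s")
  if (!is.null(seed)) set.seed(seed)
  T0 <- 1 / f0
  n_cycles <- ceiling(duration / T0) + 2
  # iid N(0, s) period perturbation: E|T[i+1]-T[i]| = 2s/sqrt(pi)
  s_jit <- jitter_local * sqrt(pi) / 2
  s_shi <- shimmer_local * sqrt(pi) / 2
  periods <- T0 * pmax(1 + stats::rnorm(n_cycles, 0, s_jit), 0.5)
  amps <- pmax(1 + stats::rnorm(n_cycles + 1, 0, s_shi), 0.2)
  bounds <- c(0, cumsum(periods))
  n <- round(duration * rate)
  tt <- (0:(n - 1)) / rate
  cyc <- findInterval(tt, bounds)
  u <- (tt - bounds[cyc]) / periods[cyc]
  beta <- 2.5
  g_mean <- exp(-beta) * besselI(beta, 0)
  g_var <- exp(-2 * beta) * besselI(2 * beta, 0) - g_mean^2
  # pulses peak at the cycle boundaries; each pulse carries a single
  # amplitude (that of its nearest boundary), so cycle-to-cycle amplitude
  # perturbation survives intact at the waveform peaks
  pulse_id <- cyc + as.integer(u >= 0.5)
  x <- amps[pulse_id] * (exp(beta * (cos(2 * pi * u) - 1)) - g_mean)
  p_harm <- mean(amps[unique(pulse_id)]^2) * g_var
  noise_sd <- sqrt(p_harm * 10^(-hnr_db / 10))
  x <- x + stats::rnorm(n, 0, noise_sd)
  0.5 * x / max(abs(x))
}

#' Simulate a full cohort
#'
#' Generates the shared actress track and `2 * n_per_group` participants
#' (ASD and NT) with the requested gender mix, plus a metadata table with a
#' synthetic severity score: for ASD subjects an ADOS-like score increasing
#' in the subject's effect multiplier (the factor scaling how far the
#' subject's parameters sit from the NT profile), uninformative for NT and
#' under the `"null"` preset.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `sit_cohort`: `spec`, `schedule`, `actress`,
#'   `metadata` (subject_id, label, gender, age, severity), `frames`
#'   (named list of frame tables), `waves` (named list of `list(wave,
#'   rate)`, absent participants `NULL`).
#' @export
simulate_cohort <- function(spec) {
  actress <- actress_reference(spec$schedule, seed = spec$seed,
                               fps = spec$fps)
  set.seed(child_seed(spec$seed, "cohort"))
  groups <- c("NT", "ASD")
  meta <- list()
  frames <- list()
  waves <- list()
  for (grp in groups) {
    n <- spec$n_per_group
    n_f <- round(n * spec$gender_mix)
    genders <- c(rep(1, n_f), rep(0, n - n_f))
    rng <- spec$groups[[grp]]$age_range
    for (i in seq_len(n)) {
      pid <- sprintf("%s%03d", tolower(grp), i)
      mult <- if (grp == "ASD" && spec$preset == "paper") {
        min(max(stats::rnorm(1, 1, 0.3), 0.2), 1.8)
      } else 1
      age <- round(stats::runif(1, rng[1], rng[2]))
      severity <- if (grp == "ASD" && spec$preset == "paper") {
        round(7 + 4 * mult + stats::rnorm(1, 0, 1), 1)
      } else if (grp == "ASD") {
        round(7 + stats::rnorm(1, 0, 2), 1)
      } else {
        round(max(stats::rnorm(1, 2, 1), 0), 1)
      }
      sim <- simulate_participant(spec, grp, genders[i], actress,
                                  seed = child_seed(spec$seed, pid),
                                  person_id = pid, effect_multiplier = mult)
      meta[[pid]] <- data.frame(subject_id = pid, label = grp,
                                gender = genders[i], age = age,
                                severity = severity,
                                stringsAsFactors = FALSE)
      frames[[pid]] <- sim$frames
      waves[[pid]] <- if (is.null(sim$wave)) NULL else
        list(wave = sim$wave, rate = sim$rate)
    }
  }
  structure(list(spec = spec, schedule = spec$schedule, actress = actress,
                 metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
                 frames = frames, waves = waves),
            class = "sit_cohort")
}

#' @export
print.sit_cohort <- function(x, ...) {
  cat(sprintf("<sit_cohort> %s preset, %d subjects (seed %s)\n",
              x$spec$preset, nrow(x$metadata), format(x$spec$seed)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' OpenFace-dialect CSV per participant (plus `actress.csv`), WAV audio,
#' `metadata.csv` and `schedule.yaml`.
#'
#' @param cohort A `sit_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame_table(cohort$actress, file.path(dir, "actress.csv"))
  for (pid in names(cohort$frames)) {
    write_frame_table(cohort$frames[[pid]], file.path(dir, paste0(pid, ".csv")))
  }
  for (pid in names(cohort$waves)) {
    w <- cohort$waves[[pid]]
    if (!is.null(w)) write_wav(w$wave, w$rate, file.path(dir, paste0(pid, ".wav")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  write_schedule(cohort$schedule, file.path(dir, "schedule.yaml"))
  invisible(dir)
}
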