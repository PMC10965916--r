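#' Synthetic E4 cohort generation
#'
#' The clinical dataset behind this kind of wristband symptom-scoring study
#' is not public, so the package ships a deterministic generator producing
#' cohorts with known ground truth. Each subject carries a latent
#' depression trait and a latent mania trait in `[0, 1]` plus
#' subject-idiosyncratic channel parameters (baselines and gains). Each
#' recording session draws a session-level latent state around the subject
#' trait, discretizes it into the 28 ordinal item scores through a
#' graded-response-like thresholded-latent model (right-skewed, so low
#' ranks dominate as in acute-care cohorts), and renders the five E4
#' channels at their native rates with symptom-linked structure:
#' accelerometer burst activity increases with mania and decreases with
#' depression, tonic/phasic electrodermal activity tracks the anxiety
#' items, heart rate carries a baseline plus an activity load term, skin
#' temperature drifts slowly, and the blood-volume pulse oscillates at the
#' instantaneous heart-rate frequency. After a configurable onset the
#' activity statistics shift (distribution drift), emulating the departure
#' from interview-time conditions seen in long ambulatory recordings.
#'
#' @name synth
NULL

#' Synthetic-cohort configuration
#'
#' Defaults emulate the study conditions of a naturalistic mood-disorder
#' wristband cohort: 75 subjects with roughly two sessions each, ~48 h of
#' recording per session, labels skewed towards rank 0, and a
#' distribution shift starting 5 h into each recording.
#'
#' @param n_subjects number of subjects.
#' @param session_rate extra sessions per subject are `rpois(session_rate)`
#'   (every subject has at least one).
#' @param duration_h session length in hours.
#' @param latent_shape1,latent_shape2 Beta parameters of the subject trait
#'   means (right-skewed: most subjects near remission).
#' @param session_latent_sd s.d. of the session latent around the trait.
#' @param item_noise_sd s.d. of the per-item Gaussian noise before
#'   discretization.
#' @param threshold_lo,threshold_hi range over which the item
#'   discretization thresholds are evenly spaced in latent units.
#' @param acc_base baseline accelerometer activity level (arbitrary g-like
#'   units).
#' @param eda_base_mean,eda_base_sd,hr_base_mean,hr_base_sd,temp_base_mean,temp_base_sd,bvp_amp_mean,bvp_amp_sd
#'   population distributions of the subject channel idiosyncrasies.
#' @param drift_onset_h hours after which activity statistics shift.
#' @param drift_mag relative magnitude of the shift (0 disables drift).
#' @param confound_mode when `TRUE`, channel baselines of *confounded*
#'   subjects (the first `confound_frac` of the cohort, intended as the
#'   training subjects) are made informative of their severity, planting
#'   the subject-specific shortcut an adversarial critic is designed to
#'   defeat; remaining subjects keep independent baselines.
#' @param confound_strength strength of that baseline-severity coupling.
#' @param confound_frac fraction of subjects confounded.
#' @param seed master seed; the full cohort (labels and signals) is a
#'   deterministic function of the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 75,
                         session_rate = 1,
                         duration_h = 48,
                         latent_shape1 = 0.7,
                         latent_shape2 = 2.2,
                         session_latent_sd = 0.12,
                         item_noise_sd = 0.08,
                         threshold_lo = 0.25,
                         threshold_hi = 0.95,
                         acc_base = 0.15,
                         eda_base_mean = 2.0, eda_base_sd = 0.5,
                         hr_base_mean = 70, hr_base_sd = 5,
                         temp_base_mean = 33.5, temp_base_sd = 0.6,
                         bvp_amp_mean = 1.0, bvp_amp_sd = 0.2,
                         drift_onset_h = 5,
                         drift_mag = 0.4,
                         confound_mode = FALSE,
                         confound_strength = 1.0,
                         confound_frac = 0.6,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 1, cfg$duration_h > 0,
            cfg$drift_mag >= 0, cfg$confound_frac >= 0,
            cfg$confound_frac <= 1)
  structure(cfg, class = "synth_config")
}

# latent driving item j: d for HDRS, m for YMRS, shared max(d, m) loading
# for the two insight items (H17, Y11), which are elevated in either pole.
.item_latent <- function(d, m, scale_name, item_id) {
  if (item_id %in% c("H17", "Y11")) return(pmax(d, m))
  if (scale_name == "HDRS") d else m
}

.discretize_item <- function(z, item, cfg) {
  thr <- seq(cfg$threshold_lo, cfg$threshold_hi,
             length.out = item$n_ranks - 1L)
  idx <- vapply(z, function(v) sum(v > thr), 0L)
  as.integer(idx * item$rank_step)  # printed rank value
}

#' Draw a synthetic cohort (subject profiles + session ground truth)
#'
#' @param cfg a [synth_config()].
#' @param schemas output of [build_schemas()].
#' @return A list with `profiles` (one per subject), `sessions` (one
#'   `session_truth` per recording session, holding the latent state and
#'   the 28 printed item scores), and `labels` (the session-label table in
#'   `labels.csv` layout).
#' @export
sample_cohort <- function(cfg = synth_config(), schemas = build_schemas()) {
  set.seed(derive_seed(cfg$seed, "cohort"))
  n <- cfg$n_subjects
  sev_link <- function(s) s - 0.3  # centred severity for confounds
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    d_mean <- stats::rbeta(1, cfg$latent_shape1, cfg$latent_shape2)
    m_mean <- stats::rbeta(1, cfg$latent_shape1, cfg$latent_shape2)
    confounded <- cfg$confound_mode && i <= ceiling(cfg$confound_frac * n)
    eda_base <- max(0.3, stats::rnorm(1, cfg$eda_base_mean, cfg$eda_base_sd))
    hr_base <- stats::rnorm(1, cfg$hr_base_mean, cfg$hr_base_sd)
    acc_gain <- exp(stats::rnorm(1, 0, 0.2))
    if (confounded) {
      s <- max(d_mean, m_mean)
      eda_base <- max(0.3, cfg$eda_base_mean +
                        4 * cfg$confound_strength * sev_link(s) +
                        stats::rnorm(1, 0, 0.1))
      hr_base <- cfg$hr_base_mean +
        30 * cfg$confound_strength * sev_link(s) + stats::rnorm(1, 0, 1)
    }
    profiles[[i]] <- structure(list(
      subject_id = sprintf("S%03d", i),
      d_mean = d_mean, m_mean = m_mean,
      acc_gain = acc_gain,
      acc_offset = stats::rnorm(1, 0, 0.02),
      eda_base = eda_base,
      hr_base = hr_base,
      temp_base = stats::rnorm(1, cfg$temp_base_mean, cfg$temp_base_sd),
      bvp_amp = max(0.2, stats::rnorm(1, cfg$bvp_amp_mean, cfg$bvp_amp_sd)),
      confounded = confounded
    ), class = "subject_profile")
  }
  items <- combined_items(schemas)
  sessions <- list()
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    n_sess <- 1L + stats::rpois(1, cfg$session_rate)
    for (k in seq_len(n_sess)) {
      d <- clamp(p$d_mean + stats::rnorm(1, 0, cfg$session_latent_sd), 0, 1)
      m <- clamp(p$m_mean + stats::rnorm(1, 0, cfg$session_latent_sd), 0, 1)
      y <- integer(nrow(items))
      names(y) <- items$id
      for (j in seq_len(nrow(items))) {
        it <- items[j, ]
        lat <- .item_latent(d, m, it$scale, it$id)
        z <- lat + stats::rnorm(1, 0, cfg$item_noise_sd)
        y[j] <- .discretize_item(z, it, cfg)
      }
      sessions[[length(sessions) + 1L]] <- structure(list(
        session_id = sprintf("%s_T%d", p$subject_id, k),
        subject_id = p$subject_id,
        d = d, m = m, items = y,
        interview_time = 0,
        duration_h = cfg$duration_h,
        drift_onset_h = cfg$drift_onset_h,
        drift_mag = cfg$drift_mag
      ), class = "session_truth")
    }
  }
  list(profiles = profiles, sessions = sessions,
       labels = cohort_labels(sessions))
}

#' Session-label table for a list of session truths
#' @param sessions list of `session_truth` objects.
#' @return data.frame in `labels.csv` layout.
#' @export
cohort_labels <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    c(list(session_id = s$session_id, subject_id = s$subject_id,
           interview_time = s$interview_time), as.list(s$items))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# Per-second activity envelope shared by ACC and the HR load term.
.activity_envelope <- function(truth, profile, cfg, Tsec) {
  level <- clamp(0.25 + 0.9 * truth$m - 0.35 * truth$d, 0.05, 1.5)
  p_burst <- clamp(0.04 + 0.20 * truth$m - 0.02 * truth$d, 0.01, 0.5)
  raw <- stats::rexp(Tsec) * (stats::runif(Tsec) < p_burst)
  e <- level * (0.25 + 2.5 * moving_average(raw, 61L))
  drift_from <- floor(truth$drift_onset_h * 3600) + 1L
  if (truth$drift_mag > 0 && drift_from <= Tsec)
    e[drift_from:Tsec] <- e[drift_from:Tsec] * (1 + truth$drift_mag)
  e
}

#' Render the five physiological channels of one session
#'
#' Deterministic given `(truth, profile, cfg)`: the render seed is derived
#' from the master seed and the session id.
#'
#' @param truth a `session_truth` from [sample_cohort()].
#' @param profile the matching `subject_profile`.
#' @param cfg the [synth_config()].
#' @return An [e4_session()] at the native E4 rates.
#' @export
render_session <- function(truth, profile, cfg) {
  set.seed(derive_seed(cfg$seed, paste0("render/", truth$session_id)))
  Tsec <- as.integer(round(truth$duration_h * 3600))
  env <- .activity_envelope(truth, profile, cfg, Tsec)

  # ACC, 32 Hz x 3 axes: zero-mean bursts scaled by the envelope, plus a
  # gravity-like constant on the third axis.
  amp <- cfg$acc_base * profile$acc_gain * env
  amp32 <- rep(amp, each = 32L)
  n_acc <- Tsec * 32L
  acc <- cbind(amp32 * stats::rnorm(n_acc),
               amp32 * stats::rnorm(n_acc),
               0.95 + profile$acc_offset + amp32 * stats::rnorm(n_acc))

  # EDA, 4 Hz: subject tonic baseline + anxiety-linked level and phasic
  # events + slow wander. Anxiety level from the psychic/somatic anxiety
  # items (H10, H11) on the unit scale.
  anx <- mean(truth$items[c("H10", "H11")]) / 4
  drift_sec <- floor(truth$drift_onset_h * 3600)
  tonic <- profile$eda_base + 1.2 * anx +
    moving_average(stats::rnorm(Tsec, 0, 0.15), 301L)
  if (truth$drift_mag > 0 && drift_sec < Tsec)
    tonic[(drift_sec + 1L):Tsec] <-
      tonic[(drift_sec + 1L):Tsec] + 1.5 * truth$drift_mag
  n_eda <- Tsec * 4L
  scr_rate <- (0.004 + 0.05 * anx) / 4  # per 0.25 s sample
  # single-deflection amplitudes capped so a clean session never crosses
  # the plausibility slope rule (10 uS/s)
  events <- pmin(stats::rexp(n_eda), 2) * (stats::runif(n_eda) < scr_rate)
  kernel <- exp(-(0:31) / 16)  # ~8 s decay at 4 Hz
  phasic <- stats::filter(events, kernel, method = "convolution",
                          sides = 1)
  phasic[is.na(phasic)] <- 0
  eda <- clamp(rep(tonic, each = 4L) + 0.8 * as.numeric(phasic) +
                 stats::rnorm(n_eda, 0, 0.01), 0.1, 50)

  # HR, 1 Hz: baseline + mania elevation + activity load, smoothed.
  hr_raw <- profile$hr_base + 12 * truth$m - 4 * truth$d +
    22 * clamp(env, 0, 2) + stats::rnorm(Tsec, 0, 1.5)
  hr <- clamp(moving_average(hr_raw, 15L), 35, 210)

  # TEMP, 1 Hz: subject baseline + slow sinusoid + smoothed noise.
  tt <- seq_len(Tsec)
  temp <- clamp(profile$temp_base +
                  0.4 * sin(2 * pi * tt / 5400 + stats::runif(1, 0, 2 * pi)) +
                  moving_average(stats::rnorm(Tsec, 0, 0.2), 601L),
                30.5, 39.5)

  # BVP, 64 Hz: harmonic pulse at the instantaneous HR frequency (the E4's
  # HR stream is itself PPG-derived, so the two are rendered consistently).
  f64 <- rep(hr / 60, each = 64L)
  phase <- 2 * pi * cumsum(f64) / 64
  n_bvp <- Tsec * 64L
  bvp <- profile$bvp_amp * (sin(phase) + 0.3 * sin(2 * phase)) +
    stats::rnorm(n_bvp, 0, 0.05)

  e4_session(truth$session_id, truth$subject_id,
             start_time = 1600000000 +
               derive_seed(cfg$seed, paste0("start/", truth$session_id)) %% 86400,
             channels = list(ACC = acc, BVP = bvp, EDA = eda,
                             HR = hr, TEMP = temp),
             interview_time = truth$interview_time)
}

#' Artifact-injection configuration
#'
#' @param eda_range_rate,temp_rate,hr_rate per-sample probability of
#'   replacing a value with a physiologically implausible one.
#' @param eda_spike_rate per-sample probability of an abrupt EDA jump
#'   (implausible slope).
#' @export
artifact_config <- function(eda_range_rate = 0.01, temp_rate = 0.01,
                            hr_rate = 0.01, eda_spike_rate = 0.005) {
  rates <- c(eda_range_rate, temp_rate, hr_rate, eda_spike_rate)
  stopifnot(all(rates >= 0), all(rates <= 1))
  list(eda_range_rate = eda_range_rate, temp_rate = temp_rate,
       hr_rate = hr_rate, eda_spike_rate = eda_spike_rate)
}

#' Inject physiologically implausible values with a known mask
#'
#' Provides ground-truth positives for the quality-control rules: EDA
#' values outside `[0.05, 60]` uS, abrupt EDA jumps (slope above 10 uS/s),
#' TEMP outside `[30, 40]` C and HR outside `[25, 250]` bpm.
#'
#' @param session an [e4_session()].
#' @param acfg an [artifact_config()].
#' @param seed integer seed (artifact placement is deterministic given it).
#' @return A list with the corrupted `session` and `mask`, a per-channel
#'   logical list marking exactly the injected sample positions.
#' @export
inject_artifacts <- function(session, acfg = artifact_config(),
                             seed = 1L) {
  set.seed(seed)
  ch <- session$channels
  mask <- list(ACC = rep(FALSE, nrow(ch$ACC)),
               BVP = rep(FALSE, length(ch$BVP)),
               EDA = rep(FALSE, length(ch$EDA)),
               HR = rep(FALSE, length(ch$HR)),
               TEMP = rep(FALSE, length(ch$TEMP)))
  n_eda <- length(ch$EDA)
  pick <- function(n, rate) which(stats::runif(n) < rate)
  i <- pick(n_eda, acfg$eda_range_rate)
  if (length(i)) {
    ch$EDA[i] <- ifelse(stats::runif(length(i)) < 0.5, 0.01, 70)
    mask$EDA[i] <- TRUE
  }
  j <- setdiff(pick(n_eda, acfg$eda_spike_rate), i)
  if (length(j)) {
    ch$EDA[j] <- pmin(ch$EDA[j] + 15, 59)  # slope ~60 uS/s at 4 Hz
    mask$EDA[j] <- TRUE
  }
  i <- pick(length(ch$TEMP), acfg$temp_rate)
  if (length(i)) {
    ch$TEMP[i] <- ifelse(stats::runif(length(i)) < 0.5, 25, 45)
    mask$TEMP[i] <- TRUE
  }
  i <- pick(length(ch$HR), acfg$hr_rate)
  if (length(i)) {
    ch$HR[i] <- ifelse(stats::runif(length(i)) < 0.5, 10, 300)
    mask$HR[i] <- TRUE
  }
  session$channels <- ch
  list(session = session, mask = mask)
}

#' Write a cohort to disk (E4 dialect + labels.csv)
#'
#' @param sessions list of rendered [e4_session()] objects.
#' @param labels session-label table (from [sample_cohort()]).
#' @param out_dir output directory; sessions go to
#'   `out_dir/sessions/<session_id>/`.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(sessions, labels, out_dir) {
  dir.create(file.path(out_dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in sessions)
    write_e4_session(s, file.path(out_dir, "sessions", s$session_id))
  write_labels(labels, file.path(out_dir, "labels.csv"))
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A list with `sessions` (list of [e4_session()]) and `labels`.
#' @export
read_cohort <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.csv"))
  sessions <- lapply(seq_len(nrow(labels)), function(i) {
    read_e4_session(file.path(dir, "sessions", labels$session_id[i]),
                    session_id = labels$session_id[i],
                    subject_id = labels$subject_id[i],
                    interview_time = labels$interview_time[i])
  })
  names(sessions) <- labels$session_id
  list(sessions = sessions, labels = labels)
}
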