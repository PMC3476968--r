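# Synthetic overnight anterior-tibialis EMG with ground-truth hypnograms.
# A two-state Markov chain drives the sleep/wake ground truth; stage labels
# within sleep are drawn with realistic overall proportions (they are
# cosmetic as far as the estimators are concerned). Signals are band-limited
# (10-75 Hz) Gaussian noise whose standard deviation follows the state, with
# movement bursts in wake, optional periodic-limb-movement burst trains in
# sleep, and optional 60 Hz mains contamination.

derive_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Specification of a synthetic overnight recording
#'
#' Defaults emulate the overnight conditions of the validation cohort this
#' package models: an approximately 8-hour night (960 epochs) sampled at
#' 250 Hz with sleep efficiency near 97.5%, low-amplitude tonic EMG in
#' sleep, elevated tone plus high-amplitude movement bursts in wake.
#' Amplitude scales are in arbitrary analog units; only their ratios
#' matter, as both estimators are self-normalizing. Wake movement bursts
#' are an order of magnitude above the wake tonic level (surface-EMG
#' movement artifacts dwarf the sleeping noise floor); periodic limb
#' movements are genuine movements too, so their bursts are of comparable
#' (slightly lower) magnitude, which is what degrades threshold-based
#' wake detection in the PLMD profile.
#'
#' @param duration_epochs night length in 30-s epochs.
#' @param fs sampling rate in Hz (positive integer, > 150 for the spectral
#'   estimator's 10--75 Hz band).
#' @param target_se stationary sleep efficiency of the state chain, in %.
#' @param mean_wake_bout mean wake-bout length in epochs (>= 1).
#' @param sigma_sleep tonic EMG amplitude SD during sleep (a.u.).
#' @param sigma_wake tonic EMG amplitude SD during wake (>= sigma_sleep).
#' @param burst_rate_wake movement bursts per minute of wake.
#' @param burst_gain amplitude multiplier of wake bursts over the wake
#'   tonic level.
#' @param plm_gain amplitude of PLM bursts as a multiple of `sigma_sleep`.
#' @param mains_amplitude amplitude of an additive 60 Hz component (a.u.).
#' @param plm_enabled add periodic limb-movement burst trains in sleep.
#' @param plm_interval_s PLM inter-burst spacing in seconds (5--90).
#' @param plm_duration_s PLM burst duration in seconds (0.5--10).
#' @param channel_correlation shared-variance fraction of the tonic noise
#'   between the two channels, in \[0, 1\].
#' @param seed integer seed making the generated night reproducible;
#'   `NULL` uses the current RNG state.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_epochs = 960L, fs = 250L,
                           target_se = 97.5, mean_wake_bout = 2,
                           sigma_sleep = 1, sigma_wake = 3,
                           burst_rate_wake = 6, burst_gain = 10,
                           plm_gain = 20, mains_amplitude = 0,
                           plm_enabled = FALSE, plm_interval_s = 25,
                           plm_duration_s = 2, channel_correlation = 0.3,
                           seed = NULL) {
  stopifnot(duration_epochs >= 1, fs >= 1, fs %% 1 == 0)
  if (target_se <= 0 || target_se >= 100)
    stop("`target_se` must lie strictly between 0 and 100")
  if (mean_wake_bout < 1) stop("`mean_wake_bout` must be >= 1 epoch")
  if (sigma_sleep <= 0) stop("`sigma_sleep` must be positive")
  if (sigma_wake < sigma_sleep)
    stop("`sigma_wake` must be >= `sigma_sleep`")
  if (plm_interval_s < 5 || plm_interval_s > 90)
    stop("`plm_interval_s` must lie in [5, 90] seconds")
  if (plm_duration_s < 0.5 || plm_duration_s > 10)
    stop("`plm_duration_s` must lie in [0.5, 10] seconds")
  if (channel_correlation < 0 || channel_correlation > 1)
    stop("`channel_correlation` must lie in [0, 1]")
  structure(list(
    duration_epochs = as.integer(duration_epochs), fs = as.integer(fs),
    target_se = target_se, mean_wake_bout = mean_wake_bout,
    sigma_sleep = sigma_sleep, sigma_wake = sigma_wake,
    burst_rate_wake = burst_rate_wake, burst_gain = burst_gain,
    plm_gain = plm_gain, mains_amplitude = mains_amplitude,
    plm_enabled = isTRUE(plm_enabled), plm_interval_s = plm_interval_s,
    plm_duration_s = plm_duration_s,
    channel_correlation = channel_correlation,
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synthetic_spec")
}

# stationary stage mix within sleep (fractions of sleep time): light sleep
# dominates, some slow-wave sleep, REM just over a fifth
SLEEP_STAGE_MIX <- c(S1 = 0.10, S2 = 0.55, S3 = 0.07, S4 = 0.05, REM = 0.23)

#' Simulate a ground-truth hypnogram
#'
#' The sleep/wake ground truth is a two-state Markov chain whose
#' transition probabilities are solved from the target sleep efficiency
#' (the stationary wake fraction) and the mean wake-bout length; the
#' initial state is drawn from the stationary distribution. Stage labels
#' within sleep follow a persistent chain whose stationary mix is
#' [SLEEP_STAGE_MIX]. Deterministic given `spec$seed`.
#'
#' @param spec a `synthetic_spec`.
#' @return a `hypnogram` (reduce with [binarize()] for the sleep/wake
#'   ground truth).
#' @export
simulate_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(derive_seed(spec$seed, 0))
  n <- spec$duration_epochs
  pi_w <- 1 - spec$target_se / 100
  p_ws <- 1 / spec$mean_wake_bout            # wake -> sleep per epoch
  p_sw <- pi_w * p_ws / (1 - pi_w)           # sleep -> wake per epoch
  if (p_sw > 1)
    stop(sprintf(
      "infeasible combination: target_se %.1f%% with mean wake bout %.1f epochs requires sleep->wake probability %.2f > 1",
      spec$target_se, spec$mean_wake_bout, p_sw))
  states <- character(n)
  u <- runif(n)
  cur <- if (runif(1L) < pi_w) "W" else "S"
  for (i in seq_len(n)) {
    states[i] <- cur
    cur <- if (cur == "W") {
      if (u[i] < p_ws) "S" else "W"
    } else {
      if (u[i] < p_sw) "W" else "S"
    }
  }
  # stage labels within sleep: persistent chain, stationary = SLEEP_STAGE_MIX
  stages <- character(n)
  persist <- 0.88
  prev <- NA_character_
  stage_names <- names(SLEEP_STAGE_MIX)
  v <- runif(n)
  draw <- sample(stage_names, n, replace = TRUE, prob = SLEEP_STAGE_MIX)
  for (i in seq_len(n)) {
    if (states[i] == "W") {
      stages[i] <- "W"
      prev <- NA_character_
    } else {
      stages[i] <- if (!is.na(prev) && v[i] < persist) prev else draw[i]
      prev <- stages[i]
    }
  }
  hypnogram(stages)
}

# unit-variance Gaussian noise band-limited to [lo, hi] Hz via FFT masking
band_limited_noise <- function(n, fs, lo = 10, hi = 75) {
  w <- rnorm(n)
  W <- stats::fft(w)
  f <- pmin(0:(n - 1L), n - (0:(n - 1L))) * fs / n
  W[f < lo | f > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a bilateral EMG recording for a given hypnogram
#'
#' Per sample the signal is band-limited (10--75 Hz) Gaussian noise whose
#' SD follows the state (sigma_sleep / sigma_wake), amplitude-modulated by
#' movement bursts: wake epochs receive Poisson-placed bursts of 0.5--3 s
#' at `burst_gain` times the wake tone; if PLMs are enabled, sleep epochs
#' receive periodic burst trains (`plm_interval_s` spacing,
#' `plm_duration_s` width) at `plm_gain` times the sleep tone. Burst
#' envelopes are shared between the two channels (movements show on both
#' legs); `channel_correlation` sets the shared-variance fraction of the
#' tonic noise. An optional 60 Hz sinusoid of amplitude `mains_amplitude`
#' is added identically to both channels. Deterministic given `spec$seed`.
#'
#' @param hyp a `hypnogram` or `binary_hypnogram` whose length equals
#'   `spec$duration_epochs`.
#' @param spec a `synthetic_spec`.
#' @return an `emg_recording` with channels `EMG_AT_L` and `EMG_AT_R`.
#' @export
simulate_emg <- function(hyp, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bh <- binarize(hyp)
  n_ep <- length(bh)
  if (n_ep != spec$duration_epochs)
    stop(sprintf("hypnogram has %d epochs but spec declares %d",
                 n_ep, spec$duration_epochs))
  if (!is.null(spec$seed)) set.seed(derive_seed(spec$seed, 1))
  fs <- spec$fs
  spe <- EPOCH_SECONDS * fs
  rho <- spec$channel_correlation
  a_common <- sqrt(rho)
  a_own <- sqrt(1 - rho)
  ch1 <- numeric(n_ep * spe)
  ch2 <- numeric(n_ep * spe)
  for (e in seq_len(n_ep)) {
    state <- bh$states[e]
    sigma <- if (state == "WAKE") spec$sigma_wake else spec$sigma_sleep
    env <- rep(sigma, spe)
    if (state == "WAKE" && spec$burst_rate_wake > 0) {
      nb <- rpois(1L, spec$burst_rate_wake * EPOCH_SECONDS / 60)
      if (nb > 0L) {
        starts <- runif(nb, 0, EPOCH_SECONDS)
        durs <- runif(nb, 0.5, 3)
        for (b in seq_len(nb)) {
          i0 <- max(1L, 1L + floor(starts[b] * fs))
          i1 <- min(spe, floor((starts[b] + durs[b]) * fs))
          if (i0 <= i1) env[i0:i1] <- sigma * spec$burst_gain
        }
      }
    } else if (state != "WAKE" && spec$plm_enabled) {
      phase <- runif(1L, 0, spec$plm_interval_s)
      onsets <- seq(phase, EPOCH_SECONDS, by = spec$plm_interval_s)
      for (t0 in onsets) {
        i0 <- max(1L, 1L + floor(t0 * fs))
        i1 <- min(spe, floor((t0 + spec$plm_duration_s) * fs))
        if (i0 <= i1) env[i0:i1] <- spec$sigma_sleep * spec$plm_gain
      }
    }
    common <- band_limited_noise(spe, fs)
    idx <- ((e - 1L) * spe + 1L):(e * spe)
    ch1[idx] <- (a_common * common + a_own * band_limited_noise(spe, fs)) * env
    ch2[idx] <- (a_common * common + a_own * band_limited_noise(spe, fs)) * env
  }
  if (spec$mains_amplitude > 0) {
    t <- (seq_len(n_ep * spe) - 1L) / fs
    mains <- spec$mains_amplitude * sin(2 * pi * 60 * t)
    ch1 <- ch1 + mains
    ch2 <- ch2 + mains
  }
  emg_recording(list(EMG_AT_L = ch1, EMG_AT_R = ch2), fs = fs)
}

#' Simulate a per-epoch posture track
#'
#' Postures change in blocks of tens of minutes, supine-dominant, never
#' prone (sleepers wired for polysomnography avoid the prone position).
#'
#' @param n_epochs night length in epochs.
#' @return a `posture_track`.
#' @export
simulate_posture <- function(n_epochs) {
  postures <- character(0L)
  while (length(postures) < n_epochs) {
    len <- 20L + rpois(1L, 120L)
    p <- sample(c("SUPINE", "LEFT", "RIGHT"), 1L, prob = c(0.7, 0.15, 0.15))
    postures <- c(postures, rep(p, len))
  }
  posture_track(postures[seq_len(n_epochs)])
}

#' Simulate a cohort of overnight recordings
#'
#' Generates `n` subjects with per-subject jittered parameters under one
#' of three profiles: `normal` (the default conditions), `osa`
#' (obstructive sleep apnea: same signal model as normal -- apnea does not
#' alter tibialis EMG -- but a more fragmented night with shorter wake
#' bouts), and `plmd` (periodic limb movement disorder: PLM burst trains
#' during sleep). Deterministic given `seed`.
#'
#' @param n number of subjects.
#' @param profile `"normal"`, `"osa"` or `"plmd"`.
#' @param seed integer seed.
#' @param duration_epochs,fs night length and sampling rate.
#' @param keep `"all"` keeps the raw recordings in each item; `"features"`
#'   computes the per-epoch features ([recording_features()]) and drops
#'   the raw signal, which keeps long cohorts small in memory.
#' @param out_dir if non-`NULL`, the cohort is also written to this
#'   directory via [write_cohort()].
#' @param format signal file format when writing (`"csv"` or `"edf"`).
#' @return an object of class `emg_cohort`: list of per-subject items
#'   (`subject_id`, `spec`, `hypnogram`, `binary`, `posture`, and
#'   `recording` or `features`).
#' @export
simulate_cohort <- function(n = 12L, profile = c("normal", "osa", "plmd"),
                            seed = 1L, duration_epochs = 960L, fs = 250L,
                            keep = c("all", "features"), out_dir = NULL,
                            format = c("csv", "edf")) {
  profile <- match.arg(profile)
  keep <- match.arg(keep)
  format <- match.arg(format)
  stopifnot(n >= 1L)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- derive_seed(seed, 1000 * i)
    set.seed(sseed)
    se_mu <- switch(profile, normal = 97.6, osa = 97.4, plmd = 97.4)
    se_sd <- switch(profile, normal = 0.8, osa = 1.0, plmd = 1.9)
    spec <- synthetic_spec(
      duration_epochs = duration_epochs, fs = fs,
      target_se = min(99.3, max(93, rnorm(1L, se_mu, se_sd))),
      mean_wake_bout = if (profile == "osa") 1 else 2,
      sigma_sleep = runif(1L, 0.9, 1.1),
      sigma_wake = 3 * runif(1L, 0.85, 1.15),
      burst_rate_wake = 6 * runif(1L, 0.8, 1.2),
      plm_enabled = profile == "plmd",
      seed = derive_seed(sseed, 7))
    hyp <- simulate_hypnogram(spec)
    rec <- simulate_emg(hyp, spec)
    rec$subject_id <- sprintf("%s_%02d", profile, i)
    set.seed(derive_seed(sseed, 13))
    post <- simulate_posture(duration_epochs)
    item <- list(subject_id = rec$subject_id, spec = spec,
                 hypnogram = hyp, binary = binarize(hyp), posture = post)
    if (keep == "features") {
      item$features <- recording_features(rec)
    } else {
      item$recording <- rec
    }
    items[[i]] <- item
  }
  cohort <- structure(list(items = items, profile = profile, seed = seed),
                      class = "emg_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir, format = format)
  cohort
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %d subject(s), profile '%s', seed %s\n",
              length(x$items), x$profile, format(x$seed)))
  for (it in x$items) {
    se <- sleep_efficiency(it$binary)
    cat(sprintf("  %s: %d epochs, SE %.1f%%\n", it$subject_id,
                length(it$binary), se))
  }
  invisible(x)
}

#' @export
length.emg_cohort <- function(x) length(x$items)

#' Write a cohort to disk with a manifest
#'
#' Writes per-subject signal, hypnogram and posture files plus a
#' `manifest.csv` (columns `subject_id, signal_path, hypnogram_path,
#' posture_path`, paths relative to the directory).
#'
#' @param cohort an `emg_cohort` whose items retain their recordings.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"` for the signals.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "emg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$items, function(it) {
    if (is.null(it$recording))
      stop("item ", it$subject_id, " has no raw recording to write")
    sig <- paste0(it$subject_id, ".", format)
    hyp <- paste0(it$subject_id, "_hypnogram.txt")
    pos <- paste0(it$subject_id, "_posture.txt")
    write_recording(it$recording, file.path(dir, sig), format = format)
    write_hypnogram(it$hypnogram, file.path(dir, hyp))
    write_posture(it$posture, file.path(dir, pos))
    data.frame(subject_id = it$subject_id, signal_path = sig,
               hypnogram_path = hyp, posture_path = pos,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path path to a `manifest.csv` as written by
#'   [write_cohort()]; relative paths resolve against its directory.
#' @param fs sampling rate for CSV signals lacking a `# fs=` header.
#' @return an `emg_cohort` (items carry recordings, staged and binary
#'   hypnograms, and posture tracks where listed).
#' @export
read_cohort <- function(manifest_path, fs = NULL) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  items <- lapply(seq_len(nrow(man)), function(i) {
    rec <- read_recording(resolve(man$signal_path[i]), fs = fs,
                          subject_id = man$subject_id[i])
    hyp <- read_hypnogram(resolve(man$hypnogram_path[i]))
    al <- align_epochs(rec, hyp)
    post <- NULL
    if (!is.null(man$posture_path) && nzchar(man$posture_path[i]))
      post <- read_posture(resolve(man$posture_path[i]))
    list(subject_id = man$subject_id[i], recording = al$recording,
         hypnogram = al$hypnogram, binary = binarize(al$hypnogram),
         posture = post)
  })
  structure(list(items = items, profile = "file", seed = NA),
            class = "emg_cohort")
}
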