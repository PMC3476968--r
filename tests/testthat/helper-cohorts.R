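# Small in-memory cohorts for calibration tests. Spectral features are
# computed with no band masking so that low sampling rates (fast tests)
# are usable; masking is exercised in the spectral unit tests.

make_item <- function(id, n_epochs = 30L, fs = 10L, sep = 10) {
  r <- random_signal(n_epochs, fs)
  # scale wake epochs up so both estimators can separate the states
  spe <- 30L * fs
  for (e in which(r$state == "WAKE")) {
    idx <- ((e - 1L) * spe + 1L):(e * spe)
    r$x[idx] <- r$x[idx] * sep
    # concentrate a burst so the time-domain count rule can fire too
    r$x[idx[1:(2 * fs)]] <- r$x[idx[1:(2 * fs)]] * 10
  }
  rec <- emg_recording(r$x, fs = fs)
  list(subject_id = id,
       features = recording_features(rec, band = c(0, Inf),
                                     mains_band = NULL),
       binary = binary_hypnogram(r$state))
}

make_test_cohort <- function(n = 4L, n_epochs = 30L, seed = 99L) {
  set.seed(seed)
  structure(list(items = lapply(seq_len(n), function(i)
    make_item(sprintf("subj_%02d", i), n_epochs)),
    profile = "test", seed = seed), class = "emg_cohort")
}
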