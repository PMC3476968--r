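# Frequency-domain analysis (FDA): per-epoch total spectral power over the
# informative surface-EMG band (10-75 Hz, mains interval excluded) and a
# mean-plus-SD spectral threshold.

#' Per-epoch band-masked spectral total power
#'
#' Each whole 30-s epoch is transformed with a plain periodogram (FFT of
#' the raw epoch, no taper, no detrending; frequency resolution 1/30 Hz)
#' and the one-sided power is summed over the retained band: frequencies
#' between `band[1]` and `band[2]` Hz inclusive, excluding the closed
#' mains interval `mains_band` (both exclusion edges excluded from the
#' sum). With no masking the result equals the epoch's sum of squared
#' samples (Parseval). An optional Hann taper is available for spectra
#' with strong leakage; the thresholding that follows is self-normalizing,
#' so the taper's power scaling is immaterial.
#'
#' @param x numeric vector of raw samples from one channel.
#' @param fs sampling rate in Hz; must satisfy `fs > 2 * band[2]` so the
#'   retained band is below Nyquist.
#' @param band retained frequency interval in Hz (default `c(10, 75)`).
#'   Use `c(0, Inf)` to retain everything.
#' @param mains_band excluded mains interval in Hz (default `c(55, 65)`;
#'   use `c(45, 55)` in 50 Hz regions, or `NULL` for no exclusion).
#' @param window `"none"` (default) or `"hann"`.
#' @return numeric vector of per-epoch total powers; trailing samples
#'   beyond the last whole epoch are dropped.
#' @export
epoch_total_power <- function(x, fs, band = c(10, 75),
                              mains_band = c(55, 65),
                              window = c("none", "hann")) {
  window <- match.arg(window)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0 || fs %% 1 != 0)
    stop("`fs` must be a single positive integer (Hz)")
  fs <- as.integer(fs)
  if (is.finite(band[2L]) && fs <= 2 * band[2L])
    stop(sprintf(
      "fs = %d Hz too low: the retained band extends to %g Hz, so fs must exceed %g Hz",
      fs, band[2L], 2 * band[2L]))
  spe <- EPOCH_SECONDS * fs
  n_ep <- length(x) %/% spe
  if (n_ep < 1L) stop("signal shorter than one 30-s epoch")
  xm <- matrix(x[seq_len(n_ep * spe)], nrow = spe)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(spe) - 1L) / (spe - 1L))
    xm <- xm * w
  }
  X <- stats::mvfft(xm)
  half <- spe %/% 2L                     # spe is even (30 * integer fs)
  p <- Mod(X[seq_len(half + 1L), , drop = FALSE])^2 / spe
  # one-sided scaling: double every bin except DC and Nyquist, so that the
  # column sums satisfy Parseval exactly
  if (half > 1L) p[2L:half, ] <- 2 * p[2L:half, ]
  freq <- (0L:half) / EPOCH_SECONDS
  eps <- 1e-9
  keep <- freq >= band[1L] - eps & freq <= band[2L] + eps
  if (!is.null(mains_band))
    keep <- keep & !(freq >= mains_band[1L] - eps & freq <= mains_band[2L] + eps)
  unname(colSums(p[keep, , drop = FALSE]))
}

#' Frequency-domain sleep/wake decision
#'
#' The spectral threshold is `tsf1 * mean(tp) + tsf2 * sd(tp)`, computed
#' once from the scored recording's whole-night series of per-epoch total
#' powers (sample standard deviation, divisor N-1). An epoch is estimated
#' as wake if its total power strictly exceeds the threshold, and as sleep
#' otherwise.
#'
#' @param tp numeric vector of per-epoch band-masked total powers (at
#'   least 2 epochs, so the SD is defined).
#' @param tsf1 weight on the mean (>= 0).
#' @param tsf2 weight on the standard deviation (>= 0).
#' @param sd_divisor `"n-1"` (sample SD, default) or `"n"` (population).
#' @return list with `prediction` (a `binary_hypnogram`), `threshold`
#'   (scalar) and `tp`.
#' @export
classify_fda <- function(tp, tsf1 = 0.5, tsf2 = 3.5,
                         sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  if (length(tp) < 2L) stop("at least 2 epochs are needed (SD undefined)")
  if (!is.numeric(tsf1) || length(tsf1) != 1L || tsf1 < 0)
    stop("`tsf1` must be a single non-negative number")
  if (!is.numeric(tsf2) || length(tsf2) != 1L || tsf2 < 0)
    stop("`tsf2` must be a single non-negative number")
  s <- stats::sd(tp)
  if (sd_divisor == "n")
    s <- s * sqrt((length(tp) - 1) / length(tp))
  thr <- tsf1 * mean(tp) + tsf2 * s
  list(prediction = binary_hypnogram(ifelse(tp > thr, "WAKE", "SLEEP")),
       threshold = thr, tp = tp)
}

#' Score a recording with the frequency-domain estimator
#'
#' Runs the full frequency-domain pipeline: per-epoch band-masked total
#' power per channel, channel combination, and the mean-plus-SD threshold
#' decision.
#'
#' @param x an `emg_recording` or a precomputed feature list from
#'   [recording_features()] (which must then contain `tp`).
#' @param tsf1,tsf2 threshold-selection factors, see [classify_fda()].
#' @param combine `"sum"` (combine channel powers, one decision) or
#'   `"or"` (classify per channel; wake if any channel says wake).
#' @param band,mains_band,window passed to [epoch_total_power()] when `x`
#'   is a recording.
#' @return list with `prediction`, `threshold`, `tp` and `method`.
#' @export
score_fda <- function(x, tsf1 = 0.5, tsf2 = 3.5, combine = c("sum", "or"),
                      band = c(10, 75), mains_band = c(55, 65),
                      window = "none") {
  combine <- match.arg(combine)
  feats <- if (inherits(x, "emg_recording"))
    recording_features(x, with_tp = TRUE, band = band,
                       mains_band = mains_band, window = window) else x
  if (is.null(feats$tp))
    stop("feature list has no spectral total power (`tp`)")
  if (combine == "sum" || length(feats$tp_channel) <= 1L) {
    res <- classify_fda(feats$tp, tsf1, tsf2)
    res$method <- "fda"
    return(res)
  }
  per <- lapply(feats$tp_channel, classify_fda, tsf1 = tsf1, tsf2 = tsf2)
  states <- Reduce(function(a, b) ifelse(a == "WAKE" | b == "WAKE",
                                         "WAKE", "SLEEP"),
                   lapply(per, function(r) r$prediction$states))
  res <- per[[1L]]
  res$prediction <- binary_hypnogram(states)
  res$channels <- per
  res$method <- "fda"
  res
}
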