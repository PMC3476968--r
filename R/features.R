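# Time-domain energy features: per-second summed squared amplitude and its
# per-epoch (30 s) aggregation. These are the quantities the adaptive
# amplitude threshold operates on.

#' Per-second signal energy
#'
#' Squares the raw EMG samples and sums them second by second:
#' `y[k] = sum(x[j]^2)` over the k-th second's `fs` samples. No filtering
#' or detrending is applied beforehand; an optional per-epoch DC-offset
#' removal is available for recordings that carry an amplifier offset,
#' which summed squares would otherwise misread as tonic activity.
#'
#' @param x numeric vector of raw samples from one channel.
#' @param fs sampling rate in Hz (positive integer).
#' @param remove_dc if `TRUE`, subtract each whole 30-s epoch's mean before
#'   squaring (off by default).
#' @return numeric vector of per-second energies; a trailing partial second
#'   is dropped.
#' @export
second_energy <- function(x, fs, remove_dc = FALSE) {
  if (length(x) == 0L) stop("empty signal")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0 || fs %% 1 != 0)
    stop("`fs` must be a single positive integer (Hz)")
  fs <- as.integer(fs)
  n_sec <- length(x) %/% fs
  if (n_sec == 0L) stop("signal shorter than one second")
  x <- x[seq_len(n_sec * fs)]
  if (remove_dc) {
    spe <- EPOCH_SECONDS * fs
    n_ep <- length(x) %/% spe
    if (n_ep > 0L) {
      idx <- seq_len(n_ep * spe)
      ep <- rep(seq_len(n_ep), each = spe)
      x[idx] <- x[idx] - ave(x[idx], ep)
    }
  }
  unname(colSums(matrix(x * x, nrow = fs)))
}

#' Per-epoch energy
#'
#' Sums the per-second energies over each 30-s epoch:
#' `z[l] = sum(y[k])` over the epoch's 30 seconds.
#'
#' @param y numeric vector of per-second energies whose length is a
#'   multiple of 30 (use [align_epochs()] / [second_energy()] truncation
#'   upstream).
#' @return numeric vector of per-epoch energies.
#' @export
epoch_energy <- function(y) {
  if (length(y) == 0L) stop("empty per-second energy series")
  if (length(y) %% EPOCH_SECONDS != 0L)
    stop("length of `y` (", length(y), ") is not a multiple of ",
         EPOCH_SECONDS, " seconds")
  unname(colSums(matrix(y, nrow = EPOCH_SECONDS)))
}

#' Combine per-channel energy (or power) series
#'
#' Energy is additive, so bilateral channels are combined by element-wise
#' summation before thresholding; a single channel is returned unchanged.
#'
#' @param per_channel list of equal-length numeric vectors (one per
#'   channel), or a single numeric vector.
#' @return a numeric vector of the combined series.
#' @export
combine_channels <- function(per_channel) {
  if (is.numeric(per_channel)) return(per_channel)
  stopifnot(is.list(per_channel), length(per_channel) >= 1L)
  lens <- vapply(per_channel, length, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("per-channel series have differing lengths")
  Reduce(`+`, per_channel)
}

#' Compute all per-epoch features of a recording
#'
#' Convenience wrapper producing, over the recording's whole epochs, the
#' per-second energies `y`, per-epoch energies `z`, and (optionally) the
#' band-masked per-epoch spectral total power `tp`, each combined across
#' channels by summation. Trailing samples beyond the last whole epoch are
#' dropped with a warning.
#'
#' @param rec an `emg_recording`.
#' @param with_tp compute the spectral feature too (requires
#'   `fs > 2 * band[2]`).
#' @param band retained frequency band in Hz for `tp` (default 10--75).
#' @param mains_band excluded mains interval in Hz for `tp`
#'   (default 55--65); `NULL` disables the exclusion.
#' @param window taper passed to [epoch_total_power()].
#' @param remove_dc passed to [second_energy()].
#' @return list with `y`, `z`, `tp` (or `NULL`), `n_epochs`, and the
#'   per-channel series in `y_channel`, `z_channel`, `tp_channel`.
#' @export
recording_features <- function(rec, with_tp = TRUE, band = c(10, 75),
                               mains_band = c(55, 65), window = "none",
                               remove_dc = FALSE) {
  stopifnot(inherits(rec, "emg_recording"))
  n_ep <- n_epochs(rec)
  if (n_ep < 1L) stop("recording shorter than one 30-s epoch")
  spe <- EPOCH_SECONDS * rec$fs
  if (length(rec$channels[[1L]]) != n_ep * spe)
    warning("dropping trailing samples beyond the last whole epoch")
  chans <- lapply(rec$channels, function(x) x[seq_len(n_ep * spe)])
  y_ch <- lapply(chans, second_energy, fs = rec$fs, remove_dc = remove_dc)
  z_ch <- lapply(y_ch, epoch_energy)
  tp_ch <- NULL
  if (with_tp)
    tp_ch <- lapply(chans, epoch_total_power, fs = rec$fs, band = band,
                    mains_band = mains_band, window = window)
  list(y = combine_channels(y_ch), z = combine_channels(z_ch),
       tp = if (with_tp) combine_channels(tp_ch),
       n_epochs = n_ep, y_channel = y_ch, z_channel = z_ch,
       tp_channel = tp_ch)
}
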