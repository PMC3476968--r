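# Time-domain analysis (TDA): an adaptive amplitude threshold derived from
# a sliding window of per-epoch energies, counting of high-EMG seconds
# (HEMG), and the whole-night mean-HEMG sleep/wake decision.

#' Adaptive amplitude threshold per epoch
#'
#' For epoch m the threshold is `tsf1` times the mean per-epoch energy over
#' the symmetric window of `tsf2` epochs on either side of m (2*tsf2 + 1
#' epochs in the interior). At the recording boundaries the window is
#' truncated and the divisor is the number of epochs actually present, so
#' the threshold remains an average of observed energies and every epoch
#' is scored.
#'
#' @param z numeric vector of per-epoch energies.
#' @param tsf1 dimensionless threshold-selection factor multiplying the
#'   windowed mean (> 0).
#' @param tsf2 half-window width in epochs (non-negative integer).
#' @return numeric vector of thresholds, one per epoch.
#' @export
adaptive_threshold <- function(z, tsf1 = 4, tsf2 = 25) {
  if (length(z) == 0L) stop("empty per-epoch energy series")
  if (!is.numeric(tsf1) || length(tsf1) != 1L || tsf1 <= 0)
    stop("`tsf1` must be a single positive number")
  if (!is.numeric(tsf2) || length(tsf2) != 1L || tsf2 < 0 || tsf2 %% 1 != 0)
    stop("`tsf2` must be a single non-negative integer")
  n <- length(z)
  m <- seq_len(n)
  lo <- pmax(1L, m - tsf2)
  hi <- pmin(n, m + tsf2)
  cs <- c(0, cumsum(z))
  tsf1 * (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Count high-EMG seconds per epoch
#'
#' Within each epoch, counts the per-second energies strictly exceeding
#' that epoch's threshold (a value exactly equal to the threshold does not
#' count). Also returns the whole-recording mean count, which is the
#' sleep/wake decision line.
#'
#' @param y numeric vector of per-second energies (30 per epoch).
#' @param threshold numeric vector of per-epoch thresholds.
#' @return an object of class `hemg_series`: list with integer `counts`
#'   (one per epoch, each in 0..30) and `mean_hemg`.
#' @export
hemg_count <- function(y, threshold) {
  if (length(y) != EPOCH_SECONDS * length(threshold))
    stop("`y` must contain exactly 30 per-second values per threshold epoch")
  counts <- colSums(matrix(y, nrow = EPOCH_SECONDS) >
                      rep(threshold, each = EPOCH_SECONDS))
  structure(list(counts = as.integer(counts), mean_hemg = mean(counts)),
            class = "hemg_series")
}

#' @export
print.hemg_series <- function(x, ...) {
  cat(sprintf("<hemg_series> %d epochs, mean HEMG %.3f, max %d\n",
              length(x$counts), x$mean_hemg, max(x$counts)))
  invisible(x)
}

#' Time-domain sleep/wake decision
#'
#' An epoch is estimated as wake if its high-EMG-second count strictly
#' exceeds the whole-recording mean count, and as sleep otherwise (ties go
#' to sleep). The mean is taken over the full night, so this is an offline
#' decision rule.
#'
#' @param hemg an `hemg_series` from [hemg_count()] (or a bare numeric
#'   vector of counts).
#' @return a `binary_hypnogram` of per-epoch SLEEP/WAKE estimates.
#' @export
classify_tda <- function(hemg) {
  counts <- if (inherits(hemg, "hemg_series")) hemg$counts else hemg
  if (length(counts) == 0L) stop("no epochs to classify")
  binary_hypnogram(ifelse(counts > mean(counts), "WAKE", "SLEEP"))
}

#' Score a recording with the time-domain estimator
#'
#' Runs the full time-domain pipeline: per-second and per-epoch energies
#' (channels combined by energy summation, or classified per channel and
#' OR-ed), adaptive threshold, high-EMG-second counts, and the mean-count
#' decision.
#'
#' @param x an `emg_recording` or a precomputed feature list from
#'   [recording_features()].
#' @param tsf1,tsf2 threshold-selection factors, see
#'   [adaptive_threshold()].
#' @param combine `"sum"` (combine channel energies, one decision) or
#'   `"or"` (classify each channel separately; wake if any channel says
#'   wake).
#' @param remove_dc passed to [second_energy()] when `x` is a recording.
#' @return list with `prediction` (a `binary_hypnogram`), `counts`,
#'   `mean_hemg`, `threshold` and `z` (for `combine = "or"` these describe
#'   the first channel; per-channel results are in `channels`).
#' @export
score_tda <- function(x, tsf1 = 4, tsf2 = 25, combine = c("sum", "or"),
                      remove_dc = FALSE) {
  combine <- match.arg(combine)
  feats <- if (inherits(x, "emg_recording"))
    recording_features(x, with_tp = FALSE, remove_dc = remove_dc) else x
  one <- function(y, z) {
    thr <- adaptive_threshold(z, tsf1, tsf2)
    h <- hemg_count(y, thr)
    list(prediction = classify_tda(h), counts = h$counts,
         mean_hemg = h$mean_hemg, threshold = thr, z = z)
  }
  if (combine == "sum" || length(feats$y_channel) <= 1L) {
    res <- one(feats$y, feats$z)
    res$method <- "tda"
    return(res)
  }
  per <- Map(one, feats$y_channel, feats$z_channel)
  states <- Reduce(function(a, b) ifelse(a == "WAKE" | b == "WAKE",
                                         "WAKE", "SLEEP"),
                   lapply(per, function(r) r$prediction$states))
  res <- per[[1L]]
  res$prediction <- binary_hypnogram(states)
  res$channels <- per
  res$method <- "tda"
  res
}
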