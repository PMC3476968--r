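# Epoch-by-epoch agreement statistics against a reference hypnogram,
# sleep-efficiency comparison, posture-stratified agreement and the
# state-wise normalized amplitude histogram.

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Agreement statistics from confusion counts
#'
#' Builds the full statistic set from the four confusion-matrix counts,
#' with sleep as the positive class: sensitivity TP/(TP+FN) (correctly
#' identified sleep), specificity TN/(FP+TN) (correctly identified wake),
#' PPV TP/(TP+FP), NPV TN/(TN+FN), accuracy, Cohen's kappa (chance
#' agreement from the marginal products) and the F-measure. Every printed
#' F value in the validation study this package reproduces matches the
#' PPV--sensitivity harmonic mean, which is therefore the default; the
#' sensitivity--specificity variant is available via `f_variant`.
#'
#' @param tp,tn,fp,fn non-negative epoch counts (positive class = sleep).
#' @param f_variant `"ppv_sens"` (default) or `"sens_spec"`.
#' @return an object of class `agreement_stats`.
#' @export
agreement_from_counts <- function(tp, tn, fp, fn,
                                  f_variant = c("ppv_sens", "sens_spec")) {
  f_variant <- match.arg(f_variant)
  n <- tp + tn + fp + fn
  if (n == 0L) stop("no scored epoch pairs")
  ref_single <- (tp + fn) == 0L || (tn + fp) == 0L
  if (ref_single)
    warning("reference contains a single class; dependent statistics are NA")
  sens <- ratio_or_na(tp, tp + fn)
  spec <- ratio_or_na(tn, tn + fp)
  ppv <- ratio_or_na(tp, tp + fp)
  npv <- ratio_or_na(tn, tn + fn)
  acc <- (tp + tn) / n
  p_o <- acc
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  # chance-corrected agreement is not meaningful against a one-class
  # reference, so it is reported as NA rather than a degenerate value
  kappa <- if (!ref_single && p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  f <- if (f_variant == "ppv_sens") {
    if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
      2 * ppv * sens / (ppv + sens) else NA_real_
  } else {
    if (!is.na(sens) && !is.na(spec) && (sens + spec) > 0)
      2 * sens * spec / (sens + spec) else NA_real_
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, accuracy = acc, kappa = kappa, f_measure = f),
            class = "agreement_stats")
}

#' Epoch-by-epoch agreement between two sleep/wake sequences
#'
#' Epochs marked `EXCLUDED` in either sequence are dropped pairwise before
#' counting. Sleep is the positive class.
#'
#' @param pred predicted `binary_hypnogram` (or character vector).
#' @param ref reference `binary_hypnogram` (or character vector).
#' @param f_variant see [agreement_from_counts()].
#' @return an `agreement_stats` object.
#' @export
agreement <- function(pred, ref, f_variant = "ppv_sens") {
  p <- if (inherits(pred, "binary_hypnogram")) pred$states else as.character(pred)
  r <- if (inherits(ref, "binary_hypnogram")) ref$states else as.character(ref)
  if (length(p) != length(r))
    stop("prediction and reference have different lengths (",
         length(p), " vs ", length(r), ")")
  keep <- p != "EXCLUDED" & r != "EXCLUDED"
  p <- p[keep]; r <- r[keep]
  if (length(p) == 0L) stop("no scored epoch pairs after exclusions")
  agreement_from_counts(
    tp = sum(p == "SLEEP" & r == "SLEEP"),
    tn = sum(p == "WAKE" & r == "WAKE"),
    fp = sum(p == "SLEEP" & r == "WAKE"),
    fn = sum(p == "WAKE" & r == "SLEEP"),
    f_variant = f_variant)
}

#' @export
print.agreement_stats <- function(x, digits = 3L, ...) {
  cat(sprintf("<agreement_stats> %d epochs (TP %d, TN %d, FP %d, FN %d)\n",
              x$n, x$tp, x$tn, x$fp, x$fn))
  v <- unlist(x[c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                  "kappa", "f_measure")])
  names(v) <- c("SENS", "SPEC", "PPV", "NPV", "ACCU", "KAPPA", "F")
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.agreement_stats <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn, n = x$n,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, npv = x$npv, accuracy = x$accuracy,
             kappa = x$kappa, f_measure = x$f_measure)
}

#' F-measure from precision and recall
#'
#' @param sens sensitivity (recall).
#' @param ppv positive predictive value (precision).
#' @return `2 * ppv * sens / (ppv + sens)`.
#' @export
f_measure <- function(sens, ppv) 2 * ppv * sens / (ppv + sens)

#' Sleep efficiency of a sleep/wake sequence
#'
#' @param x a `binary_hypnogram` (or character vector); `EXCLUDED` epochs
#'   are dropped from numerator and denominator.
#' @return percentage of scored epochs that are sleep, in 0--100.
#' @export
sleep_efficiency <- function(x) {
  s <- if (inherits(x, "binary_hypnogram")) x$states else as.character(x)
  s <- s[s != "EXCLUDED"]
  if (length(s) == 0L) stop("no scored epochs")
  100 * sum(s == "SLEEP") / length(s)
}

#' Compare reference and estimated sleep efficiency
#'
#' Accepts either sleep/wake sequences (whose efficiencies are computed)
#' or efficiency percentages directly. The absolute difference is taken
#' before any rounding; the relative difference is denominated by the
#' reference value.
#'
#' @param ref reference (PSG) `binary_hypnogram` or efficiency in 0--100.
#' @param est estimated `binary_hypnogram` or efficiency in 0--100.
#' @return list with `se_ref`, `se_est`, `abs_diff` (percentage points)
#'   and `rel_diff` (% of the reference; `NA` when the reference is 0).
#' @export
sleep_efficiency_compare <- function(ref, est) {
  se_ref <- if (is.numeric(ref)) ref else sleep_efficiency(ref)
  se_est <- if (is.numeric(est)) est else sleep_efficiency(est)
  if (se_ref < 0 || se_ref > 100 || se_est < 0 || se_est > 100)
    stop("sleep efficiencies must lie in [0, 100]")
  abs_diff <- abs(se_ref - se_est)
  rel_diff <- if (se_ref > 0) 100 * abs_diff / se_ref else NA_real_
  if (se_ref == 0) warning("reference sleep efficiency is 0; relative difference undefined")
  list(se_ref = se_ref, se_est = se_est, abs_diff = abs_diff,
       rel_diff = rel_diff)
}

#' Posture-stratified agreement
#'
#' Splits the epoch-by-epoch comparison by body posture and reports the
#' scored epoch count and Cohen's kappa per stratum. Postures with no
#' epochs are reported with count 0 and `NA` kappa.
#'
#' @param pred,ref sleep/wake sequences as in [agreement()].
#' @param postures a `posture_track` (or character vector) aligned with
#'   the sequences.
#' @return data.frame with columns `posture`, `epochs`, `kappa`.
#' @export
posture_strata <- function(pred, ref, postures) {
  p <- if (inherits(pred, "binary_hypnogram")) pred$states else as.character(pred)
  r <- if (inherits(ref, "binary_hypnogram")) ref$states else as.character(ref)
  q <- if (inherits(postures, "posture_track")) postures$postures else as.character(postures)
  if (length(p) != length(r) || length(p) != length(q))
    stop("prediction, reference and posture track must have equal lengths")
  out <- data.frame(posture = POSTURE_LEVELS, epochs = 0L,
                    kappa = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(POSTURE_LEVELS)) {
    idx <- q == POSTURE_LEVELS[i] & p != "EXCLUDED" & r != "EXCLUDED"
    out$epochs[i] <- sum(idx)
    if (any(idx)) {
      st <- suppressWarnings(agreement(p[idx], r[idx]))
      out$kappa[i] <- st$kappa
    }
  }
  out
}

#' State-wise normalized amplitude histogram
#'
#' Absolute sample amplitudes are normalized by the recording's maximum
#' absolute amplitude (so the maximum maps to exactly 1), then binned
#' separately for sleep and wake epochs with each state's histogram
#' normalized to unit mass. Per-epoch mean normalized amplitudes are
#' compared between the states with a two-sample Wilcoxon rank-sum test.
#'
#' @param rec an `emg_recording`.
#' @param ref a `binary_hypnogram` aligned with the recording's whole
#'   epochs.
#' @param bins number of equal-width bins on `[0, 1]`.
#' @param channel channel name or index used for the amplitudes.
#' @return an object of class `state_amplitude_histogram`: list with
#'   `breaks`, per-state `mass` (each summing to 1), `epoch_means`
#'   (data.frame of state and mean normalized amplitude per epoch) and
#'   `p_value` (`NA`, with a warning, if only one state is present).
#' @export
state_amplitude_histogram <- function(rec, ref, bins = 50L, channel = 1L) {
  stopifnot(inherits(rec, "emg_recording"))
  states <- if (inherits(ref, "binary_hypnogram")) ref$states else as.character(ref)
  spe <- EPOCH_SECONDS * rec$fs
  n_ep <- min(n_epochs(rec), length(states))
  if (n_ep < 1L) stop("no whole epochs")
  x <- rec$channels[[channel]][seq_len(n_ep * spe)]
  states <- states[seq_len(n_ep)]
  amax <- max(abs(x))
  if (amax == 0) stop("all-zero signal cannot be amplitude-normalized")
  a <- abs(x) / amax
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(pmax(ceiling(a * bins), 1L), bins)
  ep <- rep(seq_len(n_ep), each = spe)
  epoch_means <- data.frame(
    state = states,
    mean_amp = as.numeric(tapply(a, ep, mean)),
    stringsAsFactors = FALSE)
  mass <- list()
  for (s in c("SLEEP", "WAKE")) {
    idx <- states[ep] == s
    if (any(idx)) {
      counts <- tabulate(bin[idx], nbins = bins)
      mass[[s]] <- counts / sum(counts)
    }
  }
  p_value <- NA_real_
  if (all(c("SLEEP", "WAKE") %in% names(mass))) {
    p_value <- stats::wilcox.test(
      epoch_means$mean_amp[epoch_means$state == "SLEEP"],
      epoch_means$mean_amp[epoch_means$state == "WAKE"])$p.value
  } else {
    warning("only one state present; rank-sum test skipped")
  }
  structure(list(breaks = breaks, mass = mass, epoch_means = epoch_means,
                 p_value = p_value, n_epochs = n_ep),
            class = "state_amplitude_histogram")
}

#' @export
print.state_amplitude_histogram <- function(x, ...) {
  cat(sprintf(
    "<state_amplitude_histogram> %d epochs, %d bins; rank-sum p = %s\n",
    x$n_epochs, length(x$breaks) - 1L,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3L)))
  for (s in names(x$mass))
    cat(sprintf("  %s: mean normalized amplitude %.4f\n", s,
                mean(x$epoch_means$mean_amp[x$epoch_means$state == s])))
  invisible(x)
}

#' Plot the state-wise normalized amplitude histogram
#'
#' @param x a `state_amplitude_histogram`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.state_amplitude_histogram <- function(x, ...) {
  mids <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  cols <- c(SLEEP = "steelblue", WAKE = "firebrick")
  ylim <- c(0, max(unlist(x$mass)))
  graphics::plot(NA, xlim = c(0, 1), ylim = ylim,
                 xlab = "normalized amplitude", ylab = "probability mass",
                 ...)
  for (s in names(x$mass))
    graphics::lines(mids, x$mass[[s]], type = "h", col = cols[[s]])
  graphics::legend("topright", legend = names(x$mass),
                   col = cols[names(x$mass)], lty = 1L, bty = "n")
  invisible(x)
}

#' Mean and sample-SD aggregation of per-subject statistics
#'
#' Aggregates a table of per-subject statistics into the conventional
#' "mean (SD)" summary row, using the sample standard deviation
#' (divisor n-1).
#'
#' @param df data.frame of per-subject statistic columns (non-numeric
#'   columns are ignored).
#' @param na.rm drop missing values per column.
#' @return data.frame with rows `mean` and `sd`.
#' @export
aggregate_stats <- function(df, na.rm = FALSE) {
  num <- df[vapply(df, is.numeric, logical(1L))]
  data.frame(lapply(num, function(x)
    c(mean = mean(x, na.rm = na.rm), sd = stats::sd(x, na.rm = na.rm))),
    row.names = c("mean", "sd"))
}
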