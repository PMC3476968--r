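# Independent brute-force transcriptions of the scoring recipe and the
# agreement statistics, written as plain loops with no vectorization or
# windowing shortcuts, used as oracles against the package implementation.

naive_tda <- function(x, fs, tsf1, tsf2) {
  n_sec <- floor(length(x) / fs)
  y <- numeric(n_sec)
  for (k in seq_len(n_sec)) {
    s <- 0
    for (j in ((k - 1) * fs + 1):(k * fs)) s <- s + x[j]^2
    y[k] <- s
  }
  n_ep <- floor(n_sec / 30)
  y <- y[seq_len(n_ep * 30)]
  z <- numeric(n_ep)
  for (l in seq_len(n_ep)) {
    s <- 0
    for (k in ((l - 1) * 30 + 1):(l * 30)) s <- s + y[k]
    z[l] <- s
  }
  thr <- numeric(n_ep)
  for (m in seq_len(n_ep)) {
    s <- 0; cnt <- 0
    for (l in (m - tsf2):(m + tsf2)) {
      if (l >= 1 && l <= n_ep) { s <- s + z[l]; cnt <- cnt + 1 }
    }
    thr[m] <- tsf1 * s / cnt
  }
  hemg <- integer(n_ep)
  for (m in seq_len(n_ep)) {
    c_m <- 0
    for (k in ((m - 1) * 30 + 1):(m * 30)) {
      if (y[k] - thr[m] > 0) c_m <- c_m + 1   # sgn(y - T) = 1 iff y > T
    }
    hemg[m] <- c_m
  }
  mean_hemg <- sum(hemg) / n_ep
  states <- character(n_ep)
  for (m in seq_len(n_ep))
    states[m] <- if (hemg[m] > mean_hemg) "WAKE" else "SLEEP"
  list(y = y, z = z, threshold = thr, hemg = hemg,
       mean_hemg = mean_hemg, states = states)
}

naive_agreement <- function(pred, ref) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == "EXCLUDED" || ref[i] == "EXCLUDED") next
    if (pred[i] == "SLEEP" && ref[i] == "SLEEP") tp <- tp + 1L
    else if (pred[i] == "WAKE" && ref[i] == "WAKE") tn <- tn + 1L
    else if (pred[i] == "SLEEP" && ref[i] == "WAKE") fp <- fp + 1L
    else fn <- fn + 1L
  }
  n <- tp + tn + fp + fn
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  ppv <- tp / (tp + fp); npv <- tn / (tn + fn)
  acc <- (tp + tn) / n
  pe <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  kappa <- (acc - pe) / (1 - pe)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       accuracy = acc, kappa = kappa,
       f_measure = 2 * ppv * sens / (ppv + sens))
}

# a small random recording with a mix of quiet and bursty epochs, so both
# classes appear with high probability
random_signal <- function(n_epochs, fs = 10L) {
  spe <- 30L * fs
  state <- sample(c("SLEEP", "WAKE"), n_epochs, replace = TRUE,
                  prob = c(0.7, 0.3))
  x <- unlist(lapply(state, function(s) {
    sd <- if (s == "WAKE") runif(1, 3, 10) else runif(1, 0.5, 1.5)
    rnorm(spe, sd = sd)
  }))
  list(x = x, fs = fs, state = state)
}
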