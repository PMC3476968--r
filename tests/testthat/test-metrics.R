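test_that("agreement statistics follow their defining ratios", {
  st <- agreement_from_counts(tp = 90, tn = 5, fp = 3, fn = 2)
  expect_equal(st$sensitivity, 90 / 92)
  expect_equal(st$specificity, 5 / 8)
  expect_equal(st$accuracy, 0.95)
  expect_equal(st$kappa, 0.6398, tolerance = 1e-4)
  expect_equal(st$ppv, 90 / 93)
  expect_equal(st$npv, 5 / 7)
  # perfect agreement with both classes present
  perfect <- agreement(binary_hypnogram(c("SLEEP", "SLEEP", "WAKE")),
                       binary_hypnogram(c("SLEEP", "SLEEP", "WAKE")))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$f_measure, 1)
})

test_that("the F-measure is the precision-recall harmonic mean by default", {
  # reproduces a published row: sensitivity 0.99 with PPV 0.56 -> F 0.72
  expect_equal(round_printed(f_measure(sens = 0.99, ppv = 0.56), 2), 0.72)
  st <- agreement_from_counts(tp = 90, tn = 5, fp = 3, fn = 2)
  expect_equal(st$f_measure, 2 * st$ppv * st$sensitivity /
                 (st$ppv + st$sensitivity))
  st2 <- agreement_from_counts(tp = 90, tn = 5, fp = 3, fn = 2,
                               f_variant = "sens_spec")
  expect_equal(st2$f_measure, 2 * st2$sensitivity * st2$specificity /
                 (st2$sensitivity + st2$specificity))
})

test_that("excluded epochs are dropped pairwise; single-class references warn", {
  pred <- binary_hypnogram(c("SLEEP", "WAKE", "SLEEP", "EXCLUDED"))
  ref <- binary_hypnogram(c("SLEEP", "EXCLUDED", "WAKE", "SLEEP"))
  st <- suppressWarnings(agreement(pred, ref))
  expect_identical(st$n, 2L)                       # epochs 1 and 3 only
  expect_identical(st$tp + st$tn + st$fp + st$fn, st$n)
  expect_warning(st1 <- agreement(rep("SLEEP", 5), rep("SLEEP", 5)),
                 "single class")
  expect_true(is.na(st1$kappa))
  expect_true(is.na(st1$specificity))
  expect_identical(st1$tp, 5L)
  expect_error(agreement(rep("SLEEP", 2), rep("SLEEP", 3)), "lengths")
})

test_that("all seven statistics agree with a naive per-epoch loop", {
  set.seed(40)
  for (i in 1:30) {
    n <- sample(10:1000, 1)
    ref <- sample(c("SLEEP", "WAKE", "EXCLUDED"), n, replace = TRUE,
                  prob = c(0.8, 0.15, 0.05))
    pred <- ifelse(runif(n) < 0.85, ref,
                   ifelse(ref == "SLEEP", "WAKE", "SLEEP"))
    pred[pred == "EXCLUDED"] <- "SLEEP"
    if (!any(ref == "SLEEP") || !any(ref == "WAKE")) next
    got <- agreement(pred, ref)
    oracle <- naive_agreement(pred, ref)
    for (f in c("tp", "tn", "fp", "fn"))
      expect_identical(got[[f]], oracle[[f]])
    for (f in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                "kappa", "f_measure"))
      expect_equal(got[[f]], oracle[[f]], tolerance = 1e-12)
  }
})

test_that("kappa is invariant under swapping the class labels of both sequences", {
  set.seed(41)
  swap <- function(s) ifelse(s == "SLEEP", "WAKE", "SLEEP")
  for (i in 1:20) {
    n <- sample(20:200, 1)
    ref <- sample(c("SLEEP", "WAKE"), n, replace = TRUE, prob = c(0.7, 0.3))
    pred <- ifelse(runif(n) < 0.8, ref, swap(ref))
    if (length(unique(ref)) < 2) next
    k1 <- agreement(pred, ref)$kappa
    k2 <- agreement(swap(pred), swap(ref))$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
  }
})

test_that("sleep-efficiency comparison uses the reference as denominator", {
  cmp <- sleep_efficiency_compare(94.1, 96.6)
  expect_equal(cmp$abs_diff, 2.5)
  expect_equal(round_printed(cmp$rel_diff, 1), 2.7)
  cmp2 <- sleep_efficiency_compare(98.2, 97.5)
  expect_equal(round_printed(cmp2$abs_diff, 1), 0.7)
  expect_equal(round_printed(cmp2$rel_diff, 1), 0.7)
  # identical hypnograms -> 0, 0
  b <- binary_hypnogram(c(rep("SLEEP", 9), "WAKE"))
  cmp3 <- sleep_efficiency_compare(b, b)
  expect_equal(cmp3$se_ref, 90)
  expect_equal(cmp3$abs_diff, 0)
  expect_equal(cmp3$rel_diff, 0)
  expect_warning(cmp4 <- sleep_efficiency_compare(0, 10), "undefined")
  expect_true(is.na(cmp4$rel_diff))
  expect_error(sleep_efficiency_compare(101, 50), "0, 100")
})

test_that("posture strata reproduce per-subset agreement and report empty strata", {
  set.seed(42)
  n <- 300
  ref <- sample(c("SLEEP", "WAKE"), n, replace = TRUE, prob = c(0.8, 0.2))
  pred <- ifelse(runif(n) < 0.85, ref,
                 ifelse(ref == "SLEEP", "WAKE", "SLEEP"))
  post <- sample(c("SUPINE", "LEFT"), n, replace = TRUE, prob = c(0.7, 0.3))
  out <- posture_strata(pred, ref, post)
  expect_identical(out$posture,
                   c("SUPINE", "LEFT", "RIGHT", "PRONE", "UNKNOWN"))
  for (p in c("SUPINE", "LEFT")) {
    idx <- post == p
    direct <- agreement(pred[idx], ref[idx])
    row <- out[out$posture == p, ]
    expect_identical(row$epochs, sum(idx))
    expect_equal(row$kappa, direct$kappa)
  }
  prone <- out[out$posture == "PRONE", ]
  expect_identical(prone$epochs, 0L)
  expect_true(is.na(prone$kappa))
  # a single posture stratum equals the global kappa
  all_sup <- posture_strata(pred, ref, rep("SUPINE", n))
  expect_equal(all_sup$kappa[all_sup$posture == "SUPINE"],
               agreement(pred, ref)$kappa)
})

test_that("state histograms have unit mass and max amplitude maps to one", {
  set.seed(43)
  fs <- 10L
  n_ep <- 40L
  states <- rep(c("SLEEP", "WAKE"), each = n_ep / 2)
  x <- unlist(lapply(states, function(s)
    rnorm(30 * fs, sd = if (s == "WAKE") 3 else 1)))
  rec <- emg_recording(x, fs = fs)
  h <- state_amplitude_histogram(rec, binary_hypnogram(states), bins = 40)
  expect_equal(sum(h$mass$SLEEP), 1)
  expect_equal(sum(h$mass$WAKE), 1)
  # the recording's maximum falls in the top bin of its state
  top_state <- states[ceiling(which.max(abs(x)) / (30 * fs))]
  expect_gt(h$mass[[top_state]][40], 0)
  # wake amplitudes generated at 3x sleep scale: mean higher, p < 0.05
  m <- tapply(h$epoch_means$mean_amp, h$epoch_means$state, mean)
  expect_gt(m[["WAKE"]], m[["SLEEP"]])
  expect_lt(h$p_value, 0.05)
  # degenerate constant amplitude: single occupied bin in both states
  rec2 <- emg_recording(rep(1, 30 * fs * 4), fs = fs)
  h2 <- suppressWarnings(state_amplitude_histogram(rec2,
          binary_hypnogram(c("SLEEP", "SLEEP", "WAKE", "WAKE")), bins = 10))
  expect_identical(which(h2$mass$SLEEP > 0), 10L)
  expect_equal(h2$mass$SLEEP[10], 1)
  expect_equal(h2$mass$WAKE[10], 1)
  # single-state reference: histogram only, test skipped with warning
  expect_warning(
    h3 <- state_amplitude_histogram(rec2, binary_hypnogram(rep("SLEEP", 4))),
    "one state")
  expect_true(is.na(h3$p_value))
})

test_that("mean/SD aggregation uses the sample standard deviation", {
  df <- data.frame(kappa = c(.64, .64, .70, .61, .61, .73, .55))
  agg <- aggregate_stats(df)
  expect_equal(round_printed(agg["mean", "kappa"], 2), 0.64)
  expect_equal(round_printed(agg["sd", "kappa"], 2), 0.06)
  expect_equal(agg["sd", "kappa"], sd(df$kappa))
})
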