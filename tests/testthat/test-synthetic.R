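test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(duration_epochs = 12L, fs = 200L, seed = 77)
  h1 <- simulate_hypnogram(spec)
  h2 <- simulate_hypnogram(spec)
  expect_identical(h1$stages, h2$stages)
  r1 <- simulate_emg(h1, spec)
  r2 <- simulate_emg(h2, spec)
  expect_identical(r1$channels, r2$channels)
  # and a different seed changes the night
  spec2 <- synthetic_spec(duration_epochs = 12L, fs = 200L, seed = 78)
  expect_false(identical(simulate_hypnogram(spec2)$stages, h1$stages))
})

test_that("regenerating a cohort with the same seed writes identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2))
    simulate_cohort(n = 1, seed = 9, duration_epochs = 6, fs = 200,
                    out_dir = d)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("the state chain attains the target sleep efficiency and stage mix", {
  spec <- synthetic_spec(duration_epochs = 100000L, target_se = 97.5,
                         seed = 101)
  h <- simulate_hypnogram(spec)
  b <- binarize(h)
  se <- sleep_efficiency(b)
  expect_lt(abs(se - 97.5), 0.3)
  # stage mix within sleep: light sleep ~65%, slow-wave ~12%, REM ~23%
  sl <- h$stages[h$stages != "W"]
  expect_lt(abs(mean(sl %in% c("S1", "S2")) - 0.65), 0.03)
  expect_lt(abs(mean(sl %in% c("S3", "S4")) - 0.12), 0.03)
  expect_lt(abs(mean(sl == "REM") - 0.23), 0.03)
})

test_that("infeasible efficiency/bout combinations are rejected up front", {
  spec <- synthetic_spec(duration_epochs = 10L, target_se = 0.5,
                         mean_wake_bout = 2, seed = 1)
  expect_error(simulate_hypnogram(spec), "infeasible")
  expect_error(synthetic_spec(target_se = 0), "between 0 and 100")
  expect_error(synthetic_spec(target_se = 100), "between 0 and 100")
  expect_error(synthetic_spec(sigma_wake = 0.5), "sigma_wake")
  expect_error(synthetic_spec(plm_interval_s = 2), "5, 90")
  expect_error(synthetic_spec(plm_duration_s = 20), "0.5, 10")
  # low but feasible efficiency works
  spec_low <- synthetic_spec(duration_epochs = 2000L, target_se = 20,
                             mean_wake_bout = 8, seed = 2)
  expect_lt(sleep_efficiency(binarize(simulate_hypnogram(spec_low))), 40)
})

test_that("tonic wake/sleep epoch energies scale as the variance ratio", {
  spec <- synthetic_spec(duration_epochs = 200L, fs = 200L, target_se = 50,
                         mean_wake_bout = 5, sigma_sleep = 1, sigma_wake = 3,
                         burst_rate_wake = 0, seed = 303)
  h <- binarize(simulate_hypnogram(spec))
  rec <- simulate_emg(h, spec)
  z <- recording_features(rec, with_tp = FALSE)$z
  ratio <- mean(z[h$states == "WAKE"]) / mean(z[h$states == "SLEEP"])
  expect_lt(abs(ratio - 9) / 9, 0.1)
})

test_that("a mains component leaves the band-masked spectral power untouched", {
  base <- synthetic_spec(duration_epochs = 20L, fs = 250L, seed = 404)
  with_mains <- synthetic_spec(duration_epochs = 20L, fs = 250L,
                               mains_amplitude = 5, seed = 404)
  h <- simulate_hypnogram(base)
  tp0 <- recording_features(simulate_emg(h, base))$tp
  tp1 <- recording_features(simulate_emg(binarize(h), with_mains))$tp
  expect_lt(max(abs(tp1 - tp0) / tp0), 0.01)
  # and it dominates the unmasked power, so the mask is doing real work
  tp_open <- recording_features(simulate_emg(binarize(h), with_mains),
                                band = c(0, Inf), mains_band = NULL)$tp
  expect_gt(min(tp_open / tp1), 2)
})

test_that("PLM burst trains degrade wake specificity at fixed thresholds", {
  normal <- simulate_cohort(n = 2, profile = "normal", seed = 31,
                            duration_epochs = 200, fs = 200,
                            keep = "features")
  plmd <- simulate_cohort(n = 2, profile = "plmd", seed = 31,
                          duration_epochs = 200, fs = 200,
                          keep = "features")
  spec_of <- function(coh) {
    mean(vapply(coh$items, function(it) {
      pred <- predict_from_features(it$features, "tda", 1, 10)
      suppressWarnings(agreement(pred, it$binary))$specificity
    }, numeric(1L)), na.rm = TRUE)
  }
  expect_lt(spec_of(plmd), spec_of(normal))
})

test_that("channel correlation produces the requested shared variance", {
  spec <- synthetic_spec(duration_epochs = 30L, fs = 200L, target_se = 99,
                         mean_wake_bout = 1, burst_rate_wake = 0,
                         channel_correlation = 0.8, seed = 505)
  rec <- simulate_emg(simulate_hypnogram(spec), spec)
  r <- cor(rec$channels[[1]], rec$channels[[2]])
  expect_lt(abs(r - 0.8), 0.05)
  spec0 <- synthetic_spec(duration_epochs = 30L, fs = 200L, target_se = 99,
                          mean_wake_bout = 1, burst_rate_wake = 0,
                          channel_correlation = 0, seed = 505)
  rec0 <- simulate_emg(simulate_hypnogram(spec0), spec0)
  expect_lt(abs(cor(rec0$channels[[1]], rec0$channels[[2]])), 0.05)
})
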