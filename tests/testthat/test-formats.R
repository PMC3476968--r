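test_that("CSV recording round-trip is exact and carries the sampling rate", {
  set.seed(1)
  rec <- emg_recording(list(L = rnorm(500), R = rnorm(500)), fs = 250,
                       subject_id = "s1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  rec2 <- read_recording(f)
  expect_identical(rec2$channels$L, rec$channels$L)
  expect_identical(rec2$channels$R, rec$channels$R)
  expect_identical(rec2$fs, 250L)

  # explicit fs argument wins over missing header; absent fs errors
  writeLines(c("a,b", "1,2", "3,4"), f)
  expect_error(read_recording(f), "sampling rate")
  rec3 <- read_recording(f, fs = 2)
  expect_equal(rec3$channels$a, c(1, 3))
})

test_that("CSV loading enforces shape and numeric content", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs=250", "a,b", "1,x", "2,y"), f)
  expect_error(read_recording(f), "non-numeric")
  writeLines("# fs=250", f)
  expect_error(read_recording(f), "no channel data")
  # requested channel absent
  set.seed(2)
  rec <- emg_recording(list(L = rnorm(100)), fs = 100)
  write_recording(rec, f)
  expect_error(read_recording(f, channels = "R"), "not found")
})

test_that("EDF round-trip preserves labels and amplitudes within quantization", {
  set.seed(3)
  spec <- synthetic_spec(duration_epochs = 2L, fs = 200L, seed = 30)
  rec <- simulate_emg(simulate_hypnogram(spec), spec)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  rec2 <- read_edf(f)
  expect_identical(names(rec2$channels), names(rec$channels))
  expect_identical(rec2$fs, rec$fs)
  for (ch in names(rec$channels)) {
    step <- max(abs(rec$channels[[ch]])) / 32767
    expect_lt(max(abs(rec2$channels[[ch]] - rec$channels[[ch]])), step)
  }
})

test_that("hypnogram tokens map case-insensitively and errors name the line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("W", "1", "2", "rem"), f)
  expect_identical(read_hypnogram(f)$stages, c("W", "S1", "S2", "REM"))
  writeLines(c("wake", "n1", "s2", "3", "4", "R", "5", "MT", "?"), f)
  expect_identical(read_hypnogram(f)$stages,
                   c("W", "S1", "S2", "S3", "S4", "REM", "REM",
                     "UNSCORED", "UNSCORED"))
  # two-column dialect
  writeLines(c("1 W", "2 S2"), f)
  expect_identical(read_hypnogram(f)$stages, c("W", "S2"))
  writeLines(c("W", "N7"), f)
  expect_error(read_hypnogram(f), "'N7' at line 2")
  writeLines(character(0), f)
  expect_length(read_hypnogram(f)$stages, 0L)
})

test_that("binarize follows the stage rule, is idempotent and partitions epochs", {
  h <- hypnogram(c("W", "S1", "REM"))
  expect_identical(binarize(h)$states, c("WAKE", "SLEEP", "SLEEP"))
  expect_identical(binarize(hypnogram(rep("W", 4)))$states, rep("WAKE", 4))
  expect_identical(binarize(hypnogram(c("S3", "UNSCORED")))$states,
                   c("SLEEP", "EXCLUDED"))
  # idempotent; counts partition the input
  b <- binarize(hypnogram(c("W", "S2", "UNSCORED", "REM", "S4")))
  expect_identical(binarize(b), b)
  expect_identical(sum(b$states == "WAKE") + sum(b$states == "SLEEP") +
                     sum(b$states == "EXCLUDED"), length(b))
  # hypnogram text round-trip
  f <- withr::local_tempfile(fileext = ".txt")
  write_hypnogram(h, f)
  expect_identical(read_hypnogram(f)$stages, h$stages)
})

test_that("posture files round-trip through the short tokens", {
  p <- posture_track(c("SUPINE", "LEFT", "RIGHT", "PRONE", "UNKNOWN"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_posture(p, f)
  expect_identical(read_posture(f)$postures, p$postures)
  writeLines("sideways", f)
  expect_error(read_posture(f), "line 1")
})

test_that("recording/hypnogram alignment truncates one epoch and rejects more", {
  set.seed(4)
  rec <- emg_recording(list(a = rnorm(30 * 10 * 3 + 5)), fs = 10)  # 3 epochs + spill
  h4 <- hypnogram(rep("S2", 4))
  w <- capture_warnings(al <- align_epochs(rec, h4))
  expect_match(w, "truncating", all = TRUE)   # both signal spill and hypnogram
  expect_identical(length(al$hypnogram), 3L)
  expect_identical(length(al$recording$channels$a), 30L * 10L * 3L)
  h6 <- hypnogram(rep("S2", 6))
  expect_error(align_epochs(rec, h6), "mismatch")
})

test_that("recording construction rejects malformed inputs", {
  expect_error(emg_recording(list(), fs = 100), "non-empty")
  expect_error(emg_recording(list(a = 1:10, b = 1:5), fs = 100), "same length")
  expect_error(emg_recording(list(a = 1:10), fs = 0), "positive integer")
  expect_error(emg_recording(list(a = 1:10), fs = 10.5), "positive integer")
  expect_error(hypnogram(c("W", "X")), "invalid stage")
  expect_error(binary_hypnogram("NAP"), "invalid state")
})
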