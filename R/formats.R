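#' @importFrom stats fft rnorm runif rpois sd wilcox.test
#' @importFrom utils read.csv write.csv
NULL

EPOCH_SECONDS <- 30L

STAGE_LEVELS <- c("W", "S1", "S2", "S3", "S4", "REM", "UNSCORED")
STATE_LEVELS <- c("SLEEP", "WAKE", "EXCLUDED")
POSTURE_LEVELS <- c("SUPINE", "LEFT", "RIGHT", "PRONE", "UNKNOWN")

# ---------------------------------------------------------------- recordings

#' Construct an EMG recording
#'
#' A recording holds one or more equal-length channels of raw surface-EMG
#' samples (arbitrary analog units) at a fixed integer sampling rate.
#' Both estimators in this package are self-normalizing through adaptive
#' thresholds, so the physical unit of the amplitudes is irrelevant.
#'
#' @param channels named list of numeric sample vectors, all the same length.
#' @param fs sampling rate in Hz; must be a positive integer (fractional
#'   samples per second are not supported).
#' @param subject_id optional identifier carried through reports.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(channels, fs, subject_id = "") {
  if (is.numeric(channels)) channels <- list(ch1 = channels)
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty list of numeric vectors")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels))
  if (!all(vapply(channels, is.numeric, logical(1L))))
    stop("all channels must be numeric")
  lens <- vapply(channels, length, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("all channels must have the same length")
  if (lens[[1L]] == 0L) stop("channels are empty")
  if (any(vapply(channels, function(x) anyNA(x), logical(1L))))
    stop("channels contain missing values")
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0 || fs %% 1 != 0)
    stop("`fs` must be a single positive integer (Hz)")
  structure(
    list(channels = lapply(channels, as.numeric), fs = as.integer(fs),
         subject_id = as.character(subject_id)),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf(
    "<emg_recording> %s: %d channel(s) [%s], %d samples @ %d Hz (%.1f min, %d whole epochs)\n",
    if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    n, x$fs, n / x$fs / 60, n_epochs(x)))
  invisible(x)
}

#' Number of whole 30-s epochs in a recording
#'
#' @param rec an `emg_recording`.
#' @return integer count of complete epochs; trailing samples that do not
#'   fill an epoch are not counted.
#' @export
n_epochs <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  as.integer(length(rec$channels[[1L]]) %/% (EPOCH_SECONDS * rec$fs))
}

# ---------------------------------------------------------------- hypnograms

stage_token_map <- c(
  "W" = "W", "WAKE" = "W", "0" = "W",
  "1" = "S1", "S1" = "S1", "N1" = "S1",
  "2" = "S2", "S2" = "S2", "N2" = "S2",
  "3" = "S3", "S3" = "S3", "N3" = "S3",
  "4" = "S4", "S4" = "S4", "N4" = "S4",
  "R" = "REM", "REM" = "REM", "5" = "REM",
  "MT" = "UNSCORED", "?" = "UNSCORED", "UNSCORED" = "UNSCORED")

#' Construct a hypnogram of 30-s R&K stage labels
#'
#' @param stages character vector of stage labels, one per 30-s epoch, from
#'   `W, S1, S2, S3, S4, REM, UNSCORED`.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad))
    stop("invalid stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_length = EPOCH_SECONDS),
            class = "hypnogram")
}

#' Construct a binary sleep/wake hypnogram
#'
#' @param states character vector with values `SLEEP`, `WAKE` or `EXCLUDED`,
#'   one per 30-s epoch.
#' @return an object of class `binary_hypnogram`.
#' @export
binary_hypnogram <- function(states) {
  states <- as.character(states)
  bad <- setdiff(unique(states), STATE_LEVELS)
  if (length(bad))
    stop("invalid state label(s): ", paste(bad, collapse = ", "))
  structure(list(states = states, epoch_length = EPOCH_SECONDS),
            class = "binary_hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs (%.1f min):\n", length(x$stages),
              length(x$stages) * x$epoch_length / 60))
  print(table(factor(x$stages, levels = STAGE_LEVELS)))
  invisible(x)
}

#' @export
print.binary_hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = STATE_LEVELS))
  cat(sprintf("<binary_hypnogram> %d epochs: %d sleep, %d wake, %d excluded\n",
              length(x$states), tab[["SLEEP"]], tab[["WAKE"]], tab[["EXCLUDED"]]))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
length.binary_hypnogram <- function(x) length(x$states)

#' Reduce a staged hypnogram to sleep/wake
#'
#' Stages 1--4 and REM are regarded as sleep; stage W is wake; unscored
#' epochs are carried through as `EXCLUDED` and dropped pairwise by the
#' agreement statistics.
#'
#' @param h a `hypnogram` (a `binary_hypnogram` is returned unchanged, so
#'   the reduction is idempotent).
#' @return a `binary_hypnogram` of the same length.
#' @export
binarize <- function(h) {
  if (inherits(h, "binary_hypnogram")) return(h)
  stopifnot(inherits(h, "hypnogram"))
  map <- c(W = "WAKE", S1 = "SLEEP", S2 = "SLEEP", S3 = "SLEEP",
           S4 = "SLEEP", REM = "SLEEP", UNSCORED = "EXCLUDED")
  binary_hypnogram(unname(map[h$stages]))
}

#' Read a hypnogram from plain text
#'
#' One stage token per line, or two whitespace/comma-separated columns
#' (`epoch_index, stage`). Tokens are mapped case-insensitively:
#' `W`/`WAKE`/`0` to W; `1`/`S1`/`N1` to S1 (similarly S2--S4);
#' `R`/`REM`/`5` to REM; `MT`/`?` to UNSCORED.
#'
#' @param path file to read.
#' @return a `hypnogram`.
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  toks <- character(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "[,[:space:]]+")[[1L]]
    tok <- toupper(fields[length(fields)])
    if (!tok %in% names(stage_token_map))
      stop(sprintf("unknown stage token '%s' at line %d of %s",
                   fields[length(fields)], keep[i], path))
    toks[i] <- stage_token_map[[tok]]
  }
  hypnogram(toks)
}

#' Write a hypnogram (or binary hypnogram) as one token per line
#'
#' @param h a `hypnogram` or `binary_hypnogram`.
#' @param path file to write.
#' @export
write_hypnogram <- function(h, path) {
  labs <- if (inherits(h, "binary_hypnogram")) h$states else h$stages
  writeLines(labs, path)
  invisible(path)
}

# ------------------------------------------------------------------ posture

posture_token_map <- c(
  "SUP" = "SUPINE", "SUPINE" = "SUPINE",
  "L" = "LEFT", "LEFT" = "LEFT",
  "R" = "RIGHT", "RIGHT" = "RIGHT",
  "PRO" = "PRONE", "PRONE" = "PRONE",
  "UNK" = "UNKNOWN", "UNKNOWN" = "UNKNOWN", "?" = "UNKNOWN")

#' Construct a per-epoch body-posture track
#'
#' @param postures character vector, one label per epoch, from
#'   `SUPINE, LEFT, RIGHT, PRONE, UNKNOWN`.
#' @return an object of class `posture_track`.
#' @export
posture_track <- function(postures) {
  postures <- as.character(postures)
  bad <- setdiff(unique(postures), POSTURE_LEVELS)
  if (length(bad))
    stop("invalid posture label(s): ", paste(bad, collapse = ", "))
  structure(list(postures = postures, epoch_length = EPOCH_SECONDS),
            class = "posture_track")
}

#' @export
length.posture_track <- function(x) length(x$postures)

#' Read a per-epoch posture file (tokens SUP, L, R, PRO, UNK)
#'
#' @param path file to read, one token per epoch line.
#' @return a `posture_track`.
#' @export
read_posture <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- which(nzchar(lines))
  toks <- toupper(lines[keep])
  bad <- which(!toks %in% names(posture_token_map))
  if (length(bad))
    stop(sprintf("unknown posture token '%s' at line %d of %s",
                 lines[keep[bad[1L]]], keep[bad[1L]], path))
  posture_track(unname(posture_token_map[toks]))
}

#' Write a posture track using the short tokens
#'
#' @param p a `posture_track`.
#' @param path file to write.
#' @export
write_posture <- function(p, path) {
  short <- c(SUPINE = "SUP", LEFT = "L", RIGHT = "R", PRONE = "PRO",
             UNKNOWN = "UNK")
  writeLines(unname(short[p$postures]), path)
  invisible(path)
}

# --------------------------------------------------------------- signal I/O

#' Read an EMG recording from EDF or CSV
#'
#' The CSV dialect is one column per channel with a header row of channel
#' names, optionally preceded by a comment line `# fs=<Hz>`; the sampling
#' rate can also be supplied via `fs` (an explicit `fs` wins).
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param channels optional character vector restricting which channels to
#'   keep, in the requested order.
#' @param fs sampling rate in Hz, required for CSV files without the
#'   `# fs=` header.
#' @param subject_id optional identifier; defaults to the file name.
#' @return an `emg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           channels = NULL, fs = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  rec <- switch(format,
    edf = read_edf(path, subject_id = subject_id),
    csv = read_recording_csv(path, fs = fs, subject_id = subject_id))
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, names(rec$channels))
    if (length(missing_ch))
      stop("channel(s) not found: ", paste(missing_ch, collapse = ", "))
    rec$channels <- rec$channels[channels]
  }
  rec
}

read_recording_csv <- function(path, fs = NULL, subject_id = "") {
  first <- readLines(path, n = 1L, warn = FALSE)
  header_fs <- NULL
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("fs[[:space:]]*=[[:space:]]*([0-9.]+)", first))[[1L]]
    if (length(m) == 2L) header_fs <- as.numeric(m[2L])
  }
  if (is.null(fs)) fs <- header_fs
  if (is.null(fs))
    stop("sampling rate unknown: supply `fs` or a '# fs=<Hz>' header line")
  df <- tryCatch(read.csv(path, comment.char = "#", check.names = FALSE),
                 error = function(e) stop("CSV contains no channel data: ",
                                          path, call. = FALSE))
  if (ncol(df) == 0L || nrow(df) == 0L)
    stop("CSV contains no channel data: ", path)
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop("non-numeric samples in ", path)
  emg_recording(as.list(df), fs = fs, subject_id = subject_id)
}

#' Write an EMG recording to EDF or CSV
#'
#' CSV output is exact (full-precision text); EDF output quantizes
#' amplitudes onto the format's 16-bit grid.
#'
#' @param rec an `emg_recording`.
#' @param path file to write.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "emg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (format == "edf") return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%d", rec$fs), con)
  # %.17g guarantees the decimal text parses back to the identical double
  df <- as.data.frame(lapply(rec$channels, function(x) sprintf("%.17g", x)),
                      check.names = FALSE)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------- alignment

#' Trim a recording and a hypnogram to a common epoch count
#'
#' A mismatch of at most one epoch (a common off-by-one in exported
#' scorings, or a trailing partial signal epoch) is resolved by truncating
#' both to the shorter length with a warning; a larger mismatch is an error.
#'
#' @param rec an `emg_recording`.
#' @param h a `hypnogram` or `binary_hypnogram`.
#' @return list with elements `recording` and `hypnogram`, both covering
#'   exactly the common number of whole epochs.
#' @export
align_epochs <- function(rec, h) {
  n_r <- n_epochs(rec)
  n_h <- length(h)
  if (abs(n_r - n_h) > 1L)
    stop(sprintf("recording has %d whole epochs but hypnogram has %d (mismatch > 1)",
                 n_r, n_h))
  n <- min(n_r, n_h)
  if (n < 1L) stop("no whole epochs in common")
  spe <- EPOCH_SECONDS * rec$fs
  if (length(rec$channels[[1L]]) != n * spe) {
    if (n_r != n || length(rec$channels[[1L]]) %% spe != 0)
      warning(sprintf("truncating recording to %d whole epochs", n))
    rec$channels <- lapply(rec$channels, function(x) x[seq_len(n * spe)])
  }
  if (n_h != n) {
    warning(sprintf("truncating hypnogram from %d to %d epochs", n_h, n))
    if (inherits(h, "binary_hypnogram")) h$states <- h$states[seq_len(n)]
    else h$stages <- h$stages[seq_len(n)]
  }
  list(recording = rec, hypnogram = h)
}
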