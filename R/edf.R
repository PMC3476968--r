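# Minimal EDF (European Data Format) reader/writer for continuous
# polygraphic recordings: ASCII header blocks plus little-endian 16-bit
# samples, one-second data records. Covers plain EDF only (no EDF+
# annotations, no discontinuous files).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

# render a number in <= `width` ASCII chars such that the text parses back
# to (approximately) the same value; never blindly truncated
edf_num_str <- function(x, width = 8L) {
  for (d in seq(7L, 1L)) {
    s <- formatC(x, digits = d, width = 1, format = "g")
    if (nchar(s) <= width) return(s)
  }
  stop("cannot render ", x, " in ", width, " characters")
}

#' Write a recording as plain EDF
#'
#' Amplitudes are quantized onto the 16-bit digital grid spanning the
#' observed per-channel amplitude range; one data record per second.
#' Trailing samples beyond the last whole second are dropped.
#'
#' @param rec an `emg_recording`.
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  ns <- length(rec$channels)
  fs <- rec$fs
  n_rec <- length(rec$channels[[1L]]) %/% fs
  if (n_rec < 1L) stop("recording shorter than one second")
  con <- file(path, "wb")
  on.exit(close(con))

  phys_str <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]][seq_len(n_rec * fs)]
    lim <- max(abs(x), 1e-12)
    # quantize against the limit as *written* in the header, so the
    # round-trip error is bounded by one digital step
    phys_str[i] <- edf_num_str(lim * (1 + 1e-6), width = 7L)
    lim_w <- as.numeric(phys_str[i])
    dig[[i]] <- as.integer(round(x / lim_w * 32767))
  }

  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(rec$subject_id, 80L),
    edf_pad("emgsleep synthetic/processed recording", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L + ns * 256L, 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad(1L, 8L),
    edf_pad(ns, 4L))
  field <- function(f, width) paste0(vapply(f, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(names(rec$channels), 16L),
    field(rep("", ns), 80L),
    field(rep("uV", ns), 8L),
    field(paste0("-", phys_str), 8L),
    field(phys_str, 8L),
    field(rep("-32767", ns), 8L),
    field(rep("32767", ns), 8L),
    field(rep("", ns), 80L),
    field(rep(fs, ns), 8L),
    field(rep("", ns), 32L))
  writeChar(hdr, con, eos = NULL)

  # interleave: per record, each signal's fs samples in sequence
  mat <- vapply(dig, function(d) d, integer(n_rec * fs))    # samples x ns
  dim(mat) <- c(fs, n_rec, ns)
  out <- aperm(mat, c(1L, 3L, 2L))                          # fs x ns x n_rec
  writeBin(as.integer(out), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a plain EDF file
#'
#' All signals must share one sampling rate (the package's estimators
#' assume a single rate); amplitudes are returned as the stored physical
#' values with no further rescaling.
#'
#' @param path file to read.
#' @param subject_id optional identifier override; defaults to the EDF
#'   patient field.
#' @return an `emg_recording`.
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8L))
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  patient <- trimws(rd(80L))
  rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(trimws(rd(8L)))
  rd(44L)
  n_rec <- as.integer(trimws(rd(8L)))
  rec_dur <- as.numeric(trimws(rd(8L)))
  ns <- as.integer(trimws(rd(4L)))
  if (is.na(ns) || ns < 1L) stop("EDF file declares no signals")
  fields <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- fields(16L)
  fields(80L); fields(8L)
  phys_min <- as.numeric(fields(8L))
  phys_max <- as.numeric(fields(8L))
  dig_min <- as.numeric(fields(8L))
  dig_max <- as.numeric(fields(8L))
  fields(80L)
  spr <- as.integer(fields(8L))     # samples per record
  fields(32L)
  seek(con, header_bytes)

  if (length(unique(spr / rec_dur)) != 1L)
    stop("EDF signals have differing sampling rates; not supported")
  fs <- spr[1L] / rec_dur
  if (fs <= 0 || fs %% 1 != 0)
    stop("EDF sampling rate is not a positive integer: ", fs)

  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2L, endian = "little")
  if (length(raw) < total) stop("EDF file truncated")
  dim(raw) <- c(sum(spr), n_rec)
  offsets <- cumsum(c(0L, spr))
  channels <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- raw[(offsets[i] + 1L):offsets[i + 1L], , drop = FALSE]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    channels[[i]] <- as.numeric(d) * gain + (phys_min[i] - dig_min[i] * gain)
  }
  names(channels) <- make.unique(ifelse(nzchar(labels), labels,
                                        paste0("ch", seq_len(ns))))
  emg_recording(channels, fs = fs,
                subject_id = if (is.null(subject_id)) patient else subject_id)
}
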