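# Minimal EDF (European Data Format) codec: 16-bit integer records, one
# uniform sampling rate, 1-second data records. Sufficient for interchange of
# the synthetic recordings; not a general-purpose EDF+ implementation.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# format a number to fit an 8-character ASCII field without corrupting it
edf_num <- function(v) {
  for (digits in 6:1) {
    s <- sprintf("%.*g", digits, v)
    if (nchar(s) <= 8) return(s)
  }
  "0"
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range, so the
#' round-trip error is at most one quantization step
#' `(max - min) / 65535` per channel. Recordings are stored in 1-second data
#' records; the signal is zero-padded to a whole number of seconds if needed
#' (the synthetic generator always produces whole seconds).
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != round(rec$rate)) abort("EDF writer requires an integer sampling rate")
  x <- rec$data
  nch <- ncol(x)
  n_rec <- ceiling(nrow(x) / rec$rate)
  n_full <- n_rec * rec$rate
  if (n_full > nrow(x)) {
    x <- rbind(x, matrix(0, n_full - nrow(x), nch))
  }
  # Bounds are stored at header resolution (8 ASCII chars), so quantize
  # against the stored values; pad the range so header rounding cannot move a
  # bound inside the data.
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  margin <- 1e-4 * pmax(hi - lo, 1) + 1e-5 * pmax(abs(lo), abs(hi))
  phys_min <- vapply(lo - margin, function(v) as.numeric(edf_num(v)), 0)
  phys_max <- vapply(hi + margin, function(v) as.numeric(edf_num(v)), 0)
  flat <- phys_max <= phys_min
  phys_max[flat] <- phys_min[flat] + 1
  header <- paste0(
    edf_pad("0", 8), # version
    edf_pad("synthetic", 80), # patient id (synthetic data)
    edf_pad("mrcpspeller", 80), # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nch), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8), # record duration, seconds
    edf_pad(nch, 4)
  )
  sig_header <- paste0(
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    strrep(edf_pad("", 80), nch), # transducer
    paste(rep(edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(vapply(phys_min, edf_num, ""), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(vapply(phys_max, edf_num, ""), edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad("-32768", 8), nch), collapse = ""),
    paste(rep(edf_pad("32767", 8), nch), collapse = ""),
    strrep(edf_pad("", 80), nch), # prefiltering
    paste(rep(edf_pad(rec$rate, 8), nch), collapse = ""),
    strrep(edf_pad("", 32), nch)
  )
  dig <- round(sweep(sweep(x, 2, phys_min), 2, (phys_max - phys_min) / 65535, "/")) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  # record-major interleave: record 1 (ch1 samples, ch2 samples, ...), record 2, ...
  arr <- array(dig, dim = c(rec$rate, n_rec, nch))
  vec <- as.integer(aperm(arr, c(1, 3, 2)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, sig_header)), con)
  writeBin(vec, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Only uniform-rate EDF files (as written by [write_edf()]) are supported;
#' mixed per-signal sampling rates are rejected.
#'
#' @param path EDF file path.
#' @return An [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  if (nchar(hdr) < 256 || trimws(substr(hdr, 1, 8)) != "0") {
    abort(sprintf("malformed EDF header in %s", path))
  }
  n_rec <- as.integer(trimws(substr(hdr, 237, 244)))
  rec_dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  nch <- as.integer(trimws(substr(hdr, 253, 256)))
  if (is.na(nch) || nch < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    abort(sprintf("malformed EDF header in %s", path))
  }
  sig <- rawToChar(readBin(con, "raw", 256 * nch))
  field <- function(offset, width) {
    vapply(seq_len(nch), function(i) {
      trimws(substr(sig, offset + (i - 1) * width + 1, offset + i * width))
    }, "")
  }
  labels <- field(0, 16)
  pmin <- as.numeric(field(nch * (16 + 80 + 8), 8))
  pmax <- as.numeric(field(nch * (16 + 80 + 8 + 8), 8))
  dmin <- as.numeric(field(nch * (16 + 80 + 8 + 8 + 8), 8))
  dmax <- as.numeric(field(nch * (16 + 80 + 8 + 8 + 8 + 8), 8))
  nr <- as.integer(field(nch * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  if (length(unique(nr)) != 1) abort("mixed per-signal sampling rates are not supported")
  rate <- nr[1] / rec_dur
  raw_int <- readBin(con, "integer", n = n_rec * nch * nr[1], size = 2,
                     endian = "little", signed = TRUE)
  arr <- array(as.numeric(raw_int), dim = c(nr[1], nch, n_rec))
  dig <- array(aperm(arr, c(1, 3, 2)), dim = c(nr[1] * n_rec, nch))
  phys <- sweep(sweep(dig, 2, dmin), 2, (pmax - pmin) / (dmax - dmin), "*")
  phys <- sweep(phys, 2, pmin, "+")
  recording(phys, rate = rate, labels = labels)
}
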