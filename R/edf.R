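# Minimal European Data Format (EDF) reader/writer.
#
# Supports continuous multichannel recordings with a common sampling rate:
# the subset this package produces and consumes. Samples are stored as
# little-endian 16-bit integers with per-signal linear physical scaling, so
# a write/read round trip is exact up to the 16-bit quantization step.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  data <- rec$data
  nch <- nrow(data)
  nsamp <- ncol(data)
  fs <- rec$fs
  # one record per second when the sample count allows it, else one record
  spr <- if (fs == round(fs) && nsamp %% fs == 0) as.integer(fs) else nsamp
  nrec <- nsamp %/% spr
  rec_dur <- spr / fs
  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("mstatebci", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nch), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_num(rec_dur, 8), edf_pad(nch, 4),
    paste(edf_pad(rec$channel_names, 16), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), nch), collapse = ""),
    paste(rep(edf_pad(dmax, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 80), nch), collapse = ""),
    paste(rep(edf_pad(spr, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 32), nch), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nch)) {
      dig <- round((data[i, cols] - pmin[i]) / scale[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (ver != "0") stop("not an EDF file (version field '", ver, "')",
                       call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes (recomputed)
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)           # transducer
  for (i in seq_len(nch)) rd(8)            # physical dimension
  pmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)           # prefilter
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only",
         call. = FALSE)
  fs <- spr[1] / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      out[i, cols] <- (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }
  new_recording(out, labels, fs)
}
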