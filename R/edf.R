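# Minimal EDF (European Data Format) reader and writer for continuous
# 16-bit recordings.  Covers the plain EDF layout (no EDF+ annotations):
# 256-byte fixed header, 256 bytes of per-signal header fields, then data
# records of little-endian int16 samples with linear physical scaling.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a continuous EDF file
#'
#' @param signals numeric vector or matrix (columns are channels), physical
#'   units.  The length must be a multiple of `fs` (1-second data records).
#' @param fs sampling rate in Hz shared by all channels.
#' @param path output path.
#' @param channel_label character vector of channel labels.
#' @param individual_id stored in the patient field.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, channel_label = NULL,
                      individual_id = "X") {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1L)
  ns <- ncol(signals)
  spr <- as.integer(round(fs))  # samples per 1 s record
  if (nrow(signals) %% spr != 0)
    stop_config("EDF writer requires a whole number of 1 s records (length %d, fs %d)",
                nrow(signals), spr)
  n_rec <- nrow(signals) %/% spr
  channel_label <- channel_label %||% sprintf("ch%d", seq_len(ns))
  pmin_ <- apply(signals, 2, min); pmax_ <- apply(signals, 2, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(pad_ascii(x, width), collapse = ""),
                                     con, nchars = width * length(x), eos = NULL)
  wr("0", 8)
  wr(individual_id, 80)
  wr("bowaves synthetic recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(sprintf("%d", 256L * (1L + ns)), 8)
  wr("", 44)
  wr(sprintf("%d", n_rec), 8)
  wr("1", 8)
  wr(sprintf("%d", ns), 4)
  wr(channel_label, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  wr(sprintf("%.8g", pmin_), 8)
  wr(sprintf("%.8g", pmax_), 8)
  wr(sprintf("%d", rep(dmin, ns)), 8)
  wr(sprintf("%d", rep(dmax, ns)), 8)
  wr(rep("HP:1Hz", ns), 80)
  wr(sprintf("%d", rep(spr, ns)), 8)
  wr(rep("", ns), 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns)) {
      dig <- as.integer(round((signals[rows, j] - pmin_[j]) * scale[j]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` (matrix, physical units, one column per
#'   channel), `fs` (per-channel sampling rates), `labels`, `patient`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1L) {
    raw <- readChar(con, nchars = width * n, useBytes = TRUE)
    trimws(substring(raw, (seq_len(n) - 1L) * width + 1L, seq_len(n) * width))
  }
  rd(8)                       # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop_config("%s: not a readable EDF header", path)
  labels <- rd(16, ns); rd(80, ns); rd(8, ns)
  pmin_ <- as.numeric(rd(8, ns)); pmax_ <- as.numeric(rd(8, ns))
  dmin <- as.numeric(rd(8, ns)); dmax <- as.numeric(rd(8, ns))
  rd(80, ns)
  spr <- as.integer(rd(8, ns)); rd(32, ns)
  sig <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[j], size = 2L, signed = TRUE,
                     endian = "little")
      sig[[j]][((r - 1L) * spr[j] + 1L):(r * spr[j])] <-
        (dig - dmin[j]) * (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j]) + pmin_[j]
    }
  }
  if (length(unique(spr)) == 1L) sig <- do.call(cbind, sig)
  else stop_config("%s: channels with differing sampling rates are not supported", path)
  list(signals = sig, fs = spr / rec_dur, labels = labels, patient = patient)
}
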