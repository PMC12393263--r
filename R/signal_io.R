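#' Single-channel recording container
#'
#' @param samples numeric vector of signal values (physical units).
#' @param fs sampling rate in Hz.
#' @param individual_id identifier of the individual.
#' @param label class label (a string; for genotype tasks use
#'   [genotype_label()] to build `"strain:tsc"` labels).
#' @param valid_mask logical vector aligned to `samples`; `FALSE` marks
#'   samples excluded from all downstream sampling.
#' @return A `bow_recording` list.
#' @export
recording <- function(samples, fs, individual_id = "ind1", label = NA_character_,
                      valid_mask = NULL) {
  if (fs <= 0) stop_config("fs must be positive")
  if (!all(is.finite(samples))) stop_config("samples must be finite")
  valid_mask <- valid_mask %||% rep(TRUE, length(samples))
  if (length(valid_mask) != length(samples))
    stop_config("valid_mask length must equal sample length")
  structure(list(samples = as.numeric(samples), fs = fs,
                 individual_id = individual_id, label = label,
                 valid_mask = valid_mask),
            class = "bow_recording")
}

#' @export
print.bow_recording <- function(x, ...) {
  cat(sprintf("<bow_recording> '%s' label=%s: %d samples @ %g Hz (%.1f min), %.1f%% valid\n",
              x$individual_id, x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs / 60, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Compose / split joint genotype labels
#'
#' The joint label of an individual is the pair (strain, tsc) rendered as
#' `"strain:tsc"`.
#' @param strain,tsc character vectors.
#' @param label joint labels to split.
#' @return `genotype_label()`: character vector of joint labels;
#'   `strain_of()` / `tsc_of()`: the respective component.
#' @export
genotype_label <- function(strain, tsc) paste(strain, tsc, sep = ":")

#' @rdname genotype_label
#' @export
strain_of <- function(label) sub(":.*$", "", label)

#' @rdname genotype_label
#' @export
tsc_of <- function(label) sub("^.*:", "", label)

# ---- array container (plain text) -----------------------------------------

#' Read/write the plain-text array container
#'
#' A simple one-channel signal file: `#`-prefixed `key=value` header lines
#' (`fs`, `individual_id`, `label`) followed by one sample per line at full
#' double precision, so recordings round-trip bit-exactly.
#'
#' @param rec a `bow_recording`.
#' @param path file path.
#' @return `read_array_container()`: a `bow_recording`.
#' @export
write_array_container <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.17g", rec$fs),
               sprintf("# individual_id=%s", rec$individual_id),
               sprintf("# label=%s", rec$label)), con)
  writeLines(sprintf("%.17g", rec$samples), con)
  invisible(path)
}

#' @rdname write_array_container
#' @export
read_array_container <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA_character_) {
    m <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (!length(m)) default else sub(sprintf("^#\\s*%s=", key), "", m[1])
  }
  fs <- as.numeric(get("fs"))
  if (!is.finite(fs)) stop_config("array container %s lacks an fs header", path)
  x <- scan(path, what = double(), comment.char = "#", quiet = TRUE)
  recording(x, fs, individual_id = get("individual_id", "unknown"),
            label = get("label"))
}

#' Load a recording from EDF or the array container
#'
#' @param path `.edf` file or plain-text array container.
#' @param channel 1-based channel index (EDF only).
#' @param label optional class label to attach (overrides any stored label).
#' @param individual_id optional identifier (defaults to the stored one or
#'   the file name).
#' @return A `bow_recording` with an all-true valid mask.
#' @export
load_recording <- function(path, channel = 1L, label = NULL,
                           individual_id = NULL) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    if (channel < 1L || channel > ncol(edf$signals))
      stop_config("channel %d not present in %s (%d channels)",
                  channel, path, ncol(edf$signals))
    rec <- recording(edf$signals[, channel], edf$fs[channel],
                     individual_id = individual_id %||%
                       sub("\\.edf$", "", basename(path), ignore.case = TRUE),
                     label = label %||% NA_character_)
  } else {
    rec <- read_array_container(path)
    if (!is.null(label)) rec$label <- label
    if (!is.null(individual_id)) rec$individual_id <- individual_id
  }
  rec
}

# ---- exclusion intervals ---------------------------------------------------

#' Build a merged exclusion interval set around seizure events
#'
#' Each event interval is expanded by `pre_pad` seconds before its start and
#' `post_pad` seconds after its end, clipped to `[0, duration]`, and
#' overlapping or touching expansions are merged.  The padding convention
#' (5 min before, 60 min after) reflects peri-ictal contamination of the EEG.
#'
#' @param events data frame with columns `start_s`, `end_s` (seconds,
#'   half-open `[start, end)`), or a 2-column matrix.
#' @param pre_pad,post_pad padding in seconds (>= 0).
#' @param duration recording duration in seconds.
#' @return Data frame of merged intervals (`start_s`, `end_s`), sorted,
#'   non-overlapping.
#' @export
build_exclusion_mask <- function(events, pre_pad = 300, post_pad = 3600,
                                 duration) {
  if (pre_pad < 0 || post_pad < 0) stop_config("pads must be >= 0")
  if (is.matrix(events))
    events <- data.frame(start_s = events[, 1], end_s = events[, 2])
  if (nrow(events) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (any(events$end_s <= events$start_s))
    stop_config("event intervals must have end > start")
  if (any(events$start_s < 0 | events$end_s > duration))
    stop_config("events must lie within [0, duration]")
  s <- pmax(0, events$start_s - pre_pad)
  e <- pmin(duration, events$end_s + post_pad)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; out_s <- c(); out_e <- c()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}

#' Apply exclusion intervals to a recording's valid mask
#'
#' Sample `i` (0-based) at time `i/fs` is invalidated when it falls inside
#' any half-open interval `[start_s, end_s)`.
#'
#' @param rec a `bow_recording`.
#' @param intervals data frame from [build_exclusion_mask()].
#' @return The recording with an updated `valid_mask`.
#' @export
apply_exclusions <- function(rec, intervals) {
  if (nrow(intervals) == 0) return(rec)
  t <- (seq_along(rec$samples) - 1) / rec$fs
  for (i in seq_len(nrow(intervals)))
    rec$valid_mask[t >= intervals$start_s[i] & t < intervals$end_s[i]] <- FALSE
  rec
}

# ---- segments and windows --------------------------------------------------

#' Draw segments uniformly from one half of a recording
#'
#' The recording is halved at the midpoint sample of the full recording
#' (before exclusions); segments of `Q` samples are drawn uniformly with
#' replacement (possibly overlapping) over all start offsets for which every
#' sample lies in the chosen half and is valid.  Dictionary-training windows
#' come from first halves and encoding segments from second halves so that
#' dictionary-fold individuals contribute unseen data at encoding time.
#'
#' @param rec a `bow_recording`.
#' @param portion `"first-half"` or `"second-half"`.
#' @param n_segments number of segments to draw.
#' @param Q segment length in samples.
#' @param seed integer seed.
#' @return List of `bow_segment` objects (fields `samples`, `individual_id`,
#'   `start_s`, `fs`).
#' @export
sample_segments <- function(rec, portion = c("second-half", "first-half"),
                            n_segments, Q, seed = 1L) {
  portion <- match.arg(portion)
  n <- length(rec$samples)
  mid <- floor(n / 2)
  rng <- if (portion == "first-half") c(1L, mid) else c(mid + 1L, n)
  span <- rng[2] - rng[1] + 1L
  if (span < Q)
    stop_config("individual '%s': chosen half (%d samples) shorter than Q=%d",
                rec$individual_id, span, Q)
  v <- rec$valid_mask[rng[1]:rng[2]]
  cs <- c(0, cumsum(v))
  starts_rel <- seq_len(span - Q + 1L)
  admissible <- starts_rel[cs[starts_rel + Q] - cs[starts_rel] == Q]
  if (!length(admissible))
    stop_config("individual '%s': no admissible %d-sample segment in the %s",
                rec$individual_id, Q, portion)
  picks <- with_seed(seed,
    admissible[sample.int(length(admissible), n_segments, replace = TRUE)])
  lapply(picks, function(p) {
    g0 <- rng[1] + p - 1L  # 1-based global start
    structure(list(samples = rec$samples[g0:(g0 + Q - 1L)],
                   individual_id = rec$individual_id,
                   start_s = (g0 - 1L) / rec$fs, fs = rec$fs),
              class = "bow_segment")
  })
}

#' Cut a segment into non-overlapping windows
#'
#' Returns exactly `floor(Q/L)` consecutive `L`-sample windows; the trailing
#' remainder is dropped.
#'
#' @param segment a `bow_segment` or numeric vector.
#' @param L window length in samples.
#' @return Numeric matrix, one window per row.
#' @export
extract_windows <- function(segment, L) {
  if (L <= 0) stop_config("L must be positive")
  x <- if (inherits(segment, "bow_segment")) segment$samples else segment
  M <- length(x) %/% L
  if (M < 1L) stop_config("segment shorter than one window (Q=%d < L=%d)",
                          length(x), L)
  matrix(x[seq_len(M * L)], nrow = M, ncol = L, byrow = TRUE)
}
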