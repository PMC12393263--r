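#' Class specification for synthetic EEG cohorts
#'
#' Defines, for one class (e.g. a genotype group), the per-waveform event
#' rates, the distribution of event amplitudes, and the noise background on
#' which events are planted.
#'
#' @param class_label class name.
#' @param event_rates named numeric vector: events per minute, names are
#'   waveform identifiers from the library.
#' @param amplitude_mean,amplitude_sd mean and sd of the positive
#'   (zero-truncated normal) event scale factors, in signal units.
#' @param noise_sd standard deviation of the noise background.
#' @param noise_color `"pink"` (1/f, the default: EEG background is
#'   approximately 1/f) or `"white"`.
#' @return A `bow_class_spec` list.
#' @export
class_spec <- function(class_label, event_rates, amplitude_mean = 3,
                       amplitude_sd = 0.5, noise_sd = 1,
                       noise_color = c("pink", "white")) {
  noise_color <- match.arg(noise_color)
  if (any(event_rates < 0)) stop_config("event rates must be >= 0")
  if (amplitude_mean <= 0) stop_config("amplitude_mean must be > 0")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (length(event_rates) && is.null(names(event_rates)))
    stop_config("event_rates must be named by waveform identifier")
  structure(list(class_label = class_label, event_rates = event_rates,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 noise_sd = noise_sd, noise_color = noise_color),
            class = "bow_class_spec")
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x
}

# Zero-truncated normal via inverse transform: one uniform draw per value.
rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean, sd)
}

# 4th-order Butterworth high-pass at `cutoff` Hz, applied forward-backward.
highpass_filter <- function(x, fs, cutoff = 1) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  signal::filtfilt(bf, x)
}

#' Simulate one synthetic EEG recording
#'
#' Events of each library waveform arrive by a homogeneous Poisson process
#' at the class-specified rate, are scaled by positive truncated-normal
#' amplitude draws, added to the noise background, and the sum is 1 Hz
#' high-pass filtered (4th-order Butterworth, forward-backward) to emulate
#' the acquisition chain of long-term rodent EEG.
#'
#' @param spec a [class_spec()].
#' @param library waveform library from [make_waveform_library()].
#' @param duration recording duration in seconds (>= 10).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param individual_id identifier stored in the recording.
#' @return A list with `recording` (a [recording()] carrying `spec$class_label`
#'   as its label) and `events`, a data frame of (time_s, waveform_id,
#'   amplitude) for every planted event.
#' @export
simulate_recording <- function(spec, library, duration, fs = 256,
                               seed = 1L, individual_id = "ind1") {
  stopifnot(inherits(spec, "bow_class_spec"))
  if (duration < 10) stop_config("duration must be >= 10 s")
  missing_ids <- setdiff(names(spec$event_rates), names(library))
  if (length(missing_ids))
    stop_config("event_rates name waveforms absent from the library: %s",
                paste(missing_ids, collapse = ", "))
  n <- round(duration * fs)
  P_true <- if (length(library)) length(library[[1]]$shape) else 0L
  expected_cover <- sum(spec$event_rates) * duration / 60 * P_true
  if (expected_cover > 0.5 * n)
    stop_config("expected planted events would cover more than half of the samples; lower the rates")
  out <- with_seed(seed, {
    x <- if (spec$noise_color == "pink") pink_noise(n) else stats::rnorm(n)
    if (spec$noise_sd > 0) {
      x <- x * (spec$noise_sd / stats::sd(x))
    } else x <- numeric(n)
    ev <- list()
    for (id in names(spec$event_rates)) {
      rate <- spec$event_rates[[id]]
      if (rate <= 0) next
      shape <- library[[id]]$shape
      P <- length(shape)
      n_ev <- stats::rpois(1, rate * duration / 60)
      if (n_ev == 0) next
      t_ev <- sort(stats::runif(n_ev, 0, duration - P / fs))
      amp <- rtruncnorm_pos(n_ev, spec$amplitude_mean, spec$amplitude_sd)
      for (i in seq_len(n_ev)) {
        i0 <- floor(t_ev[i] * fs)
        x[i0 + seq_len(P)] <- x[i0 + seq_len(P)] + amp[i] * shape
      }
      ev[[id]] <- data.frame(time_s = t_ev, waveform_id = id, amplitude = amp)
    }
    list(x = x, ev = ev)
  })
  events <- if (length(out$ev)) do.call(rbind, out$ev) else
    data.frame(time_s = numeric(0), waveform_id = character(0),
               amplitude = numeric(0))
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  x <- highpass_filter(out$x, fs, 1)
  rec <- recording(x, fs, individual_id = individual_id,
                   label = spec$class_label)
  list(recording = rec, events = events)
}

#' Simulate a labelled cohort of recordings
#'
#' Generates `n_per_class` independent recordings for every class spec, with
#' per-individual seeds derived deterministically from the cohort seed.
#'
#' @param specs list of [class_spec()] objects (>= 2 classes).
#' @param library waveform library shared by all classes.
#' @param n_per_class recordings per class (>= 2).
#' @param duration seconds per recording.
#' @param fs sampling rate in Hz.
#' @param seed cohort master seed.
#' @return A `bow_cohort`: list with `recordings` (named by individual id),
#'   `event_logs` (one data frame per individual), `specs`, `seed`.
#' @export
make_cohort <- function(specs, library, n_per_class, duration, fs = 256,
                        seed = 1L) {
  if (length(specs) < 2L) stop_config("need at least 2 classes")
  if (n_per_class < 2L) stop_config("need at least 2 individuals per class")
  recs <- list(); logs <- list()
  idx <- 0L
  for (spec in specs) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", spec$class_label, i)
      sim <- simulate_recording(spec, library, duration, fs,
                                seed = derive_seed(seed, idx),
                                individual_id = id)
      recs[[id]] <- sim$recording
      logs[[id]] <- sim$events
    }
  }
  structure(list(recordings = recs, event_logs = logs, specs = specs,
                 seed = seed),
            class = "bow_cohort")
}

#' @export
print.bow_cohort <- function(x, ...) {
  labs <- vapply(x$recordings, function(r) r$label, "")
  cat(sprintf("<bow_cohort> %d recordings, %d classes (%s)\n",
              length(x$recordings), length(unique(labs)),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One signal file per individual (plain-text array container or EDF), a
#' label table `labels.csv`, an event log `events.csv`, and a `config.yaml`
#' snapshot of the class specs.
#'
#' @param cohort a `bow_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"array"` (plain-text container) or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("array", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "array") "txt" else "edf"
  for (id in names(cohort$recordings)) {
    rec <- cohort$recordings[[id]]
    path <- file.path(dir, paste0(id, ".", ext))
    if (format == "array") write_array_container(rec, path)
    else write_edf(rec$samples, rec$fs, path, channel_label = "EEG1",
                   individual_id = id)
  }
  labs <- data.frame(individual_id = names(cohort$recordings),
                     label = vapply(cohort$recordings, function(r) r$label, ""),
                     file = paste0(names(cohort$recordings), ".", ext))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  ev <- do.call(rbind, lapply(names(cohort$event_logs), function(id) {
    log <- cohort$event_logs[[id]]
    if (nrow(log) == 0) return(NULL)
    cbind(individual_id = id, log)
  }))
  if (is.null(ev))
    ev <- data.frame(individual_id = character(0), time_s = numeric(0),
                     waveform_id = character(0), amplitude = numeric(0))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  cfg <- lapply(cohort$specs, function(s)
    list(class_label = s$class_label,
         event_rates = as.list(s$event_rates),
         amplitude_mean = s$amplitude_mean, amplitude_sd = s$amplitude_sd,
         noise_sd = s$noise_sd, noise_color = s$noise_color))
  yaml::write_yaml(list(classes = cfg, seed = cohort$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
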