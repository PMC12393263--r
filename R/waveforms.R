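#' Ground-truth waveform kinds
#'
#' Describes one prototype waveform to be planted in synthetic EEG: a
#' rhythmic burst (several cycles under a Hann envelope), a transient
#' (Ricker/mexican-hat sharp wave), or a slow wave (a single tapered cycle).
#'
#' @param kind one of `"rhythmic"`, `"transient"`, `"slow-wave"`.
#' @param freq peak frequency in Hz; must lie in (0, fs/2) of the library
#'   that realizes it.
#' @param id identifier string; defaults to `"<kind>_<freq>Hz"`.
#' @return A `bow_kind` list with fields `kind`, `freq`, `id`.
#' @export
waveform_kind <- function(kind = c("rhythmic", "transient", "slow-wave"),
                          freq, id = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(freq) || length(freq) != 1L || freq <= 0)
    stop_config("freq must be a single positive number (Hz)")
  structure(list(kind = kind, freq = freq,
                 id = id %||% sprintf("%s_%gHz", kind, freq)),
            class = "bow_kind")
}

# Periodic Hann window (the convention used for the Welch taper as well).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

make_shape <- function(kind, freq, P, fs, phase) {
  t <- (seq_len(P) - 1) / fs
  tc <- t - (P - 1) / (2 * fs)
  shape <- switch(kind,
    "rhythmic" = hann_window(P) * sin(2 * pi * freq * t + phase),
    # biphasic sharp wave (first derivative of a Gaussian): antisymmetric,
    # so temporal alignment is unambiguous; spectral peak at 1/(2*pi*sigma)
    "transient" = {
      sig <- 1 / (2 * pi * freq)
      -tc * exp(-tc^2 / (2 * sig^2))
    },
    "slow-wave" = {
      # one asymmetric cycle (sharp first phase, slow recovery), as in
      # spike-and-wave complexes; the time warp breaks the half-period
      # symmetry of a pure sinusoid
      cyc <- round(fs / freq)
      cyc <- min(cyc, P)
      w <- numeric(P)
      i0 <- floor((P - cyc) / 2)
      u <- (seq_len(cyc) - 1) / cyc
      w[i0 + seq_len(cyc)] <- hann_window(cyc) * sin(2 * pi * u^0.6)
      w
    })
  shape / sqrt(sum(shape^2))
}

#' Construct a library of ground-truth waveforms
#'
#' Builds unit-norm prototype waveforms of common length `P_true` and checks
#' that they are mutually distinguishable: every pair must have
#' max-over-shifts cosine similarity below 0.8.
#'
#' @param P_true waveform length in samples (>= 8).
#' @param fs sampling rate in Hz.
#' @param kinds a list of [waveform_kind()] specs.
#' @param seed integer seed controlling the random phase of rhythmic bursts.
#' @return A named list of `bow_waveform` objects, each with fields `shape`
#'   (unit ell-2 norm), `kind`, `peak_frequency`, `id`.
#' @export
make_waveform_library <- function(P_true, fs, kinds, seed = 1L) {
  if (length(kinds) == 0L) stop_config("kinds must be non-empty")
  if (P_true < 8L) stop_config("P_true must be >= 8 samples")
  if (fs <= 0) stop_config("fs must be positive")
  if (inherits(kinds, "bow_kind")) kinds <- list(kinds)
  lib <- with_seed(seed, {
    lapply(kinds, function(k) {
      if (k$freq >= fs / 2)
        stop_config("peak frequency %g Hz not below Nyquist (%g Hz)",
                    k$freq, fs / 2)
      phase <- stats::runif(1, 0, 2 * pi)
      structure(list(shape = make_shape(k$kind, k$freq, P_true, fs, phase),
                     kind = k$kind, peak_frequency = k$freq, id = k$id),
                class = "bow_waveform")
    })
  })
  names(lib) <- vapply(lib, `[[`, "", "id")
  if (anyDuplicated(names(lib)))
    stop_config("duplicate waveform identifiers in kinds")
  if (length(lib) > 1L) {
    for (i in seq_along(lib)[-1L]) for (j in seq_len(i - 1L)) {
      s <- max_shift_cosine(lib[[i]]$shape, lib[[j]]$shape)
      if (s >= 0.8)
        stop_config("waveforms '%s' and '%s' are not distinguishable (max shifted cosine %.3f >= 0.8); detune their frequencies",
                    lib[[i]]$id, lib[[j]]$id, s)
    }
  }
  lib
}

#' Maximum cosine similarity over all relative shifts
#'
#' Cross-correlates two vectors at every lag and returns the maximum of the
#' correlation normalized by the full ell-2 norms of both inputs.  Equals 1
#' exactly when one vector is a nonneg-scaled, zero-padded shift of the
#' other.  Used both for library distinguishability and for scoring how well
#' a learned dictionary waveform recovers a planted one.
#'
#' @param a,b numeric vectors (lengths may differ).
#' @return Scalar in \[-1, 1\].
#' @export
max_shift_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  la <- length(a); lb <- length(b)
  best <- -Inf
  for (lag in -(lb - 1L):(la - 1L)) {
    ia <- max(1L, 1L + lag):min(la, lb + lag)
    ib <- ia - lag
    best <- max(best, sum(a[ia] * b[ib]))
  }
  best / (na * nb)
}
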