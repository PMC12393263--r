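# Interpretation of the fitted linear classifiers: closed-form Shapley
# values under the feature-independence assumption, average class-signed
# Shapley values (ACSSV) across the leave-one-out models, Welch power
# spectra of dictionary waveforms, and waveform occurrence rates.

# Coefficients on the additive scale used for attribution: for binary
# models the log-odds parametrization (difference of the two class rows,
# so that phi0 + sum(phi) equals log p/(1-p) exactly); for more than two
# classes the class linear score beta0(y) + <beta(y), x>.
effective_coefficients <- function(model) {
  G <- length(model$classes)
  if (G == 2L) {
    B <- model$beta - model$beta[c(2L, 1L), , drop = FALSE]
    b0 <- model$beta0 - model$beta0[c(2L, 1L)]
  } else {
    B <- model$beta; b0 <- model$beta0
  }
  list(B = B, b0 = b0)
}

#' Closed-form Shapley values for a linear classifier
#'
#' Under independent features the Shapley value of feature k for class y is
#' `phi_k(y) = beta_k(y) * (x_k - E[X_k])` with the expectation taken over
#' the training set, and the base value is
#' `phi_0(y) = beta_0(y) + sum_k beta_k(y) * E[X_k]`.  Additivity holds
#' exactly: `phi_0(y) + sum_k phi_k(y)` equals the class log-odds for
#' binary models and the class linear score for multinomial models.
#'
#' @param model a `bow_classifier` (carries training feature means).
#' @param x a feature vector.
#' @param means optional replacement for the stored training means (used
#'   for pooled-feature attribution, where the reference set is the other
#'   individuals' pooled features).
#' @return List with `phi` (classes x D matrix) and `phi0` (per class).
#' @export
shapley_values <- function(model, x, means = NULL) {
  means <- means %||% model$feature_means
  if (is.null(means)) stop_config("model carries no training feature means")
  if (length(x) != ncol(model$beta))
    stop_config("feature dimension mismatch")
  eff <- effective_coefficients(model)
  phi <- sweep(eff$B, 2L, x - means, `*`)
  rownames(phi) <- model$classes
  phi0 <- eff$b0 + as.vector(eff$B %*% means)
  list(phi = phi, phi0 = stats::setNames(phi0, model$classes))
}

#' Average class-signed Shapley value
#'
#' The mean over individuals of `(I(y_s = y) - I(y_s != y)) * phi_k(y, s)`;
#' equivalently the covariance between the Shapley value and the signed
#' class indicator when the Shapley values are mean-zero over the
#' reference set.
#'
#' @param phi matrix of Shapley values (individuals x features) for class
#'   `y`, one row per held-out individual.
#' @param labels class label per individual (row order of `phi`).
#' @param y the class being scored.
#' @return Numeric vector of per-feature ACSSV.
#' @export
acssv <- function(phi, labels, y) {
  if (nrow(phi) == 0L) stop_config("empty fold: ACSSV undefined")
  sign_ind <- ifelse(labels == y, 1, -1)
  colMeans(phi * sign_ind)
}

#' Per-individual Shapley values across the leave-one-out models
#'
#' For each held-out individual s, the attribution uses s's OWN model of
#' record (trained with s held out) and its TFIDF weights; the reference
#' mean for feature k is the average pooled feature value of all OTHER
#' individuals under those same weights.
#'
#' @param loo a `bow_loo` from [loo_evaluate()] with `store_models = TRUE`.
#' @param bags_by_ind named list of per-individual segment bag lists
#'   (covering both folds).
#' @param y class whose attribution is computed.
#' @return Matrix (held-out individuals x features) of Shapley values.
#' @export
loo_shapley <- function(loo, bags_by_ind, y) {
  if (is.null(loo$models))
    stop_config("loo_evaluate() must be run with store_models = TRUE")
  all_ids <- c(loo$dict_ids, loo$eval_ids)
  phi <- t(vapply(loo$eval_ids, function(s) {
    model <- loo$models[[s]]
    tfidf <- loo$tfidfs[[s]]
    Xp <- do.call(rbind, lapply(all_ids, function(s2)
      tfidf_transform(pool_bags(bags_by_ind[[s2]]), tfidf)))
    rownames(Xp) <- all_ids
    ref <- colMeans(Xp[setdiff(all_ids, s), , drop = FALSE])
    sv <- shapley_values(model, Xp[s, ], means = ref)
    sv$phi[y, ]
  }, numeric(length(bags_by_ind[[loo$eval_ids[1]]][[1]]$counts))))
  rownames(phi) <- loo$eval_ids
  phi
}

#' Per-feature interpretation table for one fold and class
#'
#' Combines, for every bag-of-waves feature: the ACSSV over the fold's
#' held-out individuals, the average coefficient across their LOO models,
#' in-class / out-of-class occurrence rates (counts per minute) and their
#' difference, and the waveform's Welch peak frequency.
#'
#' @param loo a `bow_loo` with stored models.
#' @param bags_by_ind per-individual segment bag lists.
#' @param labels named labels per individual.
#' @param y class of interest.
#' @param dictionaries the dictionary list used for encoding (for peak
#'   frequencies); optional.
#' @return A `bow_shapley_report` with a `per_feature` data frame and the
#'   raw `phi` matrix.
#' @export
shapley_report <- function(loo, bags_by_ind, labels, y, dictionaries = NULL) {
  phi <- loo_shapley(loo, bags_by_ind, y)
  sig <- acssv(phi, unlist(labels[loo$eval_ids]), y)
  coefs <- t(vapply(loo$eval_ids, function(s)
    effective_coefficients(loo$models[[s]])$B[y, ], numeric(ncol(phi))))
  avg_coef <- colMeans(coefs)
  rates <- occurrence_rates(bags_by_ind, labels, y)
  di <- bags_by_ind[[1]][[1]]$dict_index
  peak <- rep(NA_real_, ncol(phi))
  if (!is.null(dictionaries)) {
    for (j in seq_along(dictionaries)) {
      rows <- which(di$dict == j)
      peak[rows] <- vapply(di$waveform[rows], function(k)
        welch_psd(dictionaries[[j]]$C[k, ], dictionaries[[j]]$fs)$peak_frequency,
        0)
    }
  }
  structure(list(
    per_feature = data.frame(
      feature = seq_len(ncol(phi)),
      dict_class = di$class_label, waveform = di$waveform,
      acssv = sig, avg_coef = avg_coef,
      in_rate = rates$in_rate, out_rate = rates$out_rate,
      rate_diff = rates$in_rate - rates$out_rate,
      overall_rate = rates$overall_rate,
      peak_frequency = peak),
    phi = phi, class = y),
    class = "bow_shapley_report")
}

#' Rank the waveforms most indicative of a class
#'
#' Filters features to positive average coefficient, ranks by descending
#' ACSSV and returns the top `n` with their rate and spectral annotations.
#' If fewer than `n` features survive the filter, all survivors are
#' returned with a warning.
#'
#' @param report a `bow_shapley_report` (or its `per_feature` data frame).
#' @param n number of waveforms to return.
#' @return Data frame of the selected features.
#' @export
top_waveforms <- function(report, n = 5L) {
  tab <- if (inherits(report, "bow_shapley_report")) report$per_feature
         else report
  keep <- tab[tab$avg_coef > 0, , drop = FALSE]
  keep <- keep[order(-keep$acssv), , drop = FALSE]
  if (nrow(keep) < n)
    warning(sprintf("only %d features have a positive average coefficient (requested %d)",
                    nrow(keep), n))
  utils::head(keep, n)
}

#' Waveform occurrence rates in counts per minute
#'
#' Total counts divided by total recorded minutes, within the individuals
#' of class `y` (in-class), outside it (out-of-class), and overall.
#'
#' @param bags_by_ind named list of per-individual segment bag lists.
#' @param labels named labels per individual.
#' @param y class of interest.
#' @return List of per-feature vectors `in_rate`, `out_rate`,
#'   `overall_rate`.
#' @export
occurrence_rates <- function(bags_by_ind, labels, y) {
  ids <- names(bags_by_ind)
  tot <- function(sel_ids) {
    if (!length(sel_ids)) return(NULL)
    counts <- Reduce(`+`, lapply(sel_ids, function(s)
      pool_bags(bags_by_ind[[s]])$counts))
    mins <- sum(vapply(sel_ids, function(s)
      pool_bags(bags_by_ind[[s]])$duration_s, 0)) / 60
    if (mins <= 0) stop_config("zero total duration: rates undefined")
    counts / mins
  }
  in_ids <- ids[unlist(labels[ids]) == y]
  list(in_rate = tot(in_ids), out_rate = tot(setdiff(ids, in_ids)),
       overall_rate = tot(ids))
}

#' Welch power spectral density of a short waveform
#'
#' From a P-sample waveform, windows of length `floor(0.95 P)` are taken at
#' a stride of `floor(0.95 P) - floor(0.9 P)` (for P = 256 at 256 Hz: two
#' windows of 243 samples at offsets 0 and 13), tapered with the periodic
#' Hann function, zero-padded to `4 P` and the one-sided periodograms are
#' averaged, giving a 0.25 Hz frequency resolution at 256 Hz.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @return A `bow_spectrum`: `frequencies` (Hz), `power` (density),
#'   `peak_frequency` (argmax, ties to the lowest frequency; `NA` for an
#'   all-zero input).
#' @export
welch_psd <- function(x, fs) {
  P <- length(x)
  nper <- floor(0.95 * P)
  noverlap <- floor(0.9 * P)
  stride <- nper - noverlap
  nfft <- 4L * P
  offsets <- seq(0L, P - nper, by = stride)
  w <- hann_window(nper)
  scale <- 1 / (fs * sum(w^2))
  nhalf <- nfft %/% 2L + 1L
  psd <- numeric(nhalf)
  for (off in offsets) {
    seg <- x[(off + 1):(off + nper)] * w
    X <- stats::fft(c(seg, numeric(nfft - nper)))
    p <- Mod(X[seq_len(nhalf)])^2 * scale
    p[2:(nhalf - 1L)] <- 2 * p[2:(nhalf - 1L)]
    psd <- psd + p
  }
  psd <- psd / length(offsets)
  freqs <- (seq_len(nhalf) - 1L) * fs / nfft
  peak <- if (all(psd == 0)) NA_real_ else freqs[which.max(psd)]
  structure(list(frequencies = freqs, power = psd, peak_frequency = peak,
                 n_windows = length(offsets), window_length = nper,
                 stride = stride, nfft = nfft),
            class = "bow_spectrum")
}

#' @export
print.bow_spectrum <- function(x, ...) {
  cat(sprintf("<bow_spectrum> %d bins, %.3g Hz resolution, peak at %s Hz\n",
              length(x$frequencies), x$frequencies[2] - x$frequencies[1],
              format(x$peak_frequency)))
  invisible(x)
}
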