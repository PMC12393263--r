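# Bag-of-waves and bag-of-spectra feature encoding, TFIDF weighting and
# per-individual pooling.

#' Encode a segment as a bag-of-waves count vector
#'
#' The segment is cut into non-overlapping L-sample windows; for EACH
#' dictionary independently every window is assigned to its best-matching
#' waveform (cosine similarity over all shifts) and the assignments are
#' tabulated.  The per-dictionary count blocks are concatenated in the given
#' dictionary order, so each block sums to the number of windows M.
#'
#' @param segment a `bow_segment` or numeric vector.
#' @param dictionaries list of `bow_dictionary` objects sharing P and fs.
#' @param L window length in samples.
#' @return A `bow_bag`: list with `counts` (length `D = sum(K_j)`), `M`,
#'   `dict_index` (data frame mapping feature position to dictionary and
#'   waveform), `individual_id`, `duration_s`.
#' @export
encode_segment <- function(segment, dictionaries, L) {
  if (inherits(dictionaries, "bow_dictionary"))
    dictionaries <- list(dictionaries)
  P <- unique(vapply(dictionaries, function(d) as.integer(d$P), 0L))
  if (length(P) != 1L)
    stop_config("all dictionaries must share the same waveform length P")
  fs <- unique(vapply(dictionaries, `[[`, 0, "fs"))
  if (length(fs) != 1L)
    stop_config("all dictionaries must share the same sampling rate")
  X <- extract_windows(segment, L)
  counts <- unlist(lapply(dictionaries, function(d) {
    a <- assign_windows(X, d$C)
    tabulate(a$k, nbins = d$K)
  }))
  dict_index <- do.call(rbind, lapply(seq_along(dictionaries), function(j)
    data.frame(dict = j,
               class_label = dictionaries[[j]]$class_label,
               waveform = seq_len(dictionaries[[j]]$K))))
  dur <- if (inherits(segment, "bow_segment"))
    length(segment$samples) / segment$fs else length(segment) / fs
  structure(list(counts = counts, M = nrow(X), dict_index = dict_index,
                 individual_id = if (inherits(segment, "bow_segment"))
                   segment$individual_id else NA_character_,
                 duration_s = dur),
            class = "bow_bag")
}

bag_counts <- function(bags) {
  if (inherits(bags, "bow_bag")) bags <- list(bags)
  do.call(rbind, lapply(bags, `[[`, "counts"))
}

#' Fit TFIDF weights on training bags
#'
#' `w_k = log((1 + N_train) / (1 + N_k)) + 1` where `N_k` is the number of
#' training segments in which waveform k has a nonzero count.  Weights are
#' monotone decreasing in `N_k` with minimum 1 (reached when the waveform
#' occurs in every segment).
#'
#' @param training_bags list of `bow_bag`s (or a count matrix, one segment
#'   per row).
#' @return A `bow_tfidf`: list with `w`, `N_train`, `N_k`.
#' @export
fit_tfidf <- function(training_bags) {
  Z <- if (is.matrix(training_bags)) training_bags else bag_counts(training_bags)
  if (nrow(Z) < 1L) stop_config("need at least one training bag")
  N <- nrow(Z)
  Nk <- colSums(Z > 0)
  structure(list(w = log((1 + N) / (1 + Nk)) + 1, N_train = N, N_k = Nk),
            class = "bow_tfidf")
}

#' TFIDF-transform count vectors into unit-norm features
#'
#' Elementwise product with the weights followed by ell-2 normalization;
#' the all-zero vector maps to itself.  Because of the normalization the
#' feature is invariant to positive rescaling of the counts, so counts and
#' occurrence rates give identical features.
#'
#' @param bags a `bow_bag`, list of bags, or count matrix (rows = segments).
#' @param weights a `bow_tfidf` from [fit_tfidf()].
#' @return Feature matrix (rows unit-norm), one row per input bag.
#' @export
tfidf_transform <- function(bags, weights) {
  Z <- if (is.matrix(bags)) bags else bag_counts(bags)
  if (ncol(Z) != length(weights$w))
    stop_config("feature dimension mismatch: %d counts vs %d weights",
                ncol(Z), length(weights$w))
  V <- sweep(Z, 2L, weights$w, `*`)
  nrm <- sqrt(rowSums(V^2))
  V / ifelse(nrm == 0, 1, nrm)
}

#' Pool bags by summing counts
#'
#' Per-individual inference uses a single pooled bag: the elementwise sum of
#' that individual's segment counts (windows and durations add).
#'
#' @param bags list of `bow_bag`s with identical dictionary order.
#' @return A single `bow_bag`.
#' @export
pool_bags <- function(bags) {
  if (inherits(bags, "bow_bag")) return(bags)
  if (length(bags) == 1L) return(bags[[1]])
  d1 <- bags[[1]]$dict_index
  for (b in bags[-1])
    if (!identical(b$dict_index$class_label, d1$class_label) ||
        !identical(b$dict_index$waveform, d1$waveform))
      stop_config("cannot pool bags with different dictionary orders")
  out <- bags[[1]]
  out$counts <- Reduce(`+`, lapply(bags, `[[`, "counts"))
  out$M <- sum(vapply(bags, function(b) as.numeric(b$M), 0))
  out$duration_s <- sum(vapply(bags, `[[`, 0, "duration_s"))
  out
}

# ---- bag-of-spectra baseline ----------------------------------------------

# ell-2 normalized one-sided FFT magnitude of each window (rows of X);
# includes the DC and Nyquist bins.
window_spectra <- function(X) {
  L <- ncol(X)
  S <- t(Mod(stats::mvfft(t(X)))[seq_len(L %/% 2 + 1L), , drop = FALSE])
  nrm <- sqrt(rowSums(S^2))
  S / ifelse(nrm == 0, 1, nrm)
}

#' Fit the bag-of-spectra baseline centroids
#'
#' Windows are represented by their ell-2-normalized FFT magnitude vectors
#' and clustered with standard (Lloyd) k-means, initialized from K windows
#' chosen uniformly without replacement, for parity with the bag-of-waves
#' initializer.
#'
#' @param X window matrix (M x L).
#' @param K number of centroids.
#' @param fs sampling rate (metadata).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return A `bow_bos`: list with `centroids` (K x (L/2+1)), `K`, `L`, `fs`.
#' @export
fit_bos <- function(X, K, fs = NA_real_, seed = 1L, max_iter = 300L) {
  S <- window_spectra(X)
  if (nrow(S) < K) stop_config("need at least K=%d windows", K)
  km <- with_seed(seed, {
    init <- S[sample.int(nrow(S), K), , drop = FALSE]
    suppressWarnings(stats::kmeans(S, centers = init, iter.max = max_iter,
                                   algorithm = "Lloyd"))
  })
  structure(list(centroids = km$centers, K = K, L = ncol(X), fs = fs),
            class = "bow_bos")
}

#' Encode a segment as a bag-of-spectra count vector
#'
#' Each window's normalized magnitude spectrum is assigned to the nearest
#' centroid in Euclidean distance (ties to the lowest centroid index).
#'
#' @param segment a `bow_segment` or numeric vector.
#' @param bos a `bow_bos` from [fit_bos()].
#' @return A `bow_bag` whose counts sum to the number of windows.
#' @export
encode_segment_bos <- function(segment, bos) {
  X <- extract_windows(segment, bos$L)
  S <- window_spectra(X)
  # squared distance: ||s||^2 - 2 s.c + ||c||^2; ||s||^2 constant per row
  cross <- S %*% t(bos$centroids)
  d2 <- sweep(-2 * cross, 2L, rowSums(bos$centroids^2), `+`)
  k <- max.col(-d2, ties.method = "first")
  dur <- if (inherits(segment, "bow_segment"))
    length(segment$samples) / segment$fs else NA_real_
  structure(list(counts = tabulate(k, nbins = bos$K), M = nrow(X),
                 dict_index = data.frame(dict = 1L, class_label = "bos",
                                         waveform = seq_len(bos$K)),
                 individual_id = if (inherits(segment, "bow_segment"))
                   segment$individual_id else NA_character_,
                 duration_s = dur),
            class = "bow_bag")
}
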