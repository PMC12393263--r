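# Shift-invariant k-means dictionary learning.
#
# Each L-sample window is matched to one of K P-sample centroid waveforms at
# its best temporal offset, by cosine similarity between the waveform and the
# P-length subwindow it overlaps; centroids are then updated as the plain
# average of their assigned, shift-aligned subwindows.

#' Window operator: extract a P-length subwindow at shift tau
#'
#' @param x numeric vector of length L.
#' @param tau 0-based shift, `0 <= tau <= L - P`.
#' @param P subwindow length.
#' @return `x[tau + 1 .. tau + P]`.
#' @export
subwindow <- function(x, tau, P) {
  L <- length(x)
  if (tau < 0 || tau > L - P) stop("tau out of range", call. = FALSE)
  x[(tau + 1):(tau + P)]
}

#' Adjoint shift operator: zero-pad a waveform into an L-length vector
#'
#' Places `c` at offset `tau` in a zero vector of length `L`, so that
#' `sum(x * pad_shift(c, tau, L)) == sum(subwindow(x, tau, P) * c)` for
#' every `x` (the adjoint identity).
#'
#' @param c numeric vector of length P.
#' @param tau 0-based shift, `0 <= tau <= L - P`.
#' @param L output length.
#' @return Numeric vector of length L.
#' @export
pad_shift <- function(c, tau, L) {
  P <- length(c)
  if (tau < 0 || tau > L - P) stop("tau out of range", call. = FALSE)
  out <- numeric(L)
  out[(tau + 1):(tau + P)] <- c
  out
}

#' Fit configuration for shift-invariant k-means
#'
#' @param K number of waveforms.
#' @param P waveform length in samples (must be < window length L).
#' @param max_iter maximum iterations (default 300).
#' @param tol_factor stopping tolerance as a multiple of the pointwise
#'   variance of the training windows (default 1e-4).
#' @param seed integer seed for initialization.
#' @param n_init number of random restarts; the run with the lowest mean
#'   reconstruction error is kept.  Default 1 (a single initialization, as
#'   in the original protocol); like `nstart` in [stats::kmeans()], a
#'   handful of restarts guards against locally optimal dictionaries when
#'   K is close to the number of underlying motifs.
#' @return A `bow_fit_config` list.
#' @export
fit_config <- function(K, P, max_iter = 300L, tol_factor = 1e-4, seed = 1L,
                       n_init = 1L) {
  if (max_iter < 1L) stop_config("max_iter must be >= 1")
  if (tol_factor <= 0) stop_config("tol_factor must be > 0")
  if (K < 1L) stop_config("K must be >= 1")
  if (n_init < 1L) stop_config("n_init must be >= 1")
  structure(list(K = as.integer(K), P = as.integer(P),
                 max_iter = as.integer(max_iter), tol_factor = tol_factor,
                 seed = seed, n_init = as.integer(n_init)),
            class = "bow_fit_config")
}

# Batch assignment of all windows (rows of X) to (k, tau) pairs.
# Ties in similarity break to the smallest k, then the smallest tau.
# Zero-norm subwindows are given similarity 0.
assign_windows <- function(X, C) {
  M <- nrow(X); L <- ncol(X)
  K <- nrow(C); P <- ncol(C)
  if (P > L) stop_config("waveform length P must be <= window length L")
  c_norm <- sqrt(rowSums(C^2))
  if (any(c_norm == 0)) stop_config("dictionary contains an all-zero waveform")
  Ct <- t(C)
  sq <- X^2
  cs <- cbind(0, t(apply(sq, 1L, cumsum)))  # M x (L+1) running sums
  best_sim <- rep(-Inf, M)
  best_k <- integer(M); best_tau <- integer(M); best_ip <- numeric(M)
  for (tau in 0:(L - P)) {
    ip <- X[, (tau + 1):(tau + P), drop = FALSE] %*% Ct   # M x K
    nx <- sqrt(cs[, tau + P + 1L] - cs[, tau + 1L])
    sim <- ip / outer(nx, c_norm)
    sim[nx == 0, ] <- 0
    kbest <- max.col(sim, ties.method = "first")
    smax <- sim[cbind(seq_len(M), kbest)]
    upd <- smax > best_sim | (smax == best_sim & kbest < best_k)
    if (any(upd)) {
      best_sim[upd] <- smax[upd]
      best_k[upd] <- kbest[upd]
      best_tau[upd] <- tau
      best_ip[upd] <- ip[cbind(seq_len(M), kbest)][upd]
    }
  }
  list(k = best_k, tau = best_tau, similarity = best_sim,
       alpha = pmax(0, best_ip) / c_norm[best_k]^2,
       ip = best_ip)
}

#' Best shift-invariant match of one window against a dictionary
#'
#' Maximizes cosine similarity between every P-length subwindow of `x` and
#' every dictionary waveform over all `K * (L - P + 1)` pairs.  The optimal
#' non-negative scale is `alpha = max(0, <W_tau x, c_k>) / ||c_k||^2`.
#'
#' @param x numeric window of length L.
#' @param dict a `bow_dictionary`, or a K x P waveform matrix.
#' @return List with `k`, `tau` (0-based), `similarity`, `alpha`.
#' @export
best_match <- function(x, dict) {
  C <- if (inherits(dict, "bow_dictionary")) dict$C else dict
  a <- assign_windows(matrix(x, nrow = 1L), C)
  list(k = a$k, tau = a$tau, similarity = a$similarity, alpha = a$alpha)
}

#' Centroid update: average the shift-aligned assigned subwindows
#'
#' Each waveform becomes the plain (un-normalized) mean of the P-length
#' subwindows `W_tau(x_i)` of the windows assigned to it.  Clusters with no
#' assigned windows keep their previous waveform when `prev` is supplied,
#' else a zero row.
#'
#' @param X window matrix (M x L).
#' @param assignment list with `k` and `tau` as from [assign_windows()].
#' @param K,P dictionary dimensions.
#' @param prev optional previous K x P matrix for empty clusters.
#' @return K x P matrix of updated waveforms.
#' @export
update_centroids <- function(X, assignment, K, P, prev = NULL) {
  M <- nrow(X)
  cols <- matrix(assignment$tau, M, P) +
    matrix(seq_len(P), M, P, byrow = TRUE)
  A <- matrix(X[cbind(rep(seq_len(M), P), as.vector(cols))], M, P)
  counts <- tabulate(assignment$k, nbins = K)
  sums <- rowsum(A, group = factor(assignment$k, levels = seq_len(K)))
  Cn <- sums / pmax(counts, 1L)
  if (any(counts == 0) && !is.null(prev))
    Cn[counts == 0, ] <- prev[counts == 0, , drop = FALSE]
  attr(Cn, "counts") <- counts
  Cn
}

#' Learn a waveform dictionary by shift-invariant k-means
#'
#' Initializes K centroids as the first P samples of K windows chosen
#' uniformly without replacement, then alternates assignment (cosine
#' similarity over all shifts) and plain averaging of the aligned
#' subwindows, stopping when the mean squared centroid change
#' `(1/(P K)) * sum_k ||c_k(m-1) - c_k(m)||^2` drops to
#' `tol = tol_factor * var(training samples)` or `max_iter` is reached.
#' Clusters that lose all their windows are reinitialized from the first P
#' samples of a randomly chosen window.
#'
#' @param X window matrix (M x L), M >= K.
#' @param cfg a [fit_config()].
#' @param class_label,fs metadata stored with the dictionary.
#' @return A `bow_dictionary`: list with `C` (K x P), `K`, `P`, `fs`,
#'   `class_label`, `iterations`, `final_delta`, `tol`, `converged`.
#' @export
fit_dictionary <- function(X, cfg, class_label = NA_character_, fs = NA_real_) {
  stopifnot(inherits(cfg, "bow_fit_config"))
  if (cfg$n_init > 1L) {
    fits <- lapply(seq_len(cfg$n_init), function(i) {
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, i)
      cfg_i$n_init <- 1L
      fit <- fit_dictionary(X, cfg_i, class_label, fs)
      list(fit = fit, err = reconstruction_error(X, fit))
    })
    best <- which.min(vapply(fits, `[[`, 0, "err"))
    return(fits[[best]]$fit)
  }
  M <- nrow(X); L <- ncol(X)
  K <- cfg$K; P <- cfg$P
  if (M < K) stop_config("need at least K=%d windows, got %d", K, M)
  if (P >= L) stop_config("P (%d) must be < window length L (%d)", P, L)
  tol <- cfg$tol_factor * stats::var(as.vector(X))
  with_seed(cfg$seed, {
    C <- X[sample.int(M, K), seq_len(P), drop = FALSE]
    it <- 0L; delta <- Inf
    while (it < cfg$max_iter) {
      it <- it + 1L
      a <- assign_windows(X, C)
      Cn <- update_centroids(X, a, K, P, prev = C)
      empty <- attr(Cn, "counts") == 0
      attr(Cn, "counts") <- NULL
      if (any(empty))
        Cn[empty, ] <- X[sample.int(M, sum(empty)), seq_len(P), drop = FALSE]
      delta <- mean((C - Cn)^2)
      C <- Cn
      if (delta <= tol) break
    }
    structure(list(C = unname(C), K = K, P = P, fs = fs,
                   class_label = class_label, iterations = it,
                   final_delta = delta, tol = tol,
                   converged = delta <= tol),
              class = "bow_dictionary")
  })
}

#' @export
print.bow_dictionary <- function(x, ...) {
  cat(sprintf("<bow_dictionary> %s: K=%d waveforms of P=%d samples; %d iterations (%sconverged, delta=%.3g, tol=%.3g)\n",
              x$class_label, x$K, x$P, x$iterations,
              if (x$converged) "" else "not ", x$final_delta, x$tol))
  invisible(x)
}

#' Mean squared reconstruction error of windows under a dictionary
#'
#' The exact minimum of `||x - alpha * pad_shift(c_k, tau, L)||^2` over all
#' waveforms, shifts and non-negative scales: for each (k, tau) the optimal
#' scale gives a residual of `||x||^2 - max(0, <W_tau x, c_k>)^2 /
#' ||c_k||^2`, minimized over pairs.  Note this error-optimal assignment
#' weights the match by the subwindow norm, whereas the clustering
#' assignment ([best_match()]) uses pure cosine similarity; the two agree
#' when subwindow norms are constant.  When every match is negative, alpha
#' clamps to 0 and the error is the window's own squared norm.
#'
#' @param X window matrix (M x L).
#' @param dict a `bow_dictionary` or K x P matrix.
#' @return Mean over windows of the minimal squared ell-2 residual.
#' @export
reconstruction_error <- function(X, dict) {
  C <- if (inherits(dict, "bow_dictionary")) dict$C else dict
  M <- nrow(X); L <- ncol(X)
  K <- nrow(C); P <- ncol(C)
  c_norm <- sqrt(rowSums(C^2))
  if (any(c_norm == 0)) stop_config("dictionary contains an all-zero waveform")
  Ct <- t(C)
  best <- numeric(M)  # max over (k, tau) of max(0, ip / ||c||)^2
  for (tau in 0:(L - P)) {
    ip <- X[, (tau + 1):(tau + P), drop = FALSE] %*% Ct
    val <- sweep(pmax(ip, 0), 2L, c_norm, `/`)
    best <- pmax(best, val[cbind(seq_len(M), max.col(val, ties.method = "first"))]^2)
  }
  mean(rowSums(X^2) - best)
}

#' Serialize / load a dictionary (JSON container)
#'
#' @param dict a `bow_dictionary`.
#' @param path file path.
#' @return `read_dictionary()`: the restored `bow_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  jsonlite::write_json(
    list(C = dict$C, K = dict$K, P = dict$P, fs = dict$fs,
         class_label = dict$class_label, iterations = dict$iterations,
         final_delta = dict$final_delta, tol = dict$tol,
         converged = dict$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$C <- matrix(as.numeric(d$C), nrow = d$K)
  structure(d, class = "bow_dictionary")
}

#' Per-waveform summary table
#'
#' @param dict a `bow_dictionary` with known `fs`.
#' @return Data frame with `waveform`, `norm`, `peak_frequency_hz`.
#' @export
dictionary_summary <- function(dict) {
  pk <- vapply(seq_len(dict$K), function(k)
    welch_psd(dict$C[k, ], dict$fs)$peak_frequency, 0)
  data.frame(waveform = seq_len(dict$K),
             norm = sqrt(rowSums(dict$C^2)),
             peak_frequency_hz = pk)
}
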