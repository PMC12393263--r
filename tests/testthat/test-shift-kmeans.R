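test_that("window and shift operators slice and pad as defined", {
  expect_equal(subwindow(c(1, 2, 3, 4, 5), 1, 3), c(2, 3, 4))
  expect_equal(subwindow(c(1, 2, 3, 4, 5), 0, 5), c(1, 2, 3, 4, 5))
  expect_equal(subwindow(c(1, 2, 3, 4, 5), 2, 3), c(3, 4, 5))
  expect_error(subwindow(1:5, 3, 3), "tau")
  expect_equal(pad_shift(7, 2, 4), c(0, 0, 7, 0))
  expect_equal(pad_shift(1:4, 0, 4), c(1, 2, 3, 4))
  expect_error(pad_shift(1:3, 3, 4), "tau")
})

test_that("the adjoint identity <x, S_tau(c)> = <W_tau(x), c> holds for all shifts", {
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(8:32, 1); P <- sample(2:(L - 1), 1)
    x <- rnorm(L); c <- rnorm(P)
    for (tau in 0:(L - P))
      expect_equal(sum(x * pad_shift(c, tau, L)),
                   sum(subwindow(x, tau, P) * c), tolerance = 1e-12)
  }
})

test_that("best_match equals exhaustive search over (k, tau) on random instances", {
  set.seed(17)
  for (rep in 1:200) {
    K <- sample(2:5, 1); L <- sample(8:16, 1); P <- sample(2:(L - 2), 1)
    x <- rnorm(L)
    C <- matrix(rnorm(K * P), K, P)
    bm <- best_match(x, C)
    best <- c(-Inf, NA, NA)
    for (k in seq_len(K)) for (tau in 0:(L - P)) {
      s <- subwindow(x, tau, P)
      sim <- sum(s * C[k, ]) / sqrt(sum(s^2) * sum(C[k, ]^2))
      if (sim > best[1]) best <- c(sim, k, tau)
    }
    expect_equal(bm$k, best[2])
    expect_equal(bm$tau, best[3])
    expect_equal(bm$similarity, best[1], tolerance = 1e-9)
    a_exp <- max(0, sum(subwindow(x, best[3], P) * C[best[2], ]) /
                   sum(C[best[2], ]^2))
    expect_equal(bm$alpha, a_exp, tolerance = 1e-9)
  }
})

test_that("best_match recovers planted shifts exactly and is scale invariant", {
  set.seed(3)
  P <- 8; L <- 24; K <- 4
  C <- matrix(rnorm(K * P), K, P)
  C <- C / sqrt(rowSums(C^2))
  x <- pad_shift(C[3, ], 17 - 1, L)  # tau = 16
  bm <- best_match(x, C)
  expect_equal(bm$k, 3)
  expect_equal(bm$tau, 16)
  expect_equal(bm$similarity, 1, tolerance = 1e-12)
  expect_equal(bm$alpha, 1, tolerance = 1e-12)
  # scale invariance of the assignment
  y <- rnorm(L)
  b1 <- best_match(y, C); b2 <- best_match(5.7 * y, C)
  expect_equal(b1[c("k", "tau", "similarity")], b2[c("k", "tau", "similarity")])
  expect_equal(b2$alpha, 5.7 * b1$alpha, tolerance = 1e-12)
})

test_that("negative-similarity matches are never preferred over positive ones", {
  # x is a perfect NEGATIVE match for waveform 1 (signed similarity -1) and
  # a weak positive match for waveform 2; the positive pair must win
  P <- 4; L <- 8
  c1 <- c(1, 2, 3, 4) / sqrt(30)
  c2 <- c(1, -1, 1, -1) / 2
  C <- rbind(c1, c2)
  x <- -pad_shift(c1, 2, L)
  bm <- best_match(x, C)
  expect_gt(bm$similarity, 0)
  expect_equal(bm$k, 2)
  expect_gt(bm$alpha, 0)
})

test_that("centroid update equals an independent group-by mean of aligned subwindows", {
  # tiny hand case
  X <- rbind(c(1, 1, 9, 9), c(3, 3, 7, 7))
  a <- list(k = c(1L, 1L), tau = c(0L, 0L))
  expect_equal(update_centroids(X, a, K = 1, P = 2)[1, ], c(2, 2))
  # single assigned window -> centroid equals its subwindow
  a2 <- list(k = c(1L, 2L), tau = c(1L, 2L))
  Cn <- update_centroids(X, a2, K = 2, P = 2)
  expect_equal(Cn[1, ], c(1, 9))
  expect_equal(Cn[2, ], c(7, 7))
  # random instance vs direct aggregation
  set.seed(8)
  M <- 40; L <- 12; P <- 5; K <- 3
  X <- matrix(rnorm(M * L), M, L)
  a3 <- list(k = sample(1:K, M, replace = TRUE),
             tau = sample(0:(L - P), M, replace = TRUE))
  Cn3 <- update_centroids(X, a3, K, P)
  for (k in 1:K) {
    idx <- which(a3$k == k)
    ref <- colMeans(do.call(rbind, lapply(idx, function(i)
      subwindow(X[i, ], a3$tau[i], P))))
    expect_equal(Cn3[k, ], ref, tolerance = 1e-12)
  }
})

test_that("reconstruction error matches brute force with closed-form alpha", {
  set.seed(21)
  for (rep in 1:30) {
    K <- sample(2:4, 1); L <- sample(8:14, 1); P <- sample(2:(L - 2), 1)
    M <- 6
    X <- matrix(rnorm(M * L), M, L)
    C <- matrix(rnorm(K * P), K, P)
    err <- reconstruction_error(X, C)
    brute <- mean(vapply(seq_len(M), function(i) {
      errs <- c()
      for (k in seq_len(K)) for (tau in 0:(L - P)) {
        s <- subwindow(X[i, ], tau, P)
        a <- max(0, sum(s * C[k, ]) / sum(C[k, ]^2))
        errs <- c(errs, sum((X[i, ] - a * pad_shift(C[k, ], tau, L))^2))
      }
      min(errs)
    }, 0))
    expect_equal(err, brute, tolerance = 1e-9)
    # the error-optimal assignment can only improve on the cosine assignment
    cos_err <- mean(vapply(seq_len(M), function(i) {
      bm <- best_match(X[i, ], C)
      sum((X[i, ] - bm$alpha * pad_shift(C[bm$k, ], bm$tau, L))^2)
    }, 0))
    expect_lte(err, cos_err + 1e-12)
  }
  # exactly representable windows -> zero error
  C <- matrix(rnorm(2 * 4), 2, 4)
  X <- rbind(2 * pad_shift(C[1, ], 3, 10), 0.5 * pad_shift(C[2, ], 0, 10))
  expect_lt(abs(reconstruction_error(X, C)), 1e-12)
  # all-negative similarity -> alpha 0 and error equals the window norm
  Cpos <- matrix(abs(rnorm(4)) + 0.5, 1, 4)
  Xneg <- matrix(-abs(rnorm(10)) - 0.5, 1, 10)
  expect_equal(reconstruction_error(Xneg, Cpos), sum(Xneg^2),
               tolerance = 1e-12)
})

test_that("assignment is shift-equivariant on planted events", {
  set.seed(12)
  lib <- test_library()
  s <- lib$rhythmic_20Hz$shape
  C <- rbind(c(s, numeric(8)), matrix(rnorm(2 * 64, sd = 0.3), 2, 64))
  L <- 128
  base <- best_match(pad_shift(s, 20, L), C)
  for (delta in c(-10, -3, 5, 15)) {
    bm <- best_match(pad_shift(s, 20 + delta, L), C)
    expect_equal(bm$k, base$k)
    expect_equal(bm$tau, base$tau + delta)
  }
})

test_that("dictionary fitting is deterministic, converges, and recovers planted waveforms", {
  lib <- test_library()
  shapes <- lapply(lib, `[[`, "shape")
  X <- planted_windows(shapes, M = 400, L = 128, noise_sd = 0.1, seed = 6)
  cfg <- fit_config(3, 64, seed = 4)
  d1 <- fit_dictionary(X, cfg)
  d2 <- fit_dictionary(X, cfg)
  expect_identical(d1$C, d2$C)
  if (d1$converged) expect_lte(d1$final_delta, d1$tol)
  expect_error(fit_dictionary(X[1:2, ], fit_config(3, 64)), "at least K")
  # K = 1 with identical shifted copies converges to the common pattern
  s <- shapes[[1]]
  X1 <- t(vapply(1:50, function(i) 2 * pad_shift(s, 4 + i %% 5, 128),
                 numeric(128)))
  dk1 <- fit_dictionary(X1, fit_config(1, 64, seed = 2))
  expect_gt(max_shift_cosine(dk1$C[1, ], s), 0.99)
})

test_that("dictionaries serialize and restore through the JSON container", {
  lib <- test_library()
  X <- planted_windows(lapply(lib, `[[`, "shape"), M = 120, L = 128, seed = 2)
  d <- fit_dictionary(X, fit_config(2, 64, seed = 1), class_label = "A",
                      fs = 256)
  p <- file.path(withr::local_tempdir(), "dict.json")
  write_dictionary(d, p)
  d2 <- read_dictionary(p)
  expect_equal(d2$C, d$C)
  expect_equal(d2$class_label, "A")
  summ <- dictionary_summary(d2)
  expect_equal(nrow(summ), 2L)
  expect_true(all(summ$peak_frequency_hz >= 0))
})
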