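# Shared fixture builders, all seeded and generated at test time.

# The standard three-morphology library used throughout the tests: a 20 Hz
# burst, a sharp transient and an asymmetric 6 Hz slow wave, 56 samples at
# 256 Hz (well distinguishable: pairwise max shifted cosine < 0.15).
test_library <- function(P_true = 56, fs = 256) {
  make_waveform_library(P_true, fs, list(
    waveform_kind("rhythmic", 20),
    waveform_kind("transient", 60),
    waveform_kind("slow-wave", 6)), seed = 2)
}

# Windows with exactly one planted event each at a uniform shift, additive
# white noise; truth labels attached as attributes.
planted_windows <- function(shapes, M, L, noise_sd = 0.12, amp_mean = 3,
                            amp_sd = 0.5, seed = 1) {
  P_true <- length(shapes[[1]])
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    truek <- sample(length(shapes), M, replace = TRUE)
    tau <- sample(0:(L - P_true), M, replace = TRUE)
    amp <- abs(stats::rnorm(M, amp_mean, amp_sd))
    X <- t(vapply(seq_len(M), function(i)
      amp[i] * pad_shift(shapes[[truek[i]]], tau[i], L) +
        stats::rnorm(L, 0, noise_sd), numeric(L)))
    attr(X, "truek") <- truek
    attr(X, "tau") <- tau
    attr(X, "amp") <- amp
    X
  })
}

# Two-class synthetic cohort where the classes differ only in the rate of
# one waveform (absent in class A, `rate` per minute in class B).
two_class_cohort <- function(n_per_class = 4, duration = 900, rate = 6,
                             noise_sd = 0.3, seed = 42, fs = 256,
                             lib = test_library()) {
  rates_a <- c(rhythmic_20Hz = 4, `slow-wave_6Hz` = 3, transient_60Hz = 0)
  rates_b <- c(rhythmic_20Hz = 4, `slow-wave_6Hz` = 3, transient_60Hz = rate)
  specs <- list(
    class_spec("A", rates_a, amplitude_mean = 3, noise_sd = noise_sd),
    class_spec("B", rates_b, amplitude_mean = 3, noise_sd = noise_sd))
  make_cohort(specs, lib, n_per_class, duration, fs, seed = seed)
}

# Encode a cohort end to end at reduced sizes: per-class dictionaries fit
# on fold individuals' first halves, everyone encoded from second halves.
encode_cohort <- function(cohort, dict_ids, K = 8, P = 64, L = 128,
                          M_train = 600, Q = 256 * 300,
                          segments_per_individual = 4, seed = 7) {
  recs <- cohort$recordings
  labels <- lapply(recs, `[[`, "label")
  classes <- sort(unique(unlist(labels[dict_ids])))
  dicts <- lapply(seq_along(classes), function(ci) {
    cl_ids <- dict_ids[unlist(labels[dict_ids]) == classes[ci]]
    n_each <- ceiling(M_train / length(cl_ids))
    X <- do.call(rbind, lapply(seq_along(cl_ids), function(i) {
      segs <- sample_segments(recs[[cl_ids[i]]], "first-half", n_each, L,
                              seed = seed + 13 * i + 101 * ci)
      do.call(rbind, lapply(segs, `[[`, "samples"))
    }))
    fit_dictionary(X[seq_len(min(M_train, nrow(X))), , drop = FALSE],
                   fit_config(K, P, seed = seed + ci),
                   class_label = classes[ci], fs = recs[[1]]$fs)
  })
  bags <- lapply(seq_along(recs), function(i) {
    segs <- sample_segments(recs[[i]], "second-half",
                            segments_per_individual, Q,
                            seed = seed + 1000 + i)
    lapply(segs, encode_segment, dictionaries = dicts, L = L)
  })
  names(bags) <- names(recs)
  list(dictionaries = dicts, bags = bags, labels = labels)
}

# ---- end-to-end experiment helpers (also mirrored in scripts/acceptance.R) --

derive_seed <- bowaves:::derive_seed
with_seed <- bowaves:::with_seed

# Event-rich two-class cohort: shared 20/min rhythm + 15/min slow wave on
# pink noise; class B additionally carries the sharp transient at `rate`/min.
e2e_cohort <- function(seed, n_per_class = 4, duration = 50 * 60, rate = 6,
                       lib = test_library()) {
  specs <- list(
    class_spec("A", c(rhythmic_20Hz = 20, `slow-wave_6Hz` = 15,
                      transient_60Hz = 0), amplitude_mean = 3,
               noise_sd = 0.15),
    class_spec("B", c(rhythmic_20Hz = 20, `slow-wave_6Hz` = 15,
                      transient_60Hz = rate), amplitude_mean = 3,
               noise_sd = 0.15))
  make_cohort(specs, lib, n_per_class, duration, 256, seed = seed)
}

fit_fold_dicts <- function(recs, labels, dict_ids, K, seed, M = 2000,
                           L = 128, P = 64, n_init = 8) {
  classes <- sort(unique(unlist(labels[dict_ids])))
  lapply(seq_along(classes), function(ci) {
    cl_ids <- dict_ids[unlist(labels[dict_ids]) == classes[ci]]
    X <- do.call(rbind, lapply(seq_along(cl_ids), function(i) {
      segs <- sample_segments(recs[[cl_ids[i]]], "first-half",
                              ceiling(M / length(cl_ids)), L,
                              seed = derive_seed(seed, 13 * i + 101 * ci))
      do.call(rbind, lapply(segs, `[[`, "samples"))
    }))
    fit_dictionary(X[seq_len(M), , drop = FALSE],
                   fit_config(K, P, seed = derive_seed(seed, ci),
                              n_init = n_init),
                   class_label = classes[ci], fs = 256)
  })
}

encode_fold_bags <- function(recs, dicts, Q, nseg, seed, L = 128) {
  bags <- lapply(seq_along(recs), function(i) {
    segs <- sample_segments(recs[[i]], "second-half", nseg, Q,
                            seed = derive_seed(seed, 1000 + i))
    lapply(segs, encode_segment, dictionaries = dicts, L = L)
  })
  stats::setNames(bags, names(recs))
}

# Full two-fold-role LOO evaluation at reduced scale; returns the combined
# per-individual prediction table.
run_two_class_loo <- function(recs, labels, seed, K = 16, n_init = 8,
                              Q = 256 * 600, nseg = 4) {
  ids <- names(recs)
  plan <- fold_plan(ids[c(1, 2, 5, 6)], ids[c(3, 4, 7, 8)])
  preds <- NULL
  for (role in 0:1) {
    dict_ids <- if (role == 0) plan$fold0 else plan$fold1
    eval_ids <- if (role == 0) plan$fold1 else plan$fold0
    dicts <- fit_fold_dicts(recs, labels, dict_ids, K,
                            derive_seed(seed, role), n_init = n_init)
    bags <- encode_fold_bags(recs, dicts, Q, nseg,
                             derive_seed(seed, 50 + role))
    loo <- loo_evaluate(bags, labels, dict_ids, eval_ids, KCV = 3,
                        seed = derive_seed(seed, 90 + role))
    preds <- rbind(preds, loo$individuals)
  }
  preds
}

# Random relabelling that keeps both folds 2/2 so the LOO protocol stays
# runnable; rejection-sampled under the seed.
balanced_label_permutation <- function(labels, fold0, fold1, seed) {
  labs <- unlist(labels)
  repeat {
    seed <- seed + 1
    perm <- with_seed(seed, sample(labs))
    names(perm) <- names(labs)
    ok <- all(vapply(list(fold0, fold1), function(f)
      length(unique(perm[f])) == 2 && min(table(perm[f])) == 2, TRUE))
    if (ok && !identical(unname(perm), unname(labs))) return(as.list(perm))
  }
}
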