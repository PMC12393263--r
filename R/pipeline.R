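# End-to-end orchestration: two-fold splits, per-class dictionary fitting
# on first-half windows, second-half segment encoding, nested-LOO
# evaluation of the classification tasks, and interpretation tables.

#' Construct a two-fold plan explicitly
#'
#' @param fold0,fold1 disjoint character vectors of individual ids.
#' @return A `bow_fold_plan`.
#' @export
fold_plan <- function(fold0, fold1) {
  if (length(intersect(fold0, fold1)))
    stop_config("folds must be disjoint")
  structure(list(fold0 = fold0, fold1 = fold1), class = "bow_fold_plan")
}

#' Random two-fold splits of the cohort
#'
#' Each individual is assigned to fold 0 or 1 with equal odds
#' (`method = "bernoulli"`, the protocol's choice), or classes are split as
#' evenly as possible (`method = "balanced"`, useful for small synthetic
#' cohorts where a degenerate Bernoulli draw would leave a fold without a
#' class).  A class entirely in one fold is recorded as a warning attribute
#' but permitted.
#'
#' @param ids individual identifiers.
#' @param labels class label per individual.
#' @param n_splits number of independent splits.
#' @param seed integer seed.
#' @param method `"bernoulli"` or `"balanced"`.
#' @return List of `bow_fold_plan`s of length `n_splits`.
#' @export
make_fold_plan <- function(ids, labels, n_splits = 5L, seed = 1L,
                           method = c("bernoulli", "balanced")) {
  method <- match.arg(method)
  lapply(seq_len(n_splits), function(sp) {
    plan <- with_seed(derive_seed(seed, sp), {
      if (method == "bernoulli") {
        f <- stats::rbinom(length(ids), 1L, 0.5)
        fold_plan(ids[f == 0L], ids[f == 1L])
      } else {
        f0 <- unlist(lapply(unique(labels), function(cl) {
          m <- ids[labels == cl]
          m <- m[sample.int(length(m))]
          m[seq_len(ceiling(length(m) / 2))]
        }))
        fold_plan(f0, setdiff(ids, f0))
      }
    })
    lonely <- unique(labels)[vapply(unique(labels), function(cl) {
      m <- ids[labels == cl]
      all(m %in% plan$fold0) || all(m %in% plan$fold1)
    }, TRUE)]
    if (length(lonely))
      attr(plan, "warning") <- sprintf(
        "class(es) %s entirely in one fold", paste(lonely, collapse = ", "))
    plan
  })
}

# Draw dictionary-training windows for one class: a balanced number of
# valid L-sample windows per individual from the first half of each
# recording, M in total.
draw_training_windows <- function(recordings, ids, M, L, seed = 1L) {
  n_each <- ceiling(M / length(ids))
  X <- do.call(rbind, lapply(seq_along(ids), function(i) {
    segs <- sample_segments(recordings[[ids[i]]], "first-half", n_each, L,
                            seed = derive_seed(seed, i))
    do.call(rbind, lapply(segs, `[[`, "samples"))
  }))
  X[seq_len(min(M, nrow(X))), , drop = FALSE]
}

#' Experiment configuration
#'
#' Defaults mirror the full-scale protocol: K = 200 waveforms of P = 256
#' samples, L = 512 windows, 1-hour segments (Q = 921600 at 256 Hz),
#' M = 40000 training windows per class dictionary, 3 inner CV folds,
#' 15-point C grid, 5 two-fold splits.  Scale K, P, L, Q, M and the segment
#' counts down for desk-sized synthetic studies.
#'
#' @param K,P,L,Q,M core dictionary / windowing sizes (samples).
#' @param segments_per_individual encoding segments drawn per individual.
#' @param n_init dictionary-fit restarts (see [fit_config()]).
#' @param KCV inner cross-validation folds.
#' @param grid candidate C values.
#' @param n_splits number of two-fold splits.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param split_method fold assignment scheme (see [make_fold_plan()]).
#' @param short_Q optional shorter segment length (samples) on which the
#'   long-segment-trained classifiers are re-evaluated.
#' @param tasks subset of `"label"` (use the stored labels as-is),
#'   `"strain"`, `"tsc"`, `"joint"`, `"tsc-given-strain"`, `"factorized"`.
#' @return A `bow_config` list.
#' @export
experiment_config <- function(K = 200L, P = 256L, L = 512L, Q = 921600L,
                              M = 40000L, segments_per_individual = 10L,
                              n_init = 1L, KCV = 3L, grid = default_c_grid(),
                              n_splits = 5L, seed = 1L,
                              split_method = "balanced",
                              short_Q = NULL, tasks = "label") {
  if (!(P < L && L <= Q)) stop_config("need P < L <= Q")
  if (K < 2L) stop_config("K must be >= 2")
  if (!length(grid)) stop_config("grid must be non-empty")
  structure(list(K = K, P = P, L = L, Q = Q, M = M,
                 segments_per_individual = segments_per_individual,
                 n_init = n_init, KCV = KCV, grid = grid,
                 n_splits = n_splits, seed = seed,
                 split_method = split_method, short_Q = short_Q,
                 tasks = tasks),
            class = "bow_config")
}

# Fit per-class dictionaries on the dictionary fold and encode everyone's
# second-half segments with them.
encode_fold <- function(recordings, labels, dict_ids, cfg, seed) {
  classes <- sort(unique(unlist(labels[dict_ids])))
  fs <- recordings[[1]]$fs
  dictionaries <- lapply(seq_along(classes), function(ci) {
    cl_ids <- dict_ids[unlist(labels[dict_ids]) == classes[ci]]
    X <- draw_training_windows(recordings, cl_ids, cfg$M, cfg$L,
                               seed = derive_seed(seed, 100 + ci))
    fit_dictionary(X, fit_config(cfg$K, cfg$P,
                                 seed = derive_seed(seed, 200 + ci),
                                 n_init = cfg$n_init %||% 1L),
                   class_label = classes[ci], fs = fs)
  })
  encode_all <- function(Q) {
    ids <- names(recordings)
    bags <- lapply(seq_along(ids), function(i) {
      segs <- sample_segments(recordings[[ids[i]]], "second-half",
                              cfg$segments_per_individual, Q,
                              seed = derive_seed(seed, 300 + i))
      lapply(segs, encode_segment, dictionaries = dictionaries, L = cfg$L)
    })
    stats::setNames(bags, ids)
  }
  out <- list(dictionaries = dictionaries, bags = encode_all(cfg$Q))
  if (!is.null(cfg$short_Q)) out$short_bags <- encode_all(cfg$short_Q)
  out
}

task_labels <- function(labels, task) {
  switch(task,
         "label" = , "joint" = labels,
         "strain" = lapply(labels, strain_of),
         "tsc" = lapply(labels, tsc_of),
         stop_config("unknown task '%s'", task))
}

#' Run a bag-of-waves experiment end to end
#'
#' For each two-fold split and each fold role: per-class dictionaries are
#' fit on the dictionary fold's first-half windows, all individuals'
#' second-half segments are encoded, and the other fold's individuals are
#' evaluated leave-one-out with nested-CV hyperparameter selection.  The
#' two fold roles together yield one prediction per individual per split.
#'
#' @param recordings named list of `bow_recording`s with labels attached.
#' @param cfg an [experiment_config()].
#' @return A `bow_experiment`: per-split, per-task [evaluation_report()]s,
#'   per-task mean/sd accuracy across splits, and the first split's fitted
#'   objects (`dictionaries`, `loo`, `bags`) for interpretation.
#' @export
run_experiment <- function(recordings, cfg) {
  ids <- names(recordings)
  labels <- lapply(recordings, `[[`, "label")
  plans <- make_fold_plan(ids, unlist(labels), cfg$n_splits, cfg$seed,
                          method = cfg$split_method)
  splits <- lapply(seq_along(plans), function(sp) {
    plan <- plans[[sp]]
    seed_sp <- derive_seed(cfg$seed, 1000 * sp)
    roles <- lapply(0:1, function(i) {
      dict_ids <- if (i == 0) plan$fold0 else plan$fold1
      eval_ids <- if (i == 0) plan$fold1 else plan$fold0
      enc <- encode_fold(recordings, labels, dict_ids, cfg,
                         seed = derive_seed(seed_sp, i))
      loos <- lapply(stats::setNames(cfg$tasks, cfg$tasks), function(task) {
        if (task == "factorized")
          return(loo_evaluate_factorized(enc$bags, labels, dict_ids, eval_ids,
                                         cfg$grid, cfg$KCV,
                                         seed = derive_seed(seed_sp, 10 + i)))
        if (task == "tsc-given-strain")
          return(loo_evaluate_conditional(enc$bags, labels, dict_ids, eval_ids,
                                          cfg$grid, cfg$KCV,
                                          seed = derive_seed(seed_sp, 10 + i)))
        loo_evaluate(enc$bags, task_labels(labels, task), dict_ids, eval_ids,
                     cfg$grid, cfg$KCV, seed = derive_seed(seed_sp, 10 + i),
                     store_models = TRUE)
      })
      list(dict_fold = i, enc = enc, loos = loos,
           dict_ids = dict_ids, eval_ids = eval_ids)
    })
    reports <- lapply(stats::setNames(cfg$tasks, cfg$tasks), function(task) {
      if (task == "tsc-given-strain") {
        # one report per strain, predictions pooled over the two fold roles
        strains <- names(roles[[1]]$loos[[task]])
        return(lapply(stats::setNames(strains, strains), function(st) {
          truth <- c(); pred <- c(); probs <- NULL
          for (r in roles) {
            loo <- r$loos[[task]][[st]]
            truth <- c(truth, loo$individuals$truth)
            pred <- c(pred, loo$individuals$predicted)
            probs <- rbind(probs, loo$probs)
          }
          evaluation_report(truth, pred, probs,
                            positive_class = if (ncol(probs) == 2L)
                              colnames(probs)[2] else NULL)
        }))
      }
      truth <- c(); pred <- c(); probs <- NULL
      for (r in roles) {
        loo <- r$loos[[task]]
        truth <- c(truth, loo$individuals$truth)
        pred <- c(pred, loo$individuals$predicted)
        probs <- rbind(probs, loo$probs)
      }
      evaluation_report(truth, pred, probs,
                        positive_class = if (ncol(probs) == 2L)
                          colnames(probs)[2] else NULL)
    })
    list(plan = plan, roles = roles, reports = reports)
  })
  summary <- do.call(rbind, lapply(cfg$tasks, function(task) {
    accs <- vapply(splits, function(s) {
      r <- s$reports[[task]]
      if (is.null(r)) NA_real_
      else if (inherits(r, "bow_report")) r$accuracy
      else mean(vapply(r, function(rr) rr$accuracy, 0))  # per-strain mean
    }, 0)
    data.frame(task = task, mean_accuracy = mean(accs),
               sd_accuracy = stats::sd(accs))
  }))
  structure(list(splits = splits, summary = summary, config = cfg),
            class = "bow_experiment")
}

#' @export
print.bow_experiment <- function(x, ...) {
  cat(sprintf("<bow_experiment> %d split(s)\n", length(x$splits)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
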