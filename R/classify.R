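# L2-penalized multinomial logistic regression on TFIDF features, nested
# cross-validation for the regularization hyperparameter, and
# leave-one-individual-out evaluation with per-individual pooled prediction.

#' Default regularization grid
#'
#' 15 logarithmically spaced values from 1e-1 to 1e4 inclusive (consecutive
#' ratio 10^(5/14)).
#' @return Numeric vector of length 15.
#' @export
default_c_grid <- function() 10^seq(-1, 4, length.out = 15L)

#' Fit an L2-penalized multinomial logistic regression
#'
#' Minimizes the penalized negative mean log-likelihood
#' `-(1/N) sum log p(y_s | x_s) + lambda * sum_y ||beta(y)||^2` with
#' `lambda = 1 / (2 * N * C)`, so larger `C` means weaker regularization.
#' A true multinomial softmax is used (also for two classes); biases are
#' unpenalized.  Training feature means are stored for Shapley attribution.
#'
#' @param X feature matrix (rows = training segments).
#' @param y class labels (coerced to factor; >= 2 classes required).
#' @param C inverse-regularization hyperparameter (> 0).
#' @param tol relative convergence tolerance on the objective.
#' @return A `bow_classifier`: `classes`, `beta0` (per class), `beta`
#'   (classes x D), `C`, `lambda`, `feature_means`, `n_train`, `objective`.
#' @export
fit_multinomial <- function(X, y, C = 1, tol = 1e-8) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop_config("training set contains a single class")
  if (C <= 0) stop_config("C must be > 0")
  n <- nrow(X); D <- ncol(X); G <- nlevels(y)
  lambda <- 1 / (2 * n * C)
  Ymat <- diag(G)[as.integer(y), , drop = FALSE]
  unpack <- function(par) {
    list(b0 = par[seq_len(G)],
         B = matrix(par[-seq_len(G)], nrow = G, ncol = D))
  }
  softmax_scores <- function(S) {
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    E / rowSums(E)
  }
  obj <- function(par) {
    p <- unpack(par)
    S <- sweep(X %*% t(p$B), 2L, p$b0, `+`)
    lse <- apply(S, 1L, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
    -(mean(rowSums(S * Ymat) - lse)) + lambda * sum(p$B^2)
  }
  grad <- function(par) {
    p <- unpack(par)
    S <- sweep(X %*% t(p$B), 2L, p$b0, `+`)
    Pm <- softmax_scores(S)
    R <- Pm - Ymat
    c(colMeans(R), as.vector(t(R) %*% X / n + 2 * lambda * p$B))
  }
  fit <- stats::optim(numeric(G * (D + 1L)), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 2000L,
                                     factr = tol / .Machine$double.eps))
  p <- unpack(fit$par)
  structure(list(classes = levels(y), beta0 = stats::setNames(p$b0, levels(y)),
                 beta = `rownames<-`(p$B, levels(y)), C = C, lambda = lambda,
                 feature_means = colMeans(X), n_train = n,
                 objective = fit$value, convergence = fit$convergence),
            class = "bow_classifier")
}

#' Predict class probabilities
#'
#' @param model a `bow_classifier`.
#' @param X feature matrix (or single feature vector).
#' @return Matrix of softmax probabilities, one row per input, columns named
#'   by class; each row sums to 1.
#' @export
predict_proba <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(model$beta))
    stop_config("feature dimension mismatch: %d vs model's %d",
                ncol(X), ncol(model$beta))
  S <- sweep(X %*% t(model$beta), 2L, model$beta0, `+`)
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  P <- E / rowSums(E)
  colnames(P) <- model$classes
  P
}

#' Factorized joint prediction
#'
#' Combines a marginal model for the first label component (e.g. strain)
#' with per-component conditional models for the second (e.g. TSC genotype):
#' `p(y1, y2 | x) = p1(y1 | x) * p2(y2 | x, y1)`.
#'
#' @param strain_model `bow_classifier` for the first component.
#' @param conditional_models named list (by first-component class) of
#'   `bow_classifier`s for the second component.
#' @param X feature matrix or vector.
#' @return Probability matrix over joint labels `"y1:y2"`; rows sum to 1 and
#'   the marginal over y2 recovers the first-component model's output.
#' @export
factorized_predict <- function(strain_model, conditional_models, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  missing <- setdiff(strain_model$classes, names(conditional_models))
  if (length(missing))
    stop_config("missing conditional model for: %s",
                paste(missing, collapse = ", "))
  P1 <- predict_proba(strain_model, X)
  blocks <- lapply(strain_model$classes, function(y1) {
    P2 <- predict_proba(conditional_models[[y1]], X)
    out <- P1[, y1] * P2
    colnames(out) <- genotype_label(y1, colnames(P2))
    out
  })
  do.call(cbind, blocks)
}

#' Majority-class baseline accuracy
#'
#' @param labels vector of class labels (one per individual).
#' @return Fraction of the most frequent class.
#' @export
majority_baseline <- function(labels) {
  if (!length(labels)) stop_config("need at least one label")
  max(table(labels)) / length(labels)
}

# ---- cross-validation machinery -------------------------------------------

#' Stratified, grouped fold assignment
#'
#' Assigns individuals (groups) to `k` folds so that each class's
#' individuals are spread as evenly as possible across folds; within a
#' class, individuals are shuffled under the seed and dealt to the fold
#' with the fewest members of that class (ties to the smallest fold, then
#' the lowest fold index).
#'
#' @param ids individual identifiers.
#' @param labels class label per individual (same order as `ids`).
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold index (1..k) named by individual id.
#' @export
stratified_group_folds <- function(ids, labels, k, seed = 1L) {
  if (k < 2L) stop_config("need k >= 2 folds")
  if (length(ids) < k) stop_config("fewer individuals (%d) than folds (%d)",
                                   length(ids), k)
  fold <- stats::setNames(integer(length(ids)), ids)
  class_count <- matrix(0L, nrow = k, ncol = length(unique(labels)),
                        dimnames = list(NULL, unique(labels)))
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- ids[labels == cl]
      members <- members[sample.int(length(members))]
      for (m in members) {
        tot <- rowSums(class_count)
        ord <- order(class_count[, cl], tot, seq_len(k))
        f <- ord[1]
        fold[m] <- f
        class_count[f, cl] <- class_count[f, cl] + 1L
      }
    }
  })
  fold
}

# Pooled per-individual and segment-wise accuracy of a fitted model on a
# set of individuals, given per-individual bag lists and a fitted TFIDF.
eval_on_individuals <- function(model, bags_by_ind, labels, ids, tfidf) {
  pooled <- t(vapply(ids, function(s) {
    x <- tfidf_transform(pool_bags(bags_by_ind[[s]]), tfidf)
    predict_proba(model, x)[1, ]
  }, numeric(length(model$classes))))
  colnames(pooled) <- model$classes
  pred <- model$classes[max.col(pooled, ties.method = "first")]
  seg_correct <- unlist(lapply(ids, function(s) {
    Xs <- tfidf_transform(bags_by_ind[[s]], tfidf)
    Ps <- predict_proba(model, Xs)
    model$classes[max.col(Ps, ties.method = "first")] == labels[[s]]
  }))
  list(pooled_probs = pooled, pooled_pred = stats::setNames(pred, ids),
       pooled_acc = mean(pred == unlist(labels[ids])),
       segment_acc = mean(seg_correct))
}

train_set_fit <- function(bags_by_ind, labels, train_ids, C) {
  train_bags <- unlist(lapply(train_ids, function(s) bags_by_ind[[s]]),
                       recursive = FALSE)
  tfidf <- fit_tfidf(train_bags)
  Xtr <- tfidf_transform(train_bags, tfidf)
  ytr <- unlist(lapply(train_ids, function(s)
    rep(labels[[s]], length(bags_by_ind[[s]]))))
  list(model = fit_multinomial(Xtr, ytr, C), tfidf = tfidf)
}

#' Nested-CV selection of the regularization hyperparameter
#'
#' For each candidate `C` and each of `KCV` stratified, individual-grouped
#' folds of the non-dictionary training individuals, a model is trained on
#' the dictionary-fold individuals plus the remaining inner folds (TFIDF
#' refit on exactly that training set) and scored on the held-out fold.
#' The `C` with the highest mean pooled per-individual accuracy wins; ties
#' break by mean segment-wise accuracy, then by the smallest `C`.
#'
#' @param bags_by_ind named list: per individual, a list of segment
#'   `bow_bag`s.
#' @param labels named list/vector of class labels per individual.
#' @param dict_ids individuals of the dictionary fold (always in training).
#' @param train0_ids non-dictionary training individuals to cross-validate.
#' @param grid candidate `C` values.
#' @param KCV number of inner folds (capped at `length(train0_ids)`).
#' @param seed integer seed for the fold assignment.
#' @return List with `C` (the selection), and `table` of per-`C` mean
#'   pooled and segment accuracies.
#' @export
select_hyperparameter <- function(bags_by_ind, labels, dict_ids, train0_ids,
                                  grid = default_c_grid(), KCV = 3L,
                                  seed = 1L) {
  if (!length(grid)) stop_config("hyperparameter grid is empty")
  if (length(unique(unlist(labels[train0_ids]))) < 2L)
    stop_config("inner-CV training individuals carry a single class")
  k <- min(KCV, length(train0_ids))
  if (k < 2L) stop_config("need at least 2 non-dictionary training individuals")
  fold <- stratified_group_folds(train0_ids,
                                 unlist(labels[train0_ids]), k, seed)
  acc <- matrix(NA_real_, length(grid), k)
  seg <- matrix(NA_real_, length(grid), k)
  for (f in seq_len(k)) {
    val_ids <- names(fold)[fold == f]
    tr_ids <- c(dict_ids, names(fold)[fold != f])
    for (ci in seq_along(grid)) {
      fitres <- train_set_fit(bags_by_ind, labels, tr_ids, grid[ci])
      ev <- eval_on_individuals(fitres$model, bags_by_ind, labels, val_ids,
                                fitres$tfidf)
      acc[ci, f] <- ev$pooled_acc
      seg[ci, f] <- ev$segment_acc
    }
  }
  pooled_mean <- rowMeans(acc)
  seg_mean <- rowMeans(seg)
  best <- order(-pooled_mean, -seg_mean, grid)[1]
  list(C = grid[best],
       table = data.frame(C = grid, pooled_accuracy = pooled_mean,
                          segment_accuracy = seg_mean))
}

#' Leave-one-individual-out evaluation for one dictionary fold
#'
#' The dictionary was fit on `dict_ids`; every individual in `eval_ids` is
#' held out in turn: `C` is selected by nested CV on the remaining
#' non-dictionary individuals, a model is fit on everyone else (TFIDF
#' re-estimated on that training set's segment bags), and the held-out
#' individual is predicted from its pooled bag.
#'
#' @inheritParams select_hyperparameter
#' @param eval_ids individuals of the non-dictionary fold (each held out
#'   in turn; >= 2 required).
#' @param store_models keep each held-out individual's fitted model and
#'   TFIDF (needed for Shapley analysis).
#' @return A `bow_loo`: per-individual predictions and probabilities,
#'   chosen `C`s, and optionally the per-individual models.
#' @export
loo_evaluate <- function(bags_by_ind, labels, dict_ids, eval_ids,
                         grid = default_c_grid(), KCV = 3L, seed = 1L,
                         store_models = FALSE) {
  if (length(intersect(dict_ids, eval_ids)))
    stop_config("individuals present in both folds: %s",
                paste(intersect(dict_ids, eval_ids), collapse = ", "))
  if (length(eval_ids) < 2L)
    stop_config("cannot run leave-one-out with fewer than 2 evaluation individuals")
  res <- lapply(eval_ids, function(s) {
    train0 <- setdiff(eval_ids, s)
    sel <- select_hyperparameter(bags_by_ind, labels, dict_ids, train0,
                                 grid, KCV, seed = derive_seed(seed, match(s, eval_ids)))
    fitres <- train_set_fit(bags_by_ind, labels, c(dict_ids, train0), sel$C)
    x_pooled <- tfidf_transform(pool_bags(bags_by_ind[[s]]), fitres$tfidf)
    probs <- predict_proba(fitres$model, x_pooled)[1, ]
    seg_probs <- predict_proba(fitres$model,
                               tfidf_transform(bags_by_ind[[s]], fitres$tfidf))
    list(id = s, truth = labels[[s]], C = sel$C, probs = probs,
         pred = fitres$model$classes[which.max(probs)],
         seg_pred = fitres$model$classes[max.col(seg_probs, ties.method = "first")],
         model = if (store_models) fitres$model,
         tfidf = if (store_models) fitres$tfidf)
  })
  classes <- sort(unique(unlist(labels)))
  probs <- do.call(rbind, lapply(res, function(r) {
    p <- stats::setNames(rep(0, length(classes)), classes)
    p[names(r$probs)] <- r$probs
    p
  }))
  rownames(probs) <- eval_ids
  structure(list(
    individuals = data.frame(
      individual_id = eval_ids,
      truth = vapply(res, `[[`, "", "truth"),
      predicted = vapply(res, `[[`, "", "pred"),
      C = vapply(res, `[[`, 0, "C")),
    probs = probs,
    segment_predictions = lapply(stats::setNames(res, eval_ids), `[[`, "seg_pred"),
    models = if (store_models) lapply(stats::setNames(res, eval_ids), `[[`, "model"),
    tfidfs = if (store_models) lapply(stats::setNames(res, eval_ids), `[[`, "tfidf"),
    dict_ids = dict_ids, eval_ids = eval_ids),
    class = "bow_loo")
}

#' Assemble an evaluation report from LOO predictions
#'
#' @param truth,predicted label vectors aligned over all evaluated
#'   individuals.
#' @param probs probability matrix (rows = individuals, columns = classes).
#' @param positive_class optional class for binary sensitivity/specificity
#'   and ROC/AUC.
#' @return A `bow_report`: confusion matrix, accuracy, per-class
#'   sensitivity/specificity, and for binary tasks ROC points and AUC.
#' @export
evaluation_report <- function(truth, predicted, probs = NULL,
                              positive_class = NULL) {
  classes <- sort(unique(c(truth, predicted)))
  confusion <- table(truth = factor(truth, classes),
                     predicted = factor(predicted, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    data.frame(class = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
  out <- list(confusion = confusion, accuracy = mean(truth == predicted),
              per_class = per_class)
  if (!is.null(positive_class) && !is.null(probs)) {
    bm <- binary_metrics(probs[, positive_class], truth, positive_class)
    out <- c(out, bm[c("sensitivity", "specificity", "auc", "roc_points")])
  }
  structure(out, class = "bow_report")
}

#' @export
print.bow_report <- function(x, ...) {
  cat(sprintf("<bow_report> accuracy %.3f over %d individuals\n",
              x$accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Binary classification metrics at threshold 0.5 plus ROC/AUC
#'
#' Sensitivity is the true-positive rate for the positive class and
#' specificity the true-negative rate, both at a probability threshold of
#' 0.5; the ROC curve sweeps the threshold over the predicted probabilities
#' and the AUC is its trapezoidal area (equal to the normalized
#' Mann-Whitney U statistic).
#'
#' @param probs predicted probability of `positive_class` per case.
#' @param labels true labels.
#' @param positive_class the class scored by `probs`.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `auc`,
#'   `roc_points` (threshold, sensitivity, specificity).  When only one
#'   class is present the metrics are `NA` (undefined), not 0.
#' @export
binary_metrics <- function(probs, labels, positive_class) {
  pos <- labels == positive_class
  pred_pos <- probs > 0.5
  out <- list(
    sensitivity = if (any(pos)) mean(pred_pos[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!pred_pos[!pos]) else NA_real_,
    accuracy = mean(pred_pos == pos))
  if (any(pos) && any(!pos)) {
    r <- pROC::roc(response = pos, predictor = probs, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    out$auc <- as.numeric(pROC::auc(r))
    out$roc_points <- data.frame(threshold = r$thresholds,
                                 sensitivity = r$sensitivities,
                                 specificity = r$specificities)
  } else {
    out$auc <- NA_real_
    out$roc_points <- data.frame(threshold = numeric(0),
                                 sensitivity = numeric(0),
                                 specificity = numeric(0))
  }
  out
}

#' Leave-one-out evaluation of the TSC genotype given the true strain
#'
#' For each strain, the evaluation restricts to that strain's individuals
#' (both TSC classes): the conditional classifier is trained only on them.
#'
#' @inheritParams loo_evaluate
#' @param labels named joint labels (`"strain:tsc"`).
#' @return Named list (by strain) of `bow_loo` objects on the TSC labels.
#' @export
loo_evaluate_conditional <- function(bags_by_ind, labels, dict_ids, eval_ids,
                                     grid = default_c_grid(), KCV = 3L,
                                     seed = 1L, store_models = FALSE) {
  strains <- sort(unique(strain_of(unlist(labels))))
  out <- lapply(stats::setNames(strains, strains), function(st) {
    in_strain <- names(labels)[strain_of(unlist(labels)) == st]
    loo_evaluate(bags_by_ind[intersect(names(bags_by_ind), in_strain)],
                 lapply(labels[in_strain], tsc_of),
                 intersect(dict_ids, in_strain),
                 intersect(eval_ids, in_strain),
                 grid, KCV, seed, store_models)
  })
  out
}

#' Leave-one-out factorized joint prediction
#'
#' For each held-out individual, a strain (first-component) model and
#' per-strain conditional TSC models are fit on the remaining individuals,
#' each with its own nested-CV hyperparameter selection and TFIDF, and the
#' joint probability is the product `p1(y1|x) * p2(y2|x, y1)`.
#'
#' @inheritParams loo_evaluate
#' @param labels named joint labels (`"strain:tsc"`).
#' @return A `bow_loo` over the joint labels.
#' @export
loo_evaluate_factorized <- function(bags_by_ind, labels, dict_ids, eval_ids,
                                    grid = default_c_grid(), KCV = 3L,
                                    seed = 1L) {
  if (length(intersect(dict_ids, eval_ids)))
    stop_config("individuals present in both folds")
  strain_labels <- lapply(labels, strain_of)
  tsc_labels <- lapply(labels, tsc_of)
  strains <- sort(unique(unlist(strain_labels)))
  res <- lapply(eval_ids, function(s) {
    train0 <- setdiff(eval_ids, s)
    # strain (marginal) model
    sel1 <- select_hyperparameter(bags_by_ind, strain_labels, dict_ids,
                                  train0, grid, KCV,
                                  seed = derive_seed(seed, match(s, eval_ids)))
    fit1 <- train_set_fit(bags_by_ind, strain_labels, c(dict_ids, train0),
                          sel1$C)
    # conditional TSC models, one per strain, trained on that strain only
    fits2 <- lapply(stats::setNames(strains, strains), function(st) {
      in_strain <- setdiff(names(labels)[unlist(strain_labels) == st], s)
      tr0 <- intersect(train0, in_strain)
      C2 <- if (length(tr0) >= 2L &&
                length(unique(unlist(tsc_labels[tr0]))) >= 2L) {
        select_hyperparameter(bags_by_ind, tsc_labels,
                              intersect(dict_ids, in_strain), tr0, grid, KCV,
                              seed = derive_seed(seed, 500 + match(s, eval_ids)))$C
      } else 1  # too few in-strain individuals left to cross-validate
      train_set_fit(bags_by_ind, tsc_labels, in_strain, C2)
    })
    # joint probability: product of marginal and conditional predictions,
    # each under its own model-of-record TFIDF
    pooled <- pool_bags(bags_by_ind[[s]])
    p1 <- predict_proba(fit1$model, tfidf_transform(pooled, fit1$tfidf))[1, ]
    joint <- unlist(lapply(strains, function(st) {
      p2 <- predict_proba(fits2[[st]]$model,
                          tfidf_transform(pooled, fits2[[st]]$tfidf))[1, ]
      stats::setNames(p1[st] * p2, genotype_label(st, names(p2)))
    }))
    list(id = s, truth = labels[[s]], C = sel1$C, probs = joint,
         pred = names(joint)[which.max(joint)])
  })
  classes <- sort(unique(c(unlist(labels), unlist(lapply(res, function(r)
    names(r$probs))))))
  probs <- do.call(rbind, lapply(res, function(r) {
    p <- stats::setNames(rep(0, length(classes)), classes)
    p[names(r$probs)] <- r$probs
    p
  }))
  rownames(probs) <- eval_ids
  structure(list(
    individuals = data.frame(
      individual_id = eval_ids,
      truth = vapply(res, `[[`, "", "truth"),
      predicted = vapply(res, `[[`, "", "pred"),
      C = vapply(res, `[[`, 0, "C")),
    probs = probs, dict_ids = dict_ids, eval_ids = eval_ids),
    class = "bow_loo")
}
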