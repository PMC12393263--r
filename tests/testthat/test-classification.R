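test_that("the default regularization grid is 15 log-spaced values from 1e-1 to 1e4", {
  g <- default_c_grid()
  expect_length(g, 15L)
  expect_equal(g[1], 0.1)
  expect_equal(g[15], 1e4)
  expect_equal(unique(round(diff(log10(g)), 10)), 5 / 14)
})

test_that("penalized multinomial fit reaches the optimum of an independent optimizer", {
  set.seed(14)
  n <- 45; D <- 4
  X <- matrix(rnorm(n * D), n, D)
  y <- factor(rep(c("a", "b", "c"), length.out = n))
  C <- 2
  m <- fit_multinomial(X, y, C)
  # independent oracle: nlm on a freshly written objective
  lambda <- 1 / (2 * n * C)
  Ymat <- diag(3)[as.integer(y), ]
  f <- function(par) {
    b0 <- par[1:3]; B <- matrix(par[-(1:3)], 3, D)
    S <- sweep(X %*% t(B), 2, b0, `+`)
    lse <- log(rowSums(exp(S)))
    -mean(rowSums(S * Ymat) - lse) + lambda * sum(B^2)
  }
  o <- stats::nlm(f, rep(0, 3 * (D + 1)), iterlim = 2000, gradtol = 1e-12)
  expect_lt(abs(m$objective - o$minimum) / abs(o$minimum), 1e-6)
})

test_that("separable data reach perfect training accuracy and C -> 0 shrinks to priors", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40, mean = 3), 20, 2),
             matrix(rnorm(40, mean = -3), 20, 2))
  y <- rep(c("p", "q"), each = 20)
  m <- fit_multinomial(X, y, C = 1e4)
  pred <- colnames(predict_proba(m, X))[max.col(predict_proba(m, X))]
  expect_equal(mean(pred == y), 1)
  m0 <- fit_multinomial(X, y, C = 1e-9)
  expect_lt(max(abs(m0$beta)), 1e-3)
  expect_equal(unname(predict_proba(m0, c(5, 5))[1, ]), c(0.5, 0.5),
               tolerance = 1e-3)
  expect_error(fit_multinomial(X, rep("p", 40), 1), "single class")
})

test_that("training log-likelihood is non-decreasing along the regularization path", {
  set.seed(16)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- factor(rep(c("a", "b"), 30))
  loglik <- function(m) {
    P <- predict_proba(m, X)
    mean(log(P[cbind(seq_len(60), as.integer(y))]))
  }
  lls <- vapply(c(0.01, 0.1, 1, 10, 100), function(C)
    loglik(fit_multinomial(X, y, C)), 0)
  expect_true(all(diff(lls) > -1e-8))
})

test_that("softmax probabilities normalize and match direct evaluation", {
  set.seed(18)
  for (rep in 1:100) {
    G <- sample(2:6, 1); D <- sample(2:8, 1)
    m <- structure(list(classes = paste0("c", 1:G), beta0 = rnorm(G),
                        beta = matrix(rnorm(G * D), G, D),
                        feature_means = rep(0, D)),
                   class = "bow_classifier")
    x <- rnorm(D)
    p <- predict_proba(m, x)[1, ]
    expect_equal(sum(p), 1, tolerance = 1e-12)
    sc <- exp(m$beta0 + as.vector(m$beta %*% x))
    expect_equal(unname(p), sc / sum(sc), tolerance = 1e-12)
  }
  # zero model over 6 classes -> uniform
  m6 <- structure(list(classes = paste0("c", 1:6), beta0 = rep(0, 6),
                       beta = matrix(0, 6, 3)), class = "bow_classifier")
  expect_equal(unname(predict_proba(m6, rnorm(3))[1, ]), rep(1 / 6, 6))
})

test_that("factorized joint prediction is a normalized product with consistent marginals", {
  set.seed(19)
  for (rep in 1:100) {
    D <- 4
    strains <- c("S1", "S2", "S3")
    sm <- structure(list(classes = strains, beta0 = rnorm(3),
                         beta = matrix(rnorm(3 * D), 3, D)),
                    class = "bow_classifier")
    cms <- lapply(stats::setNames(strains, strains), function(s)
      structure(list(classes = c("Het", "WT"), beta0 = rnorm(2),
                     beta = matrix(rnorm(2 * D), 2, D)),
                class = "bow_classifier"))
    x <- rnorm(D)
    J <- factorized_predict(sm, cms, x)
    expect_equal(sum(J), 1, tolerance = 1e-12)
    P1 <- predict_proba(sm, x)[1, ]
    for (s in strains) {
      marg <- sum(J[1, startsWith(colnames(J), paste0(s, ":"))])
      expect_equal(marg, unname(P1[s]), tolerance = 1e-12)
      prod_ref <- P1[s] * predict_proba(cms[[s]], x)[1, ]
      expect_equal(unname(J[1, genotype_label(s, c("Het", "WT"))]),
                   unname(prod_ref), tolerance = 1e-12)
    }
  }
  # degenerate product concentrates on the certain pair
  sm2 <- structure(list(classes = c("A", "B"), beta0 = c(50, -50),
                        beta = matrix(0, 2, 2)), class = "bow_classifier")
  cm2 <- list(
    A = structure(list(classes = c("Het", "WT"), beta0 = c(50, -50),
                       beta = matrix(0, 2, 2)), class = "bow_classifier"),
    B = structure(list(classes = c("Het", "WT"), beta0 = c(0, 0),
                       beta = matrix(0, 2, 2)), class = "bow_classifier"))
  J2 <- factorized_predict(sm2, cm2, c(0, 0))
  expect_equal(unname(J2[1, "A:Het"]), 1, tolerance = 1e-10)
  expect_error(factorized_predict(sm2, cm2["A"], c(0, 0)), "missing")
})

test_that("majority baseline reproduces the cohort worked examples", {
  expect_equal(majority_baseline(rep(c("BXD87", "DBA2", "C57B6"),
                                     c(17, 14, 14))), 17 / 45)
  expect_equal(majority_baseline(rep(letters[1:6],
                                     c(10, 9, 8, 7, 6, 5))), 10 / 45)
  expect_equal(majority_baseline(rep(c("Het", "WT"), c(10, 7))), 10 / 17)
  expect_equal(majority_baseline(rep(c("Het", "WT"), c(8, 6))), 8 / 14)
  expect_equal(majority_baseline(rep("x", 9)), 1)
})

test_that("stratified grouped folds spread classes and are seeded", {
  ids <- sprintf("m%02d", 1:12)
  labs <- rep(c("A", "B"), each = 6)
  f <- stratified_group_folds(ids, labs, 3, seed = 5)
  expect_equal(sort(unique(f)), 1:3)
  for (k in 1:3) {
    expect_equal(sum(f == k & labs == "A"), 2L)
    expect_equal(sum(f == k & labs == "B"), 2L)
  }
  expect_identical(f, stratified_group_folds(ids, labs, 3, seed = 5))
  expect_false(identical(f, stratified_group_folds(ids, labs, 3, seed = 6)))
})

test_that("binary metrics match rank-based AUC and handle degenerate inputs", {
  probs <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labs <- c("H", "H", "H", "W", "W", "W")
  bm <- binary_metrics(probs, labs, "H")
  expect_equal(bm$sensitivity, 1)
  expect_equal(bm$specificity, 1)
  expect_equal(bm$auc, 1)
  # AUC equals the Mann-Whitney statistic on a random instance
  set.seed(22)
  for (rep in 1:20) {
    p <- runif(14)
    l <- sample(c("H", "W"), 14, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(l)) < 2) next
    bm2 <- binary_metrics(p, l, "H")
    npos <- sum(l == "H"); nneg <- sum(l == "W")
    U <- sum(rank(p)[l == "H"]) - npos * (npos + 1) / 2
    expect_equal(bm2$auc, U / (npos * nneg), tolerance = 1e-12)
  }
  # uninformative probabilities give AUC 0.5 under tie handling
  bm3 <- binary_metrics(rep(0.5, 8), rep(c("H", "W"), 4), "H")
  expect_equal(bm3$auc, 0.5)
  # one class absent -> undefined, not zero
  bm4 <- binary_metrics(runif(5), rep("H", 5), "H")
  expect_true(is.na(bm4$specificity))
  expect_true(is.na(bm4$auc))
})

test_that("hyperparameter selection returns the singleton grid and breaks ties low", {
  cohort <- two_class_cohort(n_per_class = 3, duration = 240, rate = 8,
                             noise_sd = 0.2, seed = 31)
  enc <- encode_cohort(cohort, dict_ids = c("A_01", "B_01"), K = 4,
                       M_train = 150, Q = 256 * 60,
                       segments_per_individual = 2, seed = 3)
  labels <- enc$labels
  train0 <- c("A_02", "A_03", "B_02", "B_03")
  sel1 <- select_hyperparameter(enc$bags, labels, c("A_01", "B_01"), train0,
                                grid = 3.14, KCV = 2, seed = 1)
  expect_equal(sel1$C, 3.14)
  sel <- select_hyperparameter(enc$bags, labels, c("A_01", "B_01"), train0,
                               grid = c(10, 100, 1000), KCV = 2, seed = 1)
  tab <- sel$table
  best <- tab[order(-tab$pooled_accuracy, -tab$segment_accuracy, tab$C), ][1, ]
  expect_equal(sel$C, best$C)
  expect_error(select_hyperparameter(enc$bags, labels, c("A_01", "B_01"),
                                     train0, grid = numeric(0)), "empty")
})

test_that("leave-one-out evaluation rejects degenerate fold plans", {
  cohort <- two_class_cohort(n_per_class = 2, duration = 120, seed = 33)
  enc <- encode_cohort(cohort, dict_ids = c("A_01", "B_01"), K = 3,
                       M_train = 80, Q = 256 * 30,
                       segments_per_individual = 2, seed = 5)
  expect_error(loo_evaluate(enc$bags, enc$labels, c("A_01", "B_01"),
                            c("A_01", "B_02")), "both folds")
  expect_error(loo_evaluate(enc$bags, enc$labels,
                            c("A_01", "B_01", "B_02"), "A_02"),
               "fewer than 2")
})

test_that("factorized and conditional LOO recover strain- and tsc-specific signals", {
  # synthetic bags over 12 features: features 1-3 separate the 2 strains,
  # features 4-5 separate Het/WT within each strain
  set.seed(55)
  strains <- c("S1", "S2")
  ids <- as.vector(outer(letters[1:6], seq_along(strains),
                         function(x, j) paste0(strains[j], "_", x)))
  labels <- stats::setNames(as.list(genotype_label(
    rep(strains, each = 6), rep(c("Het", "WT"), 6))), ids)
  mk_bag <- function(counts, id) structure(
    list(counts = counts, M = sum(counts),
         dict_index = data.frame(dict = 1, class_label = "X",
                                 waveform = seq_along(counts)),
         individual_id = id, duration_s = 600), class = "bow_bag")
  bags <- stats::setNames(lapply(ids, function(id) {
    lapply(1:3, function(s) {
      z <- rpois(12, 30)
      if (strain_of(labels[[id]]) == "S2") z[1:3] <- z[1:3] + 50
      if (tsc_of(labels[[id]]) == "Het") z[4:5] <- z[4:5] + 60
      mk_bag(z, id)
    })
  }), ids)
  dict_ids <- ids[c(1, 2, 7, 8)]   # 2 per strain, both tsc classes
  eval_ids <- setdiff(ids, dict_ids)
  fl <- loo_evaluate_factorized(bags, labels, dict_ids, eval_ids,
                                grid = c(1, 100), KCV = 2, seed = 3)
  expect_equal(mean(fl$individuals$truth == fl$individuals$predicted), 1)
  expect_equal(unname(rowSums(fl$probs)), rep(1, length(eval_ids)),
               tolerance = 1e-9)
  cl <- loo_evaluate_conditional(bags, labels, dict_ids, eval_ids,
                                 grid = c(1, 100), KCV = 2, seed = 4)
  expect_setequal(names(cl), strains)
  for (st in strains)
    expect_equal(mean(cl[[st]]$individuals$truth ==
                        cl[[st]]$individuals$predicted), 1)
})
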