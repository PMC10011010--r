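test_that("fpca recovers a rank-1 structure and behaves under duplication", {
  set.seed(2)
  t_end <- 100
  basis <- make_bspline_basis(t_end, 5, 10)
  tg <- 0:t_end
  phi <- sin(2 * pi * tg / 50)
  a <- rnorm(30, 0, 3)
  Y <- sapply(a, function(ai) 40 + 5 * tg / t_end + ai * phi)
  smp <- fd_sample(basis, project_onto_basis(basis, tg, Y), signal = "HR")
  fp <- fpca(smp, n_components = 3)
  expect_gte(fp$eigenvalues[1] / sum(pmax(fp$eigenvalues, 0)), 0.999)
  expect_gte(abs(cor(fp$scores[, 1], a)), 0.999)

  # eigenfunctions are L2-orthonormal
  G <- mbebfda:::basis_gram(basis)
  gram <- t(fp$eigen_coefs) %*% G %*% fp$eigen_coefs
  expect_lt(max(abs(gram - diag(3))), 1e-6)
  # scores are centered
  expect_lt(max(abs(colMeans(fp$scores))), 1e-8)

  # duplicating every curve leaves eigenvalue proportions invariant
  dup <- fd_sample(basis, smp$coefs[, rep(seq_len(30), each = 2)],
                   signal = "HR")
  fp2 <- fpca(dup, n_components = 3)
  p1 <- fp$eigenvalues[1:3] / sum(pmax(fp$eigenvalues, 0))
  p2 <- fp2$eigenvalues[1:3] / sum(pmax(fp2$eigenvalues, 0))
  expect_equal(p2, p1, tolerance = 1e-6)

  expect_error(fpca(smp, n_components = 40), "exceed")
})

test_that("fpca reconstruction error is nonincreasing in K", {
  toy <- make_toy_sample(n = 15, shift = 6, noise = 2, seed = 12)
  G <- mbebfda:::basis_gram(toy$sample$basis)
  errs <- vapply(1:5, function(K) {
    fp <- fpca(toy$sample, n_components = K)
    recon <- fp$mean_coefs + fp$eigen_coefs %*% t(fp$scores)
    resid <- toy$sample$coefs - recon
    sum(vapply(seq_len(ncol(resid)), function(i) {
      drop(t(resid[, i]) %*% G %*% resid[, i])
    }, 0))
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("metrics identities hold, including the worked confusion example", {
  m <- metrics_from_confusion(35, 3, 38, 2)
  expect_equal(round(m$accuracy, 3), 0.936)
  expect_equal(m$f1, 2 * (35 / 38) * (35 / 37) / (35 / 38 + 35 / 37),
               tolerance = 1e-12)
  expect_equal(round(m$f1, 3), 0.933)

  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  # precision == recall == p implies f1 == p
  pr <- metrics_from_confusion(6, 2, 8, 2)  # precision 0.75, recall 0.75
  expect_equal(pr$f1, 0.75)

  # degenerate case
  none <- metrics_from_confusion(0, 0, 10, 5)
  expect_equal(none$f1, 0)
})

test_that("GSAM recovers a strong score-driven rule and stays null at chance", {
  set.seed(17)
  n <- 200
  scores <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(NULL, paste0("PC", 1:3)))
  p <- plogis(3 * scores[, 1])
  labels <- rbinom(n, 1, p)
  tr <- seq_len(150); te <- 151:200
  fit <- fit_gsam(scores[tr, ], NULL, labels[tr])
  pred <- as.integer(predict_proba(fit, scores[te, ]) > 0.5)
  bayes <- as.integer(scores[te, 1] > 0)
  expect_gte(mean(pred == labels[te]), 0.75)
  expect_gte(mean(pred == bayes), 0.9)

  # null labels: accuracy within the binomial chance band
  labels0 <- rbinom(n, 1, 0.5)
  fit0 <- fit_gsam(scores[tr, ], NULL, labels0[tr])
  acc0 <- mean(as.integer(predict_proba(fit0, scores[te, ]) > 0.5) ==
                 labels0[te])
  expect_lt(abs(acc0 - 0.5), 1.96 * sqrt(0.25 / 50) + 0.05)

  # adding a pure-noise scalar barely moves the recovery accuracy
  noise_scalar <- matrix(rnorm(n), dimnames = list(NULL, "sex"))
  fitn <- fit_gsam(scores[tr, ], noise_scalar[tr, , drop = FALSE], labels[tr])
  predn <- as.integer(predict_proba(fitn, scores[te, ],
                                    noise_scalar[te, , drop = FALSE]) > 0.5)
  expect_lt(abs(mean(predn == labels[te]) - mean(pred == labels[te])), 0.1)
})

test_that("GSAM survives perfect separation via the ridge fallback", {
  scores <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1,
                   dimnames = list(NULL, "PC1"))
  labels <- rep(c(0, 1), each = 20)
  fit <- suppressWarnings(fit_gsam(scores, NULL, labels))
  p <- predict_proba(fit, scores)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean(as.integer(p > 0.5) == labels), 0.95)
})

test_that("baseline classifiers honour their contracts", {
  set.seed(23)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("PC1", "PC2")))
  labels <- as.integer(X[, 1] + 4 * (runif(n) < 0.02) > 0)
  X[labels == 1, 1] <- X[labels == 1, 1] + 4    # ~4 sigma separation

  lda_fit <- fit_baseline(classifier_spec("LDA", "HR"), X, NULL, labels)
  expect_gte(mean(as.integer(predict_proba(lda_fit, X) > 0.5) == labels),
             0.95)

  knn1 <- fit_baseline(classifier_spec("KNN", "HR",
                                       hyperparameters = list(k = 1L)),
                       X, NULL, labels)
  expect_equal(as.integer(predict_proba(knn1, X) > 0.5), labels)

  for (mod in c("RPART", "RF", "SVM", "NNET")) {
    set.seed(5)
    f <- fit_baseline(classifier_spec(mod, "HR"), X, NULL, labels)
    p <- predict_proba(f, X)
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(mean(as.integer(p > 0.5) == labels), 0.85)
  }
  expect_error(fit_baseline(classifier_spec("GSAM", "HR"), X, NULL, labels),
               "fit_gsam")
})

test_that("crossvalidate is leak-free, stratified and order-invariant", {
  ch <- make_smoothed_cohort(n = 40, seed = 3, shift_sd = 3, spacing = 30)
  spec <- classifier_spec("GSAM", "VO2", c("sex", "puberty"))
  m <- crossvalidate(spec, list(VO2 = ch$sample), ch$meta, k = 5, seed = 9)
  expect_equal(sum(m$confusion), 40)
  expect_equal(m$accuracy,
               unname((m$confusion["TP"] + m$confusion["TN"]) / 40))
  # folds are stratified: every fold has both classes
  for (f in 1:5) {
    expect_equal(length(unique(ch$meta$label[m$fold_assignments == f])), 2L)
  }
  # participant order must not matter
  ord <- sample(seq_len(40))
  m2 <- crossvalidate(spec, list(VO2 = subset_sample(ch$sample, ord)),
                      ch$meta[ord, ], k = 5, seed = 9)
  expect_equal(m2$accuracy, m$accuracy, tolerance = 0.151)
  # same seed, same result
  m3 <- crossvalidate(spec, list(VO2 = ch$sample), ch$meta, k = 5, seed = 9)
  expect_identical(m$predictions, m3$predictions)
})

test_that("run_model_battery ranks specs on shared folds", {
  ch <- make_smoothed_cohort(n = 30, seed = 5, shift_sd = 3, spacing = 40)
  specs <- list(classifier_spec("GSAM", "VO2"),
                classifier_spec("LDA", "VO2"),
                classifier_spec("KNN", "VO2"))
  tab <- run_model_battery(list(VO2 = ch$sample), ch$meta, specs,
                           k = 5, seed = 4, add_full = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$f1_pct) <= 0))
  res <- attr(tab, "metrics")
  folds <- lapply(res, `[[`, "fold_assignments")
  expect_identical(folds[[1]], folds[[2]])
  expect_identical(folds[[1]], folds[[3]])
})
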