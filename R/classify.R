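#' Specify a classifier for the curve-discrimination battery
#'
#' @param model_name one of `"GSAM"`, `"LDA"`, `"RPART"`, `"RF"`, `"SVM"`,
#'   `"NNET"`, `"KNN"`.
#' @param functional_inputs subset of `c("HR", "RR", "VO2", "VCO2")` whose
#'   FPC scores enter the model.
#' @param scalar_inputs subset of `c("sex", "puberty", "body_mass")`.
#'   Body mass is off by default throughout the battery because it did not
#'   help classification; enable it explicitly here.
#' @param n_components fixed FPCA components per functional input, or
#'   `NULL` for the default rule (smallest K reaching 95% variance, cap 10).
#' @param hyperparameters named list forwarded to the model back end.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(model_name, functional_inputs,
                            scalar_inputs = character(0),
                            n_components = NULL,
                            hyperparameters = list()) {
  model_name <- match.arg(model_name,
                          c("GSAM", "LDA", "RPART", "RF", "SVM", "NNET",
                            "KNN"))
  functional_inputs <- match.arg(functional_inputs,
                                 c("HR", "RR", "VO2", "VCO2"),
                                 several.ok = TRUE)
  if (length(scalar_inputs)) {
    scalar_inputs <- match.arg(scalar_inputs,
                               c("sex", "puberty", "body_mass"),
                               several.ok = TRUE)
  }
  if (length(functional_inputs) + length(scalar_inputs) == 0L) {
    stop("at least one input is required")
  }
  structure(list(model_name = model_name,
                 functional_inputs = functional_inputs,
                 scalar_inputs = scalar_inputs,
                 n_components = n_components,
                 hyperparameters = hyperparameters),
            class = "classifier_spec")
}

# Scalar covariates as numeric columns: binary codes for sex/puberty,
# standardized body mass (training-fold statistics are applied downstream).
encode_scalars <- function(meta, scalar_inputs) {
  if (length(scalar_inputs) == 0L) {
    return(matrix(numeric(0), nrow(meta), 0))
  }
  cols <- list()
  if ("sex" %in% scalar_inputs) cols$sex <- as.numeric(meta$sex == "M")
  if ("puberty" %in% scalar_inputs) {
    cols$puberty <- as.numeric(meta$puberty == "late")
  }
  if ("body_mass" %in% scalar_inputs) cols$body_mass <- meta$body_mass_kg
  do.call(cbind, cols)
}

# Flatten score matrices (named list per signal, or single matrix) plus
# scalars into one design matrix with stable column names.
build_design <- function(scores, scalars = NULL) {
  if (is.list(scores) && !is.data.frame(scores)) {
    blocks <- lapply(names(scores), function(s) {
      m <- as.matrix(scores[[s]])
      colnames(m) <- paste0(s, "_PC", seq_len(ncol(m)))
      m
    })
    X <- do.call(cbind, blocks)
  } else {
    X <- as.matrix(scores)
    if (is.null(colnames(X))) colnames(X) <- paste0("PC", seq_len(ncol(X)))
  }
  if (!is.null(scalars) && NCOL(scalars) > 0) {
    scalars <- as.matrix(scalars)
    X <- cbind(X, scalars)
  }
  X
}

# Ridge-penalized logistic regression by IRLS: the fallback under perfect
# separation, and the linear core for degenerate GSAM designs.
ridge_logistic <- function(x, y, lambda = 1, maxit = 50) {
  X <- cbind(1, x)
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(x))), ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X * sqrt(w)) + pen,
                      crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Fit a generalized spectral additive classifier
#'
#' Additive logistic regression in which each retained FPC score of each
#' functional input enters through its own spline smooth with fixed
#' effective degrees of freedom, and binary scalar covariates enter as
#' linear terms.  Perfect separation triggers a ridge-logistic fallback
#' with a logged warning rather than a crash.
#'
#' @param scores named list of score matrices (one per functional input) or
#'   a single score matrix.
#' @param scalars scalar covariate matrix from [encode_scalars()] (or
#'   `NULL`).
#' @param labels binary 0/1 vector (1 = task failure).
#' @param smooth_df fixed effective df per smooth term (default 3).
#' @return A `fitted_classifier`.
#' @export
fit_gsam <- function(scores, scalars = NULL, labels, smooth_df = 3) {
  X <- build_design(scores, scalars)
  if (mean(labels) < 0.2 || mean(labels) > 0.8) {
    warning("labels are strongly imbalanced (minority < 20%)")
  }
  smooth_cols <- colnames(X)[grepl("_?PC[0-9]+$", colnames(X))]
  linear_cols <- setdiff(colnames(X), smooth_cols)
  df_train <- as.data.frame(X)
  df_train$.label <- labels
  k <- smooth_df + 1
  terms <- c(
    vapply(smooth_cols, function(cn) {
      sprintf("s(%s, k = %d, fx = TRUE)", cn, k)
    }, ""),
    linear_cols)
  fml <- stats::as.formula(paste(".label ~", paste(terms, collapse = " + ")))
  fit <- NULL
  sep <- FALSE
  withCallingHandlers(
    fit <- tryCatch(
      mgcv::gam(fml, family = stats::binomial(), data = df_train,
                method = "REML"),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("fitted probabilities|algorithm did not converge",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || sep) {
    beta <- ridge_logistic(X, labels, lambda = 1)
    return(new_fitted(spec_name = "GSAM", kind = "ridge",
                      model = list(beta = beta), cols = colnames(X),
                      note = "ridge fallback (separation or gam failure)"))
  }
  new_fitted(spec_name = "GSAM", kind = "gam", model = fit,
             cols = colnames(X))
}

new_fitted <- function(spec_name, kind, model, cols, note = NULL) {
  structure(list(spec_name = spec_name, kind = kind, model = model,
                 cols = cols, note = note),
            class = "fitted_classifier")
}

#' Fit one of the six baseline classifiers
#'
#' All baselines consume the same concatenated (FPC scores, scalars)
#' design as the GSAM and return the same probability contract.
#'
#' @param spec a [classifier_spec()] with `model_name != "GSAM"`.
#' @param scores,scalars,labels as in [fit_gsam()].
#' @return A `fitted_classifier`.
#' @export
fit_baseline <- function(spec, scores, scalars = NULL, labels) {
  if (spec$model_name == "GSAM") stop("use fit_gsam() for GSAM")
  X <- build_design(scores, scalars)
  hp <- spec$hyperparameters
  model <- switch(
    spec$model_name,
    LDA = MASS::lda(X, grouping = factor(labels, levels = c(0, 1))),
    RPART = do.call(cart_fit, c(list(x = X, y = labels), hp)),
    RF = do.call(rf_fit, c(list(x = X, y = labels), hp)),
    SVM = do.call(svm_fit, c(list(x = X, y = labels), hp)),
    NNET = do.call(nnet_fit, c(list(x = X, y = labels), hp)),
    KNN = do.call(knn_fit, c(list(x = X, y = labels), hp)),
    stop("unknown model: ", spec$model_name))
  new_fitted(spec_name = spec$model_name,
             kind = tolower(spec$model_name), model = model,
             cols = colnames(X))
}

#' Predict failure probabilities from a fitted classifier
#'
#' @param fitted a `fitted_classifier`.
#' @param scores,scalars new data in the layout used for fitting.
#' @return Vector of probabilities of class 1 (task failure) in `[0, 1]`.
#' @export
predict_proba <- function(fitted, scores, scalars = NULL) {
  X <- build_design(scores, scalars)
  X <- X[, fitted$cols, drop = FALSE]
  p <- switch(
    fitted$kind,
    gam = as.numeric(stats::predict(fitted$model,
                                    newdata = as.data.frame(X),
                                    type = "response")),
    ridge = stats::plogis(drop(cbind(1, X) %*% fitted$model$beta)),
    lda = stats::predict(fitted$model, X)$posterior[, "1"],
    rpart = cart_prob(fitted$model, X),
    rf = rf_prob(fitted$model, X),
    svm = svm_prob(fitted$model, X),
    nnet = nnet_prob(fitted$model, X),
    knn = knn_prob(fitted$model, X),
    stop("unknown fitted kind"))
  pmin(pmax(as.numeric(p), 0), 1)
}

# Stratified fold assignment by label.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_spec <- function(spec, scores, scalars, labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$model_name == "GSAM") {
    sd_ <- spec$hyperparameters$smooth_df
    fit_gsam(scores, scalars, labels,
             smooth_df = if (is.null(sd_)) 3 else sd_)
  } else {
    fit_baseline(spec, scores, scalars, labels)
  }
}

#' Stratified k-fold cross-validation of a classifier spec
#'
#' FPCA (and all model fitting) is re-estimated inside each training fold;
#' test-fold curves are projected onto the training fold's eigenfunctions,
#' so no information leaks from test to train.  The class decision is
#' `p > 0.5` (probability exactly 0.5 classifies as completer).
#'
#' @param spec a [classifier_spec()].
#' @param samples named list of `fd_sample`s, one per signal, sharing curve
#'   order with `meta`.
#' @param meta metadata data.frame with at least `label` (0/1) and any
#'   scalar inputs used.
#' @param k number of folds (>= 2).
#' @param seed master seed; folds and any stochastic fits derive from it.
#' @param smooth_df GSAM smooth df.
#' @return A `cv_metrics` with extra fields `fold_assignments`, `seed`,
#'   `predictions` (per-participant probability) and `spec`.
#' @export
crossvalidate <- function(spec, samples, meta, k = 10, seed = 1,
                          smooth_df = 3) {
  labels <- meta$label
  n <- length(labels)
  if (k < 2L) stop("`k` must be >= 2")
  if (n < k) stop("more folds than participants")
  missing_sig <- setdiff(spec$functional_inputs, names(samples))
  if (length(missing_sig)) {
    stop("samples missing for: ", paste(missing_sig, collapse = ", "))
  }
  fold <- stratified_folds(labels, k, seed)
  # one retry with a derived seed if some training fold is single-class
  for (attempt in 1:2) {
    bad <- any(vapply(seq_len(k), function(f) {
      length(unique(labels[fold != f])) < 2L
    }, TRUE))
    if (!bad) break
    if (attempt == 2L) stop("could not build folds with both classes in every training set")
    fold <- stratified_folds(labels, k, seed + 1000L)
  }
  prob <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(te) == 0L) next
    tr_scores <- list(); te_scores <- list()
    for (sig in spec$functional_inputs) {
      fp <- fpca(subset_sample(samples[[sig]], tr),
                 n_components = spec$n_components)
      tr_scores[[sig]] <- fp$scores
      te_scores[[sig]] <- fpca_project(fp, subset_sample(samples[[sig]], te))
    }
    sc_tr <- encode_scalars(meta[tr, , drop = FALSE], spec$scalar_inputs)
    sc_te <- encode_scalars(meta[te, , drop = FALSE], spec$scalar_inputs)
    if ("body_mass" %in% spec$scalar_inputs) {
      mu <- mean(sc_tr[, "body_mass"]); sdv <- stats::sd(sc_tr[, "body_mass"])
      sc_tr[, "body_mass"] <- (sc_tr[, "body_mass"] - mu) / max(sdv, 1e-8)
      sc_te[, "body_mass"] <- (sc_te[, "body_mass"] - mu) / max(sdv, 1e-8)
    }
    if (spec$model_name == "GSAM") {
      sp <- spec; sp$hyperparameters$smooth_df <- smooth_df
      fitted <- suppressWarnings(fit_spec(sp, tr_scores, sc_tr, labels[tr],
                                          seed = seed + f))
    } else {
      fitted <- fit_spec(spec, tr_scores, sc_tr, labels[tr], seed = seed + f)
    }
    prob[te] <- predict_proba(fitted, te_scores, sc_te)
  }
  pred <- as.integer(prob > 0.5)   # ties -> completer
  m <- metrics_from_confusion(
    tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
  m$fold_assignments <- fold
  m$seed <- seed
  m$predictions <- prob
  m$spec <- spec
  m
}

#' Run a battery of classifier specs under shared CV folds
#'
#' Every spec is evaluated with the same master seed, hence identical
#' stratified folds, so rankings are paired.  A "full" spec (all four
#' signals plus sex and puberty) can be appended automatically.
#'
#' @param samples named list of `fd_sample`s per signal.
#' @param meta metadata aligned with the samples.
#' @param specs list of [classifier_spec()]s.
#' @param k folds.
#' @param seed master seed.
#' @param add_full append a full GSAM spec using every signal present.
#' @return A data.frame (`model`, `inputs`, `accuracy_pct`, `f1_pct`)
#'   sorted by F1 descending, with attribute `"metrics"` holding the full
#'   per-spec results.
#' @export
run_model_battery <- function(samples, meta, specs, k = 10, seed = 1,
                              add_full = TRUE) {
  if (length(specs) == 0L) stop("`specs` must be nonempty")
  if (add_full) {
    specs <- c(specs, list(classifier_spec(
      "GSAM", functional_inputs = names(samples),
      scalar_inputs = c("sex", "puberty"))))
  }
  res <- lapply(specs, function(sp) {
    crossvalidate(sp, samples, meta, k = k, seed = seed)
  })
  tab <- data.frame(
    model = vapply(specs, `[[`, "", "model_name"),
    inputs = vapply(specs, function(sp) {
      paste(c(sp$functional_inputs, sp$scalar_inputs), collapse = "+")
    }, ""),
    accuracy_pct = round(100 * vapply(res, `[[`, 0, "accuracy"), 1),
    f1_pct = round(100 * vapply(res, `[[`, 0, "f1"), 1),
    stringsAsFactors = FALSE)
  ord <- order(-tab$f1_pct)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "metrics") <- res[ord]
  tab
}
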