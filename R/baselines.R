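# Compact baseline classifiers on a numeric design matrix.  These stand in
# for the usual rpart/randomForest/e1071/nnet/class back ends, which are not
# assumed installed; each exposes the same contract: a fit object plus
# predict_proba() returning P(label = 1).  Sizes here are tiny (n ~ 78,
# p ~ 15), so plain R implementations are fast enough.

# ---- CART (Gini impurity, axis-aligned splits) -----------------------------

cart_fit <- function(x, y, max_depth = 4L, min_split = 10L, min_bucket = 5L,
                     mtry = NULL) {
  grow <- function(idx, depth) {
    n <- length(idx)
    p1 <- mean(y[idx])
    node <- list(leaf = TRUE, prob = p1)
    if (depth >= max_depth || n < min_split || p1 == 0 || p1 == 1) {
      return(node)
    }
    feats <- seq_len(ncol(x))
    if (!is.null(mtry)) feats <- sample(feats, min(mtry, length(feats)))
    best <- NULL; best_gain <- 0
    parent_gini <- 2 * p1 * (1 - p1)
    for (j in feats) {
      xv <- x[idx, j]
      cuts <- unique(stats::quantile(xv, probs = seq(0.1, 0.9, by = 0.1),
                                     names = FALSE, type = 1))
      for (cut in cuts) {
        left <- xv <= cut
        nl <- sum(left); nr <- n - nl
        if (nl < min_bucket || nr < min_bucket) next
        pl <- mean(y[idx][left]); pr <- mean(y[idx][!left])
        gain <- parent_gini - (nl * 2 * pl * (1 - pl) +
                               nr * 2 * pr * (1 - pr)) / n
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best <- list(j = j, cut = cut)
        }
      }
    }
    if (is.null(best)) return(node)
    left <- idx[x[idx, best$j] <= best$cut]
    right <- setdiff(idx, left)
    list(leaf = FALSE, j = best$j, cut = best$cut, prob = p1,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  structure(list(tree = grow(seq_len(nrow(x)), 0L)), class = "cart_model")
}

cart_prob <- function(model, x) {
  walk <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$j] <= node$cut) node$left else node$right
    }
    node$prob
  }
  apply(x, 1, function(r) walk(model$tree, r))
}

# ---- Random forest: bagged CART with random feature subsets ----------------

rf_fit <- function(x, y, n_trees = 100L, max_depth = 6L) {
  mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(nrow(x), replace = TRUE)
    cart_fit(x[idx, , drop = FALSE], y[idx], max_depth = max_depth,
             min_split = 6L, min_bucket = 3L, mtry = mtry)
  })
  structure(list(trees = trees), class = "rf_model")
}

rf_prob <- function(model, x) {
  rowMeans(vapply(model$trees, cart_prob, numeric(nrow(x)), x = x))
}

# ---- k-nearest neighbours --------------------------------------------------

knn_fit <- function(x, y, k = 5L) {
  structure(list(x = x, y = y, k = min(k, length(y)),
                 center = colMeans(x),
                 scale = pmax(apply(x, 2, stats::sd), 1e-12)),
            class = "knn_model")
}

knn_prob <- function(model, x) {
  tr <- sweep(sweep(model$x, 2, model$center), 2, model$scale, "/")
  te <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  apply(te, 1, function(r) {
    d <- sqrt(colSums((t(tr) - r)^2))
    mean(model$y[order(d)[seq_len(model$k)]])
  })
}

# ---- Linear SVM (squared hinge + L2) with Platt-scaled probabilities -------

svm_fit <- function(x, y, cost = 1) {
  center <- colMeans(x)
  scale <- pmax(apply(x, 2, stats::sd), 1e-12)
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  ys <- ifelse(y == 1, 1, -1)
  p <- ncol(xs)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    m <- 1 - ys * (xs %*% w + b)
    sum(w^2) / 2 + cost * sum(pmax(m, 0)^2)
  }
  grd <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    m <- drop(1 - ys * (xs %*% w + b))
    act <- m > 0
    gw <- w - 2 * cost * colSums((ys * m * act) * xs)
    gb <- -2 * cost * sum(ys * m * act)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grd, method = "BFGS",
                      control = list(maxit = 200))
  w <- fit$par[seq_len(p)]; b <- fit$par[p + 1L]
  dec <- drop(xs %*% w + b)
  # Platt scaling; fall back to a fixed slope when separation is perfect
  platt <- tryCatch(
    suppressWarnings(stats::glm(y ~ dec, family = stats::binomial())),
    error = function(e) NULL)
  structure(list(w = w, b = b, center = center, scale = scale,
                 platt = if (!is.null(platt)) stats::coef(platt) else c(0, 4)),
            class = "svm_model")
}

svm_prob <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  dec <- drop(xs %*% model$w + model$b)
  stats::plogis(model$platt[1] + model$platt[2] * dec)
}

# ---- Single-hidden-layer neural network (tanh units, weight decay) ---------

nnet_fit <- function(x, y, size = 4L, decay = 0.05, maxit = 300L) {
  center <- colMeans(x)
  scale <- pmax(apply(x, 2, stats::sd), 1e-12)
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  p <- ncol(xs); n <- nrow(xs)
  n_w1 <- (p + 1L) * size; n_w2 <- size + 1L
  forward <- function(th) {
    W1 <- matrix(th[seq_len(n_w1)], p + 1L, size)
    w2 <- th[n_w1 + seq_len(n_w2)]
    H <- tanh(cbind(1, xs) %*% W1)
    stats::plogis(drop(cbind(1, H) %*% w2))
  }
  obj <- function(th) {
    pr <- pmin(pmax(forward(th), 1e-10), 1 - 1e-10)
    -sum(y * log(pr) + (1 - y) * log(1 - pr)) / n + decay * sum(th^2)
  }
  th0 <- stats::runif(n_w1 + n_w2, -0.5, 0.5)
  fit <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  structure(list(theta = fit$par, size = size, p = p,
                 center = center, scale = scale),
            class = "nnet_model")
}

nnet_prob <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  p <- model$p; size <- model$size
  n_w1 <- (p + 1L) * size
  W1 <- matrix(model$theta[seq_len(n_w1)], p + 1L, size)
  w2 <- model$theta[n_w1 + seq_len(size + 1L)]
  H <- tanh(cbind(1, xs) %*% W1)
  stats::plogis(drop(cbind(1, H) %*% w2))
}
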