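# Compact binary-classification zoo: CART trees, bootstrap ensembles,
# boosting, kNN, linear SVM and SGD logistic regression, all pure R.
# Each model exposes calibrated-in-[0,1] two-class confidences; families
# without a probabilistic output (SVM margins, boosted votes) are squashed
# through the logistic function, a fixed monotone mapping.

#' Classifier families available to the zoo
#'
#' The fixed family precedence order used for deterministic tie-breaking.
#'
#' @return character vector of family names.
#' @export
classifier_families <- function() {
  c("decision_tree", "random_forest", "bagging", "adaboost",
    "gradient_boosting", "knn", "svm", "sgd")
}

## ---- CART (Gini impurity, weighted) ----

cart_best_split <- function(x, y, w, feature_idx) {
  n <- length(y)
  tot <- sum(w); tot1 <- sum(w * y)
  best <- NULL
  for (j in feature_idx) {
    xj <- x[, j]
    o <- order(xj)
    xs <- xj[o]
    cw <- cumsum(w[o]); cw1 <- cumsum((w * y)[o])
    k <- which(xs[-n] < xs[-1])       # candidate boundaries between distinct values
    if (length(k) == 0L) next
    nl <- cw[k]; nr <- tot - nl
    pl <- cw1[k] / nl; pr <- (tot1 - cw1[k]) / nr
    imp <- nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)
    b <- which.min(imp)
    if (is.null(best) || imp[b] < best$impurity - 1e-12) {
      best <- list(feature = j, threshold = (xs[k[b]] + xs[k[b] + 1L]) / 2,
                   impurity = imp[b])
    }
  }
  best
}

cart_grow <- function(x, y, w, depth, max_depth, min_split, mtry) {
  p1 <- sum(w * y) / sum(w)
  n <- length(y)
  if (depth >= max_depth || n < min_split || p1 <= 0 || p1 >= 1) {
    return(list(leaf = TRUE, prob = p1))
  }
  p <- ncol(x)
  feats <- if (is.null(mtry) || mtry >= p) seq_len(p) else sort(sample.int(p, mtry))
  parent_imp <- sum(w) * 2 * p1 * (1 - p1)
  sp <- cart_best_split(x, y, w, feats)
  if (is.null(sp) || sp$impurity >= parent_imp - 1e-12) {
    return(list(leaf = TRUE, prob = p1))
  }
  left <- x[, sp$feature] <= sp$threshold
  list(
    leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
    left = cart_grow(x[left, , drop = FALSE], y[left], w[left],
                     depth + 1L, max_depth, min_split, mtry),
    right = cart_grow(x[!left, , drop = FALSE], y[!left], w[!left],
                      depth + 1L, max_depth, min_split, mtry)
  )
}

cart_fit <- function(x, y, w = NULL, max_depth = 4L, min_split = 5L, mtry = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  cart_grow(x, y, w / sum(w), 0L, max_depth, min_split, mtry)
}

cart_predict <- function(tree, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) {
      out[idx] <<- node$prob
    } else {
      left <- x[idx, node$feature] <= node$threshold
      recurse(node$left, idx[left])
      recurse(node$right, idx[!left])
    }
  }
  recurse(tree, seq_len(nrow(x)))
  out
}

## ---- ensembles ----

forest_fit <- function(x, y, n_trees, max_depth, mtry) {
  n <- length(y)
  lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    cart_fit(x[idx, , drop = FALSE], y[idx], max_depth = max_depth, mtry = mtry)
  })
}

forest_predict <- function(trees, x) {
  rowMeans(vapply(trees, cart_predict, numeric(nrow(x)), x = x))
}

adaboost_fit <- function(x, y, n_rounds, stump_depth) {
  n <- length(y)
  ypm <- 2 * y - 1
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    st <- cart_fit(x, y, w, max_depth = stump_depth, min_split = 2L)
    pred <- ifelse(cart_predict(st, x) >= 0.5, 1, -1)
    err <- sum(w[pred != ypm])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- st; alphas[m] <- alpha
    w <- w * exp(-alpha * ypm * pred)
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  list(stumps = stumps, alphas = alphas[seq_along(stumps)])
}

adaboost_margin <- function(fit, x) {
  f <- numeric(nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(cart_predict(fit$stumps[[m]], x) >= 0.5, 1, -1)
    f <- f + fit$alphas[m] * pred
  }
  f
}

reg_stump_fit <- function(x, g, h) {
  n <- length(g)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    o <- order(xj)
    xs <- xj[o]
    cg <- cumsum(g[o]); cg2 <- cumsum(g[o]^2)
    k <- which(xs[-n] < xs[-1])
    if (length(k) == 0L) next
    sse <- (cg2[k] - cg[k]^2 / k) +
      ((cg2[n] - cg2[k]) - (cg[n] - cg[k])^2 / (n - k))
    b <- which.min(sse)
    if (is.null(best) || sse[b] < best$sse - 1e-12) {
      best <- list(feature = j, threshold = (xs[k[b]] + xs[k[b] + 1L]) / 2,
                   sse = sse[b])
    }
  }
  newton <- function(idx) {
    v <- sum(g[idx]) / max(sum(h[idx]), 1e-10)
    max(min(v, 4), -4)
  }
  if (is.null(best)) {
    return(list(feature = NA_integer_, threshold = NA_real_,
                value_left = newton(seq_len(n)), value_right = newton(seq_len(n))))
  }
  left <- x[, best$feature] <= best$threshold
  list(feature = best$feature, threshold = best$threshold,
       value_left = newton(which(left)), value_right = newton(which(!left)))
}

gboost_fit <- function(x, y, n_rounds, learning_rate) {
  pbar <- min(max(mean(y), 1e-10), 1 - 1e-10)
  f0 <- log(pbar / (1 - pbar))
  f <- rep(f0, length(y))
  stumps <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    p <- stats::plogis(f)
    st <- reg_stump_fit(x, y - p, p * (1 - p))
    stumps[[m]] <- st
    f <- f + learning_rate * reg_stump_predict(st, x)
  }
  list(f0 = f0, stumps = stumps, learning_rate = learning_rate)
}

reg_stump_predict <- function(st, x) {
  if (is.na(st$feature)) return(rep(st$value_left, nrow(x)))
  ifelse(x[, st$feature] <= st$threshold, st$value_left, st$value_right)
}

gboost_margin <- function(fit, x) {
  f <- rep(fit$f0, nrow(x))
  for (st in fit$stumps) f <- f + fit$learning_rate * reg_stump_predict(st, x)
  f
}

## ---- instance-based and linear models ----

standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}

standardize_apply <- function(std, x) {
  sweep(sweep(x, 2, std$mu, "-"), 2, std$s, "/")
}

knn_predict <- function(xtr, ytr, k, x) {
  d2 <- outer(rowSums(x^2), rowSums(xtr^2), "+") - 2 * x %*% t(xtr)
  k <- min(k, nrow(xtr))
  apply(d2, 1, function(d) mean(ytr[order(d)[seq_len(k)]]))
}

svm_fit <- function(x, y, lambda) {
  ypm <- 2 * y - 1
  n <- nrow(x); p <- ncol(x)
  obj <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1L]
    m <- drop(x %*% w) + b
    slack <- pmax(0, 1 - ypm * m)
    lambda / 2 * sum(w^2) + mean(slack^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1L]
    m <- drop(x %*% w) + b
    slack <- pmax(0, 1 - ypm * m)
    gw <- lambda * w - (2 / n) * drop(t(x) %*% (slack * ypm))
    gb <- -(2 / n) * sum(slack * ypm)
    c(gw, gb)
  }
  fit <- optim(numeric(p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 200))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L])
}

sgd_fit <- function(x, y, alpha, learning_rate, epochs) {
  n <- nrow(x); p <- ncol(x)
  w <- numeric(p); b <- 0
  t <- 0
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      lr <- learning_rate / (1 + learning_rate * alpha * t)
      pi <- stats::plogis(sum(x[i, ] * w) + b)
      g <- pi - y[i]
      w <- w - lr * (g * x[i, ] + alpha * w)
      b <- b - lr * g
    }
  }
  list(w = w, b = b)
}

## ---- unified interface ----

default_params <- function(family, p) {
  switch(family,
    decision_tree = list(max_depth = 4L, min_split = 5L),
    random_forest = list(n_trees = 25L, max_depth = 6L,
                         mtry = max(1L, floor(sqrt(p)))),
    bagging = list(n_trees = 25L, max_depth = 6L),
    adaboost = list(n_rounds = 30L, stump_depth = 1L),
    gradient_boosting = list(n_rounds = 30L, learning_rate = 0.1),
    knn = list(k_neighbors = 5L),
    svm = list(lambda = 0.01),
    sgd = list(alpha = 1e-3, learning_rate = 0.05, epochs = 20L),
    stop_config("family", paste("unknown classifier family", family))
  )
}

#' Train one classifier of the zoo
#'
#' @param family one of [classifier_families()].
#' @param x numeric feature matrix.
#' @param y factor with exactly two levels; the second level is the
#'   positive class whose confidence is reported in column 2.
#' @param params named list of family parameters (missing entries take
#'   documented defaults).
#' @param seed seed for the family's stochastic elements (bootstraps,
#'   SGD shuffling).
#' @return an object of class `perio_model`.
#' @export
train_model <- function(family, x, y, params = list(), seed = 1L) {
  stopifnot(is.factor(y), nlevels(y) == 2L)
  x <- as.matrix(x)
  pars <- utils::modifyList(default_params(family, ncol(x)), params)
  y01 <- as.integer(y == levels(y)[2])
  std <- NULL
  if (family %in% c("knn", "svm", "sgd")) {
    std <- standardizer(x)
    x <- standardize_apply(std, x)
  }
  fit <- with_seed(seed, switch(family,
    decision_tree = cart_fit(x, y01, max_depth = pars$max_depth,
                             min_split = pars$min_split),
    random_forest = forest_fit(x, y01, pars$n_trees, pars$max_depth, pars$mtry),
    bagging = forest_fit(x, y01, pars$n_trees, pars$max_depth, mtry = NULL),
    adaboost = adaboost_fit(x, y01, pars$n_rounds, pars$stump_depth),
    gradient_boosting = gboost_fit(x, y01, pars$n_rounds, pars$learning_rate),
    knn = list(x = x, y = y01, k = pars$k_neighbors),
    svm = svm_fit(x, y01, pars$lambda),
    sgd = sgd_fit(x, y01, pars$alpha, pars$learning_rate, pars$epochs)
  ))
  structure(
    list(family = family, fit = fit, params = pars, levels = levels(y),
         std = std),
    class = "perio_model"
  )
}

#' Two-class confidence scores of a trained model
#'
#' Probabilistic families report their estimated class probability; margin
#' families (SVM, boosting votes) are mapped through the logistic function,
#' a fixed monotone squashing into \[0, 1\]. Rows sum to 1.
#'
#' @param model a `perio_model`.
#' @param x feature matrix.
#' @return numeric matrix, one row per sample, columns named by the two
#'   class levels.
#' @export
predict_proba <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$std)) x <- standardize_apply(model$std, x)
  p1 <- switch(model$family,
    decision_tree = cart_predict(model$fit, x),
    random_forest = forest_predict(model$fit, x),
    bagging = forest_predict(model$fit, x),
    adaboost = stats::plogis(2 * adaboost_margin(model$fit, x)),
    gradient_boosting = stats::plogis(gboost_margin(model$fit, x)),
    knn = knn_predict(model$fit$x, model$fit$y, model$fit$k, x),
    svm = stats::plogis(drop(x %*% model$fit$w) + model$fit$b),
    sgd = stats::plogis(drop(x %*% model$fit$w) + model$fit$b)
  )
  p1 <- pmin(pmax(p1, 0), 1)
  out <- cbind(1 - p1, p1)
  colnames(out) <- model$levels
  out
}
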