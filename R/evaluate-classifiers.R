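# Compact classifier implementations for the evaluation stage.
#
# The evaluation uses two predictors (Rad-Score, Ki67 category), so
# small self-contained learners are adequate and keep the dependency
# surface limited to what is installed: KNN rides on FNN, the RBF-SVM
# on its quadprog dual, and the random forest / gradient-boosted
# stumps are implemented here.

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- CART ------------------------------------------------------------

# Recursive binary Gini tree on a numeric matrix. mtry features are
# drawn per split; leaves store the positive-class fraction.
grow_tree <- function(X, y, mtry, max_depth, min_node = 1L) {
  n <- length(y)
  if (max_depth == 0L || n <= min_node || length(unique(y)) == 1L)
    return(list(leaf = TRUE, prob = mean(y)))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL; best_gain <- 0
  imp0 <- gini_imp(y)
  for (j in feats) {
    v <- X[, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2L) next
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cv in cuts) {
      left <- v <= cv
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      gain <- imp0 - (nl * gini_imp(y[left]) +
                        (n - nl) * gini_imp(y[!left])) / n
      if (gain > best_gain + 1e-12) {
        best_gain <- gain; best <- list(j = j, cut = cv, left = left)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = mean(y)))
  list(leaf = FALSE, j = best$j, cut = best$cut,
       left = grow_tree(X[best$left, , drop = FALSE], y[best$left],
                        mtry, max_depth - 1L, min_node),
       right = grow_tree(X[!best$left, , drop = FALSE], y[!best$left],
                         mtry, max_depth - 1L, min_node))
}

gini_imp <- function(y) { p <- mean(y); 2 * p * (1 - p) }

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible(NULL))
    if (node$leaf) { out[idx] <<- node$prob; return(invisible(NULL)) }
    left <- X[idx, node$j] <= node$cut
    rec(node$left, idx[left]); rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

# ---- fitting ---------------------------------------------------------

#' Fit a classifier on \{Rad-Score, Ki67\}-type predictors
#'
#' Four classifier kinds with seeded, overridable defaults: random
#' forest (bagged Gini trees, 500 trees, mtry = floor(sqrt(p))),
#' gradient boosting on depth-1 stumps (100 rounds, shrinkage 0.1,
#' Newton leaf updates), k-nearest neighbors (k = 5, standardized
#' predictors), and a soft-margin RBF support-vector machine
#' (C = 1, gamma = 1/p, solved exactly via its quadprog dual).
#'
#' @param kind one of \code{"random_forest"}, \code{"boosting"},
#'   \code{"knn"}, \code{"svm"}.
#' @param X numeric matrix of predictors (rows = samples).
#' @param y 0/1 labels.
#' @param seed integer seed (stochastic fits: forest bootstrap).
#' @param n_trees,max_depth forest controls.
#' @param n_rounds,shrinkage boosting controls.
#' @param k KNN neighbor count.
#' @param cost,gamma SVM controls (gamma defaults to 1/ncol(X)).
#' @return a \code{us_classifier} object.
#' @export
fit_classifier <- function(kind = c("random_forest", "boosting", "knn", "svm"),
                           X, y, seed = 1L,
                           n_trees = 500L, max_depth = 6L,
                           n_rounds = 100L, shrinkage = 0.1,
                           k = 5L, cost = 1, gamma = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)

  fit <- with_local_seed(seed, switch(
    kind,
    random_forest = {
      mtry <- max(1L, floor(sqrt(ncol(X))))
      trees <- lapply(seq_len(n_trees), function(i) {
        bs <- sample.int(nrow(X), replace = TRUE)
        grow_tree(X[bs, , drop = FALSE], y[bs], mtry, max_depth)
      })
      list(trees = trees)
    },
    boosting = {
      p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
      f <- rep(log(p0 / (1 - p0)), length(y))
      stumps <- vector("list", n_rounds)
      for (m in seq_len(n_rounds)) {
        pr <- sigmoid(f)
        r <- y - pr
        wt <- pmax(pr * (1 - pr), 1e-6)
        st <- fit_stump(X, r, wt)
        stumps[[m]] <- st
        f <- f + shrinkage * predict_stump(st, X)
      }
      list(f0 = log(p0 / (1 - p0)), stumps = stumps, shrinkage = shrinkage)
    },
    knn = list(Xs = Xs, y = y, k = as.integer(k)),
    svm = fit_svm_rbf(Xs, y, cost = cost,
                      gamma = if (is.null(gamma)) 1 / ncol(X) else gamma)
  ))
  structure(list(kind = kind, fit = fit, center = ctr, scale = scl,
                 threshold = if (kind == "svm") 0 else 0.5),
            class = "us_classifier")
}

# depth-1 regression stump: split by least-squares variance reduction
# on the residuals, leaf values by the Newton step sum(r) / sum(p(1-p))
fit_stump <- function(X, r, wt) {
  best <- list(j = 1L, cut = Inf, gl = sum(r) / sum(wt), gr = 0)
  best_sse <- Inf
  n <- length(r)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    o <- order(v)
    vo <- v[o]; ro <- r[o]; wo <- wt[o]
    csr <- cumsum(ro); csw <- cumsum(wo)
    csr2 <- cumsum(ro^2)
    valid <- which(diff(vo) > 0)
    if (length(valid) == 0L) next
    # SSE about the left/right means: sum(r^2) - (sum r)^2 / k
    sse <- (csr2[valid] - csr[valid]^2 / valid) +
      ((csr2[n] - csr2[valid]) -
         (csr[n] - csr[valid])^2 / (n - valid))
    i <- which.min(sse)
    if (sse[i] < best_sse - 1e-12) {
      best_sse <- sse[i]
      best <- list(j = j, cut = (vo[valid[i]] + vo[valid[i] + 1]) / 2,
                   gl = csr[valid[i]] / csw[valid[i]],
                   gr = (csr[n] - csr[valid[i]]) / (csw[n] - csw[valid[i]]))
    }
  }
  best
}

predict_stump <- function(st, X)
  ifelse(X[, st$j] <= st$cut, st$gl, st$gr)

# exact soft-margin RBF SVM via the quadprog dual
fit_svm_rbf <- function(Xs, y, cost, gamma) {
  n <- nrow(Xs)
  ys <- ifelse(y == 1L, 1, -1)
  K <- rbf_kernel(Xs, Xs, gamma)
  Q <- (ys %o% ys) * K
  Q <- Q + diag(1e-8, n)
  A <- cbind(ys, diag(n), -diag(n))
  b <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = Q, dvec = rep(1, n), Amat = A,
                            bvec = b, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-6
  margin <- sv & alpha < cost - 1e-6
  ref <- if (any(margin)) which(margin) else which(sv)
  bias <- mean(ys[ref] - (K[ref, , drop = FALSE] %*% (alpha * ys)))
  list(alpha = alpha, ys = ys, Xs = Xs, bias = bias, gamma = gamma)
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Continuous classification scores
#'
#' The model's continuous score on new data: positive-class posterior
#' for the forest, boosting (logistic of the boosted margin) and KNN
#' (neighbor vote fraction), and the decision value for the SVM.
#'
#' @param object a \code{us_classifier}.
#' @param X predictor matrix.
#' @return numeric vector of scores.
#' @export
predict_score <- function(object, X) {
  stopifnot(inherits(object, "us_classifier"))
  X <- as.matrix(X)
  Xs <- scale(X, object$center, object$scale)
  switch(object$kind,
    random_forest = {
      sc <- vapply(object$fit$trees, function(tr) predict_tree(tr, X),
                   numeric(nrow(X)))
      if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(X))
      rowMeans(sc)
    },
    boosting = {
      f <- rep(object$fit$f0, nrow(X))
      for (st in object$fit$stumps)
        f <- f + object$fit$shrinkage * predict_stump(st, X)
      sigmoid(f)
    },
    knn = {
      nn <- FNN::get.knnx(object$fit$Xs, Xs, k = object$fit$k)
      rowMeans(matrix(object$fit$y[nn$nn.index], ncol = object$fit$k))
    },
    svm = {
      K <- rbf_kernel(Xs, object$fit$Xs, object$fit$gamma)
      as.numeric(K %*% (object$fit$alpha * object$fit$ys) + object$fit$bias)
    })
}
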