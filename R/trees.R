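# Classification tree (CART, Gini splits, class-probability leaves) and a
# bagged random forest built on it. Implemented in-package because no tree
# learner ships with the target environment; the API is deliberately small —
# binary 0/1 response, numeric covariate matrix — which is all the ensemble
# module needs.

# vectorized best-split search for one node; returns NULL or list(var, split, gain)
best_split <- function(X, y, min_leaf, mtry) {
  n <- length(y)
  p <- ncol(X)
  vars <- if (is.null(mtry) || mtry >= p) seq_len(p) else sample.int(p, mtry)
  n1 <- sum(y)
  gini_parent <- 2 * (n1 / n) * (1 - n1 / n) * n
  best <- NULL
  for (j in vars) {
    ord <- order(X[, j])
    xs <- X[ord, j]; ys <- y[ord]
    cum1 <- cumsum(ys)
    nl <- seq_len(n - 1)
    valid <- which(diff(xs) > 0)
    valid <- valid[valid >= min_leaf & (n - valid) >= min_leaf]
    if (length(valid) == 0) next
    n1l <- cum1[valid]; nll <- nl[valid]
    n1r <- n1 - n1l; nrr <- n - nll
    gini <- 2 * n1l * (1 - n1l / nll) + 2 * n1r * (1 - n1r / nrr)
    i <- which.min(gini)
    gain <- gini_parent - gini[i]
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(var = j, split = (xs[valid[i]] + xs[valid[i] + 1]) / 2, gain = gain)
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

#' Fit a classification tree (CART)
#'
#' Greedy binary recursive partitioning on the Gini criterion with
#' class-probability leaves, so predictions are continuous in `[0, 1]`.
#'
#' @param X Numeric covariate matrix.
#' @param y 0/1 response vector.
#' @param min_split Minimum node size to attempt a split.
#' @param min_leaf Minimum rows per child.
#' @param max_depth Maximum tree depth.
#' @param mtry Features sampled per split (NULL = all; used by the forest).
#' @return A `cart_tree` object.
#' @export
cart_fit <- function(X, y, min_split = 10, min_leaf = 5, max_depth = 12,
                     mtry = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  nodes <- list()
  new_node <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(leaf = TRUE, prob = mean(y[rows]), var = NA, split = NA,
                         left = NA, right = NA)
    n <- length(rows)
    if (n >= min_split && depth < max_depth && length(unique(y[rows])) > 1) {
      sp <- best_split(X[rows, , drop = FALSE], y[rows], min_leaf, mtry)
      if (!is.null(sp)) {
        go_left <- X[rows, sp$var] <= sp$split
        l <- new_node(rows[go_left], depth + 1)
        r <- new_node(rows[!go_left], depth + 1)
        nodes[[id]]$leaf <<- FALSE
        nodes[[id]]$var <<- sp$var; nodes[[id]]$split <<- sp$split
        nodes[[id]]$left <<- l; nodes[[id]]$right <<- r
      }
    }
    id
  }
  new_node(seq_along(y), 0L)
  structure(list(nodes = nodes, p = ncol(X), vars = colnames(X)),
            class = "cart_tree")
}

#' Predict class-1 probability from a CART tree
#' @param object A `cart_tree`.
#' @param X Numeric covariate matrix (columns in training order).
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`.
#' @export
predict.cart_tree <- function(object, X, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  node <- rep(1L, n)
  out <- rep(NA_real_, n)
  repeat {
    done <- TRUE
    for (id in unique(node[is.na(out)])) {
      nd <- object$nodes[[id]]
      rows <- which(node == id & is.na(out))
      if (nd$leaf) {
        out[rows] <- nd$prob
      } else {
        done <- FALSE
        left <- X[rows, nd$var] <= nd$split
        node[rows[left]] <- nd$left
        node[rows[!left]] <- nd$right
      }
    }
    if (done) break
  }
  out
}

#' Fit a bagged random forest of CART trees
#'
#' Bootstrap-resampled trees with per-split feature subsampling
#' (`mtry = floor(sqrt(p))` by default); prediction is the mean of tree
#' probabilities.
#'
#' @param X Numeric covariate matrix.
#' @param y 0/1 response.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features per split.
#' @param min_leaf,max_depth Tree controls.
#' @param seed Integer seed.
#' @return An `rf_model` object.
#' @export
rf_fit <- function(X, y, n_trees = 500, mtry = max(1L, floor(sqrt(ncol(X)))),
                   min_leaf = 5, max_depth = 12, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  trees <- vector("list", n_trees)
  n <- nrow(X)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- cart_fit(X[idx, , drop = FALSE], y[idx], min_split = 2 * min_leaf,
                           min_leaf = min_leaf, max_depth = max_depth, mtry = mtry)
  }
  structure(list(trees = trees, p = ncol(X), vars = colnames(X)), class = "rf_model")
}

#' Predict class-1 probability from a random forest
#' @param object An `rf_model`.
#' @param X Numeric covariate matrix.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`.
#' @export
predict.rf_model <- function(object, X, ...) {
  acc <- 0
  for (tr in object$trees) acc <- acc + predict(tr, X)
  acc / length(object$trees)
}
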