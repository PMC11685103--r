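# Gradient-boosted classification trees (logistic loss), built for the
# two-feature interaction problem but generic over small feature matrices.
# Classic Friedman boosting: each round fits a depth-limited regression
# tree to the negative gradient, with Newton leaf values
# sum(residual) / sum(p (1 - p)).

fit_tree <- function(Xm, grad, hess, depth, min_leaf = 5L) {
  build <- function(idx, d) {
    g <- sum(grad[idx]); h <- sum(hess[idx])
    leaf_val <- g / max(h, 1e-12)
    if (d >= depth || length(idx) < 2L * min_leaf) {
      return(list(leaf = TRUE, value = leaf_val))
    }
    best <- NULL; best_gain <- 0
    base_score <- g * g / max(h, 1e-12)
    for (j in seq_len(ncol(Xm))) {
      xv <- Xm[idx, j]
      ord <- order(xv)
      xs <- xv[ord]; gs <- grad[idx][ord]; hs <- hess[idx][ord]
      cg <- cumsum(gs); ch <- cumsum(hs)
      nn <- length(idx)
      cand <- which(diff(xs) > 0)
      cand <- cand[cand >= min_leaf & cand <= nn - min_leaf]
      if (!length(cand)) next
      gl <- cg[cand]; hl <- ch[cand]
      gr <- g - gl; hr <- h - hl
      gain <- gl^2 / pmax(hl, 1e-12) + gr^2 / pmax(hr, 1e-12) - base_score
      k <- which.max(gain)
      if (gain[k] > best_gain) {
        best_gain <- gain[k]
        best <- list(feature = j, threshold = (xs[cand[k]] + xs[cand[k] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = leaf_val))
    go <- Xm[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = build(idx[go], d + 1L), right = build(idx[!go], d + 1L))
  }
  build(seq_len(nrow(Xm)), 0L)
}

predict_tree <- function(tree, Xm) {
  out <- numeric(nrow(Xm))
  walk <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    go <- Xm[idx, node$feature] <= node$threshold
    walk(node$left, idx[go])
    walk(node$right, idx[!go])
  }
  walk(tree, seq_len(nrow(Xm)))
  out
}

#' Fit a gradient-boosted tree classifier
#'
#' Binary logistic boosting with depth-limited trees and Newton leaf steps.
#'
#' @param Xm numeric feature matrix.
#' @param y 0/1 labels.
#' @param n_trees number of boosting rounds (default 200).
#' @param depth maximum tree depth (default 3).
#' @param shrinkage learning rate (default 0.1).
#' @param min_leaf minimum observations per leaf.
#' @return object of class `gbm_model`.
#' @export
gbm_fit <- function(Xm, y, n_trees = 200L, depth = 3L, shrinkage = 0.1,
                    min_leaf = 5L) {
  Xm <- as.matrix(Xm)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  p0 <- mean(y)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    p <- sigmoid(f)
    grad <- y - p
    hess <- p * (1 - p)
    tr <- fit_tree(Xm, grad, hess, depth, min_leaf)
    trees[[i]] <- tr
    f <- f + shrinkage * predict_tree(tr, Xm)
  }
  structure(list(f0 = f0, trees = trees, shrinkage = shrinkage,
                 n_features = ncol(Xm)), class = "gbm_model")
}

#' Predict probabilities from a gradient-boosted classifier
#'
#' @param object a `gbm_model`.
#' @param Xm feature matrix with the training column count.
#' @param ... unused.
#' @return probabilities in \[0,1\].
#' @export
predict.gbm_model <- function(object, Xm, ...) {
  Xm <- as.matrix(Xm)
  if (ncol(Xm) != object$n_features)
    stop("expected ", object$n_features, " feature column(s), got ", ncol(Xm))
  f <- rep(object$f0, nrow(Xm))
  for (tr in object$trees) f <- f + object$shrinkage * predict_tree(tr, Xm)
  sigmoid(f)
}
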