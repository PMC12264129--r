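#' Sparse partial least squares discriminant analysis
#'
#' Fits a sparse PLS-DA model by a NIPALS-type algorithm with hard
#' cardinality sparsification of the X-weights.  The class labels are
#' dummy-coded as a column-centred one-hot indicator matrix `Y`; for each
#' component the Y-score `u` is initialised from the dominant right
#' singular direction of `X'Y` (sign fixed so its largest-magnitude entry
#' is positive) and the iteration
#' `w = X'u` (keep the `keepX` largest `|w|`, renormalise to unit norm),
#' `t = Xw`, `c = Y't / t't`, `u = Yc / c'c`
#' runs until `max |dw| < tol` or `max_iter` sweeps.  Both `X` and `Y` are
#' then deflated in regression mode (`X <- X - t p'` with `p = X't/t't`,
#' `Y <- Y - t c'`).  Ties in the sparsification are broken toward the
#' lower feature index; each weight vector is sign-flipped so its
#' largest-magnitude entry is positive, removing the sign indeterminacy.
#' With `keepX = p` the model is ordinary dense PLS2-DA.
#'
#' `X` is expected to be preprocessed (autoscaled); the function does not
#' rescale it.
#'
#' @param X numeric matrix, samples x features (autoscaled).
#' @param y class labels (factor or character), at least two classes.
#' @param ncomp number of components.
#' @param keepX number of features allowed a nonzero weight per component;
#'   a scalar is recycled.  Default `ncol(X)` (dense).
#' @param tol convergence tolerance on the weight update (default 1e-6).
#' @param max_iter iteration cap per component (default 500).
#' @return an object of class `splsda` with components `weights` (p x H),
#'   `scores` (n x H), `loadings` (p x H), `y_coef` (K x H), `keepX`,
#'   `levels`, `y_means` (dummy centring offsets), `prevalence`, `iters`.
#' @export
splsda <- function(X, y, ncomp = 2, keepX = NULL, tol = 1e-6,
                   max_iter = 500) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  y <- factor(y)
  y <- droplevels(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (nlevels(y) < 2) {
    stop("y must contain at least two classes", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(p))
  ncomp <- check_count(ncomp, "ncomp", min = 1)
  rank_bound <- min(n - 1, p)
  if (ncomp > rank_bound) {
    stop(sprintf("ncomp (%d) exceeds the rank bound min(n-1, p) = %d",
                 ncomp, rank_bound), call. = FALSE)
  }
  if (is.null(keepX)) keepX <- p
  keepX <- as.integer(rep_len(keepX, ncomp))
  if (any(keepX < 1) || any(keepX > p)) {
    stop(sprintf("keepX must lie in [1, %d]", p), call. = FALSE)
  }

  K <- nlevels(y)
  Y <- matrix(0, n, K, dimnames = list(NULL, levels(y)))
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  y_means <- colMeans(Y)
  Yd <- sweep(Y, 2, y_means)
  Xd <- X

  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Cc <- matrix(0, K, ncomp, dimnames = list(levels(y), NULL))
  Tm <- matrix(0, n, ncomp)
  iters <- integer(ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(Xd, Yd)
    v <- svd(M, nu = 0, nv = 1)$v[, 1]
    jmax <- which.max(abs(v))
    if (v[jmax] < 0) v <- -v
    u <- drop(Yd %*% v)
    w_old <- rep(Inf, p)
    w <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u))
      w <- sparsify_weights(w, keepX[h])
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) {
        stop(sprintf("degenerate component %d: zero weight vector", h),
             call. = FALSE)
      }
      w <- w / nw
      tt <- drop(Xd %*% w)
      tss <- sum(tt^2)
      if (tss < .Machine$double.eps) {
        stop(sprintf("degenerate component %d: zero score variance", h),
             call. = FALSE)
      }
      cc <- drop(crossprod(Yd, tt)) / tss
      u <- drop(Yd %*% cc) / sum(cc^2)
      if (max(abs(w - w_old)) < tol) break
      w_old <- w
    }
    iters[h] <- it
    # sign convention: largest-magnitude weight positive
    jmax <- which.max(abs(w))
    if (w[jmax] < 0) {
      w <- -w
      tt <- -tt
      cc <- -cc
    }
    pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
    W[, h] <- w
    P[, h] <- pp
    Cc[, h] <- cc
    Tm[, h] <- tt
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, cc)
  }

  structure(list(weights = W, scores = Tm, loadings = P, y_coef = Cc,
                 ncomp = ncomp, keepX = keepX, levels = levels(y),
                 y = y, y_means = y_means,
                 prevalence = as.vector(table(y)),
                 features = colnames(X), tol = tol, iters = iters),
            class = "splsda")
}

# zero all but the k largest |w|; ties broken toward lower feature index
sparsify_weights <- function(w, k) {
  p <- length(w)
  if (k >= p) return(w)
  keep <- order(-abs(w), seq_len(p))[seq_len(k)]
  out <- numeric(p)
  out[keep] <- w[keep]
  out
}

#' @export
print.splsda <- function(x, ...) {
  cat("sPLS-DA model:", x$ncomp, "component(s),",
      length(x$features), "features, classes:",
      paste(x$levels, collapse = ", "), "\n")
  cat("  keepX:", paste(x$keepX, collapse = ", "),
      "| nonzero weights:", paste(colSums(x$weights != 0), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict classes from a sparse PLS-DA model
#'
#' Computes the PLS regression coefficients `B = W (P'W)^{-1} C'` from the
#' sparse weights, loadings and Y-coefficients, evaluates the predicted
#' dummy scores `Xnew B` plus the training dummy centring offsets, and
#' assigns classes by the requested distance rule:
#' * `"max"` (default): the class with the largest predicted dummy score;
#' * `"centroid"`: the class whose training centroid in latent-score space
#'   is nearest (Euclidean) to the sample's projected scores — the robust
#'   choice when one class lies between two others, as a prodromal group
#'   does, since such a class is invisible to the argmax rule;
#' * `"mahalanobis"`: as `"centroid"` but with the pooled within-class
#'   covariance of the training scores.
#'
#' Ties are broken toward the class with larger training prevalence, then
#' label order.  `Xnew` must already carry the training preprocessing
#' (e.g. training-fold autoscaling parameters).
#'
#' @param object an [splsda()] model.
#' @param newdata numeric matrix with the training feature set (matched by
#'   column name when named).
#' @param ncomp number of components to use (default all).
#' @param dist prediction distance rule (see above).
#' @param ... ignored.
#' @return a list with `class` (factor) and `scores` (matrix of predicted
#'   dummy scores, samples x classes).
#' @export
predict.splsda <- function(object, newdata, ncomp = object$ncomp,
                           dist = c("max", "centroid", "mahalanobis"),
                           ...) {
  dist <- match.arg(dist)
  Xn <- as.matrix(newdata)
  if (!is.null(colnames(Xn))) {
    missing <- setdiff(object$features, colnames(Xn))
    if (length(missing)) {
      stop(sprintf("newdata lacks training feature(s): %s",
                   paste(utils::head(missing, 10), collapse = ", ")),
           call. = FALSE)
    }
    Xn <- Xn[, object$features, drop = FALSE]
  } else if (ncol(Xn) != length(object$features)) {
    stop("newdata must have the training feature set", call. = FALSE)
  }
  h <- seq_len(ncomp)
  W <- object$weights[, h, drop = FALSE]
  P <- object$loadings[, h, drop = FALSE]
  Cc <- object$y_coef[, h, drop = FALSE]
  R <- W %*% solve(crossprod(P, W))        # projection to latent scores
  scores <- Xn %*% R %*% t(Cc)
  scores <- sweep(scores, 2, object$y_means, "+")
  colnames(scores) <- object$levels
  prev <- object$prevalence
  pick_best <- function(crit) {            # crit: larger is better
    apply(crit, 1, function(s) {
      best <- which(s == max(s))
      if (length(best) > 1) best <- best[order(-prev[best], best)][1]
      best
    })
  }
  if (dist == "max") {
    pick <- pick_best(scores)
  } else {
    Tn <- Xn %*% R
    Ttr <- object$scores[, h, drop = FALSE]
    cent <- do.call(rbind, lapply(object$levels, function(cl) {
      colMeans(Ttr[object$y == cl, , drop = FALSE])
    }))
    if (dist == "mahalanobis") {
      within <- Ttr - cent[as.integer(object$y), , drop = FALSE]
      S <- crossprod(within) / (nrow(Ttr) - length(object$levels))
      Sinv <- solve(S)
      d2 <- t(apply(Tn, 1, function(t_i) {
        diff <- sweep(cent, 2, t_i)
        rowSums((diff %*% Sinv) * diff)
      }))
    } else {
      d2 <- t(apply(Tn, 1, function(t_i) {
        rowSums(sweep(cent, 2, t_i)^2)
      }))
    }
    pick <- pick_best(-d2)
  }
  list(class = factor(object$levels[pick], levels = object$levels),
       scores = scores)
}

#' Variable importance in projection (VIP) scores
#'
#' Computes, for each feature, the VIP score over components `1..upto`:
#' `VIP_j = sqrt( p * sum_h SS_h w_jh^2 / sum_h SS_h )`, where
#' `SS_h = ||c_h||^2 (t_h' t_h)` is the Y-variance explained by component
#' `h` and the `w_h` are the unit-norm sparse weights.  Because each `w_h`
#' has unit norm, `sum_j VIP_j^2 = p` exactly.
#'
#' @param model an [splsda()] model.
#' @param upto highest component to accumulate (default all); when
#'   `cumulative = TRUE` (default) a matrix of the views for
#'   `upto = 1, ..., ncomp` is returned.
#' @param cumulative return all cumulative views as a matrix
#'   (features x components) rather than a single vector.
#' @return named numeric vector (if `cumulative = FALSE`) or matrix of VIP
#'   scores; column `h` of the matrix is the VIP over components `1..h`.
#' @export
splsda_vip <- function(model, upto = model$ncomp, cumulative = TRUE) {
  stopifnot(inherits(model, "splsda"))
  upto <- check_count(upto, "upto", min = 1)
  if (upto > model$ncomp) {
    stop(sprintf("upto (%d) exceeds the fitted ncomp (%d)", upto,
                 model$ncomp), call. = FALSE)
  }
  p <- nrow(model$weights)
  ss <- vapply(seq_len(model$ncomp), function(h) {
    sum(model$y_coef[, h]^2) * sum(model$scores[, h]^2)
  }, numeric(1))
  one_view <- function(H) {
    hs <- seq_len(H)
    num <- model$weights[, hs, drop = FALSE]^2 %*% ss[hs]
    sqrt(p * num / sum(ss[hs]))[, 1]
  }
  if (!cumulative) {
    return(stats::setNames(one_view(upto), model$features))
  }
  out <- vapply(seq_len(upto), one_view, numeric(p))
  dimnames(out) <- list(model$features, sprintf("upto%d", seq_len(upto)))
  out
}

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification rate; robust to
#' class imbalance and the criterion used throughout model tuning.
#'
#' @param truth true class labels.
#' @param predicted predicted class labels (same length).
#' @return a number in \[0, 1\].
#' @examples
#' balanced_error_rate(c("A", "A", "A", "A", "B", "B"),
#'                     c("A", "A", "A", "B", "B", "A"))  # (1/4 + 1/2) / 2
#' @export
balanced_error_rate <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  classes <- unique(truth)
  if (anyNA(truth) || any(table(truth)[classes] == 0)) {
    stop("every true class must be nonempty", call. = FALSE)
  }
  per_class <- vapply(classes, function(cl) {
    idx <- truth == cl
    mean(predicted[idx] != cl)
  }, numeric(1))
  mean(per_class)
}
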