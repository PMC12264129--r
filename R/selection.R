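#' Repeated stratified k-fold cross-validation assignments
#'
#' Builds seeded, reproducible fold assignments: within each repeat, each
#' class is distributed across the `k` folds as evenly as possible and the
#' folds partition the samples.
#'
#' @param labels class labels, one per sample.
#' @param k number of folds (default 3).
#' @param repeats number of repeats (default 100).
#' @param seed integer seed.
#' @return an object of class `cv_splits`: a list with `folds` (a list of
#'   `repeats` integer vectors of fold ids in `1..k`), `k`, `repeats`,
#'   `seed`.
#' @export
cv_splits <- function(labels, k = 3, repeats = 100, seed = 1) {
  labels <- as.character(labels)
  k <- check_count(k, "k", min = 2)
  repeats <- check_count(repeats, "repeats", min = 1)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(tab)[which(tab < k)[1]], k), call. = FALSE)
  }
  n <- length(labels)
  folds <- with_seed(seed, lapply(seq_len(repeats), function(r) {
    f <- integer(n)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  }))
  structure(list(folds = folds, k = k, repeats = repeats, seed = seed,
                 labels = labels),
            class = "cv_splits")
}

# Fit one training fold: learn autoscaling on the training rows only,
# apply it to the held-out rows, fit the model on the scaled training data.
# This is the single place fold preprocessing happens, so held-out data can
# never leak into the fitted model.
fit_one_fold <- function(X, y, train, ncomp, keepX, tol = 1e-6) {
  Xtr <- X[train, , drop = FALSE]
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, sample_sd)
  scl[scl == 0 | is.na(scl)] <- 1  # constant-in-fold features carry 0 signal
  Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  model <- splsda(Xtr, y[train], ncomp = ncomp, keepX = keepX, tol = tol)
  list(model = model, center = ctr, scale = scl)
}

predict_fold <- function(fit, X, test, dist = "centroid") {
  Xte <- sweep(sweep(X[test, , drop = FALSE], 2, fit$center), 2,
               fit$scale, "/")
  predict(fit$model, Xte, dist = dist)$class
}

# Evaluate a (ncomp, keepX) configuration over every fold of every repeat.
# Returns the per-fold balanced error rates and, optionally, the selection
# support (nonzero weight on any component) of each fold model.
cv_evaluate <- function(X, y, ncomp, keepX, cv, collect_support = FALSE,
                        dist = "centroid") {
  y <- factor(y)
  nfits <- cv$repeats * cv$k
  bers <- numeric(nfits)
  support <- if (collect_support) {
    matrix(FALSE, ncol(X), nfits, dimnames = list(colnames(X), NULL))
  } else NULL
  i <- 0L
  for (r in seq_len(cv$repeats)) {
    fold_id <- cv$folds[[r]]
    for (f in seq_len(cv$k)) {
      i <- i + 1L
      train <- fold_id != f
      fit <- fit_one_fold(X, y, train, ncomp, keepX)
      pred <- predict_fold(fit, X, !train, dist = dist)
      bers[i] <- balanced_error_rate(y[!train], pred)
      if (collect_support) {
        support[, i] <- rowSums(fit$model$weights != 0) > 0
      }
    }
  }
  list(ber = bers, support = support)
}

#' Tune sparse PLS-DA by grid search under repeated cross-validation
#'
#' Sequential per-component tuning of `keepX`, the criterion being the mean
#' balanced error rate (BER) over all folds of all repeats: component 1's
#' `keepX` is chosen by the minimal mean BER of one-component models, then
#' fixed while component 2 is tuned, and so on.  Ties go to the smaller
#' `keepX`.  The number of components is then chosen as the smallest `H`
#' whose mean BER is within one SD (of the fold-level BERs at the global
#' minimum) of the global minimum, favouring parsimonious models.
#' Autoscaling is learned on each training fold only and applied to the
#' held-out fold, so `X` should be on the TIC-normalised log scale, not
#' pre-autoscaled.
#'
#' @param X numeric matrix, samples x features (log scale; fold autoscaling
#'   is internal).
#' @param y class labels.
#' @param ncomp_max maximum number of components to consider (default 2).
#' @param keepx_grid candidate `keepX` values; default
#'   `seq(5, min(100, p), by = 5)`.
#' @param cv fold assignments from [cv_splits()].
#' @param dist prediction distance rule used for the held-out folds
#'   (see [predict.splsda()]).  The default here is `"centroid"`: BER-based
#'   tuning must be able to score a class that lies between two others
#'   (the prodromal pattern), which the argmax dummy-score rule cannot.
#' @return an object of class `splsda_tune`: `grid` (data frame of
#'   component, keepX, mean and SD of BER), `ncomp`, `keepX` (chosen, one
#'   per retained component), `ber` (mean BER of the chosen
#'   configuration), `scheme`.
#' @export
splsda_tune <- function(X, y, ncomp_max = 2, keepx_grid = NULL, cv,
                        dist = "centroid") {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(keepx_grid)) {
    keepx_grid <- seq(5, min(100, p), by = 5)
    if (!length(keepx_grid)) keepx_grid <- p
  }
  keepx_grid <- sort(unique(as.integer(keepx_grid)))
  if (any(keepx_grid > p) || any(keepx_grid < 1)) {
    stop(sprintf("keepx_grid values must lie in [1, %d]", p), call. = FALSE)
  }
  ncomp_max <- check_count(ncomp_max, "ncomp_max", min = 1)
  stopifnot(inherits(cv, "cv_splits"))

  chosen <- integer(0)
  grid_rows <- list()
  best_mean <- numeric(ncomp_max)
  best_sd <- numeric(ncomp_max)
  for (h in seq_len(ncomp_max)) {
    means <- sds <- numeric(length(keepx_grid))
    for (g in seq_along(keepx_grid)) {
      res <- cv_evaluate(X, y, ncomp = h,
                         keepX = c(chosen, keepx_grid[g]), cv = cv,
                         dist = dist)
      means[g] <- mean(res$ber)
      sds[g] <- sample_sd(res$ber)
    }
    grid_rows[[h]] <- data.frame(component = h, keepX = keepx_grid,
                                 mean_ber = means, sd_ber = sds)
    best <- which.min(means)  # grid ascending: ties -> smallest keepX
    chosen <- c(chosen, keepx_grid[best])
    best_mean[h] <- means[best]
    best_sd[h] <- sds[best]
  }
  h_star <- which.min(best_mean)
  ncomp <- which(best_mean <= best_mean[h_star] + best_sd[h_star])[1]
  structure(list(grid = do.call(rbind, grid_rows),
                 ncomp = ncomp,
                 keepX = chosen[seq_len(ncomp)],
                 keepX_all = chosen,
                 ber = best_mean[ncomp],
                 per_component_ber = best_mean,
                 scheme = list(k = cv$k, repeats = cv$repeats,
                               seed = cv$seed)),
            class = "splsda_tune")
}

#' @export
print.splsda_tune <- function(x, ...) {
  cat(sprintf(
    "sPLS-DA tuning (%d-fold x %d repeats): ncomp = %d, keepX = %s\n",
    x$scheme$k, x$scheme$repeats, x$ncomp,
    paste(x$keepX, collapse = ", ")))
  cat(sprintf("  mean balanced error rate: %.4f\n", x$ber))
  invisible(x)
}

#' Cross-validation stability of feature selection
#'
#' Refits the model at a fixed `(ncomp, keepX)` on every training fold of
#' every repeat and scores each feature by the fraction of fold fits in
#' which it receives a nonzero weight on any component.  Features that the
#' model selects consistently across resampling are considered stable.
#'
#' @inheritParams splsda_tune
#' @param ncomp number of components.
#' @param keepX per-component cardinality (from tuning).
#' @return an object of class `stability_table`: named numeric vector of
#'   selection frequencies in \[0, 1\], with attribute `n_fits`
#'   (`k x repeats`).
#' @export
splsda_stability <- function(X, y, ncomp, keepX, cv, dist = "centroid") {
  X <- as.matrix(X)
  stopifnot(inherits(cv, "cv_splits"))
  res <- cv_evaluate(X, y, ncomp = ncomp, keepX = keepX, cv = cv,
                     collect_support = TRUE, dist = dist)
  freq <- rowMeans(res$support)
  structure(freq, class = "stability_table",
            n_fits = ncol(res$support), ber = mean(res$ber))
}

#' Flag significant features by VIP and cross-validation stability
#'
#' A feature is significant when its VIP score exceeds 1 on the designated
#' component view(s) and its selection stability exceeds 0.8; both
#' inequalities are strict.  The direction of regulation is the sign of
#' the difference in normalised group means (disease minus control).
#'
#' @param vips VIP scores from [splsda_vip()]: either the cumulative-view
#'   matrix (features x components) or a single named vector.
#' @param stability a [splsda_stability()] table over the same features.
#' @param components which cumulative VIP views to consider when `vips` is
#'   a matrix; the criterion uses the maximum over them.  Default: the last
#'   view (all fitted components).
#' @param X,y optional normalised data matrix and labels used to compute
#'   the direction of regulation; omit to skip directions.
#' @param disease,control group labels contrasted for the direction.
#' @param vip_threshold,stability_threshold strict cut-offs (defaults 1
#'   and 0.8).
#' @return an object of class `selection_report`: data frame with
#'   `feature_id`, `vip`, `stability`, `direction`, `significant`.
#' @export
select_significant <- function(vips, stability, components = NULL,
                               X = NULL, y = NULL,
                               disease = "PD", control = "Control",
                               vip_threshold = 1,
                               stability_threshold = 0.8) {
  if (is.matrix(vips)) {
    if (is.null(components)) components <- ncol(vips)
    if (any(components > ncol(vips))) {
      stop("designated components exceed the fitted VIP views",
           call. = FALSE)
    }
    vip_val <- apply(vips[, components, drop = FALSE], 1, max)
  } else {
    vip_val <- vips
  }
  feats <- names(vip_val)
  if (is.null(feats) || is.null(names(stability)) ||
      !setequal(feats, names(stability))) {
    stop("VIP and stability tables must cover the same features",
         call. = FALSE)
  }
  stab <- as.numeric(stability)[match(feats, names(stability))]
  direction <- rep(NA_character_, length(feats))
  if (!is.null(X) && !is.null(y)) {
    X <- as.matrix(X)[, feats, drop = FALSE]
    y <- as.character(y)
    diff <- colMeans(X[y == disease, , drop = FALSE]) -
      colMeans(X[y == control, , drop = FALSE])
    direction <- ifelse(diff > 0, "up", ifelse(diff < 0, "down", "none"))
  }
  out <- data.frame(feature_id = feats,
                    vip = as.numeric(vip_val),
                    stability = stab,
                    direction = direction,
                    significant = vip_val > vip_threshold &
                      stab > stability_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("selection_report", "data.frame"),
            vip_threshold = vip_threshold,
            stability_threshold = stability_threshold,
            components = components)
}

#' @export
print.selection_report <- function(x, ...) {
  vt <- attr(x, "vip_threshold")
  st <- attr(x, "stability_threshold")
  cat(sprintf(
    "Selection report: %d of %d features significant (VIP > %g, stability > %g)\n",
    sum(x$significant), nrow(x), if (is.null(vt)) NA else vt,
    if (is.null(st)) NA else st))
  print.data.frame(utils::head(x[order(-x$vip), ], 10), digits = 3)
  invisible(x)
}
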