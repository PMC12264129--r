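#' Matthews correlation coefficient
#'
#' Balanced agreement between observed and predicted classes: +1 is
#' perfect prediction, 0 is random-level, -1 complete disagreement.  For
#' two classes this is the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; for more than
#' two classes the standard multiclass generalisation (Gorodkin) is used,
#' which reduces to the binary formula at K = 2.  A zero denominator
#' (e.g. all predictions one class) returns 0, the random-level value.
#'
#' @param truth true class labels; at least two distinct classes.
#' @param predicted predicted class labels.
#' @return a number in \[-1, 1\].
#' @examples
#' mcc(rep(c("a", "b"), c(6, 5)),
#'     rep(c("a", "b", "a", "b"), c(4, 2, 1, 4)))  # 10 / sqrt(600)
#' @export
mcc <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(unique(truth)) < 2) {
    stop("truth must contain at least two distinct classes", call. = FALSE)
  }
  classes <- sort(unique(c(truth, predicted)))
  Cm <- table(factor(truth, classes), factor(predicted, classes))
  s <- sum(Cm)
  c_ <- sum(diag(Cm))
  t_k <- rowSums(Cm)
  p_k <- colSums(Cm)
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' Parameters of the constrained random-forest protocol
#'
#' The battery guards against overfitting small, imbalanced cohorts by
#' constraining every forest: tree depth at most 3, no split of a node
#' smaller than 5, `floor(sqrt(p))` attributes drawn at each node, and
#' class weights inversely proportional to class frequencies.  Data are
#' repeatedly split 66% training / 34% testing.
#'
#' @param n_splits number of train/test splits (default 100).
#' @param train_fraction fraction used for training (default 0.66).
#' @param max_depth maximum tree depth (default 3).
#' @param min_split_size smallest node that may be split (default 5).
#' @param num_trees trees per forest (default 500).
#' @param seed integer seed; each split derives its own sub-seed.
#' @return a list of class `rf_params`.
#' @export
rf_params <- function(n_splits = 100, train_fraction = 0.66, max_depth = 3,
                      min_split_size = 5, num_trees = 500, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_field("train_fraction", "must lie in (0, 1)")
  }
  structure(list(n_splits = check_count(n_splits, "n_splits", min = 1),
                 train_fraction = train_fraction,
                 max_depth = check_count(max_depth, "max_depth", min = 1),
                 min_split_size = check_count(min_split_size,
                                              "min_split_size", min = 1),
                 num_trees = check_count(num_trees, "num_trees", min = 1),
                 seed = check_count(seed, "seed")),
            class = "rf_params")
}

#' Constrained random-forest protocol with repeated splits
#'
#' Runs the full protocol on a significant-feature matrix: for each of
#' `n_splits` seeded 66/34 train/test splits (stratified by class for
#' classification), fits a random forest under the constraints of
#' [rf_params()] and predicts the held-out third.  Per-sample test
#' predictions are aggregated across splits by majority vote
#' (classification) or mean (regression); the summary reports the mean
#' per-split accuracy, the aggregated-vote accuracy and MCC for
#' classification, or the aggregated R-squared (`1 - SSE/SST` on the
#' aggregated test predictions) for regression, plus attribute importances
#' (impurity decrease) averaged across splits.
#'
#' @param X numeric matrix of attributes (typically the significant
#'   features), samples x features.
#' @param outcome factor/character/logical (classification) or numeric
#'   (regression) outcome, one per row.
#' @param params an [rf_params()] object.
#' @param extra_attribute optional additional attribute column (e.g. a
#'   confounder) appended to `X`; the attributes-per-node rule then uses
#'   `floor(sqrt(p + 1))`.
#' @param extra_name column name for the extra attribute.
#' @return a list of class `rf_protocol` with `type`, `mean_split_accuracy`
#'   (classification), `vote_accuracy`, `mcc` or `r2`, `importance`,
#'   `mtry`, `params`.
#' @export
rf_protocol <- function(X, outcome, params = rf_params(),
                        extra_attribute = NULL, extra_name = "confounder") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(outcome) != n) {
    stop("outcome length must match rows of X", call. = FALSE)
  }
  attrs <- as.data.frame(X, check.names = FALSE)
  if (!is.null(extra_attribute)) {
    if (is.factor(extra_attribute) || is.character(extra_attribute)) {
      extra_attribute <- factor(extra_attribute)
    }
    attrs[[extra_name]] <- extra_attribute
  }
  # canonical attribute order, so results are invariant to the column
  # order of X (the per-node attribute draw is index-based)
  attrs <- attrs[, order(colnames(attrs)), drop = FALSE]
  p_attr <- ncol(attrs)
  mtry <- max(1L, floor(sqrt(p_attr)))

  classification <- is.factor(outcome) || is.character(outcome) ||
    is.logical(outcome)
  if (classification) {
    y <- droplevels(factor(outcome))
    tab <- table(y)
    if (any(tab < 2)) {
      stop(sprintf("class '%s' has fewer than 2 members",
                   names(tab)[which(tab < 2)[1]]), call. = FALSE)
    }
    votes <- matrix(0L, n, nlevels(y), dimnames = list(NULL, levels(y)))
  } else {
    y <- as.numeric(outcome)
    if (stats::var(y) == 0) {
      stop("continuous outcome has zero variance", call. = FALSE)
    }
    pred_sum <- pred_n <- numeric(n)
  }

  split_acc <- numeric(params$n_splits)
  imp_sum <- stats::setNames(numeric(p_attr), colnames(attrs))
  for (i in seq_len(params$n_splits)) {
    seed_i <- derive_seed(params$seed, i)
    # the whole split runs under a pinned RNG state: ranger consults the
    # global R stream when breaking prediction-vote ties
    split_res <- with_seed(seed_i, {
      train <- if (classification) {
        unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          n_tr <- min(length(idx) - 1L,
                      max(1L, round(params$train_fraction * length(idx))))
          sample(idx, n_tr)
        }), use.names = FALSE)
      } else {
        sample.int(n, min(n - 1L,
                          max(2L, round(params$train_fraction * n))))
      }
      cw <- NULL
      if (classification) {
        tr_tab <- table(y[train])
        cw <- as.numeric(1 / pmax(tr_tab, 0.5))
      }
      rf <- ranger::ranger(
        x = attrs[train, , drop = FALSE], y = y[train],
        num.trees = params$num_trees, mtry = mtry,
        max.depth = params$max_depth,
        min.node.size = params$min_split_size,
        class.weights = cw, importance = "impurity",
        seed = seed_i, num.threads = 1
      )
      test <- setdiff(seq_len(n), train)
      list(test = test,
           pred = stats::predict(rf, data = attrs[test, , drop = FALSE],
                                 num.threads = 1)$predictions,
           importance = rf$variable.importance)
    })
    test <- split_res$test
    pred <- split_res$pred
    imp_sum <- imp_sum + split_res$importance[colnames(attrs)]
    if (classification) {
      split_acc[i] <- mean(pred == y[test])
      votes[cbind(test, as.integer(factor(pred, levels(y))))] <-
        votes[cbind(test, as.integer(factor(pred, levels(y))))] + 1L
    } else {
      split_acc[i] <- NA_real_
      pred_sum[test] <- pred_sum[test] + pred
      pred_n[test] <- pred_n[test] + 1L
    }
  }

  out <- list(type = if (classification) "classification" else "regression",
              importance = imp_sum / params$n_splits,
              mtry = mtry, params = params, n = n)
  if (classification) {
    covered <- rowSums(votes) > 0
    vote_class <- levels(y)[max.col(votes[covered, , drop = FALSE],
                                    ties.method = "first")]
    out$mean_split_accuracy <- mean(split_acc)
    out$vote_accuracy <- mean(vote_class == as.character(y)[covered])
    out$mcc <- mcc(as.character(y)[covered], vote_class)
  } else {
    covered <- pred_n > 0
    pred_mean <- pred_sum[covered] / pred_n[covered]
    sse <- sum((y[covered] - pred_mean)^2)
    sst <- sum((y[covered] - mean(y[covered]))^2)
    out$r2 <- 1 - sse / sst
  }
  structure(out, class = "rf_protocol")
}

#' @export
print.rf_protocol <- function(x, ...) {
  if (x$type == "classification") {
    cat(sprintf(
      "RF protocol (classification, %d splits): vote accuracy %.3f, MCC %.3f\n",
      x$params$n_splits, x$vote_accuracy, x$mcc))
  } else {
    cat(sprintf("RF protocol (regression, %d splits): R2 %.3f\n",
                x$params$n_splits, x$r2))
  }
  invisible(x)
}

#' Adjusted-versus-unadjusted confounder comparison
#'
#' Runs the random-forest protocol on the significant features without and
#' with a candidate confounder added as an attribute.  A confounding
#' effect is concluded when the adjusted model's aggregated classification
#' accuracy improves by at least 10 percentage points.  Also reports the
#' confounder's importance rank among all attributes of the adjusted model
#' and whether it falls in the top half.
#'
#' @param X significant-feature matrix, samples x features.
#' @param phenotype class labels.
#' @param confounder confounder column (numeric, or factor/character for
#'   categorical); rows with missing values are dropped with a warning.
#' @param params an [rf_params()] object.
#' @param confounder_name label used in reports.
#' @param improvement_points flag threshold in absolute percentage points
#'   (default 10).
#' @return a list of class `confounder_comparison` with unadjusted and
#'   adjusted accuracy/MCC, `improvement_points`, `confounded` flag,
#'   `importance_rank`, `top_half`.
#' @export
adjusted_comparison <- function(X, phenotype, confounder,
                                params = rf_params(),
                                confounder_name = "confounder",
                                improvement_points = 10) {
  X <- as.matrix(X)
  keep <- !is.na(confounder)
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with missing confounder",
                    sum(!keep)), call. = FALSE)
    X <- X[keep, , drop = FALSE]
    phenotype <- phenotype[keep]
    confounder <- confounder[keep]
  }
  unadj <- rf_protocol(X, phenotype, params)
  adj <- rf_protocol(X, phenotype, params, extra_attribute = confounder,
                     extra_name = confounder_name)
  improvement <- 100 * (adj$vote_accuracy - unadj$vote_accuracy)
  rk <- rank(-adj$importance, ties.method = "min")[confounder_name]
  structure(list(confounder = confounder_name,
                 unadjusted_accuracy = unadj$vote_accuracy,
                 adjusted_accuracy = adj$vote_accuracy,
                 unadjusted_mcc = unadj$mcc,
                 adjusted_mcc = adj$mcc,
                 improvement_points = improvement,
                 confounded = improvement >= improvement_points,
                 importance_rank = unname(rk),
                 n_attributes = length(adj$importance),
                 top_half = unname(rk) <= length(adj$importance) / 2,
                 unadjusted = unadj, adjusted = adj),
            class = "confounder_comparison")
}

#' @export
print.confounder_comparison <- function(x, ...) {
  cat(sprintf(
    "Confounder '%s': accuracy %.3f -> %.3f (%+.1f points) => %s\n",
    x$confounder, x$unadjusted_accuracy, x$adjusted_accuracy,
    x$improvement_points,
    if (x$confounded) "CONFOUNDED" else "no confounding"))
  cat(sprintf("  importance rank %d of %d (%s half)\n", x$importance_rank,
              x$n_attributes, if (x$top_half) "top" else "bottom"))
  invisible(x)
}

#' Predict a confounder from the significant features
#'
#' Turns the tables: uses each candidate confounder as the outcome of the
#' random-forest protocol, asking whether the significant features can
#' classify (categorical) or regress against (continuous) the confounder.
#' The MCC or R-squared is reported without a pass/fail threshold: values
#' near zero indicate the features carry no confounder information.
#'
#' @inheritParams adjusted_comparison
#' @param confounder outcome column; factor/character/logical is treated as
#'   categorical (MCC), numeric as continuous (R-squared).
#' @return a list with `type`, `metric` (`"mcc"` or `"r2"`), `value` and
#'   the full `rf_protocol` result.
#' @export
confounder_as_outcome <- function(X, confounder, params = rf_params()) {
  keep <- !is.na(confounder)
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with missing confounder",
                    sum(!keep)), call. = FALSE)
    X <- as.matrix(X)[keep, , drop = FALSE]
    confounder <- confounder[keep]
  }
  res <- rf_protocol(X, confounder, params)
  if (res$type == "classification") {
    list(type = "classification", metric = "mcc", value = res$mcc,
         protocol = res)
  } else {
    list(type = "regression", metric = "r2", value = res$r2,
         protocol = res)
  }
}

#' Pearson correlation screen against clinical covariates
#'
#' Correlates every feature with every covariate (medication doses,
#' clinical scores, binary-coded flags) and flags absolute Pearson
#' correlations above the threshold.  Zero-variance columns make the
#' correlation undefined and are reported as `NA` with a note.
#'
#' @param X feature matrix, samples x features.
#' @param covariates data frame of numeric or binary-codable covariates
#'   (logical and two-level factors are coded 0/1).
#' @param threshold absolute-correlation flag bound (default 0.5, strict).
#' @return data frame (class `correlation_screen`) with `feature_id`,
#'   `covariate`, `r`, `flagged`, `note`.
#' @export
correlation_screen <- function(X, covariates, threshold = 0.5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  covariates <- as.data.frame(covariates)
  num <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) return(v)
    if (is.logical(v)) return(as.numeric(v))
    f <- factor(v)
    if (nlevels(f) == 2) return(as.numeric(f) - 1)
    stop(sprintf(
      "covariate '%s' is neither numeric nor binary-codable", nm),
      call. = FALSE)
  })
  cm <- do.call(cbind, num)
  colnames(cm) <- names(covariates)
  suppressWarnings(r <- stats::cor(X, cm))  # zero variance -> NA
  out <- data.frame(
    feature_id = rep(colnames(X), times = ncol(cm)),
    covariate = rep(colnames(cm), each = ncol(X)),
    r = as.vector(r),
    stringsAsFactors = FALSE
  )
  out$flagged <- !is.na(out$r) & abs(out$r) > threshold
  out$note <- ifelse(is.na(out$r), "undefined (zero variance)", "")
  structure(out, class = c("correlation_screen", "data.frame"),
            threshold = threshold)
}
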