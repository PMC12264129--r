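# Shared fixture builders, all generated in code at test time.

# Two (or three) Gaussian clouds with a shift planted on the first
# `n_shift` features of the non-reference classes.
make_clouds <- function(n_per = 12, p = 20, n_shift = 3, shift = 2,
                        classes = c("A", "B"), seed = 1) {
  withr_seed <- function(code) sebovol:::with_seed(seed, code)
  withr_seed({
    n <- n_per * length(classes)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("V%02d", seq_len(p))))
    y <- rep(classes, each = n_per)
    for (k in seq_along(classes)[-1]) {
      X[y == classes[k], seq_len(n_shift)] <-
        X[y == classes[k], seq_len(n_shift)] + (k - 1) * shift
    }
    list(X = X, y = y)
  })
}

# Minimal feature_matrix with prescribed per-group feature means
# (groups x features), one sample per group per replicate plus iid noise 0.
fm_from_means <- function(means, groups, n_rep = 2, timepoint = NULL,
                          subject = NULL) {
  idx <- rep(seq_along(groups), each = n_rep)
  ab <- means[idx, , drop = FALSE]
  ns <- length(idx)
  sm <- data.frame(
    sample_id = sprintf("S%03d", seq_len(ns)),
    phenotype = if (all(groups %in% c("PD", "Control", "iRBD")))
      groups[idx] else "PD",
    stringsAsFactors = FALSE
  )
  if (!is.null(timepoint)) sm$timepoint <- timepoint[idx]
  if (!is.null(subject)) sm$subject_id <- subject
  colnames(ab) <- sprintf("F%03d", seq_len(ncol(ab)))
  # construct with non-negative raw values, then restore the requested
  # (possibly negative, i.e. normalised-scale) means
  m <- feature_matrix(ab - min(ab) + 1, sm)
  m$abundance <- ab
  rownames(m$abundance) <- sm$sample_id
  m
}

# Column-centred one-hot dummy matrix for labels.
dummy_y <- function(y) {
  Y <- stats::model.matrix(~ factor(y) - 1)
  colnames(Y) <- levels(factor(y))
  scale(Y, scale = FALSE)
}
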