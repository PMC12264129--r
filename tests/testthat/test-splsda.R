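test_that("dense fit (keepX = p) reproduces reference NIPALS PLS2 scores", {
  cases <- list(
    list(n_per = 10, p = 15, classes = c("A", "B"), ncomp = 3, seed = 42),
    list(n_per = 7, p = 20, classes = c("A", "B", "C"), ncomp = 2, seed = 9),
    list(n_per = 10, p = 8, classes = c("A", "B"), ncomp = 2, seed = 5)
  )
  for (cs in cases) {
    d <- make_clouds(cs$n_per, cs$p, n_shift = 3, shift = 1.5,
                     classes = cs$classes, seed = cs$seed)
    Xs <- scale(d$X)
    fit <- splsda(Xs, d$y, ncomp = cs$ncomp, keepX = cs$p)
    ref <- suppressMessages(
      mixOmics::pls(Xs, dummy_y(d$y), ncomp = cs$ncomp, scale = FALSE,
                    mode = "regression"))
    for (h in seq_len(cs$ncomp)) {
      expect_gt(abs(stats::cor(fit$scores[, h], ref$variates$X[, h])),
                0.999)
    }
  }
})

test_that("dense fit reproduces reference PLS-DA predictions held out", {
  d <- make_clouds(15, 12, n_shift = 3, shift = 2, seed = 9)
  tr <- c(1:10, 16:25)
  te <- setdiff(seq_len(30), tr)
  ctr <- colMeans(d$X[tr, ])
  scl <- apply(d$X[tr, ], 2, stats::sd)
  Xtr <- scale(d$X[tr, ], ctr, scl)
  Xte <- scale(d$X[te, ], ctr, scl)
  fit <- splsda(Xtr, d$y[tr], ncomp = 2, keepX = 12)
  mine <- predict(fit, Xte)$class
  ref <- suppressMessages(
    mixOmics::plsda(Xtr, factor(d$y[tr]), ncomp = 2, scale = FALSE))
  theirs <- predict(ref, Xte)$class$max.dist[, 2]
  expect_equal(as.character(mine), unname(as.character(theirs)))
})

test_that("component-1 support matches the exhaustive best pair", {
  for (seed in c(3, 11, 27)) {
    d <- make_clouds(12, 20, n_shift = 2, shift = 3, seed = seed)
    Xs <- scale(d$X)
    fit <- splsda(Xs, d$y, ncomp = 1, keepX = 2)
    supp <- which(fit$weights[, 1] != 0)
    # brute force: the support maximising the leading eigenvalue of the
    # corresponding 2x2 block of (X'Y)(X'Y)'
    M <- crossprod(Xs, dummy_y(d$y))
    MM <- tcrossprod(M)
    p <- ncol(Xs)
    best <- NULL
    bestval <- -Inf
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        val <- max(eigen(MM[c(i, j), c(i, j)], symmetric = TRUE)$values)
        if (val > bestval) {
          bestval <- val
          best <- c(i, j)
        }
      }
    }
    expect_equal(sort(unname(supp)), best)
  }
})

test_that("fitted models satisfy the structural invariants", {
  d <- make_clouds(8, 15, n_shift = 4, shift = 1.5,
                   classes = c("A", "B", "C"), seed = 2)
  Xs <- scale(d$X)
  for (keepX in list(c(5, 3), c(15, 15), 4)) {
    fit <- splsda(Xs, d$y, ncomp = 2, keepX = keepX)
    kx <- rep_len(keepX, 2)
    for (h in 1:2) {
      expect_equal(sum(fit$weights[, h]^2), 1, tolerance = 1e-10)
      expect_lte(sum(fit$weights[, h] != 0), kx[h])
      # sign convention: largest-magnitude weight positive
      expect_gt(fit$weights[which.max(abs(fit$weights[, h])), h], 0)
    }
    orth <- abs(sum(fit$scores[, 1] * fit$scores[, 2]))
    expect_lt(orth, 1e-8 * sqrt(sum(fit$scores[, 1]^2)) *
                sqrt(sum(fit$scores[, 2]^2)))
  }
  # deterministic: identical inputs, identical model
  expect_identical(splsda(Xs, d$y, ncomp = 2, keepX = 5),
                   splsda(Xs, d$y, ncomp = 2, keepX = 5))
  # reducing keepX never increases the number of nonzero weights
  nnz <- vapply(c(12, 8, 4, 2), function(k) {
    sum(splsda(Xs, d$y, ncomp = 1, keepX = k)$weights != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("degenerate fits are rejected", {
  d <- make_clouds(8, 10, seed = 1)
  Xs <- scale(d$X)
  expect_error(splsda(Xs, rep("A", 16), ncomp = 1), "two classes")
  expect_error(splsda(Xs, d$y, ncomp = 1, keepX = 11), "keepX")
  expect_error(splsda(Xs, d$y, ncomp = 40), "rank")
})

test_that("VIP satisfies its sum identity and one-hot special case", {
  d <- make_clouds(10, 12, n_shift = 3, shift = 2, seed = 8)
  Xs <- scale(d$X)
  for (kx in c(3, 7, 12)) {
    fit <- splsda(Xs, d$y, ncomp = 2, keepX = kx)
    v <- splsda_vip(fit)
    for (h in 1:2) {
      expect_equal(sum(v[, h]^2), ncol(Xs), tolerance = 1e-6 * ncol(Xs))
    }
  }
  # keepX = 1 forces a one-hot weight: VIP sqrt(p) for it, 0 elsewhere
  fit1 <- splsda(Xs, d$y, ncomp = 1, keepX = 1)
  v1 <- splsda_vip(fit1, cumulative = FALSE)
  sel <- which(fit1$weights[, 1] != 0)
  expect_equal(unname(v1[sel]), sqrt(ncol(Xs)))
  expect_equal(unname(v1[-sel]), rep(0, ncol(Xs) - 1))
  # planted features outrank null features
  v2 <- splsda_vip(splsda(Xs, d$y, ncomp = 1, keepX = 12),
                   cumulative = FALSE)
  expect_gt(min(v2[1:3]), max(v2[4:12]))
  expect_error(splsda_vip(fit1, upto = 5), "upto")
})

test_that("balanced error rate matches forced arithmetic", {
  expect_equal(balanced_error_rate(c("a", "b", "a"), c("a", "b", "a")), 0)
  # class A: 4 samples 1 wrong; class B: 2 samples 1 wrong
  truth <- c("A", "A", "A", "A", "B", "B")
  pred <- c("A", "A", "A", "B", "B", "A")
  expect_equal(balanced_error_rate(truth, pred), 0.375)
  # all predictions one class, K = 3 -> (K-1)/K
  truth3 <- rep(c("A", "B", "C"), each = 2)
  expect_equal(balanced_error_rate(truth3, rep("A", 6)), 2 / 3)
  expect_error(balanced_error_rate(c("a", "b"), c("a", "b", "b")),
               "equal length")
})

test_that("prediction behaves at the training data and the centre point", {
  d <- make_clouds(10, 10, n_shift = 3, shift = 4, seed = 12)
  Xs <- scale(d$X)
  fit <- splsda(Xs, d$y, ncomp = 2, keepX = 10)
  expect_equal(as.character(predict(fit, Xs)$class), d$y)
  # the autoscaled mean point scores exactly the centring offsets
  centre <- matrix(0, 1, 10, dimnames = list(NULL, colnames(Xs)))
  pr <- predict(fit, centre)
  expect_equal(unname(drop(pr$scores)), unname(fit$y_means))
  # feature mismatch errors list the missing ids
  bad <- Xs[, 1:8]
  expect_error(predict(fit, bad), "V09")
})

test_that("centroid rule recovers an intermediate class argmax cannot", {
  # class M lies exactly between A and B along the signal axis
  set.seed(31)
  n_per <- 20
  X <- matrix(stats::rnorm(3 * n_per * 10, sd = 0.5), 3 * n_per, 10,
              dimnames = list(NULL, sprintf("V%02d", 1:10)))
  y <- rep(c("A", "M", "B"), each = n_per)
  X[y == "A", 1:4] <- X[y == "A", 1:4] - 2
  X[y == "B", 1:4] <- X[y == "B", 1:4] + 2
  Xs <- scale(X)
  fit <- splsda(Xs, y, ncomp = 2, keepX = 10)
  ber_max <- balanced_error_rate(y, predict(fit, Xs, dist = "max")$class)
  ber_cen <- balanced_error_rate(y, predict(fit, Xs,
                                            dist = "centroid")$class)
  ber_mah <- balanced_error_rate(y, predict(fit, Xs,
                                            dist = "mahalanobis")$class)
  expect_lt(ber_cen, 0.1)
  expect_lt(ber_mah, 0.15)
  expect_gt(ber_max, ber_cen)  # argmax cannot see the middle class
})
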