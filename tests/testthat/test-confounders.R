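test_that("MCC matches its closed form on every small 2x2 table", {
  # exhaustive oracle over all confusion tables with cell counts <= 5
  binary_closed_form <- function(tp, fn, fp, tn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  for (tp in 0:5) for (fn in 0:5) for (fp in 0:5) for (tn in 0:5) {
    if (tp + fn == 0 || fp + tn == 0) next  # needs two true classes
    truth <- rep(c("pos", "neg"), c(tp + fn, fp + tn))
    pred <- c(rep(c("pos", "neg"), c(tp, fn)),
              rep(c("pos", "neg"), c(fp, tn)))
    expect_equal(mcc(truth, pred), binary_closed_form(tp, fn, fp, tn),
                 tolerance = 1e-12)
  }
})

test_that("MCC endpoints and degenerate predictions behave as defined", {
  expect_equal(mcc(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_equal(mcc(c("a", "b"), c("b", "a")), -1)
  # worked example: TP=4, TN=3, FP=1, FN=2 -> 10/sqrt(600)
  truth <- rep(c("pos", "neg"), c(6, 4))
  pred <- c(rep("pos", 4), rep("neg", 2), "pos", rep("neg", 3))
  expect_equal(mcc(truth, pred), 10 / sqrt(600))
  # all predictions one class: zero-denominator convention -> 0
  expect_equal(mcc(c("a", "a", "b"), c("a", "a", "a")), 0)
  expect_error(mcc(c("a", "a"), c("a", "b")), "two distinct")
})

test_that("rf protocol learns a deterministic single-attribute rule", {
  set.seed(1)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("A%02d", 1:10)))
  y <- ifelse(X[, 1] > 0, "hi", "lo")
  params <- rf_params(n_splits = 40, num_trees = 200, seed = 3)
  res <- rf_protocol(X, y, params)
  expect_gte(res$vote_accuracy, 0.95)
  expect_equal(res$mtry, 3)  # floor(sqrt(10))
  expect_equal(which.max(res$importance), c(A01 = 1L))
  # with an extra attribute the sqrt rule counts p + 1
  res2 <- rf_protocol(X[, 1:8], y, params, extra_attribute = rnorm(n))
  expect_equal(res2$mtry, 3)  # floor(sqrt(9))
  # reproducible under a fixed seed, invariant to column order
  res_b <- rf_protocol(X, y, params)
  expect_identical(res$vote_accuracy, res_b$vote_accuracy)
  expect_identical(res$importance, res_b$importance)
  res_perm <- rf_protocol(X[, sample(10)], y, params)
  expect_identical(res$vote_accuracy, res_perm$vote_accuracy)
  expect_identical(res$importance, res_perm$importance)
})

test_that("permuted labels give random-level MCC", {
  set.seed(7)
  n <- 50
  X <- matrix(rnorm(n * 10), n, 10)
  params <- rf_params(n_splits = 30, num_trees = 150, seed = 11)
  mccs <- vapply(1:5, function(s) {
    y <- sebovol:::with_seed(s, sample(rep(c("u", "v"), each = n / 2)))
    rf_protocol(X, y, params)$mcc
  }, numeric(1))
  expect_true(all(abs(mccs) < 0.35))
  expect_lt(abs(mean(mccs)), 0.2)
})

test_that("rf protocol rejects degenerate outcomes", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(rf_protocol(X, c("a", rep("b", 19)), rf_params()),
               "fewer than 2")
  expect_error(rf_protocol(X, rep(1, 20), rf_params()), "zero variance")
  expect_error(rf_protocol(X, rep("a", 10), rf_params()), "length")
})

test_that("a constant confounder neither helps nor ranks", {
  sim <- generate_volatilome(simulation_spec(
    n_per_group = 15, n_features = 15, n_discriminative = 8,
    effect_size = 2, phenotypes = c("PD", "Control"), seed = 4))
  mn <- normalize_matrix(sim$matrix)
  params <- rf_params(n_splits = 25, num_trees = 150, seed = 5)
  cmp <- adjusted_comparison(mn$abundance, mn$sample_meta$phenotype,
                             rep(1.5, nrow(mn$abundance)), params,
                             confounder_name = "const")
  expect_false(cmp$confounded)
  expect_lt(abs(cmp$adjusted$importance[["const"]]),
            1e-8 + 0.01 * max(cmp$adjusted$importance))
  expect_false(cmp$top_half)
})

test_that("confounder-as-outcome separates leak from independence", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  params <- rf_params(n_splits = 30, num_trees = 150, seed = 6)
  conf <- rnorm(n)
  # independent continuous confounder: no predictive signal
  expect_lte(confounder_as_outcome(X, conf, params)$value, 0.1)
  # gross leak: confounder copied into half the columns; even the
  # depth-limited forests then regress it near-perfectly
  X_leak <- X
  X_leak[, 1:4] <- conf
  expect_gte(confounder_as_outcome(X_leak, conf, params)$value, 0.9)
  # a single leaked column among 8 still shows a clear signal, though the
  # sqrt(p) attribute draw under depth 3 attenuates it
  X_one <- X
  X_one[, 1] <- conf
  expect_gte(confounder_as_outcome(X_one, conf, params)$value, 0.4)
  # binary confounder perfectly separated by one feature
  bin <- ifelse(X[, 2] > 0, "yes", "no")
  out <- confounder_as_outcome(X, bin, params)
  expect_equal(out$metric, "mcc")
  expect_gte(out$value, 0.9)
})

test_that("correlation screen flags exact and negated copies only", {
  set.seed(3)
  n <- 50
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  cov <- data.frame(same = X[, 1], neg = -X[, 2], indep = rnorm(n),
                    flat = rep(2, n))
  scr <- correlation_screen(X, cov)
  expect_equal(scr$r[scr$feature_id == "f1" & scr$covariate == "same"], 1)
  expect_equal(scr$r[scr$feature_id == "f2" & scr$covariate == "neg"], -1)
  expect_true(scr$flagged[scr$feature_id == "f1" & scr$covariate == "same"])
  expect_true(scr$flagged[scr$feature_id == "f2" & scr$covariate == "neg"])
  # an independent covariate rarely exceeds |r| = 0.5 at n = 50
  indep <- scr[scr$covariate == "indep", ]
  expect_gte(mean(abs(indep$r) < 0.5), 0.95)
  # zero variance: undefined, reported as NA with a note
  flat <- scr[scr$covariate == "flat", ]
  expect_true(all(is.na(flat$r)))
  expect_match(flat$note[1], "zero variance")
  expect_error(correlation_screen(X, data.frame(
    bad = rep(letters[1:3], length.out = 50))), "binary")
})

test_that("the 10-point rule flags confounder-driven but not direct signal", {
  params <- rf_params(n_splits = 60, num_trees = 200, seed = 8)
  # positive control: phenotype-linked confounder drives a few weak
  # features; the features alone classify poorly, the confounder well
  pos <- generate_volatilome(simulation_spec(
    n_per_group = 25, n_features = 20, n_discriminative = 0,
    n_confounded = 5, confounder_strength = 0.3, confounder_assoc = 2.5,
    phenotypes = c("PD", "Control"), seed = 12))
  mp <- normalize_matrix(pos$matrix)
  cmp_pos <- adjusted_comparison(mp$abundance, mp$sample_meta$phenotype,
                                 mp$sample_meta$age, params, "age")
  expect_true(cmp_pos$confounded)
  # negative control: direct phenotype signal, independent confounder
  neg <- generate_volatilome(simulation_spec(
    n_per_group = 25, n_features = 20, n_discriminative = 20,
    effect_size = 1.5, n_confounded = 0, confounder_assoc = 0,
    phenotypes = c("PD", "Control"), seed = 12))
  mneg <- normalize_matrix(neg$matrix)
  cmp_neg <- adjusted_comparison(mneg$abundance,
                                 mneg$sample_meta$phenotype,
                                 mneg$sample_meta$age, params, "age")
  expect_false(cmp_neg$confounded)
  expect_false(cmp_neg$top_half)
})
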