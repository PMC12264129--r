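test_that("write then read round-trips the matrix and metadata", {
  sim <- generate_volatilome(simulation_spec(n_per_group = 4, n_features = 15,
                                             n_discriminative = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(sim$matrix, path)
  back <- read_matrix(path)
  expect_equal(back$abundance, sim$matrix$abundance, tolerance = 1e-12)
  expect_equal(back$sample_meta$phenotype, sim$matrix$sample_meta$phenotype)
  expect_equal(back$feature_meta$feature_id,
               sim$matrix$feature_meta$feature_id)
})

test_that("a small hand-written file parses to its literal values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,phenotype,f1,f2",
               "s1,PD,1,2", "s2,Control,3,4", "s3,iRBD,5,6"), path)
  m <- read_matrix(path)
  expect_equal(unname(m$abundance),
               matrix(c(1, 3, 5, 2, 4, 6), 3, 2))
  expect_equal(m$feature_meta$feature_id, c("f1", "f2"))
})

test_that("validation errors name the offending row or value", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,phenotype,f1", "s1,PD,1", "s2,PDD,2"), path)
  expect_error(read_matrix(path), "PDD.*s2")
  writeLines(c("sample_id,phenotype,f1", "s1,PD,1", "s1,PD,2"), path)
  expect_error(read_matrix(path), "duplicate sample id.*s1")
  writeLines(c("sample_id,phenotype,f1", "s1,PD,-3"), path)
  expect_error(read_matrix(path), "negative abundance.*s1")
})

test_that("annotation filter removes TMS/siloxane and weak matches only", {
  ab <- matrix(1:10, 2, 5,
               dimnames = list(c("s1", "s2"), paste0("F", 1:5)))
  sm <- data.frame(sample_id = c("s1", "s2"), phenotype = c("PD", "Control"))
  fmeta <- data.frame(
    feature_id = paste0("F", 1:5),
    annotation = c("hexadecane", "hexamethylcyclotrisiloxane",
                   "glycine, N,N-bis(trimethylsilyl)-", "unknown", NA),
    match_factor = c(70, 95, 95, 69, NA),
    stringsAsFactors = FALSE
  )
  m <- feature_matrix(ab, sm, fmeta)
  out <- suppressMessages(filter_annotations(m))
  # F1: MF exactly 70 kept (strict <); F2 siloxane and F3 TMS removed;
  # F4 MF 69 removed; F5 unannotated kept
  expect_setequal(out$feature_meta$feature_id, c("F1", "F5"))
  removed <- attr(out, "removed")
  expect_setequal(removed$feature_id, c("F2", "F3", "F4"))
  expect_match(removed$reason[removed$feature_id == "F4"], "match factor")
  # matrix with no annotation metadata passes through with a warning
  m2 <- feature_matrix(ab, sm)
  m2$feature_meta$annotation <- NULL
  m2$feature_meta$match_factor <- NULL
  expect_warning(out2 <- filter_annotations(m2), "unchanged")
  expect_equal(out2$abundance, m2$abundance)
})

test_that("%RSD QC matches hand computation and strict threshold", {
  # areas 10, 12, 8: mean 10, sample SD 2 -> %RSD exactly 20, which
  # fails the strict < 20 rule
  qc <- rsd_qc(cbind(mix = c(10, 12, 8)))
  expect_equal(qc$rsd_percent, 20)
  expect_false(attr(qc, "pass"))
  # identical areas -> 0, pass
  qc0 <- rsd_qc(cbind(a = c(5, 5, 5), b = c(3, 3, 3)))
  expect_equal(qc0$rsd_percent, c(0, 0))
  expect_true(attr(qc0, "pass"))
  # just under the bound passes
  x <- c(10, 10 * (1 + sqrt(2) * 0.199 / 2), 10 * (1 - sqrt(2) * 0.199 / 2))
  qcb <- rsd_qc(cbind(near = x))
  expect_lt(qcb$rsd_percent, 20)
  expect_true(attr(qcb, "pass"))
  expect_error(rsd_qc(cbind(z = c(-1, 1))), "zero mean")
  expect_error(rsd_qc(cbind(a = 1)), "at least 2")
})

test_that("TIC, log and autoscale satisfy their identities", {
  sim <- generate_volatilome(simulation_spec(n_per_group = 5, n_features = 20,
                                             n_discriminative = 3, seed = 4))
  m1 <- tic_normalize(sim$matrix)
  expect_equal(unname(rowSums(m1$abundance)),
               rep(1, nrow(m1$abundance)), tolerance = 1e-12)
  mn <- autoscale(log_transform(m1))
  expect_lt(max(abs(colMeans(mn$abundance))), 1e-10)
  expect_equal(unname(apply(mn$abundance, 2, stats::sd)),
               rep(1, ncol(mn$abundance)), tolerance = 1e-10)
  # hand-computed toy for the TIC step
  toy <- feature_matrix(matrix(c(1, 2, 3, 2), 2, 2),
                        data.frame(sample_id = c("a", "b"),
                                   phenotype = c("PD", "Control")))
  expect_equal(unname(tic_normalize(toy)$abundance),
               matrix(c(0.25, 0.5, 0.75, 0.5), 2, 2))
})

test_that("autoscaling is idempotent and TIC absorbs sample loading", {
  sim <- generate_volatilome(simulation_spec(n_per_group = 5, n_features = 20,
                                             n_discriminative = 3, seed = 6))
  mn <- normalize_matrix(sim$matrix)
  again <- autoscale(mn)
  expect_equal(again$abundance, mn$abundance, tolerance = 1e-8)
  # multiplying one raw sample by a constant changes nothing downstream
  m2 <- sim$matrix
  m2$abundance[3, ] <- m2$abundance[3, ] * 37.5
  expect_equal(normalize_matrix(m2)$abundance, mn$abundance,
               tolerance = 1e-10)
})

test_that("degenerate preprocessing inputs raise informative conditions", {
  ab <- matrix(c(0, 0, 1, 2), 2, 2,
               dimnames = list(NULL, c("f1", "f2")))
  ab[1, ] <- 0
  m <- feature_matrix(ab, data.frame(sample_id = c("sA", "sB"),
                                     phenotype = c("PD", "PD")))
  expect_error(tic_normalize(m), "sA")
  # constant feature dropped with a warning before scaling
  ab2 <- cbind(f1 = c(1, 2, 3), f2 = c(4, 4, 4))
  m2 <- feature_matrix(ab2, data.frame(sample_id = paste0("s", 1:3),
                                       phenotype = rep("PD", 3)))
  expect_warning(out <- autoscale(m2), "constant")
  expect_equal(out$feature_meta$feature_id, "f1")
})
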