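#' Construct a feature matrix with sample and feature metadata
#'
#' The central container of the pipeline: a samples-by-features table of
#' non-negative abundances (arbitrary ion-count units) together with
#' per-sample metadata (phenotype, site, timepoint, covariates) and
#' per-feature annotation metadata (putative identification, library match
#' factor).
#'
#' @param abundance numeric matrix, samples in rows, features in columns;
#'   values must be non-negative.  Row and column names, if absent, are
#'   taken from the metadata.
#' @param sample_meta data frame with at least `sample_id` and `phenotype`
#'   columns; phenotypes must come from `{PD, Control, iRBD}`.
#' @param feature_meta optional data frame with at least a `feature_id`
#'   column (plus typically `annotation` and `match_factor`).
#' @return an object of class `feature_matrix` (a list with elements
#'   `abundance`, `sample_meta`, `feature_meta`).
#' @export
feature_matrix <- function(abundance, sample_meta, feature_meta = NULL) {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) stop("abundance must be numeric", call. = FALSE)
  if (!is.data.frame(sample_meta) || is.null(sample_meta$sample_id)) {
    stop("sample_meta must be a data frame with a 'sample_id' column",
         call. = FALSE)
  }
  if (nrow(sample_meta) != nrow(abundance)) {
    stop("sample_meta rows must match abundance rows", call. = FALSE)
  }
  if (is.null(feature_meta)) {
    ids <- colnames(abundance)
    if (is.null(ids)) ids <- sprintf("F%04d", seq_len(ncol(abundance)))
    feature_meta <- data.frame(feature_id = ids,
                               annotation = NA_character_,
                               match_factor = NA_real_,
                               stringsAsFactors = FALSE)
  }
  if (is.null(feature_meta$feature_id) ||
      nrow(feature_meta) != ncol(abundance)) {
    stop("feature_meta must have a 'feature_id' row per feature",
         call. = FALSE)
  }
  rownames(abundance) <- sample_meta$sample_id
  colnames(abundance) <- feature_meta$feature_id
  m <- structure(list(abundance = abundance,
                      sample_meta = sample_meta,
                      feature_meta = feature_meta),
                 class = "feature_matrix")
  validate_feature_matrix(m)
  m
}

validate_feature_matrix <- function(m) {
  ab <- m$abundance
  sm <- m$sample_meta
  neg <- which(ab < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance at sample '%s', feature '%s'",
                 rownames(ab)[neg[1, 1]], colnames(ab)[neg[1, 2]]),
         call. = FALSE)
  }
  dup <- sm$sample_id[duplicated(sm$sample_id)]
  if (length(dup)) {
    stop(sprintf("duplicate sample id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  dupf <- m$feature_meta$feature_id[duplicated(m$feature_meta$feature_id)]
  if (length(dupf)) {
    stop(sprintf("duplicate feature id(s): %s",
                 paste(unique(dupf), collapse = ", ")), call. = FALSE)
  }
  if (is.null(sm$phenotype) || anyNA(sm$phenotype)) {
    bad <- if (is.null(sm$phenotype)) sm$sample_id else
      sm$sample_id[is.na(sm$phenotype)]
    stop(sprintf("missing phenotype label for sample(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  known <- c("PD", "Control", "iRBD")
  bad <- which(!(as.character(sm$phenotype) %in% known))
  if (length(bad)) {
    stop(sprintf(
      "unknown phenotype '%s' for sample '%s' (expected PD, Control or iRBD)",
      sm$phenotype[bad[1]], sm$sample_id[bad[1]]), call. = FALSE)
  }
  invisible(m)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$abundance), "samples x",
      ncol(x$abundance), "features\n")
  tab <- table(x$sample_meta$phenotype)
  cat("  phenotypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$sample_meta$timepoint) &&
      length(unique(x$sample_meta$timepoint)) > 1) {
    cat("  timepoints:",
        paste(sort(unique(x$sample_meta$timepoint)), collapse = ", "), "\n")
  }
  steps <- attr(x, "processing")
  if (!is.null(steps)) cat("  processing:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Subset a feature matrix
#'
#' @param x a `feature_matrix`.
#' @param i sample index (logical, integer or sample ids).
#' @param j feature index (logical, integer or feature ids).
#' @param ... ignored.
#' @return the subset `feature_matrix`.
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$abundance))
  if (missing(j)) j <- seq_len(ncol(x$abundance))
  if (is.character(i)) i <- match(i, x$sample_meta$sample_id)
  if (is.character(j)) j <- match(j, x$feature_meta$feature_id)
  out <- x
  out$abundance <- x$abundance[i, j, drop = FALSE]
  out$sample_meta <- x$sample_meta[i, , drop = FALSE]
  out$feature_meta <- x$feature_meta[j, , drop = FALSE]
  out
}

# columns of the on-disk layout that are sample metadata, not features
.meta_columns <- c("sample_id", "subject_id", "phenotype", "site",
                   "timepoint", "age", "sex", "bmi", "high_cholesterol",
                   "hypertension", "heart_condition", "alcohol_units",
                   "cigarettes_per_week", "levodopa_mg")
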