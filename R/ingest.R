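#' Write a feature matrix to delimited text
#'
#' Writes one row per sample: the sample-metadata columns first, then one
#' column per feature.  Feature metadata (annotation, match factor) goes to
#' a sidecar file `<path stem>_features.<ext>` so the layout round-trips.
#'
#' @param m a [feature_matrix()].
#' @param path output file; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- cbind(m$sample_meta,
              as.data.frame(m$abundance, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  utils::write.table(m$feature_meta, feature_sidecar_path(path), sep = sep,
                     row.names = FALSE, quote = TRUE)
  invisible(path)
}

feature_sidecar_path <- function(path) {
  sub("(\\.[^.]+)$", "_features\\1", path)
}

#' Read a feature matrix from delimited text
#'
#' Reads the layout written by [write_matrix()]: one row per sample with
#' metadata columns followed by feature columns.  The delimiter is sniffed
#' from the header line (comma vs tab) unless given.  Feature columns are
#' identified from the sidecar feature-metadata file when present,
#' otherwise every column not in the recognised metadata set (or
#' `meta_cols`) is treated as a feature.  Validation failures (duplicate
#' ids, negative abundances, unknown phenotype labels) raise errors naming
#' the offending row or column.
#'
#' @param path input file.
#' @param feature_meta_path optional explicit sidecar path; defaults to
#'   `<path stem>_features.<ext>` if that file exists.
#' @param meta_cols optional character vector naming the sample-metadata
#'   columns, for files without a sidecar.
#' @param sep optional field separator, overriding sniffing.
#' @return a [feature_matrix()].
#' @export
read_matrix <- function(path, feature_meta_path = NULL, meta_cols = NULL,
                        sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(feature_meta_path) && file.exists(feature_sidecar_path(path))) {
    feature_meta_path <- feature_sidecar_path(path)
  }
  feature_meta <- NULL
  if (!is.null(feature_meta_path)) {
    feature_meta <- utils::read.table(feature_meta_path, sep = sep,
                                      header = TRUE, check.names = FALSE,
                                      stringsAsFactors = FALSE)
    feat_cols <- feature_meta$feature_id
    missing <- setdiff(feat_cols, names(df))
    if (length(missing)) {
      stop(sprintf("feature(s) in metadata but not in matrix: %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
  } else {
    if (is.null(meta_cols)) meta_cols <- .meta_columns
    feat_cols <- setdiff(names(df), meta_cols)
  }
  if (!("sample_id" %in% names(df))) {
    stop("input lacks a 'sample_id' column", call. = FALSE)
  }
  ab <- df[, feat_cols, drop = FALSE]
  nonnum <- names(ab)[!vapply(ab, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop(sprintf("non-numeric abundance column(s): %s",
                 paste(utils::head(nonnum, 5), collapse = ", ")),
         call. = FALSE)
  }
  sm <- df[, intersect(names(df), setdiff(names(df), feat_cols)),
           drop = FALSE]
  feature_matrix(as.matrix(ab), sm, feature_meta)
}

#' Remove TMS derivatives, siloxanes and weak library matches
#'
#' Applies the annotation filters used before statistical analysis:
#' features whose putative annotation matches a trimethylsilyl-derivative
#' or siloxane pattern, or whose spectral-library match factor is below 70
#' (strictly), are removed.  Features with no annotation or no match factor
#' are retained (they stay in the matrix as unidentified features).
#'
#' @param m a [feature_matrix()].
#' @param match_factor_min features with `match_factor < match_factor_min`
#'   are removed (default 70; the comparison is strict, so 70 is kept).
#' @return the filtered `feature_matrix`; the removed features and reasons
#'   are attached as attribute `"removed"` (a data frame) and reported via
#'   `message()`.
#' @export
filter_annotations <- function(m, match_factor_min = 70) {
  stopifnot(inherits(m, "feature_matrix"))
  fm <- m$feature_meta
  if (is.null(fm$annotation) && is.null(fm$match_factor)) {
    warning("no annotation metadata present; matrix returned unchanged",
            call. = FALSE)
    return(m)
  }
  ann <- if (is.null(fm$annotation)) rep(NA_character_, nrow(fm)) else
    as.character(fm$annotation)
  mf <- if (is.null(fm$match_factor)) rep(NA_real_, nrow(fm)) else
    as.numeric(fm$match_factor)
  pat <- "(trimethylsilyl|\\bTMS\\b|silox)"
  is_tms <- !is.na(ann) & grepl(pat, ann, ignore.case = TRUE)
  low_mf <- !is.na(mf) & mf < match_factor_min
  reason <- ifelse(is_tms, "TMS/siloxane annotation",
                   ifelse(low_mf, sprintf("match factor < %g",
                                          match_factor_min), NA))
  drop <- is_tms | low_mf
  removed <- data.frame(feature_id = fm$feature_id[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  if (nrow(removed)) {
    message(sprintf("filter_annotations: removed %d of %d features (%s)",
                    nrow(removed), nrow(fm),
                    paste(sprintf("%s: %s", removed$feature_id,
                                  removed$reason), collapse = "; ")))
  }
  out <- m[, !drop]
  if (ncol(out$abundance) == 0) {
    warning("all features removed by annotation filter", call. = FALSE)
  }
  attr(out, "removed") <- removed
  attr(out, "processing") <- c(attr(m, "processing"), "annotation_filter")
  out
}

#' System-suitability QC by relative standard deviation
#'
#' Computes the per-compound percentage relative standard deviation
#' (%RSD = 100 x sample SD / mean, with the n-1 SD) of repeated
#' system-suitability injections, and passes the run only if every
#' compound's %RSD is strictly below the threshold.
#'
#' @param sst numeric matrix or data frame, injections x compounds.
#' @param threshold_percent pass bound; default 20 (strict `<`).
#' @return an object of class `qc_report`: data frame of compound, mean,
#'   SD and %RSD, with attributes `pass` (logical) and `threshold`.
#' @examples
#' rsd_qc(cbind(a = c(10, 12, 8)))         # %RSD exactly 20 -> fails
#' @export
rsd_qc <- function(sst, threshold_percent = 20) {
  sst <- as.matrix(sst)
  if (nrow(sst) < 2) stop("need at least 2 injections per compound",
                          call. = FALSE)
  if (is.null(colnames(sst))) {
    colnames(sst) <- sprintf("compound%02d", seq_len(ncol(sst)))
  }
  mu <- colMeans(sst)
  if (any(mu == 0)) {
    stop(sprintf("%%RSD undefined: compound(s) with zero mean: %s",
                 paste(colnames(sst)[mu == 0], collapse = ", ")),
         call. = FALSE)
  }
  sds <- apply(sst, 2, sample_sd)
  rsd <- 100 * sds / mu
  rep_df <- data.frame(compound = colnames(sst), mean = mu, sd = sds,
                       rsd_percent = rsd, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(rep_df, class = c("qc_report", "data.frame"),
            pass = all(rsd < threshold_percent),
            threshold = threshold_percent)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("SST QC (%%RSD < %g): %s\n", attr(x, "threshold"),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Total-ion-count normalisation
#'
#' Divides each sample's row by its total abundance, so every row sums to
#' one and per-sample loading differences cancel.
#'
#' @param m a [feature_matrix()].
#' @return the normalised `feature_matrix`.
#' @export
tic_normalize <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  rs <- rowSums(m$abundance)
  if (any(rs == 0)) {
    stop(sprintf("zero total abundance for sample(s): %s",
                 paste(rownames(m$abundance)[rs == 0], collapse = ", ")),
         call. = FALSE)
  }
  m$abundance <- m$abundance / rs
  attr(m, "processing") <- c(attr(m, "processing"), "tic")
  m
}

#' Log transform with a data-derived offset
#'
#' Natural log of `value + offset`.  Since TIC-normalised matrices can
#' contain exact zeros, the default offset is half the smallest nonzero
#' value in the matrix, a deterministic choice recorded in the result.
#'
#' @param m a [feature_matrix()].
#' @param offset optional explicit offset; `NULL` (default) derives it
#'   from the data as above.  If the matrix has no zeros the offset is 0.
#' @return the transformed `feature_matrix`; the offset used is attached
#'   as attribute `"log_offset"`.
#' @export
log_transform <- function(m, offset = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  ab <- m$abundance
  if (is.null(offset)) {
    offset <- if (any(ab == 0)) min(ab[ab > 0]) / 2 else 0
  }
  if (any(ab + offset <= 0)) {
    stop("log transform undefined: non-positive values after offset",
         call. = FALSE)
  }
  m$abundance <- log(ab + offset)
  attr(m, "log_offset") <- offset
  attr(m, "processing") <- c(attr(m, "processing"), "log")
  m
}

#' Autoscale (unit-variance scale) each feature
#'
#' Centres every feature column to mean zero and scales it to unit sample
#' SD (n-1 denominator).  Constant columns carry no information and are
#' dropped with a warning before scaling.
#'
#' @param m a [feature_matrix()].
#' @param center,scale optional pre-learned centring/scaling vectors (e.g.
#'   from a training fold) to apply instead of learning them from `m`.
#' @return the autoscaled `feature_matrix`, with attributes `"center"` and
#'   `"scale"` holding the parameters used.
#' @export
autoscale <- function(m, center = NULL, scale = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  ab <- m$abundance
  learned <- is.null(center)
  if (learned) {
    center <- colMeans(ab)
    scale <- apply(ab, 2, sample_sd)
    const <- scale == 0 | is.na(scale)
    if (any(const)) {
      warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                      paste(utils::head(colnames(ab)[const], 5),
                            collapse = ", ")), call. = FALSE)
      m <- m[, !const]
      ab <- m$abundance
      center <- center[!const]
      scale <- scale[!const]
    }
  }
  m$abundance <- sweep(sweep(ab, 2, center), 2, scale, "/")
  attr(m, "center") <- center
  attr(m, "scale") <- scale
  attr(m, "processing") <- c(attr(m, "processing"), "autoscale")
  m
}

#' Full preprocessing: TIC normalisation, log transform, autoscaling
#'
#' Convenience composition of [tic_normalize()], [log_transform()] and
#' [autoscale()] in that order, the standard preprocessing applied before
#' the multivariate analysis.
#'
#' @param m a [feature_matrix()].
#' @param tic,log,scale logical switches for the individual stages.
#' @return the processed `feature_matrix`.
#' @export
normalize_matrix <- function(m, tic = TRUE, log = TRUE, scale = TRUE) {
  if (tic) m <- tic_normalize(m)
  if (log) m <- log_transform(m)
  if (scale) m <- autoscale(m)
  m
}
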