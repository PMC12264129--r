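#' Screen features for prodromal (iRBD) intermediacy
#'
#' For each feature, flags whether the iRBD group mean lies strictly
#' between the PD and control group means on the supplied (normalised)
#' scale — the pattern expected of a marker that tracks progression from
#' healthy through prodromal to manifest disease.  Exactly equal PD and
#' control means leave no room in between, so such features are never
#' flagged; the screen is descriptive (an ordering of three means), not a
#' statistical test.
#'
#' @param m a (normalised) [feature_matrix()] whose samples include all
#'   three phenotypes.
#' @param features feature ids to screen; default all.
#' @return an object of class `screen_result`: data frame with per-feature
#'   group means, `intermediate` flag and `direction`
#'   (`"up_in_PD"`/`"down_in_PD"`).
#' @export
intermediacy_screen <- function(m, features = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  pheno <- as.character(m$sample_meta$phenotype)
  need <- c("PD", "Control", "iRBD")
  missing <- setdiff(need, unique(pheno))
  if (length(missing)) {
    stop(sprintf("phenotype(s) absent from the data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(features)) features <- m$feature_meta$feature_id
  ab <- m$abundance[, features, drop = FALSE]
  gm <- vapply(need, function(g) colMeans(ab[pheno == g, , drop = FALSE]),
               numeric(ncol(ab)))
  if (!is.matrix(gm)) gm <- matrix(gm, nrow = 1, dimnames = list(features, need))
  lo <- pmin(gm[, "PD"], gm[, "Control"])
  hi <- pmax(gm[, "PD"], gm[, "Control"])
  flag <- gm[, "iRBD"] > lo & gm[, "iRBD"] < hi
  structure(data.frame(feature_id = features,
                       mean_PD = gm[, "PD"],
                       mean_iRBD = gm[, "iRBD"],
                       mean_Control = gm[, "Control"],
                       intermediate = flag,
                       direction = ifelse(gm[, "PD"] > gm[, "Control"],
                                          "up_in_PD", "down_in_PD"),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("screen_result", "data.frame"),
            mode = "irbd")
}

#' Screen features for longitudinal regulation across three visits
#'
#' For subjects observed at three timepoints, flags features whose mean at
#' the middle visit lies strictly between the means at the first and last
#' visits — i.e. a monotone trend in group mean over the disease course.
#' Means are computed over the repeated-measures subjects only; subjects
#' missing a timepoint are excluded with a warning.
#'
#' @param m a (normalised) [feature_matrix()] with `subject_id` and a
#'   `timepoint` column taking three values.
#' @param features feature ids to screen; default all.
#' @return an object of class `screen_result`: data frame with per-feature
#'   means at each timepoint, `regulated` flag and `direction`
#'   (`"increasing"`/`"decreasing"`).
#' @export
longitudinal_screen <- function(m, features = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  sm <- m$sample_meta
  if (is.null(sm$timepoint) || is.null(sm$subject_id)) {
    stop("sample metadata must carry 'subject_id' and 'timepoint'",
         call. = FALSE)
  }
  tps <- sort(unique(sm$timepoint))
  if (length(tps) != 3) {
    stop(sprintf("expected 3 timepoints, found %d", length(tps)),
         call. = FALSE)
  }
  counts <- table(sm$subject_id)
  complete <- names(counts)[vapply(names(counts), function(s) {
    setequal(sm$timepoint[sm$subject_id == s], tps)
  }, logical(1))]
  dropped <- setdiff(unique(sm$subject_id), complete)
  if (length(dropped)) {
    warning(sprintf("excluding subject(s) missing a timepoint: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (length(complete) < 3) {
    stop("fewer than 3 subjects with all three timepoints", call. = FALSE)
  }
  keep <- sm$subject_id %in% complete
  if (is.null(features)) features <- m$feature_meta$feature_id
  ab <- m$abundance[keep, features, drop = FALSE]
  tp <- sm$timepoint[keep]
  tm <- vapply(tps, function(t) colMeans(ab[tp == t, , drop = FALSE]),
               numeric(ncol(ab)))
  if (!is.matrix(tm)) tm <- matrix(tm, nrow = 1)
  lo <- pmin(tm[, 1], tm[, 3])
  hi <- pmax(tm[, 1], tm[, 3])
  flag <- tm[, 2] > lo & tm[, 2] < hi
  structure(data.frame(feature_id = features,
                       mean_t1 = tm[, 1], mean_t2 = tm[, 2],
                       mean_t3 = tm[, 3],
                       regulated = flag,
                       direction = ifelse(tm[, 3] > tm[, 1],
                                          "increasing", "decreasing"),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("screen_result", "data.frame"),
            mode = "longitudinal", n_subjects = length(complete))
}

#' @export
print.screen_result <- function(x, ...) {
  mode <- attr(x, "mode")
  if (is.null(mode)) mode <- if ("intermediate" %in% names(x)) "irbd"
                             else "longitudinal"
  flag_col <- if (mode == "irbd") "intermediate" else "regulated"
  cat(sprintf("%s screen: %d of %d features flagged\n",
              if (mode == "irbd") "iRBD intermediacy" else "Longitudinal",
              sum(x[[flag_col]]), nrow(x)))
  print.data.frame(utils::head(x, 10), digits = 3)
  invisible(x)
}
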