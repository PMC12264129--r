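#' Configuration for an end-to-end pipeline run
#'
#' Collects every input, switch and threshold of the analysis in one
#' validated object.  Thresholds default to the values used throughout the
#' marker-discovery protocol (VIP > 1, stability > 0.8, %RSD < 20, match
#' factor >= 70, confounder improvement >= 10 points, |r| > 0.5) and are
#' recorded in the run manifest.  One master seed deterministically derives
#' the per-stage seeds.
#'
#' @param mode analysis mode: `"two_class"` (PD vs control),
#'   `"three_class"` (PD vs control vs iRBD) or `"longitudinal"`
#'   (PD timepoints).
#' @param input a [feature_matrix()] or a path readable by
#'   [read_matrix()].
#' @param sst optional system-suitability peak-area table for %RSD QC.
#' @param out_dir optional directory for report tables and the manifest.
#' @param seed master seed.
#' @param k,repeats cross-validation scheme (default 3-fold x 100
#'   repeats).
#' @param ncomp_max,keepx_grid tuning search space (see [splsda_tune()]).
#' @param vip_threshold,stability_threshold significance cut-offs.
#' @param rsd_threshold %RSD QC bound.
#' @param match_factor_min annotation-filter bound.
#' @param improvement_points confounder-flag bound in accuracy points.
#' @param correlation_threshold absolute-correlation flag bound.
#' @param confounders sample-metadata columns tested by the
#'   random-forest battery.
#' @param correlation_covariates sample-metadata columns for the Pearson
#'   screen (medication/lifestyle variables).
#' @param rf_splits,rf_trees random-forest protocol size.
#' @param prediction_dist distance rule for cross-validated predictions
#'   (default `"centroid"`; see [predict.splsda()]).
#' @param run_confounders logical; disable to skip the battery.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("three_class", "two_class",
                                     "longitudinal"),
                            input = NULL, sst = NULL, out_dir = NULL,
                            seed = 1, k = 3, repeats = 100,
                            ncomp_max = 2, keepx_grid = NULL,
                            vip_threshold = 1, stability_threshold = 0.8,
                            rsd_threshold = 20, match_factor_min = 70,
                            improvement_points = 10,
                            correlation_threshold = 0.5,
                            confounders = c("age", "sex", "bmi",
                                            "high_cholesterol",
                                            "hypertension",
                                            "heart_condition",
                                            "alcohol_units",
                                            "cigarettes_per_week"),
                            correlation_covariates = c("levodopa_mg",
                                                       "alcohol_units",
                                                       "cigarettes_per_week"),
                            rf_splits = 100, rf_trees = 500,
                            prediction_dist = "centroid",
                            run_confounders = TRUE) {
  structure(list(mode = match.arg(mode), input = input, sst = sst,
                 out_dir = out_dir, seed = check_count(seed, "seed"),
                 k = k, repeats = repeats, ncomp_max = ncomp_max,
                 keepx_grid = keepx_grid,
                 vip_threshold = vip_threshold,
                 stability_threshold = stability_threshold,
                 rsd_threshold = rsd_threshold,
                 match_factor_min = match_factor_min,
                 improvement_points = improvement_points,
                 correlation_threshold = correlation_threshold,
                 confounders = confounders,
                 correlation_covariates = correlation_covariates,
                 rf_splits = rf_splits, rf_trees = rf_trees,
                 prediction_dist = prediction_dist,
                 run_confounders = run_confounders),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the marker-discovery pipeline end to end
#'
#' Executes annotation filtering, QC, TIC/log/autoscale preprocessing,
#' grid-search tuning under repeated stratified cross-validation, the
#' final sparse PLS-DA fit, VIP and stability scoring, significance
#' selection, the mode-specific screen (iRBD intermediacy or longitudinal
#' regulation) and the random-forest confounder battery; writes report
#' tables and a JSON manifest when `out_dir` is set.  Re-running with the
#' same configuration reproduces every table.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `volatilome_run` with components `qc`,
#'   `tuning`, `model`, `vip`, `stability`, `selection`, `screen`,
#'   `confounders`, `correlations`, `manifest`; invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- run_stage("ingest", {
    if (inherits(config$input, "feature_matrix")) config$input
    else read_matrix(config$input)
  })

  qc <- NULL
  if (!is.null(config$sst)) {
    qc <- run_stage("qc", rsd_qc(config$sst, config$rsd_threshold))
    if (!attr(qc, "pass")) {
      warning("system-suitability QC failed the %RSD bound", call. = FALSE)
    }
  }

  m <- run_stage("annotation_filter",
                 suppressMessages(
                   filter_annotations(m, config$match_factor_min)))

  # mode-specific sample subset and outcome
  sel <- run_stage("mode", {
    pheno <- as.character(m$sample_meta$phenotype)
    switch(config$mode,
      two_class = {
        keep <- pheno %in% c("PD", "Control")
        list(m = m[keep, ], y = factor(pheno[keep]),
             disease = "PD", control = "Control")
      },
      three_class = {
        if (!all(c("PD", "Control", "iRBD") %in% pheno)) {
          stop("three_class mode needs PD, Control and iRBD samples")
        }
        list(m = m, y = factor(pheno), disease = "PD", control = "Control")
      },
      longitudinal = {
        keep <- pheno == "PD"
        mm <- m[keep, ]
        tps <- sort(unique(mm$sample_meta$timepoint))
        if (length(tps) < 2) stop("longitudinal mode needs repeated visits")
        y <- factor(paste0("T", mm$sample_meta$timepoint))
        list(m = mm, y = y, disease = utils::tail(levels(y), 1),
             control = levels(y)[1])
      })
  })
  m <- sel$m
  y <- sel$y

  m_log <- run_stage("normalise", log_transform(tic_normalize(m)))
  cv <- run_stage("cv_splits",
                  cv_splits(y, k = config$k, repeats = config$repeats,
                            seed = derive_seed(config$seed, 11)))
  tuning <- run_stage("tune",
                      splsda_tune(m_log$abundance, y,
                                  ncomp_max = config$ncomp_max,
                                  keepx_grid = config$keepx_grid, cv = cv,
                                  dist = config$prediction_dist))
  m_norm <- run_stage("autoscale", autoscale(m_log))
  model <- run_stage("fit",
                     splsda(m_norm$abundance, y, ncomp = tuning$ncomp,
                            keepX = tuning$keepX))
  vips <- run_stage("vip", splsda_vip(model))
  stab <- run_stage("stability",
                    splsda_stability(m_log$abundance, y,
                                     ncomp = tuning$ncomp,
                                     keepX = tuning$keepX, cv = cv,
                                     dist = config$prediction_dist))
  designated <- switch(config$mode,
                       two_class = tuning$ncomp,
                       three_class = seq_len(min(2, tuning$ncomp)),
                       longitudinal = seq_len(tuning$ncomp))
  selection <- run_stage("select",
    select_significant(vips, stab, components = designated,
                       X = m_norm$abundance, y = y,
                       disease = sel$disease, control = sel$control,
                       vip_threshold = config$vip_threshold,
                       stability_threshold = config$stability_threshold))
  sig_ids <- selection$feature_id[selection$significant]

  screen <- NULL
  if (length(sig_ids)) {
    screen <- switch(config$mode,
      three_class = run_stage("screen",
                              intermediacy_screen(m_norm, sig_ids)),
      longitudinal = run_stage("screen",
                               longitudinal_screen(m_norm, sig_ids)),
      two_class = NULL)
  }

  conf_report <- NULL
  correlations <- NULL
  if (config$run_confounders && length(sig_ids) >= 2) {
    Xsig <- m_norm$abundance[, sig_ids, drop = FALSE]
    params <- rf_params(n_splits = config$rf_splits,
                        num_trees = config$rf_trees,
                        seed = derive_seed(config$seed, 13))
    present <- intersect(config$confounders, names(m$sample_meta))
    conf_report <- run_stage("confound", do.call(rbind, lapply(
      present, function(cf) {
        v <- m$sample_meta[[cf]]
        categorical <- is.factor(v) || is.character(v) ||
          length(unique(v[!is.na(v)])) <= 2
        if (categorical) v <- factor(v)
        if (categorical && nlevels(droplevels(factor(v))) < 2) {
          return(NULL)  # constant confounder: nothing to adjust for
        }
        cmp <- adjusted_comparison(Xsig, y, v, params,
                                   confounder_name = cf,
                                   improvement_points =
                                     config$improvement_points)
        out <- confounder_as_outcome(Xsig, v, params)
        data.frame(confounder = cf,
                   unadjusted_accuracy = cmp$unadjusted_accuracy,
                   adjusted_accuracy = cmp$adjusted_accuracy,
                   improvement_points = cmp$improvement_points,
                   confounded = cmp$confounded,
                   importance_rank = cmp$importance_rank,
                   top_half = cmp$top_half,
                   outcome_metric = out$metric,
                   outcome_value = out$value,
                   stringsAsFactors = FALSE)
      })))
    cov_cols <- intersect(config$correlation_covariates,
                          names(m$sample_meta))
    cov_cols <- cov_cols[vapply(cov_cols, function(cc) {
      length(unique(m$sample_meta[[cc]])) > 1
    }, logical(1))]
    if (length(cov_cols)) {
      correlations <- run_stage("correlate",
        correlation_screen(Xsig, m$sample_meta[cov_cols],
                           threshold = config$correlation_threshold))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sebovol")),
    mode = config$mode,
    seed = config$seed,
    derived_seeds = list(cv = derive_seed(config$seed, 11),
                         rf = derive_seed(config$seed, 13)),
    cv_scheme = list(k = config$k, repeats = config$repeats),
    prediction_dist = config$prediction_dist,
    thresholds = list(vip = config$vip_threshold,
                      stability = config$stability_threshold,
                      rsd_percent = config$rsd_threshold,
                      match_factor = config$match_factor_min,
                      improvement_points = config$improvement_points,
                      correlation = config$correlation_threshold),
    log_offset = attr(m_log, "log_offset"),
    ncomp = tuning$ncomp, keepX = tuning$keepX,
    designated_components = designated,
    n_samples = nrow(m$abundance), n_features = ncol(m$abundance),
    n_significant = length(sig_ids)
  )

  result <- structure(list(qc = qc, tuning = tuning, model = model,
                           vip = vips, stability = stab,
                           selection = selection, screen = screen,
                           confounders = conf_report,
                           correlations = correlations,
                           matrix_normalised = m_norm, outcome = y,
                           manifest = manifest),
                      class = "volatilome_run")
  if (!is.null(config$out_dir)) write_run(result, config$out_dir)
  invisible(result)
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x)) {
      utils::write.csv(as.data.frame(x), file.path(out_dir, name),
                       row.names = FALSE)
    }
  }
  wr(result$tuning$grid, "tuning_grid.csv")
  wr(result$selection, "selection.csv")
  wr(data.frame(feature_id = names(result$stability),
                stability = as.numeric(result$stability)),
     "stability.csv")
  wr(result$screen, "screen.csv")
  wr(result$confounders, "confounders.csv")
  wr(result$correlations, "correlations.csv")
  wr(result$qc, "qc.csv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.volatilome_run <- function(x, ...) {
  cat("Volatilome pipeline run (", x$manifest$mode, ")\n", sep = "")
  cat(sprintf("  %d samples x %d features; tuned ncomp = %d, keepX = %s\n",
              x$manifest$n_samples, x$manifest$n_features,
              x$manifest$ncomp, paste(x$manifest$keepX, collapse = ", ")))
  cat(sprintf("  mean CV balanced error rate: %.4f\n", x$tuning$ber))
  cat(sprintf("  significant features: %d\n", x$manifest$n_significant))
  if (!is.null(x$screen)) {
    flag_col <- if (attr(x$screen, "mode") == "irbd") "intermediate"
                else "regulated"
    cat(sprintf("  screen: %d of %d flagged\n",
                sum(x$screen[[flag_col]]), nrow(x$screen)))
  }
  if (!is.null(x$confounders)) {
    cat(sprintf("  confounders flagged: %d of %d\n",
                sum(x$confounders$confounded), nrow(x$confounders)))
  }
  invisible(x)
}
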