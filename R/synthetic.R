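#' Specification for a synthetic volatilome experiment
#'
#' Bundles and validates the parameters of the synthetic feature-matrix
#' generator.  The defaults emulate the kind of cohort the pipeline targets:
#' three phenotype groups (PD, control, iRBD) of 25 subjects each and 613
#' deconvolved GC-MS features whose log abundances span several orders of
#' magnitude, with a subset of features carrying a planted disease effect
#' that is attenuated in the prodromal (iRBD) group.
#'
#' All effects are additive on the natural-log scale (multiplicative on the
#' abundance scale), matching the log transform applied downstream.  Effect
#' and drift magnitudes are expressed in units of the residual log-scale SD
#' (`noise_sd`) so "effect_size = 2" means a two-SD group shift.
#'
#' @param n_per_group subjects per phenotype group.
#' @param n_features number of features (default 613).
#' @param n_discriminative number of features with a planted phenotype
#'   effect (sign drawn at random per feature).
#' @param effect_size log-scale shift of the PD group in `noise_sd` units.
#' @param intermediacy_alpha fraction in \[0, 1\] of the PD shift applied to
#'   the iRBD group (0.5 places iRBD exactly halfway between PD and control
#'   in population log-mean).
#' @param n_longitudinal number of features with a monotone per-visit drift.
#' @param drift_per_visit log-scale shift per visit in `noise_sd` units.
#' @param n_visits visits per subject (1 = cross-sectional; 3 emulates a
#'   baseline / 12-month / 24-month longitudinal design).
#' @param n_confounded number of features driven by a confounder (age)
#'   instead of phenotype.
#' @param confounder_strength log-scale shift per confounder SD, in
#'   `noise_sd` units, for confounded features.
#' @param confounder_assoc shift of the driving confounder's mean in the PD
#'   group, in confounder SD units (0 = confounder independent of
#'   phenotype; > 0 creates a genuinely confounded design).
#' @param loading_sd SD of the per-sample global log-scale loading factor
#'   (sample-amount variation that TIC normalisation should absorb).
#' @param noise_sd residual log-scale SD.
#' @param subject_sd SD of the subject-level random intercept (shared
#'   across a subject's visits, so repeated visits are correlated).
#' @param baseline_mean,baseline_sd mean and SD of per-feature baseline
#'   log abundance; the default SD of 2 natural-log units spans roughly
#'   3.5 orders of magnitude, a realistic GC-MS dynamic range.
#' @param phenotypes character vector of group labels to simulate, a subset
#'   of `c("PD", "Control", "iRBD")`.
#' @param seed integer seed; the same spec reproduces the matrix exactly.
#' @return an object of class `simulation_spec`.
#' @seealso [generate_volatilome()]
#' @export
simulation_spec <- function(n_per_group = 25,
                            n_features = 613,
                            n_discriminative = 40,
                            effect_size = 2,
                            intermediacy_alpha = 0.5,
                            n_longitudinal = 0,
                            drift_per_visit = 1,
                            n_visits = 1,
                            n_confounded = 0,
                            confounder_strength = 1,
                            confounder_assoc = 0,
                            loading_sd = 0.5,
                            noise_sd = 1,
                            subject_sd = 0.5,
                            baseline_mean = 10,
                            baseline_sd = 2,
                            phenotypes = c("PD", "Control", "iRBD"),
                            seed = 1) {
  spec <- list(
    n_per_group = check_count(n_per_group, "n_per_group", min = 1),
    n_features = check_count(n_features, "n_features", min = 1),
    n_discriminative = check_count(n_discriminative, "n_discriminative"),
    effect_size = check_nonneg(effect_size, "effect_size"),
    intermediacy_alpha = intermediacy_alpha,
    n_longitudinal = check_count(n_longitudinal, "n_longitudinal"),
    drift_per_visit = check_nonneg(drift_per_visit, "drift_per_visit"),
    n_visits = check_count(n_visits, "n_visits", min = 1),
    n_confounded = check_count(n_confounded, "n_confounded"),
    confounder_strength = check_nonneg(confounder_strength,
                                       "confounder_strength"),
    confounder_assoc = check_nonneg(confounder_assoc, "confounder_assoc"),
    loading_sd = check_nonneg(loading_sd, "loading_sd"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    subject_sd = check_nonneg(subject_sd, "subject_sd"),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = check_nonneg(baseline_sd, "baseline_sd"),
    phenotypes = phenotypes,
    seed = check_count(seed, "seed")
  )
  if (length(intermediacy_alpha) != 1 || is.na(intermediacy_alpha) ||
      intermediacy_alpha < 0 || intermediacy_alpha > 1) {
    stop_field("intermediacy_alpha", "must lie in [0, 1]")
  }
  if (!all(phenotypes %in% c("PD", "Control", "iRBD")) ||
      anyDuplicated(phenotypes)) {
    stop_field("phenotypes",
               "must be distinct labels from {PD, Control, iRBD}")
  }
  if (spec$n_discriminative + spec$n_confounded > spec$n_features) {
    stop_field("n_discriminative",
               "n_discriminative + n_confounded must not exceed n_features")
  }
  if (spec$n_discriminative + spec$n_confounded + spec$n_longitudinal >
      spec$n_features) {
    stop_field("n_longitudinal",
               "planted feature sets together must not exceed n_features")
  }
  if (spec$n_visits > 3) {
    stop_field("n_visits", "at most 3 visits are supported")
  }
  structure(spec, class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Synthetic volatilome spec:",
      length(x$phenotypes) * x$n_per_group * x$n_visits, "samples x",
      x$n_features, "features\n")
  cat("  groups:", paste(x$phenotypes, collapse = ", "),
      "| visits:", x$n_visits, "\n")
  cat("  planted: ", x$n_discriminative, " discriminative (effect ",
      x$effect_size, " SD, alpha ", x$intermediacy_alpha, "), ",
      x$n_longitudinal, " longitudinal, ", x$n_confounded,
      " confounded\n", sep = "")
  invisible(x)
}

#' Generate a synthetic volatilome feature matrix with known ground truth
#'
#' Simulates a samples-by-features abundance matrix with the statistical
#' structure the analysis pipeline assumes: per-feature baselines spanning a
#' wide dynamic range, multiplicative per-sample loading factors, planted
#' phenotype effects with an intermediate prodromal group, optional
#' per-visit drift with subject-level random intercepts, and optional
#' features driven by a confounder rather than phenotype.  Log abundance is
#' built as
#' `baseline_j + group effect + visit drift + confounder effect +
#'  subject intercept + sample loading + noise`,
#' and exponentiated, so abundances are strictly positive.
#'
#' @param spec a [simulation_spec()].
#' @return a list with components `matrix` (a [feature_matrix()]) and
#'   `truth` (class `ground_truth`: data frames of planted discriminative,
#'   longitudinal and confounded features with their signed effects, plus
#'   `intermediate_ids`).
#' @examples
#' sim <- generate_volatilome(simulation_spec(n_per_group = 5,
#'                                            n_features = 40,
#'                                            n_discriminative = 5))
#' dim(sim$matrix$abundance)
#' @export
generate_volatilome <- function(spec) {
  if (!inherits(spec, "simulation_spec")) spec <- do.call(simulation_spec, spec)
  with_seed(spec$seed, generate_volatilome_impl(spec))
}

generate_volatilome_impl <- function(spec) {
  groups <- spec$phenotypes
  n_subj <- length(groups) * spec$n_per_group
  subject_pheno <- rep(groups, each = spec$n_per_group)
  subject_id <- sprintf("SUBJ%03d", seq_len(n_subj))

  feat_id <- sprintf("F%04d", seq_len(spec$n_features))
  baseline <- stats::rnorm(spec$n_features, spec$baseline_mean,
                           spec$baseline_sd)

  # planted feature sets, mutually disjoint
  pool <- sample.int(spec$n_features)
  take <- function(n) {
    ids <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    sort(ids)
  }
  disc_idx <- if (spec$n_discriminative > 0) take(spec$n_discriminative) else integer(0)
  conf_idx <- if (spec$n_confounded > 0) take(spec$n_confounded) else integer(0)
  long_idx <- if (spec$n_longitudinal > 0) take(spec$n_longitudinal) else integer(0)
  disc_sign <- sample(c(-1, 1), length(disc_idx), replace = TRUE)
  long_sign <- sample(c(-1, 1), length(long_idx), replace = TRUE)

  # subject-level covariates (ages/BMI roughly matching a PD cohort)
  age_sd <- 8
  age <- stats::rnorm(n_subj, 65, age_sd) +
    ifelse(subject_pheno == "PD", spec$confounder_assoc * age_sd, 0)
  sex <- factor(ifelse(stats::runif(n_subj) < 0.7, "M", "F"),
                levels = c("F", "M"))
  bmi <- stats::rnorm(n_subj, 27, 3.7)
  high_cholesterol <- stats::rbinom(n_subj, 1, 0.3)
  hypertension <- stats::rbinom(n_subj, 1, 0.3)
  heart_condition <- stats::rbinom(n_subj, 1, 0.15)
  alcohol_units <- round(pmax(0, stats::rnorm(n_subj, 5, 4)), 1)
  cigarettes_per_week <- ifelse(stats::runif(n_subj) < 0.2,
                                round(stats::runif(n_subj, 5, 80)), 0)
  levodopa_mg <- ifelse(subject_pheno == "PD",
                        round(stats::rnorm(n_subj, 400, 100)), 0)
  subj_intercept <- stats::rnorm(n_subj, 0, spec$subject_sd)
  conf_z <- (age - mean(age)) / stats::sd(age)  # driving confounder (age)

  # expand subjects x visits into sample rows
  visits <- seq_len(spec$n_visits) - 1L
  srow <- expand.grid(visit = visits, subject = seq_len(n_subj))
  srow <- srow[order(srow$subject, srow$visit), ]
  n_samp <- nrow(srow)
  s_subj <- srow$subject
  s_visit <- srow$visit

  group_shift <- function(pheno) {
    switch(pheno,
           PD = spec$effect_size,
           iRBD = spec$intermediacy_alpha * spec$effect_size,
           Control = 0)
  }
  pheno_mult <- vapply(subject_pheno, group_shift, numeric(1)) * spec$noise_sd

  logab <- matrix(rep(baseline, each = n_samp), n_samp, spec$n_features)
  if (length(disc_idx)) {
    logab[, disc_idx] <- logab[, disc_idx] +
      outer(pheno_mult[s_subj], disc_sign)
  }
  if (length(long_idx) && spec$n_visits > 1) {
    logab[, long_idx] <- logab[, long_idx] +
      outer(s_visit * spec$drift_per_visit * spec$noise_sd, long_sign)
  }
  if (length(conf_idx)) {
    logab[, conf_idx] <- logab[, conf_idx] +
      matrix(conf_z[s_subj] * spec$confounder_strength * spec$noise_sd,
             n_samp, length(conf_idx))
  }
  loading <- stats::rnorm(n_samp, 0, spec$loading_sd)
  logab <- logab + subj_intercept[s_subj] + loading +
    matrix(stats::rnorm(n_samp * spec$n_features, 0, spec$noise_sd),
           n_samp, spec$n_features)

  abundance <- exp(logab)
  sample_id <- sprintf("%s_T%d", subject_id[s_subj], s_visit)
  rownames(abundance) <- sample_id
  colnames(abundance) <- feat_id

  sample_meta <- data.frame(
    sample_id = sample_id,
    subject_id = subject_id[s_subj],
    phenotype = subject_pheno[s_subj],
    site = "SiteA",
    timepoint = s_visit,
    age = round(age[s_subj], 1),
    sex = sex[s_subj],
    bmi = round(bmi[s_subj], 1),
    high_cholesterol = high_cholesterol[s_subj],
    hypertension = hypertension[s_subj],
    heart_condition = heart_condition[s_subj],
    alcohol_units = alcohol_units[s_subj],
    cigarettes_per_week = cigarettes_per_week[s_subj],
    levodopa_mg = levodopa_mg[s_subj],
    stringsAsFactors = FALSE
  )
  feature_meta <- data.frame(
    feature_id = feat_id,
    annotation = NA_character_,
    match_factor = NA_real_,
    retention_index = NA_real_,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    discriminative = data.frame(feature_id = feat_id[disc_idx],
                                sign = disc_sign,
                                stringsAsFactors = FALSE),
    intermediate_ids = if (spec$intermediacy_alpha > 0 &&
                           spec$intermediacy_alpha < 1 &&
                           "iRBD" %in% groups) feat_id[disc_idx]
                       else character(0),
    longitudinal = data.frame(feature_id = feat_id[long_idx],
                              sign = long_sign,
                              stringsAsFactors = FALSE),
    confounded_ids = feat_id[conf_idx],
    driving_confounder = "age"
  ), class = "ground_truth")

  list(matrix = feature_matrix(abundance, sample_meta, feature_meta),
       truth = truth)
}

#' Generate a synthetic system-suitability (SST) peak-area table
#'
#' Emulates repeated injections of a standard mix (by default the seven
#' compounds of a GC-MS system-suitability mixture) whose per-compound
#' relative standard deviation converges to a requested target, for testing
#' the %RSD quality-control stage.
#'
#' @param n_injections number of injections (rows); at least 2, since the
#'   sample SD is undefined below that.
#' @param target_rsd_percent named numeric vector of target %RSD per
#'   compound; names become column names.  A target of 0 produces identical
#'   areas for that compound.
#' @param seed integer seed.
#' @return numeric matrix, injections x compounds, of peak areas.
#' @export
generate_sst_table <- function(n_injections = 13,
                               target_rsd_percent = c(
                                 carvone = 5, delta_decalactone = 8,
                                 ethyl_butyrate = 10, ethyl_hexanoate = 6,
                                 hexadecane = 12, nonane = 9, vanillin = 7),
                               seed = 1) {
  n_injections <- check_count(n_injections, "n_injections")
  if (n_injections < 2) {
    stop_field("n_injections", "must be >= 2 (sample SD undefined)")
  }
  if (any(target_rsd_percent < 0) || anyNA(target_rsd_percent)) {
    stop_field("target_rsd_percent", "targets must be non-negative")
  }
  if (is.null(names(target_rsd_percent))) {
    names(target_rsd_percent) <-
      sprintf("compound%02d", seq_along(target_rsd_percent))
  }
  with_seed(seed, {
    n_c <- length(target_rsd_percent)
    mu <- 10^stats::runif(n_c, 5, 6.5)  # typical peak-area magnitudes
    areas <- vapply(seq_len(n_c), function(j) {
      if (target_rsd_percent[j] == 0) {
        rep(mu[j], n_injections)
      } else {
        stats::rnorm(n_injections, mu[j], mu[j] * target_rsd_percent[j] / 100)
      }
    }, numeric(n_injections))
    colnames(areas) <- names(target_rsd_percent)
    rownames(areas) <- sprintf("inj%03d", seq_len(n_injections))
    areas
  })
}
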