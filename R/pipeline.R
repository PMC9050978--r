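#' End-to-end pipeline configuration
#'
#' One declarative object driving [run_full_pipeline()]: cohort sizes and
#' linkage, feature-extraction settings, forest hyperparameters, evaluation
#' horizons, and one mandatory seed per stage (no wall-clock seeding).
#'
#' @param out_dir Run directory (created; existing files overwritten).
#' @param n_train_cohort,n_external_cohort,n_repeat_cohort Subjects in the
#'   development cohort (split 2:1), the external validation cohort, and the
#'   test-retest cohort.
#' @param log_hr Named log hazard ratios per 1 SD injected by the generator.
#' @param censor_rate Target censoring fraction.
#' @param grade_link Named target Spearman correlation for grade.
#' @param mutation_shift Mutation feature-shift specification (see
#'   [cohort_config()]).
#' @param feature_config A [feature_extraction_config()].
#' @param rsf A [rsf_params()].
#' @param horizons Evaluation horizons in months.
#' @param alpha Significance level.
#' @param repeat_noise_sd,repeat_shift_px Test-retest acquisition parameters.
#' @param contour A [contour_params()] for the segmentation stage.
#' @param seed Master seed; per-stage seeds derive from it by fixed offsets.
#' @param input_dir Optional existing cohort directory to ingest for the
#'   development cohort instead of simulating (must contain `clinical.csv`,
#'   `images/`, `masks/`).
#' @param write_images If `TRUE`, also write the simulated cohort rasters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            n_train_cohort = 90L,
                            n_external_cohort = 40L,
                            n_repeat_cohort = 20L,
                            log_hr = c(longhem = 0.7, kurtosis = -0.4),
                            censor_rate = 0.35,
                            grade_link = c(longhem = 0.33),
                            mutation_shift = list(
                              egfr = list(feature = "kurtosis", shift = 1.0),
                              kras = list(feature = "energy", shift = 0.0),
                              alk = list(feature = "variance", shift = -0.5)),
                            feature_config = feature_extraction_config(),
                            rsf = rsf_params(),
                            horizons = c(24, 60),
                            alpha = 0.05,
                            repeat_noise_sd = 5,
                            repeat_shift_px = 2L,
                            contour = contour_params("region"),
                            seed = 1L,
                            input_dir = NULL,
                            write_images = FALSE) {
  if (any(horizons <= 0)) stopf("horizons must be positive")
  structure(list(out_dir = out_dir, n_train_cohort = as.integer(n_train_cohort),
                 n_external_cohort = as.integer(n_external_cohort),
                 n_repeat_cohort = as.integer(n_repeat_cohort),
                 log_hr = log_hr, censor_rate = censor_rate,
                 grade_link = grade_link, mutation_shift = mutation_shift,
                 feature_config = feature_config, rsf = rsf,
                 horizons = horizons, alpha = alpha,
                 repeat_noise_sd = repeat_noise_sd,
                 repeat_shift_px = as.integer(repeat_shift_px),
                 contour = contour, seed = as.integer(seed),
                 input_dir = input_dir, write_images = write_images),
            class = "pipeline_config")
}

segment_cohort <- function(cohort, contour) {
  lapply(seq_along(cohort$images), function(i) {
    init <- default_threshold_init(cohort$images[[i]])
    refine_active_contour(cohort$images[[i]], init, contour)
  })
}

evaluate_scores <- function(scores, clinical, horizons) {
  res <- list(
    n = length(scores),
    harrell_c = harrell_c(scores, clinical$time_months, clinical$event))
  auc <- list()
  for (h in horizons) {
    auc[[paste0("month_", h)]] <- tryCatch(
      auc_t(scores, clinical$time_months, clinical$event, h),
      error = function(e) NA_real_)
  }
  res$auc_t <- auc
  grp <- tryCatch(median_split(scores), error = function(e) NULL)
  if (!is.null(grp)) {
    lr <- logrank_test(clinical$time_months, clinical$event, grp)
    hr <- tryCatch(cox_hr_binary(grp, clinical$time_months, clinical$event),
                   error = function(e) NULL)
    res$logrank_p <- lr$p
    if (!is.null(hr)) {
      res$hr_high_vs_low <- hr$hr
      res$hr_ci <- c(hr$ci_lower, hr$ci_upper)
    }
  }
  res
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) cohorts, segment every lesion (threshold
#' initialization + active-contour refinement), extract the radiomic panel,
#' split the development cohort 2:1, fit the survival forest on the training
#' group, score train / test / external subjects on the 0-100 scale, evaluate
#' prognosis (C, time-dependent AUC, median-split log-rank, Cox hazard ratios
#' with demographic subgroups), run the feature x profile association table,
#' and run the test-retest and between-algorithm reliability studies. Every
#' artifact is written under `config$out_dir` together with a manifest
#' (config hash, seeds, package version). Rerunning an identical config
#' reproduces every output byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory and the in-memory results.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) message(sprintf("[ctrad] stage: %s", name))

  stage("simulate")
  if (!is.null(config$input_dir)) {
    cohort_a <- read_cohort(config$input_dir)
  } else {
    cfg_a <- cohort_config(n_subjects = config$n_train_cohort,
                           log_hr = config$log_hr,
                           censor_rate = config$censor_rate,
                           grade_link = config$grade_link,
                           mutation_shift = config$mutation_shift,
                           id_prefix = "A", seed = config$seed)
    cohort_a <- simulate_cohort(cfg_a, config$feature_config)
  }
  cfg_b <- cohort_config(n_subjects = config$n_external_cohort,
                         log_hr = config$log_hr,
                         censor_rate = config$censor_rate,
                         grade_link = config$grade_link,
                         mutation_shift = config$mutation_shift,
                         id_prefix = "B", seed = config$seed + 1000L)
  cohort_b <- simulate_cohort(cfg_b, config$feature_config)
  cfg_c <- cohort_config(n_subjects = config$n_repeat_cohort,
                         log_hr = config$log_hr,
                         id_prefix = "C", seed = config$seed + 2000L)
  ph_c <- simulate_phantom_cohort(cfg_c)
  cohort_c <- structure(list(images = ph_c$images, masks = ph_c$masks,
                             params = ph_c$params), class = "ct_cohort")
  if (isTRUE(config$write_images)) {
    write_cohort(cohort_a, file.path(config$out_dir, "cohort_a"))
    write_cohort(cohort_b, file.path(config$out_dir, "cohort_b"))
  }

  stage("segment")
  seg_a <- segment_cohort(cohort_a, config$contour)
  seg_b <- segment_cohort(cohort_b, config$contour)

  stage("extract")
  feats_a <- as.data.frame(extract_panel(cohort_a$images, seg_a,
                                         config$feature_config))
  feats_b <- as.data.frame(extract_panel(cohort_b$images, seg_b,
                                         config$feature_config))
  feats_a <- cbind(subject_id = cohort_a$clinical$subject_id, feats_a)
  feats_b <- cbind(subject_id = cohort_b$clinical$subject_id, feats_b)
  utils::write.csv(feats_a, file.path(config$out_dir, "features_a.csv"),
                   row.names = FALSE)
  utils::write.csv(feats_b, file.path(config$out_dir, "features_b.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_a$clinical, file.path(config$out_dir,
                                                "clinical_a.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_b$clinical, file.path(config$out_dir,
                                                "clinical_b.csv"),
                   row.names = FALSE)

  stage("score")
  rec_a <- cbind(feats_a, cohort_a$clinical[, c("time_months", "event")])
  sp <- split_cohort(rec_a, seed = config$seed + 11L)
  forest <- fit_rsf(sp$train, features = radiomic_feature_names(),
                    params = config$rsf)
  score_of <- function(recs) normalize_score(forest,
                                             predict_mortality(forest, recs))
  rec_b <- cbind(feats_b, cohort_b$clinical[, c("time_months", "event")])
  s_train <- score_of(sp$train)
  s_test <- score_of(sp$test)
  s_ext <- score_of(rec_b)
  s_all_a <- score_of(rec_a)
  scores_df <- rbind(
    data.frame(subject_id = sp$train$subject_id, cohort = "train",
               score = s_train, stringsAsFactors = FALSE),
    data.frame(subject_id = sp$test$subject_id, cohort = "test",
               score = s_test, stringsAsFactors = FALSE),
    data.frame(subject_id = rec_b$subject_id, cohort = "external",
               score = s_ext, stringsAsFactors = FALSE))
  utils::write.csv(scores_df, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)
  write_forest_json(forest, file.path(config$out_dir, "forest.json"))

  stage("evaluate")
  clin_a <- cohort_a$clinical
  evaluation <- list(
    train = evaluate_scores(s_train, sp$train, config$horizons),
    test = evaluate_scores(s_test, sp$test, config$horizons),
    external = evaluate_scores(s_ext, cohort_b$clinical, config$horizons),
    cohort_a = evaluate_scores(s_all_a, clin_a, config$horizons))
  evaluation$subgroups <- subgroup_hr(
    s_all_a, clin_a$time_months, clin_a$event,
    list(age_70_plus = clin_a$age >= 70,
         age_under_70 = clin_a$age < 70,
         female = clin_a$sex == "female",
         male = clin_a$sex == "male",
         never_smoker = clin_a$smoking == "never",
         ever_smoker = clin_a$smoking != "never"))
  jsonlite::write_json(evaluation, file.path(config$out_dir,
                                             "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  stage("associate")
  assoc <- association_table(feats_a, clin_a, alpha = config$alpha)
  utils::write.csv(assoc, file.path(config$out_dir, "associations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(association_matrix(assoc)),
                   file.path(config$out_dir, "association_matrix.csv"))

  stage("reliability")
  rel_scan <- reliability_study(cohort_c, "repeat_scan",
                                noise_sd = config$repeat_noise_sd,
                                shift_px = config$repeat_shift_px,
                                feature_config = config$feature_config,
                                seed = config$seed + 31L)
  rel_algo <- reliability_study(cohort_c, "algorithm",
                                feature_config = config$feature_config)
  rel <- rbind(cbind(comparison = "repeat_scan", rel_scan),
               cbind(comparison = "algorithm", rel_algo))
  utils::write.csv(rel, file.path(config$out_dir, "reliability.csv"),
                   row.names = FALSE)

  stage("manifest")
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_as_list(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "ctrad",
    version = as.character(utils::packageVersion("ctrad")),
    config_md5 = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    stage_seeds = list(simulate = config$seed, split = config$seed + 11L,
                       forest = config$rsf$seed,
                       reliability = config$seed + 31L),
    outputs = c("features_a.csv", "features_b.csv", "clinical_a.csv",
                "clinical_b.csv", "scores.csv", "forest.json",
                "evaluation.json", "associations.csv",
                "association_matrix.csv", "reliability.csv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dir = config$out_dir, forest = forest,
                 evaluation = evaluation, associations = assoc,
                 reliability = rel, scores = scores_df))
}

# plain-list view of the config for hashing/serialization
config_as_list <- function(config) {
  out <- unclass(config)
  out$feature_config <- unclass(out$feature_config)
  out$rsf <- unclass(out$rsf)
  out$contour <- unclass(out$contour)
  out$mutation_shift <- lapply(out$mutation_shift, unclass)
  out
}
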