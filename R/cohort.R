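#' Configuration of a synthetic lesion cohort
#'
#' Describes the statistical structure linking image-generating phantom
#' parameters, radiomic features, and clinical labels: an exponential
#' proportional-hazards survival model on standardized features, threshold
#' rules mapping phantom parameters to semantic flags, liability-threshold
#' models injecting feature mean shifts between mutant and wild-type tumours,
#' and a latent-Gaussian ordinal grade with a stated Spearman correlation to a
#' named feature.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param log_hr Named numeric: log hazard ratio per 1 SD of each named
#'   radiomic feature (canonical names, e.g. `c(longhem = 0.7)`).
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censor_rate Target fraction censored, in `[0, 1)`.
#' @param semantic_link Named list: semantic flag -> `list(param, cutoff)`;
#'   the flag is 1 when the named phantom parameter exceeds the cutoff.
#' @param mutation_shift Named list: gene -> `list(feature, shift)`; `shift` is
#'   the mutant-minus-wild mean difference in SD (normal-scores) units.
#' @param mutation_prevalence Named numeric, mutation prevalence per gene.
#' @param grade_link Length-1 named numeric: target Spearman correlation
#'   between histopathological grade (1-3) and the named feature.
#' @param histology_probs Probabilities for adeno / squamous / other.
#' @param param_ranges Named list of `c(min, max)` ranges (or integer vectors)
#'   for the per-subject phantom parameter draws.
#' @param image_size,pixel_spacing Frame geometry shared by all phantoms.
#' @param id_prefix Prefix for generated subject identifiers (keep distinct
#'   across cohorts that will be analysed together).
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 150,
                          log_hr = c(longhem = 0.7, kurtosis = -0.4),
                          baseline_hazard = 0.012,
                          censor_rate = 0.35,
                          semantic_link = list(
                            spiculated   = list(param = "spiculation_amp", cutoff = 0.15),
                            solid        = list(param = "lesion_mean",     cutoff = 400),
                            lobular      = list(param = "spiculation_freq", cutoff = 6),
                            juxtapleural = list(param = "lesion_radius",   cutoff = 13),
                            pleura_tag   = list(param = "lesion_sd",       cutoff = 60)),
                          mutation_shift = list(
                            egfr = list(feature = "kurtosis", shift = 1.0),
                            kras = list(feature = "energy",   shift = 0.0),
                            alk  = list(feature = "variance", shift = -0.5)),
                          mutation_prevalence = c(egfr = 0.2, kras = 0.23, alk = 0.05),
                          grade_link = c(longhem = 0.33),
                          histology_probs = c(adeno = 0.55, squamous = 0.30, other = 0.15),
                          param_ranges = list(
                            lesion_radius    = c(8, 16),
                            spiculation_amp  = c(0, 0.3),
                            spiculation_freq = 4:10,
                            texture_corr_len = c(2, 6),
                            texture_gamma    = c(0.6, 1.8),
                            lesion_mean      = c(250, 550),
                            lesion_sd        = c(30, 80),
                            n_inclusions     = 1:5),
                          image_size = 64,
                          pixel_spacing = 1,
                          id_prefix = "S",
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), log_hr = log_hr,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              semantic_link = semantic_link, mutation_shift = mutation_shift,
              mutation_prevalence = mutation_prevalence,
              grade_link = grade_link, histology_probs = histology_probs,
              param_ranges = param_ranges, image_size = as.integer(image_size),
              pixel_spacing = pixel_spacing, id_prefix = id_prefix,
              seed = as.integer(seed))
  if (cfg$n_subjects < 2) stopf("n_subjects must be >= 2")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stopf("censor_rate must be in [0, 1)")
  }
  if (cfg$baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (length(cfg$log_hr) && is.null(names(cfg$log_hr))) {
    stopf("log_hr must be a named vector of feature effects")
  }
  structure(cfg, class = "cohort_config")
}

known_semantic_flags <- c("solid", "lobular", "spiculated", "juxtapleural",
                          "pleura_tag")
known_genes <- c("egfr", "kras", "alk")

#' Clinical table column schema
#'
#' Exact column names of the cohort clinical CSV.
#' @return Character vector of column names.
#' @export
clinical_schema <- function() {
  c("subject_id", "time_months", "event", "age", "sex", "smoking",
    "stage_group", "grade", "histology", "egfr", "kras", "alk",
    "solid", "lobular", "spiculated", "juxtapleural", "pleura_tag")
}

# per-subject phantom parameter draws
draw_phantom_params <- function(config, seed = config$seed) {
  n <- config$n_subjects
  pr <- config$param_ranges
  draw <- function(rng) {
    if (length(rng) == 2L && is.double(rng)) {
      stats::runif(n, rng[1], rng[2])
    } else {
      sample(rng, n, replace = TRUE)
    }
  }
  with_seed(seed, {
    data.frame(subject_id = sprintf("%s%04d", config$id_prefix %||% "S",
                                    seq_len(n)),
               lesion_radius = draw(pr$lesion_radius),
               spiculation_amp = draw(pr$spiculation_amp),
               spiculation_freq = as.integer(draw(pr$spiculation_freq)),
               texture_corr_len = draw(pr$texture_corr_len),
               texture_gamma = draw(pr$texture_gamma %||% 1),
               lesion_mean = draw(pr$lesion_mean),
               lesion_sd = draw(pr$lesion_sd),
               n_inclusions = as.integer(draw(pr$n_inclusions %||% 3L)),
               image_size = config$image_size,
               pixel_spacing = config$pixel_spacing,
               phantom_seed = sample.int(2^30, n),
               stringsAsFactors = FALSE)
  })
}

#' Generate the image side of a synthetic cohort
#'
#' Draws per-subject phantom parameters and renders one phantom per subject.
#'
#' @param config A [cohort_config()].
#' @return List with `params` (data frame), `images`, `masks` (lists).
#' @export
simulate_phantom_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  params <- draw_phantom_params(config)
  phantoms <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    make_lesion_phantom(phantom_config(
      image_size = p$image_size, pixel_spacing = p$pixel_spacing,
      lesion_radius = p$lesion_radius, spiculation_amp = p$spiculation_amp,
      spiculation_freq = p$spiculation_freq, lesion_mean = p$lesion_mean,
      lesion_sd = p$lesion_sd, texture_corr_len = p$texture_corr_len,
      texture_gamma = p$texture_gamma %||% 1,
      n_inclusions = p$n_inclusions %||% 3L,
      seed = p$phantom_seed))
  })
  list(params = params,
       images = lapply(phantoms, `[[`, "image"),
       masks = lapply(phantoms, `[[`, "mask"))
}

#' Simulate survival outcomes from radiomic features
#'
#' Event times follow an exponential proportional-hazards model with linear
#' predictor `sum(log_hr_f * z_f)` over internally standardized features.
#' Censoring is an independent exponential whose rate is calibrated (by root
#' finding on the marginal censoring probability) to the configured
#' `censor_rate`. Times are reported in months, rounded to two decimals.
#' Demographics (age, sex, smoking, stage group) are drawn independently.
#'
#' @param features Data frame of radiomic features, one row per subject.
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return Data frame of subject records (clinical schema columns; profile
#'   labels left NA until [simulate_profiles()]).
#' @export
simulate_survival <- function(features, config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(features)
  missing_f <- setdiff(names(config$log_hr), names(features))
  if (length(missing_f)) {
    stopf("features named in log_hr are missing from the table: %s",
          paste(missing_f, collapse = ", "))
  }
  lp <- rep(0, n)
  for (f in names(config$log_hr)) {
    x <- features[[f]]
    s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
    lp <- lp + config$log_hr[[f]] * z
  }
  rate <- config$baseline_hazard * exp(lp)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate)
    if (config$censor_rate > 0) {
      # E[ c / (c + rate_i) ] = censor_rate, solved for the censoring rate c
      f <- function(logc) mean(exp(logc) / (exp(logc) + rate)) -
        config$censor_rate
      logc <- stats::uniroot(f, c(-25, 25))$root
      t_cens <- stats::rexp(n, exp(logc))
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmax(round(pmin(t_event, t_cens), 2), 0.01)
    event <- as.integer(t_event <= t_cens)
    age <- pmin(pmax(round(stats::rnorm(n, 68, 9)), 40), 90)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4))
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.35, 0.4, 0.25))
    stage <- sample(c("0-IIB", "IIIA-IVB"), n, replace = TRUE,
                    prob = c(0.8, 0.2))
    out <- data.frame(subject_id = features$subject_id %||%
                        sprintf("S%04d", seq_len(n)),
                      time_months = time, event = event, age = age, sex = sex,
                      smoking = smoking, stage_group = stage,
                      grade = NA_integer_, histology = NA_character_,
                      egfr = NA_character_, kras = NA_character_,
                      alk = NA_character_, solid = NA_integer_,
                      lobular = NA_integer_, spiculated = NA_integer_,
                      juxtapleural = NA_integer_, pleura_tag = NA_integer_,
                      stringsAsFactors = FALSE)
    out
  })
}

# ---- latent-Gaussian calibration helpers -----------------------------------

# normal scores of a feature (rank-based, ties by midrank)
normal_scores <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

# population Spearman correlation between a standard normal Z and a 3-level
# grade formed by cutting a latent L (corr(Z, L) = r) at tertiles
spearman_latent_grade <- function(r) {
  breaks <- stats::qnorm(c(0, 1/3, 2/3, 1))
  eus <- 0
  for (k in 1:3) {
    ik <- stats::integrate(function(l) {
      stats::dnorm(l) * stats::pnorm(r * l / sqrt(2 - r^2))
    }, breaks[k], breaks[k + 1], rel.tol = 1e-10)$value
    eus <- eus + k * ik
  }
  (eus - 1) / sqrt((1 / 12) * (2 / 3))    # cov / sqrt(varU * varS)
}

# latent correlation achieving a target Spearman for the tertile grade
solve_grade_latent_r <- function(target) {
  if (abs(target) < 1e-12) return(0)
  lim <- spearman_latent_grade(0.999) # ~0.943, attainable maximum
  if (abs(target) >= lim) {
    stopf("grade Spearman target %.3f exceeds the attainable maximum %.3f",
          target, lim)
  }
  stats::uniroot(function(r) spearman_latent_grade(r) - target,
                 c(-0.999, 0.999), tol = 1e-9)$root
}

# liability-threshold label with an exact mean shift (normal-scores scale):
# r = delta * p * (1 - p) / phi(qnorm(1 - p))
draw_shifted_label <- function(z, shift, prevalence) {
  tau <- stats::qnorm(1 - prevalence)
  r <- shift * prevalence * (1 - prevalence) / stats::dnorm(tau)
  if (abs(r) >= 0.995) {
    stopf("mutation shift %.2f SD is too large for prevalence %.2f", shift,
          prevalence)
  }
  lat <- r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
  as.integer(lat > tau)
}

#' Fill semantic, genetic and histopathological labels
#'
#' Semantic flags are deterministic thresholds on the phantom parameters that
#' generated each lesion. Mutation labels are drawn from a liability-threshold
#' model calibrated so the mutant-minus-wild mean difference of the named
#' feature (normal-scores scale) equals the configured shift. Grade 1-3 is cut
#' from a latent Gaussian whose mixing weight is solved analytically so the
#' population Spearman correlation with the named feature equals the target.
#' Histology is drawn independently from the configured proportions.
#'
#' @param records Subject records from [simulate_survival()].
#' @param features Feature table aligned with `records`.
#' @param phantom_params Phantom parameter table aligned with `records`.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return `records` with profile columns filled.
#' @export
simulate_profiles <- function(records, features, phantom_params, config,
                              seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(records)
  for (flag in names(config$semantic_link)) {
    if (!flag %in% known_semantic_flags) {
      stopf("unknown semantic flag '%s'", flag)
    }
    link <- config$semantic_link[[flag]]
    if (!link$param %in% names(phantom_params)) {
      stopf("semantic link for '%s' names unknown parameter '%s'", flag,
            link$param)
    }
    records[[flag]] <- as.integer(phantom_params[[link$param]] > link$cutoff)
  }
  with_seed(seed, {
    for (gene in names(config$mutation_shift)) {
      if (!gene %in% known_genes) stopf("unknown gene '%s'", gene)
      ms <- config$mutation_shift[[gene]]
      if (!ms$feature %in% names(features)) {
        stopf("mutation shift for '%s' names unknown feature '%s'", gene,
              ms$feature)
      }
      prev <- config$mutation_prevalence[[gene]]
      lab <- draw_shifted_label(normal_scores(features[[ms$feature]]),
                                ms$shift, prev)
      records[[gene]] <- ifelse(lab == 1L, "mutant", "wild")
    }
    if (length(config$grade_link)) {
      gf <- names(config$grade_link)[1]
      if (!gf %in% names(features)) {
        stopf("grade link names unknown feature '%s'", gf)
      }
      r <- solve_grade_latent_r(config$grade_link[[1]])
      lat <- r * normal_scores(features[[gf]]) +
        sqrt(1 - r^2) * stats::rnorm(n)
      records$grade <- as.integer(cut(lat, c(-Inf, stats::qnorm(1/3),
                                             stats::qnorm(2/3), Inf)))
    }
    records$histology <- sample(names(config$histology_probs), n,
                                replace = TRUE, prob = config$histology_probs)
    records
  })
}

#' Simulate a complete synthetic cohort
#'
#' Renders phantoms, extracts the radiomic panel from the ground-truth masks,
#' and attaches survival outcomes and profile labels, giving a fully linked
#' cohort: every clinical label traces back to image-generating parameters or
#' extracted features with stated effect sizes.
#'
#' @param config A [cohort_config()].
#' @param feature_config Passed to [extract_all()].
#' @return A `ct_cohort` list: `images`, `masks`, `params`, `features`,
#'   `clinical`.
#' @export
simulate_cohort <- function(config, feature_config = feature_extraction_config()) {
  ph <- simulate_phantom_cohort(config)
  feats <- do.call(rbind, lapply(seq_along(ph$images), function(i) {
    as.data.frame(extract_all(ph$images[[i]], ph$masks[[i]], feature_config))
  }))
  feats <- cbind(subject_id = ph$params$subject_id, feats,
                 stringsAsFactors = FALSE)
  clin <- simulate_survival(feats, config, seed = config$seed + 101L)
  clin <- simulate_profiles(clin, feats, ph$params, config,
                            seed = config$seed + 202L)
  structure(list(images = ph$images, masks = ph$masks, params = ph$params,
                 features = feats, clinical = clin),
            class = "ct_cohort")
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("<ct_cohort> %d subjects, %d x %d px frames\n",
              nrow(x$clinical), nrow(x$images[[1]]$pixels),
              ncol(x$images[[1]]$pixels)))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Images are written as 16-bit grayscale TIFF, masks as 8-bit PNG (0/255),
#' and the clinical table (plus the phantom parameter table when present) as
#' CSV. The array round trip is exact.
#'
#' @param cohort A `ct_cohort` (or a list with `images`, `masks`, `clinical`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  clin <- cohort$clinical
  if (is.null(clin)) {
    clin <- as.data.frame(stats::setNames(
      replicate(length(clinical_schema()), character(0), simplify = FALSE),
      clinical_schema()))
  }
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  if (!is.null(cohort$params)) {
    utils::write.csv(cohort$params, file.path(dir, "phantom_params.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$features)) {
    utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  }
  ids <- clin$subject_id
  for (i in seq_along(cohort$images)) {
    id <- if (length(ids) >= i) ids[i] else sprintf("S%04d", i)
    write_image_tiff(cohort$images[[i]],
                     file.path(dir, "images", paste0(id, ".tif")))
    write_mask_png(cohort$masks[[i]],
                   file.path(dir, "masks", paste0(id, ".png")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stopf("clinical table not found: '%s'", clin_path)
  clin <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  params <- NULL
  pp <- file.path(dir, "phantom_params.csv")
  if (file.exists(pp)) params <- utils::read.csv(pp, stringsAsFactors = FALSE)
  feats <- NULL
  fp <- file.path(dir, "features.csv")
  if (file.exists(fp)) feats <- utils::read.csv(fp, stringsAsFactors = FALSE)
  spacing <- if (!is.null(params)) params$pixel_spacing[1] else 1
  ids <- clin$subject_id
  images <- lapply(ids, function(id) {
    read_image_tiff(file.path(dir, "images", paste0(id, ".tif")),
                    spacing = spacing)
  })
  masks <- lapply(ids, function(id) {
    read_mask_png(file.path(dir, "masks", paste0(id, ".png")),
                  spacing = spacing)
  })
  structure(list(images = images, masks = masks, params = params,
                 features = feats, clinical = clin), class = "ct_cohort")
}
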