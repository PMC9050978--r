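test_that("phantom generation is deterministic and validates its geometry", {
  cfg <- phantom_config(seed = 4)
  p1 <- make_lesion_phantom(cfg)
  p2 <- make_lesion_phantom(cfg)
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$mask$pixels, p2$mask$pixels)

  # disk limit and spiculation contrast at the same seed
  disk <- make_lesion_phantom(phantom_config(spiculation_amp = 0, seed = 9))
  spic <- make_lesion_phantom(phantom_config(spiculation_amp = 0.3,
                                             spiculation_freq = 8, seed = 9))
  expect_gte(shape_circularity(disk$mask), 0.95)
  expect_lt(shape_circularity(spic$mask), shape_circularity(disk$mask))

  expect_error(phantom_config(lesion_radius = 40, image_size = 64),
               "does not fit")
})

test_that("repeat pairs translate exactly and degrade with noise", {
  ph <- make_lesion_phantom(phantom_config(seed = 12))
  same <- make_repeat_pair(ph$image, ph$mask, noise_sd = 0, shift_px = 0)
  expect_identical(same$image$pixels, ph$image$pixels)
  expect_identical(same$mask$pixels, ph$mask$pixels)

  moved <- make_repeat_pair(ph$image, ph$mask, noise_sd = 0, shift_px = 3)
  expect_identical(sum(moved$mask$pixels), sum(ph$mask$pixels))

  expect_error(make_repeat_pair(ph$image, ph$mask, shift_px = 60),
               "out of frame")

  # reliability of "energy" decreases monotonically with acquisition noise
  cohort <- small_phantom_cohort(25, seed = 61)
  icc_at <- function(noise) {
    m1 <- ctrad:::extract_panel(cohort$images, cohort$masks)
    reps <- lapply(seq_along(cohort$images), function(i) {
      make_repeat_pair(cohort$images[[i]], cohort$masks[[i]],
                       noise_sd = noise, shift_px = 0, seed = 700 + i)
    })
    m2 <- ctrad:::extract_panel(lapply(reps, `[[`, "image"),
                                lapply(reps, `[[`, "mask"))
    icc(cbind(m1[, "energy"], m2[, "energy"]))$icc
  }
  expect_gt(icc_at(5), icc_at(50))
})

test_that("survival simulation follows the proportional-hazards model", {
  feats <- synthetic_feature_table(1000, seed = 3)

  # null model: no feature is prognostic
  cfg0 <- cohort_config(n_subjects = 1000, log_hr = c(longhem = 0),
                        censor_rate = 0.3, seed = 8)
  clin0 <- simulate_survival(feats, cfg0)
  c0 <- harrell_c(feats$longhem, clin0$time_months, clin0$event)
  expect_lt(abs(c0 - 0.5), 0.05)

  # injected effect: median-split Cox HR of the target feature exceeds 1
  cfg1 <- cohort_config(n_subjects = 1000, log_hr = c(longhem = 0.7),
                        censor_rate = 0.3, seed = 8)
  clin1 <- simulate_survival(feats, cfg1)
  grp <- median_split(feats$longhem)
  hr <- cox_hr_binary(grp, clin1$time_months, clin1$event)
  expect_gt(hr$hr, 1)
  expect_gt(hr$ci_lower, 1)

  # censoring calibration and the uncensored limit
  expect_lt(abs(mean(clin1$event == 0) - 0.3), 0.05)
  cfg2 <- cohort_config(n_subjects = 1000, log_hr = c(longhem = 0.7),
                        censor_rate = 0, seed = 8)
  expect_true(all(simulate_survival(feats, cfg2)$event == 1))

  expect_error(simulate_survival(feats,
                                 cohort_config(log_hr = c(nosuch = 1))),
               "nosuch")
})

test_that("profile simulation injects recoverable shifts and correlations", {
  feats <- synthetic_feature_table(500, seed = 5)
  params <- data.frame(spiculation_amp = runif(500, 0, 0.3),
                       lesion_mean = runif(500, 250, 550),
                       spiculation_freq = sample(4:10, 500, TRUE),
                       lesion_radius = runif(500, 8, 16),
                       lesion_sd = runif(500, 30, 80))
  cfg <- cohort_config(n_subjects = 500,
                       mutation_shift = list(
                         egfr = list(feature = "kurtosis", shift = 1.0)),
                       grade_link = c(longhem = 0.33), seed = 1)
  base <- simulate_survival(feats, cfg)

  # Wilcoxon power for a +1 SD shift at n = 500 exceeds 0.8
  rej <- vapply(1:60, function(r) {
    rec <- simulate_profiles(base, feats, params, cfg, seed = 5000 + r)
    wilcoxon_de(feats$kurtosis, factor(rec$egfr,
                                       levels = c("wild", "mutant")))$p_value <
      0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)

  # semantic flags are deterministic threshold rules on phantom parameters
  rec <- simulate_profiles(base, feats, params, cfg, seed = 77)
  expect_identical(rec$spiculated, as.integer(params$spiculation_amp > 0.15))

  # grade correlation recovered within +-0.1 of the 0.33 target
  rho <- cor(feats$longhem, rec$grade, method = "spearman")
  expect_lt(abs(rho - 0.33), 0.1)

  # null shifts: type-I error near nominal
  cfg0 <- cohort_config(n_subjects = 500,
                        mutation_shift = list(
                          egfr = list(feature = "kurtosis", shift = 0)),
                        grade_link = c(longhem = 0), seed = 1)
  rej0 <- vapply(1:200, function(r) {
    rec0 <- simulate_profiles(base, feats, params, cfg0, seed = 9000 + r)
    wilcoxon_de(feats$kurtosis, factor(rec0$egfr,
                                       levels = c("wild", "mutant")))$p_value <
      0.05
  }, logical(1))
  expect_lt(abs(mean(rej0) - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 0.01)

  expect_error(simulate_profiles(base, feats, params,
                                 cohort_config(mutation_shift = list(
                                   tp53 = list(feature = "kurtosis",
                                               shift = 1)))),
               "unknown gene")
})

test_that("cohort directories round-trip exactly", {
  dir <- tempfile("cohort")
  cfg <- cohort_config(n_subjects = 4, seed = 2)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, dir)
  expect_length(list.files(file.path(dir, "images")), 4L)
  expect_length(list.files(file.path(dir, "masks")), 4L)
  back <- read_cohort(dir)
  expect_equal(nrow(back$clinical), 4L)
  for (i in 1:4) {
    expect_identical(back$images[[i]]$pixels, cohort$images[[i]]$pixels)
    expect_identical(back$masks[[i]]$pixels, cohort$masks[[i]]$pixels)
  }
  expect_identical(names(back$clinical), clinical_schema())

  # empty cohort: header-only clinical table, no image files
  dir2 <- tempfile("empty")
  write_cohort(list(images = list(), masks = list(), clinical = NULL), dir2)
  empty <- utils::read.csv(file.path(dir2, "clinical.csv"))
  expect_identical(names(empty), clinical_schema())
  expect_equal(nrow(empty), 0L)
  expect_length(list.files(file.path(dir2, "images")), 0L)

  expect_error(read_cohort(tempfile("nope")), "clinical table not found")
})

test_that("fixed seeds reproduce an entire cohort bit-identically", {
  cfg <- cohort_config(n_subjects = 3, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$images[[2]]$pixels, c2$images[[2]]$pixels)
})
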