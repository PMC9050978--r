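test_that("cohort splitting gives round(2n/3) training subjects, reproducibly", {
  rec <- synthetic_feature_table(9)
  sp <- split_cohort(rec, seed = 1)
  expect_equal(nrow(sp$train), 6L)
  expect_equal(nrow(sp$test), 3L)

  rec143 <- synthetic_feature_table(143)
  sp143 <- split_cohort(rec143, seed = 1)
  expect_equal(nrow(sp143$train), 95L)
  expect_equal(nrow(sp143$test), 48L)
  expect_length(intersect(sp143$train$subject_id, sp143$test$subject_id), 0L)
  expect_setequal(c(sp143$train$subject_id, sp143$test$subject_id),
                  rec143$subject_id)

  sp2 <- split_cohort(rec143, seed = 1)
  expect_identical(sp143$train$subject_id, sp2$train$subject_id)
  expect_error(split_cohort(rec143[1:2, ]), "at least 3")
})

test_that("log-rank split statistic matches the survival package on fixtures", {
  # identical survival in both groups: statistic is exactly 0
  t0 <- rep(c(3, 6, 9, 12), 2)
  e0 <- rep(1, 8)
  expect_equal(logrank_split_stat(t0, e0, rep(c(TRUE, FALSE), each = 4)), 0)

  set.seed(2)
  for (rep in 1:10) {
    tt <- round(rexp(30, 0.1), 2) + 0.01
    ee <- rbinom(30, 1, 0.8)
    if (sum(ee) == 0) ee[1] <- 1
    left <- c(rep(TRUE, 15), rep(FALSE, 15))
    stat <- logrank_split_stat(tt, ee, left)
    sd_fit <- survival::survdiff(survival::Surv(tt, ee) ~ left)
    expect_equal(stat^2, sd_fit$chisq, tolerance = 1e-8)
  }

  expect_error(logrank_split_stat(t0, rep(0, 8), rep(c(TRUE, FALSE), 4)),
               "event")
  expect_error(logrank_split_stat(t0, e0, rep(TRUE, 8)), "nonempty")
})

test_that("depth-0 forests predict a constant and refitting is deterministic", {
  feats <- synthetic_feature_table(80, seed = 4)
  cfg <- cohort_config(n_subjects = 80, log_hr = c(longhem = 0.8),
                       censor_rate = 0.2, seed = 3)
  rec <- cbind(feats, simulate_survival(feats, cfg)[, c("time_months",
                                                        "event")])
  f0 <- fit_rsf(rec, params = rsf_params(ntree = 10, nodedepth = 0, seed = 1))
  r0 <- predict_mortality(f0, rec)
  expect_equal(length(unique(round(r0, 12))), 1L)

  f1 <- fit_rsf(rec, params = rsf_params(seed = 7))
  f2 <- fit_rsf(rec, params = rsf_params(seed = 7))
  expect_identical(predict_mortality(f1, rec), predict_mortality(f2, rec))

  rec_cens <- rec
  rec_cens$event <- 0
  expect_error(fit_rsf(rec_cens, params = rsf_params(seed = 1)),
               "all-censored")
})

test_that("tree structure is invariant to monotone feature transforms", {
  feats <- synthetic_feature_table(60, seed = 8)
  cfg <- cohort_config(n_subjects = 60, log_hr = c(variance = 1),
                       censor_rate = 0.2, seed = 5)
  rec <- cbind(feats, simulate_survival(feats, cfg)[, c("time_months",
                                                        "event")])
  f_raw <- fit_rsf(rec, params = rsf_params(ntree = 15, seed = 2))
  rec_tr <- rec
  for (f in radiomic_feature_names()) rec_tr[[f]] <- exp(rec_tr[[f]] / 10)
  f_tr <- fit_rsf(rec_tr, params = rsf_params(ntree = 15, seed = 2))

  tree_shape <- function(node) {
    if (node$leaf) return("leaf")
    list(f = node$feature, l = tree_shape(node$left),
         r = tree_shape(node$right))
  }
  expect_identical(lapply(f_raw$trees, tree_shape),
                   lapply(f_tr$trees, tree_shape))
  # and the induced risk ranking is identical
  expect_identical(order(predict_mortality(f_raw, rec)),
                   order(predict_mortality(f_tr, rec_tr)))
})

test_that("ensemble mortality matches a by-hand traversal on a toy forest", {
  feats <- synthetic_feature_table(40, seed = 10)
  cfg <- cohort_config(n_subjects = 40, log_hr = c(longhem = 1),
                       censor_rate = 0.1, seed = 6)
  rec <- cbind(feats, simulate_survival(feats, cfg)[, c("time_months",
                                                        "event")])
  f <- fit_rsf(rec, params = rsf_params(ntree = 2, nodesize = 5,
                                        nodedepth = 2, seed = 3))
  traverse <- function(node, x) {
    while (!node$leaf) {
      node <- if (x[[node$feature]] <= node$threshold) node$left else
        node$right
    }
    node$mortality
  }
  X <- as.matrix(rec[, f$features])
  want <- vapply(seq_len(nrow(X)), function(i) {
    mean(vapply(f$trees, traverse, numeric(1), x = X[i, ]))
  }, numeric(1))
  expect_equal(predict_mortality(f, rec), want)
})

test_that("score normalization maps the training range to 0-100 and clips", {
  feats <- synthetic_feature_table(60, seed = 12)
  cfg <- cohort_config(n_subjects = 60, log_hr = c(longhem = 1),
                       censor_rate = 0.2, seed = 2)
  rec <- cbind(feats, simulate_survival(feats, cfg)[, c("time_months",
                                                        "event")])
  f <- fit_rsf(rec, params = rsf_params(seed = 4))
  risks <- predict_mortality(f, rec)
  sc <- normalize_score(f, risks)
  expect_equal(min(sc), 0)
  expect_equal(max(sc), 100)
  mid <- mean(f$train_range)
  expect_equal(normalize_score(f, mid), 50)
  expect_equal(normalize_score(f, f$train_range[2] + 10), 100)
  expect_equal(normalize_score(f, f$train_range[1] - 10), 0)

  f_bad <- f
  f_bad$train_range <- c(1, 1)
  expect_error(normalize_score(f_bad, risks), "degenerate")
})

test_that("forest JSON serialization round-trips its structure", {
  feats <- synthetic_feature_table(40, seed = 14)
  cfg <- cohort_config(n_subjects = 40, log_hr = c(longhem = 1),
                       censor_rate = 0.2, seed = 2)
  rec <- cbind(feats, simulate_survival(feats, cfg)[, c("time_months",
                                                        "event")])
  f <- fit_rsf(rec, params = rsf_params(ntree = 3, seed = 4))
  path <- tempfile(fileext = ".json")
  write_forest_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(unlist(back$features), f$features)
  expect_equal(unlist(back$grid), f$grid)
  expect_equal(unlist(back$train_range), f$train_range)
})
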