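test_that("Harrell's C handles rankings, censoring, and ties as defined", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  # censored middle subject: 2 comparable pairs, both concordant
  expect_equal(harrell_c(c(3, 1, 2), c(1, 2, 3), c(1, 0, 1)), 1)
  # score ties count one half
  expect_equal(harrell_c(c(2, 2), c(1, 2), c(1, 1)), 0.5)
  expect_error(harrell_c(c(1, 2), c(3, 3), c(1, 1)), "comparable")

  set.seed(3)
  for (rep in 1:20) {
    n <- 25
    sc <- rnorm(n); tt <- rexp(n) + 0.01; ee <- rbinom(n, 1, 0.7)
    if (sum(ee) == 0) ee[1] <- 1
    expect_equal(harrell_c(sc, tt, ee), harrell_oracle(sc, tt, ee))
    # complement property without score ties
    expect_equal(harrell_c(sc, tt, ee) + harrell_c(-sc, tt, ee), 1)
  }
})

test_that("time-dependent AUC reduces to pair counting without censoring", {
  set.seed(5)
  for (rep in 1:50) {
    n <- 30
    sc <- sample(1:8, n, replace = TRUE)       # ties included on purpose
    tt <- rexp(n, 0.2) + 0.01
    t_star <- median(tt)
    expect_equal(auc_t(sc, tt, rep(1, n), t_star), auc_oracle(sc, tt, t_star))
  }

  # null scores: AUC near 0.5 at a useful horizon
  set.seed(9)
  n <- 1000
  tt <- rexp(n, 0.05); ee <- rbinom(n, 1, 0.8); sc <- rnorm(n)
  expect_lt(abs(auc_t(sc, tt, ee, median(tt)) - 0.5), 0.05)

  # perfectly separating score
  tt2 <- c(1, 2, 3, 10, 20, 30)
  expect_equal(auc_t(c(6:4, 3:1), tt2, rep(1, 6), 5), 1)
  expect_error(auc_t(sc, tt, ee, 1e6), "controls")
})

test_that("Kaplan-Meier and log-rank match hand-worked survival tables", {
  # no events: survival stays at 1
  km0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # hand-computed product-limit estimate: times 1,2,3 events 1,0,1 (n = 3)
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 2 / 3 * 0)
  # no censoring: KM equals the empirical survival function
  km2 <- km_curve(1:4, rep(1, 4))
  expect_equal(km2$surv, c(3, 2, 1, 0) / 4)

  # identical groups: log-rank chi-square 0, p = 1
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)

  # textbook two-group fixture, hand O-E worksheet:
  # group A times 1,3 (events), group B times 2,4 (events)
  # O_A = 2; E_A = 1/2 + 1/3 + ... computed by hand below
  tt <- c(1, 3, 2, 4); ee <- rep(1, 4); gg <- c("A", "A", "B", "B")
  # at t=1: n=4, nA=2, d=1, eA=0.5, v=(1*2*2*3)/(16*3)=0.25
  # at t=2: n=3, nA=1, d=1, eA=1/3, v=(1*1*2*2)/(9*2)=2/9
  # at t=3: n=2, nA=1, d=1, eA=1/2, v=(1*1*1*1)/(4*1)=0.25
  # at t=4: n=1, nA=0 -> no contribution
  u <- 2 - (0.5 + 1 / 3 + 0.5)
  v <- 0.25 + 2 / 9 + 0.25
  lr <- logrank_test(tt, ee, gg)
  expect_equal(lr$chisq, u^2 / v, tolerance = 1e-10)
})

test_that("median split sends ties to the low group", {
  expect_identical(as.character(median_split(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(c(1, 2, 2, 3))),
                   c("low", "low", "low", "high"))
  expect_identical(as.character(median_split(c(5, 1))), c("high", "low"))
  expect_error(median_split(rep(2, 5)), "degenerate")
})

test_that("binary Cox HR is symmetric, calibrated, and flags separation", {
  # identical groups: log HR ~ 0
  tt <- rep(c(1, 2, 3, 4, 5), 2); ee <- rep(1, 10)
  gg <- rep(c("a", "b"), 5)
  hr0 <- cox_hr_binary(gg, tt, ee)
  expect_lt(abs(log(hr0$hr)), 1e-6)

  # label swap inverts the HR exactly
  set.seed(4)
  tt2 <- rexp(60, 0.1); ee2 <- rbinom(60, 1, 0.8); g2 <- rep(c("a", "b"), 30)
  h1 <- cox_hr_binary(factor(g2, c("a", "b")), tt2, ee2)
  h2 <- cox_hr_binary(factor(g2, c("b", "a")), tt2, ee2)
  expect_equal(h1$hr, 1 / h2$hr, tolerance = 1e-8)
  expect_equal(h1$ci_lower, 1 / h2$ci_upper, tolerance = 1e-8)

  # CI coverage of a true HR = 2 under exponential PH
  set.seed(11)
  cover <- vapply(1:100, function(r) {
    n <- 1000
    g <- rep(0:1, each = n / 2)
    t_ <- rexp(n, 0.02 * 2^g)
    cens <- rexp(n, 0.01)
    hr <- cox_hr_binary(factor(g), pmin(t_, cens), as.integer(t_ <= cens))
    hr$ci_lower <= 2 && 2 <= hr$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # β within 2 SE of the analytic log-rate ratio on a no-censoring fixture
  set.seed(12)
  g <- rep(0:1, each = 500)
  t_ <- rexp(1000, 0.05 * exp(0.7 * g))
  fit <- cox_hr_binary(factor(g), t_, rep(1, 1000))
  expect_lt(abs(log(fit$hr) - 0.7), 2 * fit$log_hr_se)

  # complete separation of event order is refused
  expect_error(cox_hr_binary(factor(rep(c("a", "b"), each = 5)),
                             c(1:5, 101:105), rep(1, 10)),
               "exact method")
})

test_that("subgroup hazard ratios reuse the full-cohort split and NA cleanly", {
  feats <- synthetic_feature_table(200, seed = 6)
  cfg <- cohort_config(n_subjects = 200, log_hr = c(longhem = 1),
                       censor_rate = 0.2, seed = 7)
  clin <- simulate_survival(feats, cfg)
  sc <- feats$longhem
  tab <- subgroup_hr(sc, clin$time_months, clin$event,
                     list(all = rep(TRUE, 200),
                          none = rep(FALSE, 200)))
  whole <- cox_hr_binary(median_split(sc), clin$time_months, clin$event)
  expect_equal(tab$hr[tab$subgroup == "all"], whole$hr)
  expect_true(is.na(tab$hr[tab$subgroup == "none"]))
  expect_false(is.na(tab$reason[tab$subgroup == "none"]))
})
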