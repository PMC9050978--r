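#!/usr/bin/env Rscript
# Stage 4: prognosis evaluation of the composite score.
#
# Harrell's C and IPCW time-dependent AUC at 2 and 5 years for the training,
# testing, and external groups; Kaplan-Meier median-split stratification with
# log-rank tests and binary Cox hazard ratios; demographic subgroup hazard
# ratios in the development cohort.

suppressPackageStartupMessages(library(ctrad))

scores <- read.csv("results/scores.csv")
clin_a <- read.csv("scratch/cohort_a/clinical.csv")
clin_b <- read.csv("scratch/cohort_b/clinical.csv")
clin <- rbind(clin_a, clin_b)
sc <- scores$score[match(clin$subject_id, scores$subject_id)]
grp_of <- function(ids) scores$cohort[match(ids, scores$subject_id)]

report <- list()
for (g in c("train", "test", "external")) {
  keep <- grp_of(clin$subject_id) == g
  s <- sc[keep]; t_ <- clin$time_months[keep]; e <- clin$event[keep]
  entry <- list(n = sum(keep), harrell_c = harrell_c(s, t_, e))
  for (h in c(24, 60)) {
    entry[[paste0("auc_month_", h)]] <- tryCatch(auc_t(s, t_, e, h),
                                                 error = function(err) NA)
  }
  hl <- median_split(s)
  entry$logrank_p <- logrank_test(t_, e, hl)$p
  hr <- tryCatch(cox_hr_binary(hl, t_, e), error = function(err) NULL)
  if (!is.null(hr)) {
    entry$hr <- hr$hr; entry$hr_ci <- c(hr$ci_lower, hr$ci_upper)
  }
  report[[g]] <- entry
  cat(sprintf("%-8s n=%3d  C=%.3f  AUC(5y)=%.3f  HR(high vs low)=%.2f  logrank p=%.2g\n",
              g, entry$n, entry$harrell_c, entry$auc_month_60,
              if (is.null(hr)) NA else hr$hr, entry$logrank_p))
  # KM step functions for plotting
  for (lvl in levels(hl)) {
    km <- km_curve(t_[hl == lvl], e[hl == lvl])
    write.csv(km, sprintf("results/km_%s_%s.csv", g, lvl), row.names = FALSE)
  }
}

ids_a <- grp_of(clin$subject_id) %in% c("train", "test")
report$subgroups <- subgroup_hr(
  sc[ids_a], clin$time_months[ids_a], clin$event[ids_a],
  list(age_70_plus = clin$age[ids_a] >= 70,
       age_under_70 = clin$age[ids_a] < 70,
       female = clin$sex[ids_a] == "female",
       male = clin$sex[ids_a] == "male",
       never_smoker = clin$smoking[ids_a] == "never",
       ever_smoker = clin$smoking[ids_a] != "never"))
print(report$subgroups[, c("subgroup", "hr", "ci_lower", "ci_upper", "n")])

jsonlite::write_json(report, "results/prognosis.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, dataframe = "rows")
cat("wrote results/prognosis.json and per-group KM curves\n")
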