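#' Harrell's concordance index
#'
#' Over pairs where the shorter observed time is an event: the pair is
#' concordant when the shorter-time subject has the higher score; score ties
#' count 0.5. Tied times are not comparable.
#'
#' @param scores Risk scores (higher = predicted earlier death).
#' @param times Survival times.
#' @param events Event indicators (0/1).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(scores, times, events) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  dt <- outer(times, times, "<")                    # i strictly earlier than j
  comparable <- dt & matrix(events == 1, n, n)      # and i is an event
  n_comp <- sum(comparable)
  if (n_comp == 0) stopf("no comparable pair")
  ds <- outer(scores, scores, "-")
  conc <- sum(comparable & ds > 0) + 0.5 * sum(comparable & ds == 0)
  conc / n_comp
}

# Kaplan-Meier estimate of the censoring distribution G(t); returns a function
# evaluating G at t (left limit when left = TRUE). Used for IPCW weights.
censoring_km <- function(times, events) {
  ord <- order(times)
  t_s <- times[ord]; c_s <- 1 - events[ord]         # censorings are "events"
  ut <- unique(t_s)
  d <- vapply(ut, function(u) sum(c_s == 1 & t_s == u), numeric(1))
  n <- vapply(ut, function(u) sum(t_s >= u), numeric(1))
  surv <- cumprod(1 - d / n)
  function(t, left = FALSE) {
    idx <- if (left) findInterval(t - .Machine$double.eps^0.5, ut)
           else findInterval(t, ut)
    ifelse(idx == 0, 1, surv[pmax(idx, 1)])
  }
}

#' Time-dependent AUC (cumulative/dynamic, IPCW)
#'
#' Discriminates cases (event by horizon `t`) from controls (still at risk
#' beyond `t`). Observations are weighted by inverse probability of censoring
#' from the Kaplan-Meier estimate of the censoring distribution: cases by
#' `1/G(T_i-)`, controls by `1/G(t)`. With no censoring this reduces exactly
#' to the empirical ROC AUC by pair counting.
#'
#' @param scores Risk scores (higher = earlier death predicted).
#' @param times,events Survival data.
#' @param t Evaluation horizon (same units as `times`).
#' @return AUC at horizon `t`.
#' @export
auc_t <- function(scores, times, events, t) {
  is_case <- times <= t & events == 1
  is_ctrl <- times > t
  if (!any(is_case) || !any(is_ctrl)) {
    stopf("no %s at horizon t = %g", if (!any(is_case)) "cases" else
      "controls", t)
  }
  G <- censoring_km(times, events)
  w_case <- 1 / G(times[is_case], left = TRUE)
  w_ctrl <- rep(1 / G(t), sum(is_ctrl))
  sc <- scores[is_case]; sk <- scores[is_ctrl]
  W <- outer(w_case, w_ctrl)
  gt <- outer(sc, sk, ">"); eq <- outer(sc, sk, "==")
  sum(W * (gt + 0.5 * eq)) / sum(W)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with at-risk counts, via the survival package.
#'
#' @param times,events Survival data.
#' @return A `km_curve`: data frame with `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stopf("empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Two-sample log-rank test
#'
#' @param times,events Survival data.
#' @param group Two-level group labels.
#' @return List with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stopf("exactly two nonempty groups required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Median split of a score
#'
#' Scores `<=` median are labelled `"low"`, the rest `"high"`.
#'
#' @param scores Numeric scores, `n >= 2`.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stopf("need at least 2 scores")
  if (length(unique(scores)) == 1L) stopf("degenerate stratification: all scores identical")
  med <- stats::median(scores)
  factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
}

#' Binary-covariate Cox hazard ratio
#'
#' One-covariate Cox proportional-hazards fit (Breslow tie handling, Newton
#' maximization of the partial likelihood) comparing the second group level
#' against the first. The 95% CI is Wald on the log scale.
#'
#' @param group Two-level factor (reference level first).
#' @param times,events Survival data.
#' @return An `hr_result` list: `hr`, `ci_lower`, `ci_upper`, `log_hr_se`,
#'   `n_per_group`.
#' @export
cox_hr_binary <- function(group, times, events) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stopf("exactly two group levels required")
  ev_by_grp <- tapply(events, group, sum)
  if (any(ev_by_grp == 0)) stopf("both groups need at least one event")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ group, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        stopf("monotone partial likelihood (complete separation): use an exact method")
      }
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (abs(beta) > 15) {
    stopf("monotone partial likelihood (complete separation): use an exact method")
  }
  structure(list(hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se), log_hr_se = se,
                 n_per_group = as.integer(table(group))),
            class = "hr_result")
}

#' Hazard ratios within subgroups
#'
#' The high/low split is computed once on the full cohort's scores; the Cox
#' hazard ratio of high vs low is then fitted within each subgroup. Subgroups
#' failing the fit preconditions are reported as `NA` with the reason.
#'
#' @param scores Full-cohort scores.
#' @param times,events Full-cohort survival data.
#' @param subgroups Named list of logical vectors selecting subjects.
#' @return Data frame: one row per subgroup with `hr`, `ci_lower`, `ci_upper`,
#'   `n`, `reason` (`NA` on success).
#' @export
subgroup_hr <- function(scores, times, events, subgroups) {
  grp <- median_split(scores)
  rows <- lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]]
    res <- tryCatch(cox_hr_binary(grp[sel], times[sel], events[sel]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(subgroup = nm, hr = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, n = sum(sel), reason = res,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subgroup = nm, hr = res$hr, ci_lower = res$ci_lower,
                 ci_upper = res$ci_upper, n = sum(sel), reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
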