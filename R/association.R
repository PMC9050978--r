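#' Wilcoxon differential expression of one feature
#'
#' Two-sided rank-sum test of feature values between label groups: exact
#' enumeration when `min(n1, n2) <= 8` and there are no ties, otherwise the
#' normal approximation with tie and continuity correction. Direction is the
#' sign of the median difference (label-present minus label-absent); `"ns"`
#' when `p >= alpha`.
#'
#' @param values Feature values.
#' @param label Binary labels (0/1, logical, or two-level factor; the second
#'   level / 1 is "present").
#' @param feature,profile Optional names recorded in the result.
#' @param alpha Significance level for the direction call.
#' @return An `association_result` data frame row: feature, profile, direction
#'   (`up`/`down`/`ns`), `p_value`, `effect` (median difference), `test`, `n1`,
#'   `n0`.
#' @export
wilcoxon_de <- function(values, label, feature = "feature",
                        profile = "profile", alpha = 0.05) {
  lab <- as_binary_label(label)
  x1 <- values[lab == 1L]; x0 <- values[lab == 0L]
  if (length(x1) == 0L || length(x0) == 0L) stopf("both groups must be nonempty")
  ties <- any(duplicated(c(x1, x0)))
  use_exact <- min(length(x1), length(x0)) <= 8L && !ties
  p <- suppressWarnings(stats::wilcox.test(x1, x0, exact = use_exact,
                                           correct = TRUE))$p.value
  eff <- stats::median(x1) - stats::median(x0)
  dir <- if (p >= alpha || eff == 0) "ns" else if (eff > 0) "up" else "down"
  structure(data.frame(feature = feature, profile = profile, direction = dir,
                       p_value = p, effect = eff, test = "wilcoxon",
                       n1 = length(x1), n0 = length(x0),
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

as_binary_label <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.factor(label) || is.character(label)) {
    f <- droplevels(as.factor(label))
    if (nlevels(f) != 2L) stopf("label must have exactly two levels")
    return(as.integer(f) - 1L)
  }
  if (!all(label %in% c(0, 1))) stopf("numeric label must be 0/1")
  as.integer(label)
}

#' Spearman association of a feature with an ordinal profile
#'
#' Spearman correlation with midrank ties; the two-sided p-value uses the
#' t approximation.
#'
#' @param values Feature values (`n >= 3`).
#' @param ordinal Ordinal profile (>= 2 distinct values).
#' @param feature,profile Optional names recorded in the result.
#' @param alpha Significance level for the direction call.
#' @return An `association_result` row (`effect` holds rho; `test` =
#'   `"spearman"`).
#' @export
spearman_assoc <- function(values, ordinal, feature = "feature",
                           profile = "profile", alpha = 0.05) {
  keep <- !is.na(values) & !is.na(ordinal)
  values <- values[keep]; ordinal <- ordinal[keep]
  if (length(values) < 3L) stopf("need n >= 3")
  if (length(unique(ordinal)) < 2L) stopf("ordinal profile is constant")
  ct <- suppressWarnings(stats::cor.test(values, as.numeric(ordinal),
                                         method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  dir <- if (p >= alpha || rho == 0) "ns" else if (rho > 0) "up" else "down"
  structure(data.frame(feature = feature, profile = profile, direction = dir,
                       p_value = p, effect = rho, test = "spearman",
                       n1 = length(values), n0 = NA_integer_,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Feature x profile association table
#'
#' Differential expression of every feature against every available profile:
#' Wilcoxon for the five semantic flags, for each gene (mutant vs wild), and
#' for pairwise histology groups (with a Kruskal-Wallis omnibus p-value
#' reported alongside); Spearman for the ordinal grade. P-values are
#' unadjusted, as per-test significance is reported at two tiers (`alpha` and
#' `alpha/5`, i.e. 0.05 and 0.01 by default); optional Benjamini-Hochberg
#' adjustment is available.
#'
#' @param features Feature data frame (canonical columns).
#' @param profiles Clinical data frame (clinical schema columns; absent
#'   profile columns are skipped with a warning).
#' @param alpha Significance level.
#' @param adjust If `TRUE`, apply Benjamini-Hochberg across all tests before
#'   calling directions.
#' @param feature_names Features to test.
#' @return Data frame of association rows, with `stars` (`""`, `"*"`, `"**"`)
#'   and an attribute `omnibus` holding the histology Kruskal-Wallis results.
#' @export
association_table <- function(features, profiles, alpha = 0.05,
                              adjust = FALSE,
                              feature_names = setdiff(radiomic_feature_names(),
                                                      "diameter_mm")) {
  stopifnot(nrow(features) == nrow(profiles))
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  binary_profiles <- c(known_semantic_flags, known_genes)
  for (pr in binary_profiles) {
    if (!pr %in% names(profiles)) {
      warning(sprintf("profile column '%s' absent: skipped", pr))
      next
    }
    lab <- profiles[[pr]]
    if (pr %in% known_genes) {
      keep <- lab %in% c("mutant", "wild")
      lab <- factor(lab[keep], levels = c("wild", "mutant"))
    } else {
      keep <- !is.na(lab)
      lab <- lab[keep]
    }
    if (length(unique(lab)) < 2L) next
    for (f in feature_names) {
      add(wilcoxon_de(features[[f]][keep], lab, f, pr, alpha))
    }
  }

  omnibus <- NULL
  if ("histology" %in% names(profiles)) {
    h <- profiles$histology
    lv <- sort(unique(h[!is.na(h)]))
    if (length(lv) >= 2L) {
      for (pair in utils::combn(lv, 2, simplify = FALSE)) {
        keep <- h %in% pair
        lab <- factor(h[keep], levels = pair)
        for (f in feature_names) {
          add(wilcoxon_de(features[[f]][keep], lab, f,
                          paste0("histology:", pair[2], "_vs_", pair[1]),
                          alpha))
        }
      }
      omnibus <- do.call(rbind, lapply(feature_names, function(f) {
        kw <- stats::kruskal.test(features[[f]][!is.na(h)],
                                  factor(h[!is.na(h)]))
        data.frame(feature = f, profile = "histology", test = "kruskal",
                   p_value = kw$p.value, stringsAsFactors = FALSE)
      }))
    }
  } else {
    warning("profile column 'histology' absent: skipped")
  }

  if ("grade" %in% names(profiles)) {
    for (f in feature_names) {
      add(spearman_assoc(features[[f]], profiles$grade, f, "grade", alpha))
    }
  } else {
    warning("profile column 'grade' absent: skipped")
  }

  out <- do.call(rbind, rows)
  if (adjust) {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    recall <- out$p_value < alpha & out$direction != "ns"
    out$direction[!recall] <- "ns"
  } else {
    out$direction[out$p_value >= alpha] <- "ns"
  }
  out$stars <- ifelse(out$p_value < alpha / 5, "**",
                      ifelse(out$p_value < alpha, "*", ""))
  attr(out, "omnibus") <- omnibus
  out
}

#' Wide up/down/ns matrix of an association table
#'
#' @param assoc Output of [association_table()].
#' @return Character matrix, features x profiles, cells like `"up**"`.
#' @export
association_matrix <- function(assoc) {
  feats <- unique(assoc$feature)
  profs <- unique(assoc$profile)
  m <- matrix("ns", length(feats), length(profs),
              dimnames = list(feats, profs))
  for (k in seq_len(nrow(assoc))) {
    cell <- assoc$direction[k]
    if (cell != "ns") cell <- paste0(cell, assoc$stars[k])
    m[assoc$feature[k], assoc$profile[k]] <- cell
  }
  m
}
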