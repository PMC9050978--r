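#' Random split of a cohort into training and testing groups
#'
#' 2:1 split by default: training size is `round(2n/3)`; the partition is
#' disjoint, exhaustive and reproducible given the seed.
#'
#' @param records Data frame of subject records.
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_cohort <- function(records, train_fraction = 2 / 3, seed = 1L) {
  n <- nrow(records)
  if (n < 3L) stopf("need at least 3 subjects to split")
  n_train <- as.integer(round(train_fraction * n))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Standardized two-sample log-rank statistic
#'
#' The statistic `U / sqrt(V)` with `U = sum_t (d1_t - n1_t d_t / n_t)` and
#' the hypergeometric variance `V`; larger absolute values indicate better
#' separation. Used as the node-splitting criterion of the survival forest.
#'
#' @param times Survival times.
#' @param events Event indicators (0/1).
#' @param left Logical vector marking the left group.
#' @return Signed standardized log-rank statistic.
#' @export
logrank_split_stat <- function(times, events, left) {
  if (!any(left) || all(left)) stopf("both sides must be nonempty")
  if (sum(events) == 0) stopf("log-rank statistic needs at least one event")
  s <- logrank_stats_matrix(times, events, matrix(left, ncol = 1))
  as.numeric(s)
}

# Vectorized standardized log-rank statistics for many candidate left-groups
# at once. `left` is an n x k logical matrix; returns length-k vector
# (NA where the variance is 0).
logrank_stats_matrix <- function(times, events, left) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  L <- left[ord, , drop = FALSE] * 1
  m <- length(t_s); k <- ncol(L)
  n_left_total <- colSums(L)
  cumL <- apply(L, 2, cumsum)
  # at-risk in the left group at each row's time (rows sorted by time)
  atrisk_left <- rbind(n_left_total,
                       matrix(n_left_total, m - 1, k, byrow = TRUE) -
                         cumL[-m, , drop = FALSE])
  grp <- match(t_s, unique(t_s))             # unique-time group per row
  first_row <- which(!duplicated(grp))
  n_t <- m - first_row + 1                   # at risk at each unique time
  d_t <- as.vector(rowsum(e_s, grp))         # deaths at each unique time
  has_death <- d_t > 0
  d1 <- rowsum(L * e_s, grp)                 # deaths in left, per time x k
  n1 <- atrisk_left[first_row, , drop = FALSE]
  nt <- n_t[has_death]; dt <- d_t[has_death]
  d1 <- d1[has_death, , drop = FALSE]; n1 <- n1[has_death, , drop = FALSE]
  expd <- n1 * (dt / nt)
  U <- colSums(d1 - expd)
  vterm <- (dt / nt) * (1 - n1 / nt) * ifelse(nt > 1, (nt - dt) / (nt - 1), 0)
  V <- colSums(n1 * vterm)
  out <- rep(NA_real_, k)
  pos <- V > 1e-12
  out[pos] <- U[pos] / sqrt(V[pos])
  out
}

#' Random survival forest hyperparameters
#'
#' @param ntree Number of trees.
#' @param nodesize Minimum subjects per terminal node.
#' @param nodedepth Maximum tree depth (0 = root-only trees).
#' @param mtry Features tried per split; default `ceiling(sqrt(p))` resolved
#'   at fit time.
#' @param seed Integer seed.
#' @return An `rsf_params` list.
#' @export
rsf_params <- function(ntree = 50L, nodesize = 10L, nodedepth = 4L,
                       mtry = NULL, seed = 1L) {
  if (ntree < 1) stopf("ntree must be >= 1")
  if (nodesize < 1) stopf("nodesize must be >= 1")
  if (nodedepth < 0) stopf("nodedepth must be >= 0")
  structure(list(ntree = as.integer(ntree), nodesize = as.integer(nodesize),
                 nodedepth = as.integer(nodedepth),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 seed = as.integer(seed)), class = "rsf_params")
}

# Nelson-Aalen cumulative hazard of a (sub)sample, evaluated on a time grid
nelson_aalen_on_grid <- function(times, events, grid) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  ut <- unique(t_s[e_s == 1])
  if (length(ut) == 0L) return(rep(0, length(grid)))
  d <- vapply(ut, function(u) sum(e_s == 1 & t_s == u), numeric(1))
  n <- vapply(ut, function(u) sum(t_s >= u), numeric(1))
  chf_at <- cumsum(d / n)
  idx <- findInterval(grid, ut)
  ifelse(idx == 0, 0, chf_at[pmax(idx, 1)])
}

grow_node <- function(times, events, X, depth, hp) {
  n <- length(times)
  make_leaf <- function() list(leaf = TRUE, n = n)
  if (depth >= hp$nodedepth || n < 2L * hp$nodesize || sum(events) == 0) {
    return(make_leaf())
  }
  p <- ncol(X)
  cand_feats <- sort(sample.int(p, min(hp$mtry, p)))
  best <- list(stat = -Inf)
  for (f in cand_feats) {
    x <- X[, f]
    ux <- sort(unique(x))
    if (length(ux) < 2L) next
    ths <- (ux[-1] + ux[-length(ux)]) / 2          # midpoints: deterministic
    left <- outer(x, ths, "<=")
    nl <- colSums(left)
    adm <- nl >= hp$nodesize & (n - nl) >= hp$nodesize
    if (!any(adm)) next
    stats <- rep(NA_real_, length(ths))
    stats[adm] <- logrank_stats_matrix(times, events,
                                       left[, adm, drop = FALSE])
    stats <- abs(stats)
    if (all(is.na(stats))) next
    j <- which.max(stats)                           # first max: deterministic
    if (is.finite(stats[j]) && stats[j] > best$stat) {
      best <- list(stat = stats[j], feature = f, threshold = ths[j])
    }
  }
  if (!is.finite(best$stat)) return(make_leaf())
  go_left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_node(times[go_left], events[go_left],
                        X[go_left, , drop = FALSE], depth + 1L, hp),
       right = grow_node(times[!go_left], events[!go_left],
                         X[!go_left, , drop = FALSE], depth + 1L, hp))
}

# attach Nelson-Aalen leaf hazards (on the shared grid) to a grown tree
attach_leaf_chf <- function(node, times, events, idx, X, grid) {
  if (node$leaf) {
    chf <- nelson_aalen_on_grid(times[idx], events[idx], grid)
    node$chf <- chf
    node$mortality <- sum(chf)
    return(node)
  }
  go_left <- X[idx, node$feature] <= node$threshold
  node$left <- attach_leaf_chf(node$left, times, events, idx[go_left], X, grid)
  node$right <- attach_leaf_chf(node$right, times, events, idx[!go_left], X,
                                grid)
  node
}

#' Fit a random survival forest
#'
#' An ensemble of binary survival trees: each tree is grown on a bootstrap
#' sample (with replacement, same size as the training set); at each node,
#' `mtry` randomly chosen features are screened over all midpoint thresholds
#' and the split with the largest absolute standardized log-rank statistic is
#' taken, subject to `nodesize` on both children and `nodedepth`. Terminal
#' nodes store the Nelson-Aalen cumulative hazard of their in-bag subjects on
#' the grid of all training event times. Fitting is deterministic given the
#' seed.
#'
#' @param records Data frame with `time_months`, `event`, and the feature
#'   columns.
#' @param features Character vector of feature column names (default: the
#'   radiomic panel).
#' @param params An [rsf_params()].
#' @return A `survival_forest`: trees, the event-time grid, feature names, and
#'   the training risk range used by [normalize_score()].
#' @export
fit_rsf <- function(records, features = radiomic_feature_names(),
                    params = rsf_params()) {
  stopifnot(inherits(params, "rsf_params"))
  missing_f <- setdiff(features, names(records))
  if (length(missing_f)) stopf("missing feature column(s): %s",
                               paste(missing_f, collapse = ", "))
  times <- records$time_months
  events <- records$event
  if (sum(events) == 0) stopf("all-censored training data: cannot fit")
  n <- length(times)
  if (n < 2L * params$nodesize) {
    stopf("need at least 2 * nodesize = %d subjects", 2L * params$nodesize)
  }
  X <- as.matrix(records[, features, drop = FALSE])
  hp <- params
  if (is.null(hp$mtry)) hp$mtry <- as.integer(ceiling(sqrt(ncol(X))))
  grid <- sort(unique(times[events == 1]))
  trees <- with_seed(params$seed, {
    lapply(seq_len(params$ntree), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tb <- times[idx]; eb <- events[idx]; Xb <- X[idx, , drop = FALSE]
      if (sum(eb) == 0) {
        node <- list(leaf = TRUE, n = n)
      } else {
        node <- grow_node(tb, eb, Xb, 0L, hp)
      }
      attach_leaf_chf(node, tb, eb, seq_len(n), Xb, grid)
    })
  })
  forest <- structure(list(trees = trees, grid = grid, features = features,
                           params = hp, train_range = NULL),
                      class = "survival_forest")
  train_risk <- predict_mortality(forest, records)
  forest$train_range <- range(train_risk)
  forest
}

# vectorized descent: returns per-subject mortality for one tree
tree_mortality <- function(node, X, idx, out) {
  if (node$leaf) {
    out[idx] <- node$mortality
    return(out)
  }
  go_left <- X[idx, node$feature] <= node$threshold
  out <- tree_mortality(node$left, X, idx[go_left], out)
  tree_mortality(node$right, X, idx[!go_left], out)
}

#' Predict ensemble mortality
#'
#' The predicted risk is the ensemble mortality: the tree-average terminal
#' Nelson-Aalen cumulative hazard summed over the training event-time grid.
#' Higher values mean higher death risk.
#'
#' @param forest A [fit_rsf()] forest.
#' @param newdata Data frame containing the forest's feature columns.
#' @return Numeric risk per subject (dimensionless).
#' @export
predict_mortality <- function(forest, newdata) {
  stopifnot(inherits(forest, "survival_forest"))
  missing_f <- setdiff(forest$features, names(newdata))
  if (length(missing_f)) stopf("missing feature column(s): %s",
                               paste(missing_f, collapse = ", "))
  X <- as.matrix(newdata[, forest$features, drop = FALSE])
  n <- nrow(X)
  acc <- rep(0, n)
  for (tr in forest$trees) {
    acc <- acc + tree_mortality(tr, X, seq_len(n), rep(0, n))
  }
  acc / length(forest$trees)
}

#' Rescale forest risks to a 0-100 score
#'
#' `score = 100 * (risk - min_train) / (max_train - min_train)`, clipped to
#' `[0, 100]` for out-of-range external risks.
#'
#' @param forest A fitted forest (supplies the training risk range).
#' @param risks Numeric risks from [predict_mortality()].
#' @return Scores in `[0, 100]`.
#' @export
normalize_score <- function(forest, risks) {
  stopifnot(inherits(forest, "survival_forest"))
  rng <- forest$train_range
  if (is.null(rng) || diff(rng) <= 0) {
    stopf("degenerate training risk range: cannot normalize")
  }
  pmin(pmax(100 * (risks - rng[1]) / (rng[2] - rng[1]), 0), 100)
}

#' Serialize a survival forest to JSON
#'
#' Trees are written as nested node objects (`feature`, `threshold`, `left`,
#' `right`; leaves carry `mortality` and the cumulative hazard on the shared
#' event-time grid).
#'
#' @param forest A `survival_forest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  obj <- list(features = forest$features, grid = forest$grid,
              params = unclass(forest$params),
              train_range = forest$train_range,
              trees = forest$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
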