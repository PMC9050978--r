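# Independent brute-force oracles and small fixture builders. Every oracle is
# a direct enumeration, written without reference to the package internals it
# checks.

offset_of <- function(direction) {
  switch(as.character(direction),
         `0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
         `135` = c(-1L, -1L))
}

# exhaustive pair enumeration for the co-occurrence matrix
glcm_oracle <- function(lv, G, distance = 1L, directions = c(0, 45, 90, 135)) {
  C <- matrix(0, G, G)
  nr <- nrow(lv); nc <- ncol(lv)
  for (d in directions) {
    o <- offset_of(d) * distance
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
          !is.na(lv[i, j]) && !is.na(lv[i2, j2])) {
        C[lv[i, j], lv[i2, j2]] <- C[lv[i, j], lv[i2, j2]] + 1
        C[lv[i2, j2], lv[i, j]] <- C[lv[i2, j2], lv[i, j]] + 1
      }
    }
  }
  C / sum(C)
}

glcm_features_oracle <- function(P) {
  G <- nrow(P)
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    mu_i <- mu_i + i * P[i, j]; mu_j <- mu_j + j * P[i, j]
  }
  cs <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    cs <- cs + (i + j - mu_i - mu_j)^3 * P[i, j]
  }
  list(cluster_shade = cs, maximum_probability = max(P))
}

# scan-line run enumeration: a run starts where the predecessor along the
# direction is absent or different, and extends while the level repeats
glrlm_oracle <- function(lv, G, direction) {
  o <- offset_of(direction)
  nr <- nrow(lv); nc <- ncol(lv)
  R <- matrix(0, G, max(nr, nc))
  inb <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(lv[i, j])) next
    pi <- i - o[1]; pj <- j - o[2]
    if (inb(pi, pj) && !is.na(lv[pi, pj]) && lv[pi, pj] == lv[i, j]) next
    len <- 1L; ci <- i + o[1]; cj <- j + o[2]
    while (inb(ci, cj) && !is.na(lv[ci, cj]) && lv[ci, cj] == lv[i, j]) {
      len <- len + 1L; ci <- ci + o[1]; cj <- cj + o[2]
    }
    R[lv[i, j], len] <- R[lv[i, j], len] + 1
  }
  R
}

glrlm_stats_oracle <- function(R) {
  nr_runs <- sum(R)
  lre <- 0; lrhge <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    lre <- lre + R[i, j] * j^2
    lrhge <- lrhge + R[i, j] * j^2 * i^2
  }
  list(lre = lre / nr_runs, lrhge = lrhge / nr_runs)
}

# pairwise concordance by explicit double loop
harrell_oracle <- function(scores, times, events) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# censoring-free ROC AUC at horizon t by case-control pair counting
auc_oracle <- function(scores, times, t) {
  cases <- scores[times <= t]
  ctrls <- scores[times > t]
  num <- 0
  for (a in cases) for (b in ctrls) {
    num <- num + (a > b) + 0.5 * (a == b)
  }
  num / (length(cases) * length(ctrls))
}

# fixtures ------------------------------------------------------------------

disk_mask <- function(r_px, pad = 4, spacing = 1) {
  n <- 2L * as.integer(ceiling(r_px + pad)) + 1L
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  lesion_mask(d <= r_px, spacing = spacing)
}

# small random ROI: image + mask with irregular support
random_roi <- function(nr, nc, G = 5, p_mask = 0.8) {
  img <- gray_image(matrix(sample.int(40, nr * nc, replace = TRUE), nr, nc))
  mk <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
  if (!any(mk)) mk[sample.int(nr * nc, 2)] <- TRUE
  list(image = img, mask = lesion_mask(mk), G = G)
}

# relative error with an absolute floor of 1: quantities like cluster shade
# cross zero, where a pure relative error is ill-defined
rel_err <- function(a, b) abs(a - b) / max(abs(b), 1)

# minimal feature table for cohort-level operations that do not need images
synthetic_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             circularity = stats::runif(n, 0.4, 1),
             variance = stats::rnorm(n, 10, 3),
             kurtosis = stats::rnorm(n, 3, 0.8),
             energy = stats::runif(n, 0.05, 0.4),
             cluster_shade = stats::rnorm(n, 0, 50),
             maximum_probability = stats::runif(n, 0.05, 0.6),
             longhem = stats::rlnorm(n, 5, 0.6),
             a_lre = stats::rlnorm(n, 1, 0.4),
             diameter_mm = sample(8:35, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

small_phantom_cohort <- function(n, seed) {
  ph <- simulate_phantom_cohort(cohort_config(n_subjects = n, seed = seed))
  structure(list(images = ph$images, masks = ph$masks, params = ph$params),
            class = "ct_cohort")
}
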