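#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard mean-squares decomposition of an n x k measurement matrix
#' (subjects x repeated measurements):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Negative estimates are reported as-is with a flag.
#'
#' @param measurements Numeric n x k matrix, `n >= 3`, `k >= 2`, no missing
#'   cells.
#' @return An `icc_estimate` list: `icc`, `model`, `n`, `k`, variance
#'   components (`var_subject`, `var_measurement`, `var_error`), `negative`.
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stopf("ICC requires complete measurements (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stopf("ICC needs n >= 3 subjects")
  if (k < 2L) stopf("ICC needs k >= 2 measurements")
  if (stats::var(as.vector(m)) == 0) stopf("zero total variance")
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = val,
                 model = "two-way random, absolute agreement, single measure",
                 n = n, k = k,
                 var_subject = max((msr - mse) / k, 0),
                 var_measurement = max((msc - mse) / n, 0),
                 var_error = mse,
                 negative = val < 0),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  [%s; n = %d, k = %d]\n", x$icc, x$model, x$n,
              x$k))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `m1 - m2`; bias is their mean, `sd` the sample standard
#' deviation (n - 1), and the 95% limits of agreement are `bias +/- 1.96 sd`.
#'
#' @param pairs Numeric n x 2 matrix of paired measurements, `n >= 2`.
#' @return A `ba_result` list: `bias`, `sd`, `loa_lower`, `loa_upper`,
#'   `means`, `diffs`.
#' @export
bland_altman <- function(pairs) {
  m <- as.matrix(pairs)
  if (nrow(m) < 2L) stopf("Bland-Altman needs n >= 2 pairs")
  if (ncol(m) != 2L) stopf("`pairs` must have exactly 2 columns")
  diffs <- m[, 1] - m[, 2]
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(bias = bias, sd = s, loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s,
                 means = rowMeans(m), diffs = diffs),
            class = "ba_result")
}

# extract the radiomic panel for a list of image/mask pairs -> matrix
extract_panel <- function(images, masks, config = feature_extraction_config()) {
  out <- t(vapply(seq_along(images), function(i) {
    unlist(extract_all(images[[i]], masks[[i]], config))
  }, numeric(length(radiomic_feature_names()))))
  colnames(out) <- radiomic_feature_names()
  out
}

#' Feature reliability study on a synthetic cohort
#'
#' Produces paired measurements per subject for the requested comparison, runs
#' the full extraction pipeline on both members of each pair, and reports
#' per-feature ICC(2,1) and Bland-Altman summaries; features with
#' `ICC >= threshold` are flagged robust.
#'
#' Comparisons:
#' \describe{
#'   \item{repeat_scan}{a second acquisition per subject via
#'     [make_repeat_pair()] (additive noise + small translation), measured on
#'     the translated ground-truth masks.}
#'   \item{algorithm}{region- vs edge-based active-contour refinement of the
#'     same threshold initialization.}
#'   \item{operator}{two synthetic "operators": refinements started from a
#'     dilated vs an eroded copy of the ground-truth mask.}
#' }
#'
#' @param cohort A `ct_cohort` (images, masks, params).
#' @param comparison One of `"repeat_scan"`, `"operator"`, `"algorithm"`.
#' @param threshold Robustness ICC threshold (default 0.8).
#' @param noise_sd,shift_px Repeat-scan acquisition parameters.
#' @param feature_config Passed to the extractor.
#' @param contour_region,contour_edge Active-contour parameter sets.
#' @param seed Integer seed for repeat-scan noise.
#' @return Data frame: per feature, `icc`, `bias`, `loa_lower`, `loa_upper`,
#'   `robust`.
#' @export
reliability_study <- function(cohort,
                              comparison = c("repeat_scan", "operator",
                                             "algorithm"),
                              threshold = 0.8, noise_sd = 5, shift_px = 2L,
                              feature_config = feature_extraction_config(),
                              contour_region = contour_params("region"),
                              contour_edge = contour_params("edge"),
                              seed = 1L) {
  comparison <- match.arg(comparison)
  images <- cohort$images; masks <- cohort$masks
  n <- length(images)
  if (n < 3L) stopf("reliability study needs at least 3 subjects")

  if (comparison == "repeat_scan") {
    repeats <- lapply(seq_len(n), function(i) {
      make_repeat_pair(images[[i]], masks[[i]], noise_sd = noise_sd,
                       shift_px = shift_px, seed = seed + i)
    })
    m1 <- extract_panel(images, masks, feature_config)
    m2 <- extract_panel(lapply(repeats, `[[`, "image"),
                        lapply(repeats, `[[`, "mask"), feature_config)
  } else if (comparison == "algorithm") {
    init <- lapply(seq_len(n), function(i) default_threshold_init(images[[i]]))
    seg1 <- lapply(seq_len(n), function(i) {
      refine_active_contour(images[[i]], init[[i]], contour_region)
    })
    seg2 <- lapply(seq_len(n), function(i) {
      refine_active_contour(images[[i]], init[[i]], contour_edge)
    })
    m1 <- extract_panel(images, seg1, feature_config)
    m2 <- extract_panel(images, seg2, feature_config)
  } else {
    op_init <- function(mask, grow) {
      px <- if (grow) dilate8(mask$pixels * 1) else erode8(mask$pixels * 1)
      px <- px > 0.5
      if (!any(px)) px <- mask$pixels
      lesion_mask(px, spacing = mask$spacing)
    }
    seg1 <- lapply(seq_len(n), function(i) {
      refine_active_contour(images[[i]], op_init(masks[[i]], TRUE),
                            contour_region)
    })
    seg2 <- lapply(seq_len(n), function(i) {
      refine_active_contour(images[[i]], op_init(masks[[i]], FALSE),
                            contour_region)
    })
    m1 <- extract_panel(images, seg1, feature_config)
    m2 <- extract_panel(images, seg2, feature_config)
  }

  rows <- lapply(radiomic_feature_names(), function(f) {
    pair <- cbind(m1[, f], m2[, f])
    ic <- tryCatch(icc(pair)$icc, error = function(e) NA_real_)
    # identical columns have zero total variance only if constant across
    # subjects; identical paired measurements are perfect agreement
    if (is.na(ic) && all(pair[, 1] == pair[, 2])) ic <- 1
    ba <- bland_altman(pair)
    data.frame(feature = f, icc = ic, bias = ba$bias,
               loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
               robust = !is.na(ic) && ic >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "comparison") <- comparison
  out
}

# deterministic threshold initialization: halfway between the robust
# background and lesion intensity levels
default_threshold_init <- function(image) {
  px <- image$pixels
  lo <- stats::median(px)                       # background-dominated median
  hi <- stats::quantile(px, 0.99)
  thr <- lo + 0.5 * (hi - lo)
  m <- threshold_mask(image, low = thr)
  if (mask_area_px(m) == 0L) stopf("threshold initialization produced an empty mask")
  m
}
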