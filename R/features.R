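#' Feature extraction configuration
#'
#' @param G Number of gray levels for fixed-bin-count discretization.
#'   Default 32; the printed magnitudes of histogram features in this panel
#'   (variance of a few units, energy of a few percent) correspond to a few
#'   tens of levels.
#' @param distance Co-occurrence offset in pixels (default 1).
#' @param wavelet Wavelet family for the approximation subband; one-level
#'   `"haar"` is the supported default.
#' @return A `feature_extraction_config` list.
#' @export
feature_extraction_config <- function(G = 32L, distance = 1L,
                                      wavelet = "haar") {
  if (G < 2) stopf("G must be >= 2")
  if (distance < 1) stopf("distance must be >= 1")
  if (!identical(wavelet, "haar")) {
    stopf("unsupported wavelet '%s' (only 'haar' is implemented)", wavelet)
  }
  structure(list(G = as.integer(G), distance = as.integer(distance),
                 wavelet = wavelet), class = "feature_extraction_config")
}

#' Canonical names of the radiomic panel
#' @return Character vector: the eight selected features plus diameter.
#' @export
radiomic_feature_names <- function() {
  c("circularity", "variance", "kurtosis", "energy", "cluster_shade",
    "maximum_probability", "longhem", "a_lre", "diameter_mm")
}

#' Discretize a masked ROI to integer gray levels
#'
#' Fixed-bin-count mapping over the masked intensity range:
#' `level = min(G, floor(G * (x - min) / (max - min)) + 1)`. A constant ROI
#' maps every pixel to level 1. Pixel positions are retained (levels are `NA`
#' outside the mask) so texture matrices can respect the mask geometry.
#'
#' @param image A `gray_image`.
#' @param mask A nonempty `lesion_mask`.
#' @param G Number of gray levels (>= 2).
#' @return A `discretized_roi`: list with `levels` (integer matrix, `NA`
#'   outside the mask), `G`, and `spacing`.
#' @export
discretize <- function(image, mask, G = 32L) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "lesion_mask"))
  check_same_shape(image, mask, "image and mask")
  if (G < 2) stopf("G must be >= 2")
  if (mask_area_px(mask) == 0L) stopf("cannot discretize an empty mask")
  x <- image$pixels[mask$pixels]
  lo <- min(x); hi <- max(x)
  lev <- matrix(NA_integer_, nrow(image$pixels), ncol(image$pixels))
  if (hi == lo) {
    lev[mask$pixels] <- 1L
  } else {
    lev[mask$pixels] <- pmin(as.integer(G),
                             as.integer(floor(G * (x - lo) / (hi - lo))) + 1L)
  }
  structure(list(levels = lev, G = as.integer(G), spacing = image$spacing),
            class = "discretized_roi")
}

roi_levels <- function(droi) droi$levels[!is.na(droi$levels)]

#' First-order histogram features
#'
#' With `p(i)` the gray-level histogram and `mu = sum(i p(i))`:
#' variance `= sum((i - mu)^2 p(i))`; kurtosis `= m4 / m2^2` (Pearson
#' convention: a normal histogram gives 3); energy `= sum(p(i)^2)` (histogram
#' uniformity, in `(0, 1]`).
#'
#' @param droi A [discretize()]d ROI.
#' @return Named list: `variance`, `kurtosis`, `energy`.
#' @export
first_order <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  lv <- roi_levels(droi)
  if (length(lv) < 2L) stopf("variance needs at least 2 pixels")
  p <- tabulate(lv, nbins = droi$G) / length(lv)
  i <- seq_len(droi$G)
  mu <- sum(i * p)
  m2 <- sum((i - mu)^2 * p)
  if (m2 == 0) stopf("degenerate ROI: zero variance, kurtosis undefined")
  m4 <- sum((i - mu)^4 * p)
  list(variance = m2, kurtosis = m4 / m2^2, energy = sum(p^2))
}

# ---- boundary tracing -------------------------------------------------------
# Moore-neighbour tracing (Jacob's stopping criterion); returns the boundary
# pixel chain in traversal order (k x 2 matrix of (row, col))
trace_boundary <- function(bw) {
  D <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
              ncol = 2, byrow = TRUE)            # clockwise from East
  dir_index <- function(d) which(D[, 1] == d[1] & D[, 2] == d[2])
  nr <- nrow(bw); nc <- ncol(bw)
  fg <- which(bw, arr.ind = TRUE)
  start <- fg[order(fg[, 1], fg[, 2])[1], ]      # topmost, then leftmost
  inb <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc
  chain <- matrix(start, ncol = 2)
  cur <- start
  prev <- start + c(0, -1)                        # west neighbour: background
  first_prev <- prev
  first_move <- NULL
  max_steps <- 4L * nrow(fg) + 8L
  for (step in seq_len(max_steps)) {
    b <- dir_index(prev - cur)
    nxt <- NULL
    for (k in seq_len(8L)) {
      di <- ((b + k - 1L) %% 8L) + 1L
      cand <- cur + D[di, ]
      if (inb(cand) && bw[cand[1], cand[2]]) {
        nxt <- cand
        prev <- cur + D[((b + k - 2L) %% 8L) + 1L, ]
        break
      }
    }
    if (is.null(nxt)) return(chain)               # isolated pixel
    if (is.null(first_move)) first_move <- nxt
    if (all(nxt == start) && all(prev == first_prev) && step > 1L) break
    chain <- rbind(chain, nxt)
    cur <- nxt
  }
  # drop a duplicated closing vertex if tracing re-appended the start
  if (nrow(chain) > 1L && all(chain[nrow(chain), ] == chain[1L, ])) {
    chain <- chain[-nrow(chain), , drop = FALSE]
  }
  chain
}

# corner-corrected chain perimeter (Vossepoel-Smeulders weights). The traced
# polygon joins pixel centres, which sit half a pixel inside the true region
# boundary; by the Steiner formula an outward offset of a closed convex curve
# by t adds 2*pi*t, so pi * spacing is added to remove that bias.
chain_perimeter <- function(chain, spacing) {
  n <- nrow(chain)
  if (n == 1L) return(pi * spacing)               # a point offset by half a px
  nxt <- rbind(chain[-1L, , drop = FALSE], chain[1L, , drop = FALSE])
  d <- nxt - chain
  diag_step <- d[, 1] != 0 & d[, 2] != 0
  n_odd <- sum(diag_step); n_even <- n - n_odd
  code <- d[, 1] * 3 + d[, 2]                     # unique per direction
  n_corner <- sum(code != c(code[-1L], code[1L]))
  (0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner + pi) * spacing
}

#' Shape circularity
#'
#' `4 * pi * A / P^2`, with the area from the pixel count and the perimeter
#' from Moore-neighbour boundary tracing with corner-corrected step weights
#' (0.980 per axial step, 1.406 per diagonal step, -0.091 per corner), which
#' removes most of the rasterisation bias of naive chain-length perimeters.
#' A perfect disk gives ~1.
#'
#' @param mask A single-component `lesion_mask` with isotropic spacing.
#' @return Circularity (dimensionless).
#' @export
shape_circularity <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (mask_area_px(mask) == 0L) stopf("mask is empty")
  if (abs(mask$spacing[1] - mask$spacing[2]) > 1e-9) {
    stopf("circularity requires isotropic pixel spacing")
  }
  lab <- label_components(mask$pixels, 8)
  if (max(lab) > 1L) stopf("circularity requires a single connected component")
  sp <- mask$spacing[1]
  area <- mask_area_px(mask) * sp^2
  per <- chain_perimeter(trace_boundary(mask$pixels), sp)
  4 * pi * area / per^2
}

#' Lesion diameter in millimetres
#'
#' Major and minor axis lengths of the ellipse with the same normalized second
#' central moments as the mask (pixels treated as unit squares, i.e. with the
#' `spacing^2/12` moment of a square pixel added); the diameter is the average
#' of the two axes rounded to the nearest integer, half away from zero.
#'
#' @param mask A nonempty `lesion_mask`.
#' @return Integer diameter in mm (>= 1).
#' @export
lesion_diameter <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (mask_area_px(mask) == 0L) stopf("mask is empty")
  co <- which(mask$pixels, arr.ind = TRUE)
  y <- co[, 1] * mask$spacing[1]
  x <- co[, 2] * mask$spacing[2]
  n <- length(x)
  cxx <- sum((x - mean(x))^2) / n + mask$spacing[2]^2 / 12
  cyy <- sum((y - mean(y))^2) / n + mask$spacing[1]^2 / 12
  cxy <- sum((x - mean(x)) * (y - mean(y))) / n
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  axes <- 4 * sqrt(pmax(ev, 0))
  max(1L, round_half_up(mean(axes)))
}

glcm_offsets <- function(directions) {
  map <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
              `135` = c(-1L, -1L))
  unknown <- setdiff(as.character(directions), names(map))
  if (length(unknown)) stopf("unknown direction(s): %s",
                             paste(unknown, collapse = ", "))
  map[as.character(directions)]
}

#' Gray-level co-occurrence matrix
#'
#' Counts symmetric pairs of gray levels at the given pixel offset(s) among
#' pairs with both pixels inside the mask, sums the counts over directions,
#' and normalizes to a probability matrix.
#'
#' @param droi A [discretize()]d ROI.
#' @param distance Offset length in pixels.
#' @param directions Subset of `c(0, 45, 90, 135)` degrees.
#' @return A `glcm` object: list with `P` (G x G symmetric, sums to 1),
#'   `distance`, `directions`.
#' @export
glcm <- function(droi, distance = 1L, directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(droi, "discretized_roi"))
  G <- droi$G
  lv <- droi$levels
  counts <- matrix(0, G, G)
  for (off in glcm_offsets(directions)) {
    nb <- shift_matrix(lv, -off[1] * distance, -off[2] * distance,
                       fill = NA_integer_)
    ok <- !is.na(lv) & !is.na(nb)
    if (!any(ok)) next
    tab <- tabulate(lv[ok] + G * (nb[ok] - 1L), nbins = G * G)
    cmat <- matrix(tab, G, G)
    counts <- counts + cmat + t(cmat)
  }
  tot <- sum(counts)
  if (tot == 0) stopf("no valid in-mask pixel pair at distance %d", distance)
  structure(list(P = counts / tot, distance = as.integer(distance),
                 directions = directions), class = "glcm")
}

#' Co-occurrence features: cluster shade and maximum probability
#'
#' `maximum_probability = max p(i, j)`;
#' `cluster_shade = sum((i + j - mu_i - mu_j)^3 p(i, j))` with `mu_i`, `mu_j`
#' the marginal means (equal for a symmetric matrix). Cluster shade measures
#' the asymmetry of the co-occurrence distribution; maximum probability the
#' predominance of the most common pixel pair.
#'
#' @param m A [glcm()] object.
#' @return Named list: `cluster_shade`, `maximum_probability`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  P <- m$P
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  mu_i <- sum(i * P)
  mu_j <- sum(j * P)
  list(cluster_shade = sum((i + j - mu_i - mu_j)^3 * P),
       maximum_probability = max(P))
}

# matrix lines along a lattice direction, each a vector with NA breaks
direction_lines <- function(lv, dir) {
  nr <- nrow(lv); nc <- ncol(lv)
  switch(as.character(dir),
    `0` = lapply(seq_len(nr), function(r) lv[r, ]),
    `90` = lapply(seq_len(nc), function(c) lv[, c]),
    `45` = {
      ri <- row(lv); ci <- col(lv)
      unname(split(lv[order(ri + ci, ci)], sort(ri + ci)))
    },
    `135` = {
      ri <- row(lv); ci <- col(lv)
      unname(split(lv[order(ci - ri, ci)], sort(ci - ri)))
    },
    stopf("unknown direction '%s'", dir))
}

#' Gray-level run-length matrices
#'
#' Counts maximal runs of equal gray level along each direction, broken at the
#' mask boundary: `R(i, j)` is the number of runs of level `i` and length `j`.
#' One matrix is produced per direction.
#'
#' @param droi A [discretize()]d ROI.
#' @param directions Subset of `c(0, 45, 90, 135)` degrees.
#' @return A `glrlm` object: list of per-direction entries, each with `R`
#'   (G x Lmax run-count matrix) and `N_r` (total run count).
#' @export
glrlm <- function(droi, directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(droi, "discretized_roi"))
  G <- droi$G
  lv <- droi$levels
  lmax <- max(dim(lv))
  per_dir <- lapply(directions, function(d) {
    R <- matrix(0, G, lmax)
    for (line in direction_lines(lv, d)) {
      v <- line
      v[is.na(v)] <- 0L
      r <- rle(as.integer(v))
      keep <- r$values > 0L
      if (any(keep)) {
        idx <- r$values[keep] + G * (pmin(r$lengths[keep], lmax) - 1L)
        tab <- tabulate(idx, nbins = G * lmax)
        R <- R + matrix(tab, G, lmax)
      }
    }
    list(R = R, N_r = sum(R))
  })
  names(per_dir) <- as.character(directions)
  structure(list(matrices = per_dir, directions = directions,
                 G = G), class = "glrlm")
}

#' Run-length features: long-run emphasis and LongHEM
#'
#' Per direction, with `R(i, j)` the run counts and `N_r` the total runs:
#' `LRE = sum(R(i, j) * j^2) / N_r` and
#' `LRHGE = sum(R(i, j) * j^2 * i^2) / N_r` (long-run high gray-level
#' emphasis, high for bright coarse textures). The "mean" variants returned
#' here average over the supplied directions.
#'
#' @param mats A [glrlm()] object.
#' @return Named list: `lre_mean`, `longhem`.
#' @export
glrlm_features <- function(mats) {
  stopifnot(inherits(mats, "glrlm"))
  if (length(mats$matrices) == 0L) stopf("at least one direction required")
  per <- vapply(mats$matrices, function(m) {
    if (m$N_r == 0) return(c(NA_real_, NA_real_))
    G <- nrow(m$R); L <- ncol(m$R)
    j2 <- matrix((seq_len(L))^2, G, L, byrow = TRUE)
    i2 <- matrix((seq_len(G))^2, G, L)
    c(sum(m$R * j2) / m$N_r, sum(m$R * j2 * i2) / m$N_r)
  }, numeric(2))
  list(lre_mean = mean(per[1, ]), longhem = mean(per[2, ]))
}

# one-level 2-D Haar approximation (low-low) subband; orthonormal scaling
haar_ll <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% 2L == 1L) m <- rbind(m, m[nr, ])
  if (nc %% 2L == 1L) m <- cbind(m, m[, nc])
  oi <- seq(1L, nrow(m), by = 2L); oj <- seq(1L, ncol(m), by = 2L)
  (m[oi, oj, drop = FALSE] + m[oi + 1L, oj, drop = FALSE] +
     m[oi, oj + 1L, drop = FALSE] + m[oi + 1L, oj + 1L, drop = FALSE]) / 2
}

#' Long-run emphasis on the wavelet approximation signal
#'
#' Takes a one-level 2-D discrete wavelet transform (Haar) of the ROI
#' bounding-box image, keeps the approximation (low-low) subband, downsamples
#' the mask to match (a subband pixel is in-mask when all four source pixels
#' are), discretizes to `G` levels, and returns the run-length long-run
#' emphasis averaged over the four principal directions. This reads the run
#' structure of the texture at half resolution.
#'
#' @param image A `gray_image`.
#' @param mask A `lesion_mask` whose bounding box is at least 2 x 2.
#' @param G Gray levels for the subband discretization.
#' @return Approximation-signal long-run emphasis (scalar).
#' @export
wavelet_approx_lre <- function(image, mask, G = 32L) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "lesion_mask"))
  check_same_shape(image, mask, "image and mask")
  if (mask_area_px(mask) == 0L) stopf("mask is empty")
  co <- which(mask$pixels, arr.ind = TRUE)
  rr <- range(co[, 1]); cr <- range(co[, 2])
  if (diff(rr) < 1L || diff(cr) < 1L) {
    stopf("ROI bounding box must be at least 2 x 2")
  }
  sub_img <- image$pixels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  sub_msk <- mask$pixels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  ll <- haar_ll(sub_img)
  mk <- haar_ll(sub_msk * 1.0) >= 2 - 1e-9     # all four source pixels in-mask
  if (!any(mk)) stopf("degenerate approximation subband: empty mask")
  droi <- discretize(gray_image(ll, spacing = 2 * image$spacing),
                     lesion_mask(mk, spacing = 2 * mask$spacing), G = G)
  glrlm_features(glrlm(droi))$lre_mean
}

#' Extract the full radiomic panel from one lesion
#'
#' Computes the eight selected features (circularity; variance, kurtosis,
#' energy; cluster shade, maximum probability; LongHEM; approximation-signal
#' long-run emphasis) plus the integer diameter. Deterministic; component
#' errors are re-signalled with the failing feature named.
#'
#' @param image A `gray_image`.
#' @param mask The aligned `lesion_mask`.
#' @param config A [feature_extraction_config()].
#' @return A `feature_vector`: named list of the nine values.
#' @export
extract_all <- function(image, mask, config = feature_extraction_config()) {
  stopifnot(inherits(config, "feature_extraction_config"))
  grab <- function(feature, expr) {
    tryCatch(expr, error = function(e) {
      stopf("feature '%s': %s", feature, conditionMessage(e))
    })
  }
  droi <- grab("discretization", discretize(image, mask, config$G))
  fo <- grab("variance", first_order(droi))
  circ <- grab("circularity", shape_circularity(mask))
  diam <- grab("diameter_mm", lesion_diameter(mask))
  gl <- grab("maximum_probability",
             glcm_features(glcm(droi, distance = config$distance)))
  rl <- grab("longhem", glrlm_features(glrlm(droi)))
  al <- grab("a_lre", wavelet_approx_lre(image, mask, config$G))
  structure(list(circularity = circ, variance = fo$variance,
                 kurtosis = fo$kurtosis, energy = fo$energy,
                 cluster_shade = gl$cluster_shade,
                 maximum_probability = gl$maximum_probability,
                 longhem = rl$longhem, a_lre = al,
                 diameter_mm = diam), class = "feature_vector")
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
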