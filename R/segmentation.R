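#' Select the maximum-area slice
#'
#' Given an ordered stack of per-slice masks, returns the (1-based) index of
#' the mask with the largest pixel count; ties go to the smallest index.
#'
#' @param mask_stack List of `lesion_mask` objects.
#' @return Integer slice index.
#' @export
max_area_slice <- function(mask_stack) {
  if (length(mask_stack) == 0L) stopf("mask stack is empty")
  areas <- vapply(mask_stack, mask_area_px, numeric(1))
  if (all(areas == 0)) stopf("all masks in the stack are empty")
  which.max(areas)
}

#' Threshold segmentation
#'
#' Keeps pixels with intensity in `[low, high]`, retains only the largest
#' 8-connected component, and fills interior holes. An empty result is
#' returned as an empty mask (the caller decides how to proceed).
#'
#' @param image A `gray_image`.
#' @param low,high Intensity window bounds, `low <= high`.
#' @return A `lesion_mask` (possibly empty).
#' @export
threshold_mask <- function(image, low, high = Inf) {
  stopifnot(inherits(image, "gray_image"))
  if (low > high) stopf("threshold window requires low <= high")
  bw <- image$pixels >= low & image$pixels <= high
  if (!any(bw)) return(lesion_mask(bw, spacing = image$spacing))
  lesion_mask(fill_holes(largest_component(bw)), spacing = image$spacing)
}

#' Active-contour parameters
#'
#' @param method `"region"` (two-phase piecewise-constant / Chan-Vese-type
#'   energy) or `"edge"` (evolution under an image-gradient stopping function).
#' @param max_iter Maximum iterations (>= 1).
#' @param mu Smoothing weight: number of curvature-smoothing passes per
#'   iteration (non-negative integer). Default: 1 for the region method, 0 for
#'   the edge method (whose gradient-driven motion is already regular; extra
#'   smoothing erodes spiculations).
#' @param lambda1,lambda2 Region weights for inside/outside intensity
#'   mismatch (region method).
#' @param edge_sigma Gaussian pre-smoothing (px) for the gradient map (edge
#'   method).
#' @param edge_sensitivity Gradient scale of the stopping function
#'   `g = 1 / (1 + (|grad| / sensitivity)^2)`; `NULL` picks the 90th
#'   percentile of the gradient magnitude (deterministic in the image).
#' @param balloon_threshold Stopping-function level above which the shrinking
#'   balloon force acts (edge method).
#' @param band_px Refinement corridor half-width in pixels: the contour is
#'   confined between the initialization eroded and dilated `band_px` times.
#'   Keeps the refinement local to the supplied initialization (this operation
#'   refines a contour, it does not re-detect the lesion) and rules out
#'   leak-driven collapse across weak boundary segments. `NULL` disables it.
#' @param tol Convergence tolerance: fraction of pixels changed per iteration.
#' @return A `contour_params` list.
#' @export
contour_params <- function(method = c("region", "edge"), max_iter = 150L,
                           mu = NULL, lambda1 = 1, lambda2 = 1,
                           edge_sigma = 2, edge_sensitivity = NULL,
                           balloon_threshold = 0.5, band_px = 3L,
                           tol = 2e-4) {
  method <- match.arg(method)
  if (max_iter < 1) stopf("max_iter must be >= 1")
  if (is.null(mu)) mu <- if (method == "region") 1L else 0L
  if (mu < 0 || lambda1 < 0 || lambda2 < 0) stopf("weights must be >= 0")
  structure(list(method = method, max_iter = as.integer(max_iter),
                 mu = as.integer(mu), lambda1 = lambda1, lambda2 = lambda2,
                 edge_sigma = edge_sigma, edge_sensitivity = edge_sensitivity,
                 balloon_threshold = balloon_threshold,
                 band_px = if (!is.null(band_px)) as.integer(band_px),
                 tol = tol),
            class = "contour_params")
}

# ---- morphological curvature operators (sup-inf / inf-sup) -----------------
# line structuring elements of length 3 in 4 orientations
line_min <- function(u, dr, dc) {
  pmin(u, shift_edge(u, dr, dc), shift_edge(u, -dr, -dc))
}
line_max <- function(u, dr, dc) {
  pmax(u, shift_edge(u, dr, dc), shift_edge(u, -dr, -dc))
}
ORIENTS <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

inf_sup <- function(u) { # SI: inf over orientations of line suprema
  out <- NULL
  for (o in ORIENTS) {
    v <- line_max(u, o[1], o[2])
    out <- if (is.null(out)) v else pmin(out, v)
  }
  out
}
sup_inf <- function(u) { # IS: sup over orientations of line infima
  out <- NULL
  for (o in ORIENTS) {
    v <- line_min(u, o[1], o[2])
    out <- if (is.null(out)) v else pmax(out, v)
  }
  out
}

# one curvature-smoothing pass; alternation keeps the operator unbiased
smooth_pass <- function(u, alt) {
  if (alt) sup_inf(inf_sup(u)) else inf_sup(sup_inf(u))
}

dilate8 <- function(u) {
  out <- u
  for (o in list(c(0L,1L), c(1L,0L), c(1L,1L), c(1L,-1L))) {
    out <- pmax(out, shift_edge(u, o[1], o[2]), shift_edge(u, -o[1], -o[2]))
  }
  out
}
erode8 <- function(u) {
  out <- u
  for (o in list(c(0L,1L), c(1L,0L), c(1L,1L), c(1L,-1L))) {
    out <- pmin(out, shift_edge(u, o[1], o[2]), shift_edge(u, -o[1], -o[2]))
  }
  out
}

central_diff <- function(m) {
  list(dr = (shift_edge(m, -1L, 0L) - shift_edge(m, 1L, 0L)) / 2,
       dc = (shift_edge(m, 0L, -1L) - shift_edge(m, 0L, 1L)) / 2)
}

#' Refine a lesion mask with a morphological active contour
#'
#' Deterministic morphological implementations of the two classical active
#' contour families. The region method evolves the binary level set of a
#' two-phase piecewise-constant (Chan-Vese-type) energy: boundary pixels flip
#' toward the phase whose mean intensity they match better (weights `lambda1`,
#' `lambda2`), followed by `mu` curvature-smoothing passes. The edge method
#' evolves under the gradient stopping function
#' `g = 1/(1 + (|grad G_sigma * I| / a)^2)`: a shrinking balloon force erodes
#' the contour where `g` is high (flat image), an attraction term pins it to
#' gradient ridges, and the same curvature smoothing applies. Evolution stops
#' when the fraction of changed pixels drops below `tol` or at `max_iter`.
#' The result is post-processed to a single filled component.
#'
#' @param image A `gray_image`.
#' @param init Nonempty initial `lesion_mask`.
#' @param params A [contour_params()].
#' @return Refined `lesion_mask`.
#' @export
refine_active_contour <- function(image, init, params = contour_params()) {
  stopifnot(inherits(image, "gray_image"), inherits(init, "lesion_mask"),
            inherits(params, "contour_params"))
  check_same_shape(image, init, "image and init mask")
  if (mask_area_px(init) == 0L) stopf("initial mask is empty")
  img <- image$pixels
  u <- init$pixels * 1.0
  npx <- length(u)

  lower <- NULL; upper <- NULL
  if (!is.null(params$band_px)) {
    lower <- upper <- fill_holes(init$pixels) * 1.0
    for (b in seq_len(params$band_px)) {
      lower <- erode8(lower)
      upper <- dilate8(upper)
    }
  }

  if (params$method == "edge") {
    sm <- gaussian_blur(img, params$edge_sigma)
    g2 <- central_diff(sm)
    gmag <- sqrt(g2$dr^2 + g2$dc^2)
    # default gradient scale: 3x the typical background gradient, so the
    # shrinking balloon acts only on background-flat pixels and stops at any
    # real edge or interior texture (deterministic in image + init)
    a <- params$edge_sensitivity
    if (is.null(a)) {
      bg <- fill_holes(init$pixels)
      for (b in 1:5) bg <- dilate8(bg * 1) > 0.5
      bg <- !bg
      a <- if (any(bg)) 3 * stats::median(gmag[bg]) else
        stats::quantile(gmag, 0.5)
      a <- max(a, .Machine$double.eps)
    }
    g <- 1 / (1 + (gmag / a)^2)
    dg <- central_diff(g)
    balloon_on <- g > params$balloon_threshold
  }

  for (it in seq_len(params$max_iter)) {
    u_prev <- u
    if (params$method == "region") {
      n_in <- sum(u); n_out <- npx - n_in
      if (n_in == 0 || n_out == 0) {
        if (n_in == 0) stopf("contour collapsed")
        break
      }
      c1 <- sum(img * u) / n_in
      c0 <- sum(img * (1 - u)) / n_out
      boundary <- (dilate8(u) - erode8(u)) > 0
      force <- params$lambda1 * (img - c1)^2 - params$lambda2 * (img - c0)^2
      u[boundary & force < 0] <- 1
      u[boundary & force > 0] <- 0
    } else {
      # shrinking balloon: erode where the stopping function is high
      ue <- erode8(u)
      u[balloon_on] <- ue[balloon_on]
      # edge attraction: move the contour along the gradient of g
      du <- central_diff(u)
      adv <- du$dr * dg$dr + du$dc * dg$dc
      u[adv > 0] <- 1
      u[adv < 0] <- 0
    }
    if (params$mu > 0) {
      for (s in seq_len(params$mu)) u <- smooth_pass(u, alt = it %% 2L == 0L)
    }
    if (!is.null(lower)) u <- pmin(pmax(u, lower), upper)
    if (sum(u) == 0) stopf("contour collapsed")
    if (mean(u != u_prev) < params$tol) break
  }
  out <- fill_holes(largest_component(u > 0.5))
  if (!any(out)) stopf("contour collapsed")
  lesion_mask(out, spacing = image$spacing)
}
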