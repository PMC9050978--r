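#' Grayscale image container
#'
#' A 2-D intensity raster (HU-like; values may be negative) with physical pixel
#' spacing in millimetres. Coordinates are (row, col), 1-based, row-major, as
#' usual in R matrices.
#'
#' @param pixels Numeric matrix of intensities.
#' @param spacing Pixel spacing in mm, length 1 (isotropic) or 2 `(row, col)`.
#' @return An object of class `gray_image`: list with `pixels` and `spacing`.
#' @export
gray_image <- function(pixels, spacing = c(1, 1)) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("`pixels` must be a numeric matrix")
  }
  if (any(!is.finite(pixels))) stopf("image intensities must be finite")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be one or two positive numbers (mm)")
  }
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "gray_image")
}

#' Binary lesion mask
#'
#' A binary raster aligned with its image (same shape, same spacing).
#'
#' @param pixels Logical (or 0/1 numeric) matrix.
#' @param spacing Pixel spacing in mm, length 1 or 2.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels, spacing = c(1, 1)) {
  if (!is.matrix(pixels)) stopf("`pixels` must be a matrix")
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 1))) stopf("numeric mask values must be 0/1")
    pixels <- pixels > 0
  }
  if (!is.logical(pixels)) stopf("mask must be logical or 0/1 numeric")
  if (anyNA(pixels)) stopf("mask must not contain NA")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(spacing <= 0)) {
    stopf("`spacing` must be one or two positive numbers (mm)")
  }
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "lesion_mask")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, spacing %.3g x %.3g mm, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d px, spacing %.3g x %.3g mm, area %d px\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              sum(x$pixels)))
  invisible(x)
}

mask_area_px <- function(mask) sum(mask$pixels)

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    stopf("%s must have the same shape (%s vs %s)", what,
          paste(dim(a$pixels), collapse = "x"),
          paste(dim(b$pixels), collapse = "x"))
  }
  invisible(TRUE)
}

#' Label connected components of a binary matrix
#'
#' 8-connectivity for the foreground by default (4-connectivity is used
#' internally for background hole detection). Labelling is delegated to a
#' pixel-adjacency graph.
#'
#' @param bw Logical matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(bw, connectivity = 8) {
  stopifnot(is.logical(bw), connectivity %in% c(4, 8))
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  fg <- which(bw)
  if (length(fg) == 0L) return(lab)
  idx <- matrix(NA_integer_, nr, nc)
  idx[fg] <- seq_along(fg)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    nb <- shift_matrix(idx, o[1], o[2], fill = NA_integer_)
    both <- !is.na(idx) & !is.na(nb)
    if (any(both)) edges <- c(edges, rbind(idx[both], nb[both]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  lab[fg] <- igraph::components(g)$membership
  lab
}

# keep only the largest connected component (8-connectivity); ties broken by
# smallest label (first in raster order)
largest_component <- function(bw) {
  lab <- label_components(bw, 8)
  if (all(lab == 0L)) return(bw & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill holes: background regions (4-connectivity) not touching the frame border
fill_holes <- function(bw) {
  lab <- label_components(!bw, 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  bw | !(lab %in% c(0L, border))
}

# separable Gaussian blur with renormalised (edge-corrected) kernels
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kmat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > ceiling(4 * sigma)] <- 0
    k / rowSums(k)
  }
  kmat(nrow(m)) %*% m %*% t(kmat(ncol(m)))
}

#' Dice overlap between two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks give 1 by convention.
#'
#' @param a,b `lesion_mask` objects of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "lesion_mask"), inherits(b, "lesion_mask"))
  check_same_shape(a, b, "masks")
  na <- sum(a$pixels); nb <- sum(b$pixels)
  if (na + nb == 0L) return(1)
  2 * sum(a$pixels & b$pixels) / (na + nb)
}

#' Write / read a 16-bit grayscale TIFF
#'
#' Intensities must be integers in \[0, 65535\]; the round trip is exact.
#'
#' @param image A `gray_image` with integer-valued pixels in \[0, 65535\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  px <- image$pixels
  if (any(px < 0 | px > 65535) || any(px != round(px))) {
    stopf("16-bit TIFF output requires integer intensities in [0, 65535]")
  }
  ok <- try(tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error")) stopf("failed to write TIFF '%s'", path)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param spacing Pixel spacing (mm) to attach on read.
#' @export
read_image_tiff <- function(path, spacing = c(1, 1)) {
  if (!file.exists(path)) stopf("image file not found: '%s'", path)
  px <- tiff::readTIFF(path)
  gray_image(round(px * 65535), spacing = spacing)
}

#' Write / read an 8-bit PNG mask (0/255)
#'
#' @param mask A `lesion_mask`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  ok <- try(png::writePNG(mask$pixels * 1.0, path), silent = TRUE)
  if (inherits(ok, "try-error")) stopf("failed to write PNG '%s'", path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param spacing Pixel spacing (mm) to attach on read.
#' @export
read_mask_png <- function(path, spacing = c(1, 1)) {
  if (!file.exists(path)) stopf("mask file not found: '%s'", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  lesion_mask(px > 0.5, spacing = spacing)
}
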