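#' Configuration for a single lesion phantom
#'
#' Describes a 2-D CT-like lesion phantom: a cosine-perturbed disk of
#' controllable circularity/spiculation filled with a stationary correlated
#' intensity texture on a noisy background.
#'
#' The lesion boundary is the analytic curve
#' `r(theta) = lesion_radius * (1 + spiculation_amp * cos(spiculation_freq * theta))`,
#' so ground-truth shape is known exactly. The texture field is white noise
#' smoothed with a Gaussian kernel of standard deviation `texture_corr_len`
#' pixels and renormalised to `lesion_sd`, which makes the spatial correlation
#' length a single tunable dial driving run-length texture features.
#'
#' @param image_size Pixels per side of the square frame.
#' @param pixel_spacing Pixel spacing in mm (isotropic).
#' @param lesion_radius Mean lesion radius in mm.
#' @param spiculation_amp Radial perturbation amplitude (dimensionless, >= 0).
#' @param spiculation_freq Number of lobes per revolution (integer >= 0).
#' @param lesion_mean Lesion intensity added above background (intensity units).
#' @param lesion_sd Standard deviation of the lesion texture field.
#' @param texture_corr_len Spatial correlation length of the texture, px (>= 0).
#' @param texture_gamma Histogram shape of the texture: the standardized
#'   correlated field is passed through the signed power transform
#'   `sign(x) |x|^gamma` before rescaling. 1 keeps the Gaussian shape; > 1
#'   gives heavier tails (peaked, high-kurtosis texture), < 1 lighter tails.
#'   Varying it across subjects emulates the between-lesion differences in
#'   brightness distribution that histogram features respond to.
#' @param background_mean,background_sd Background intensity mean / sd.
#' @param psf_sigma Scanner point-spread function: Gaussian blur (px, sd)
#'   applied to the composed image. Gives lesions the soft, partial-volume
#'   edges of real CT instead of a step edge; 0 disables.
#' @param n_inclusions Number of small high/low-intensity inclusions placed in
#'   the lesion interior (vessels, calcifications, air bronchograms, necrotic
#'   foci). They anchor the ROI intensity range from inside the lesion, the
#'   way internal structure does in real tumours, so histogram features do not
#'   hinge on which boundary pixels a segmentation includes.
#' @param inclusion_amp Intensity amplitude of the inclusions (added for
#'   bright, subtracted for dark); default equals `lesion_mean`.
#' @param seed Integer seed; the phantom is bit-reproducible given the config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 64,
                           pixel_spacing = 1,
                           lesion_radius = 12,
                           spiculation_amp = 0,
                           spiculation_freq = 8,
                           lesion_mean = 400,
                           lesion_sd = 50,
                           texture_corr_len = 3,
                           texture_gamma = 1,
                           background_mean = 100,
                           background_sd = 10,
                           psf_sigma = 0.8,
                           n_inclusions = 3L,
                           inclusion_amp = NULL,
                           seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              pixel_spacing = pixel_spacing,
              lesion_radius = lesion_radius,
              spiculation_amp = spiculation_amp,
              spiculation_freq = as.integer(spiculation_freq),
              lesion_mean = lesion_mean, lesion_sd = lesion_sd,
              texture_corr_len = texture_corr_len,
              texture_gamma = texture_gamma,
              background_mean = background_mean, background_sd = background_sd,
              psf_sigma = psf_sigma, n_inclusions = as.integer(n_inclusions),
              inclusion_amp = inclusion_amp %||% lesion_mean,
              seed = as.integer(seed))
  if (cfg$image_size <= 0) stopf("image_size must be positive")
  if (cfg$lesion_radius <= 0) stopf("lesion_radius must be positive")
  if (cfg$spiculation_amp < 0) stopf("spiculation_amp must be >= 0")
  if (cfg$spiculation_freq < 0) stopf("spiculation_freq must be >= 0")
  if (cfg$lesion_sd < 0 || cfg$background_sd < 0) stopf("sd must be >= 0")
  if (cfg$texture_corr_len < 0) stopf("texture_corr_len must be >= 0")
  if (cfg$texture_gamma <= 0) stopf("texture_gamma must be positive")
  max_r_px <- cfg$lesion_radius * (1 + cfg$spiculation_amp) / cfg$pixel_spacing
  if (max_r_px > cfg$image_size / 2 - 2) {
    stopf("lesion (max radius %.1f px) does not fit inside a %d px frame",
          max_r_px, cfg$image_size)
  }
  structure(cfg, class = "phantom_config")
}

#' Generate a lesion phantom image and its ground-truth mask
#'
#' The mask is the exact rasterisation of the analytic boundary (a pixel is
#' foreground when its centre lies inside `r(theta)`); the image is a
#' background field plus, on the lesion support, a correlated texture field
#' with the configured mean, sd and correlation length. Intensities are
#' rounded to integers (CT stores integer values) and clipped at 0.
#'
#' @param config A [phantom_config()].
#' @return List with `image` (`gray_image`) and `mask` (`lesion_mask`).
#' @export
make_lesion_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  sp <- config$pixel_spacing
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)          # row index
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- (rr - ctr) * sp
  dx <- (cc - ctr) * sp
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rmax <- config$lesion_radius *
    (1 + config$spiculation_amp * cos(config$spiculation_freq * theta))
  inside <- r <= rmax

  img <- with_seed(config$seed, {
    bg <- config$background_mean +
      matrix(stats::rnorm(n * n, sd = config$background_sd), n, n)
    tex <- matrix(stats::rnorm(n * n), n, n)
    if (config$texture_corr_len > 0) {
      tex <- gaussian_blur(tex, config$texture_corr_len)
    }
    s <- stats::sd(as.vector(tex))
    if (s > 0 && config$lesion_sd > 0) {
      tex <- tex / s
      if (config$texture_gamma != 1) {
        tex <- sign(tex) * abs(tex)^config$texture_gamma
        tex <- (tex - mean(tex)) / stats::sd(as.vector(tex))
      }
      tex <- tex * config$lesion_sd
    } else {
      tex <- tex * 0
    }
    out <- bg
    out[inside] <- out[inside] + config$lesion_mean + tex[inside]
    if (config$n_inclusions > 0L) {
      # deep interior: keep inclusions clear of the boundary so every
      # reasonable segmentation contains them
      interior <- inside
      for (b in 1:4) interior <- erode8(interior * 1) > 0.5
      cand <- which(interior)
      if (length(cand) > 0L) {
        ctrs <- cand[sample.int(length(cand),
                                min(config$n_inclusions, length(cand)))]
        for (cidx in ctrs) {
          ri <- ((cidx - 1L) %% n) + 1L
          ci <- ((cidx - 1L) %/% n) + 1L
          rad <- stats::runif(1, 1, 2)
          bright <- stats::runif(1) < 0.6
          blob <- (rr - ri)^2 + (cc - ci)^2 <= rad^2
          blob <- blob & inside
          out[blob] <- out[blob] +
            (if (bright) 1 else -1) * config$inclusion_amp
        }
      }
    }
    if (config$psf_sigma > 0) out <- gaussian_blur(out, config$psf_sigma)
    out
  })
  img <- pmax(round(img), 0)
  list(image = gray_image(img, spacing = sp),
       mask = lesion_mask(inside, spacing = sp))
}

#' Simulate a repeat scan of the same lesion
#'
#' Emulates a short-interval test-retest acquisition: the image is translated
#' by an integer pixel offset (patient repositioning) and independent Gaussian
#' noise is added; the mask is translated identically, so its area is
#' unchanged. Vacated border pixels take the median background (off-mask)
#' intensity.
#'
#' @param image A `gray_image`.
#' @param mask The aligned `lesion_mask`.
#' @param noise_sd Standard deviation of the added noise (intensity units).
#' @param shift_px Integer translation, length 1 (both axes) or 2 `(row, col)`.
#' @param noise_corr_len Spatial correlation (px, Gaussian sd) of the added
#'   noise. Acquisition noise in reconstructed CT passes through the same
#'   reconstruction kernel as the signal, so it is not white at pixel scale;
#'   the default matches the phantom's point-spread function. 0 gives white
#'   noise.
#' @param seed Integer seed for the noise.
#' @return List with translated, noise-perturbed `image` and translated `mask`.
#' @export
make_repeat_pair <- function(image, mask, noise_sd = 0, shift_px = 0L,
                             noise_corr_len = 0.8, seed = 1L) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "lesion_mask"))
  check_same_shape(image, mask, "image and mask")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(shift_px) == 1L) shift_px <- rep(shift_px, 2L)
  shift_px <- as.integer(shift_px)
  m2 <- shift_matrix(mask$pixels, shift_px[1], shift_px[2], fill = FALSE)
  if (sum(m2) != sum(mask$pixels)) {
    stopf("shift (%d, %d) pushes the lesion out of frame",
          shift_px[1], shift_px[2])
  }
  fill <- stats::median(image$pixels[!mask$pixels])
  if (!is.finite(fill)) fill <- stats::median(image$pixels)
  i2 <- shift_matrix(image$pixels, shift_px[1], shift_px[2], fill = fill)
  if (noise_sd > 0) {
    i2 <- with_seed(seed, {
      nz <- matrix(stats::rnorm(length(i2)), nrow(i2), ncol(i2))
      if (noise_corr_len > 0) {
        nz <- gaussian_blur(nz, noise_corr_len)
        nz <- nz / stats::sd(as.vector(nz))
      }
      i2 + nz * noise_sd
    })
    i2 <- pmax(round(i2), 0)
  }
  list(image = gray_image(i2, spacing = image$spacing),
       mask = lesion_mask(m2, spacing = mask$spacing))
}
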