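test_that("discretization follows the fixed-bin-count rule", {
  mk <- lesion_mask(matrix(TRUE, 1, 32))
  img <- gray_image(matrix(0:31, 1, 32))
  d <- discretize(img, mk, G = 32)
  expect_identical(sort(as.vector(d$levels)), 1:32)  # bijective on 0..31

  img2 <- gray_image(matrix(c(0, 10, 0, 10), 2, 2))
  d2 <- discretize(img2, lesion_mask(matrix(TRUE, 2, 2)), G = 4)
  expect_setequal(unique(as.vector(d2$levels)), c(1L, 4L))

  const <- gray_image(matrix(7, 3, 3))
  d3 <- discretize(const, lesion_mask(matrix(TRUE, 3, 3)), G = 8)
  expect_true(all(d3$levels == 1L))

  expect_error(discretize(const, lesion_mask(matrix(FALSE, 3, 3))), "empty")
})

test_that("first-order features match hand-worked values and limits", {
  img <- gray_image(matrix(c(1, 1, 2, 4), 2, 2))
  d <- discretize(img, lesion_mask(matrix(TRUE, 2, 2)), G = 4)
  fo <- first_order(d)
  expect_equal(fo$variance, 1.5)
  expect_equal(fo$kurtosis, 2.0)
  expect_equal(fo$energy, 0.375)

  # uniform histogram over G levels: energy = 1/G
  G <- 16
  du <- discretize(gray_image(matrix(rep(0:(G - 1), 4), 4, G, byrow = TRUE)),
                   lesion_mask(matrix(TRUE, 4, G)), G = G)
  expect_equal(first_order(du)$energy, 1 / G)

  # Pearson kurtosis of a large Gaussian sample approaches 3
  set.seed(1)
  n <- 316                                     # ~1e5 pixels
  dg <- discretize(gray_image(matrix(rnorm(n * n, 0, 100), n, n)),
                   lesion_mask(matrix(TRUE, n, n)), G = 256)
  expect_lt(abs(first_order(dg)$kurtosis - 3), 0.2)

  const <- discretize(gray_image(matrix(5, 2, 2)),
                      lesion_mask(matrix(TRUE, 2, 2)), G = 8)
  expect_error(first_order(const), "degenerate")
})

test_that("circularity reaches its analytic limits on disks and squares", {
  expect_gt(shape_circularity(disk_mask(50)), 0.95)
  expect_lt(shape_circularity(disk_mask(50)), 1.05)
  sq <- matrix(FALSE, 50, 50); sq[6:45, 6:45] <- TRUE
  expect_lt(abs(shape_circularity(lesion_mask(sq)) - pi / 4), 0.05)

  p0 <- make_lesion_phantom(phantom_config(seed = 5))
  p1 <- make_lesion_phantom(phantom_config(spiculation_amp = 0.3,
                                           spiculation_freq = 8, seed = 5))
  expect_gte(shape_circularity(p0$mask), 0.95)
  expect_lt(shape_circularity(p1$mask), shape_circularity(p0$mask))

  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(shape_circularity(lesion_mask(two)), "single connected")
})

test_that("diameter is the rounded mean of the moment-ellipse axes", {
  n <- 31; ctr <- 16
  el <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
              function(y, x) (x / 5)^2 + (y / 3)^2 <= 1)
  expect_identical(lesion_diameter(lesion_mask(el)), 8L)     # (10 + 6) / 2
  expect_identical(lesion_diameter(disk_mask(10.5)), 21L)
  # half-up rounding rule at the .5 tie
  expect_identical(ctrad:::round_half_up(7.5), 8L)
  expect_identical(ctrad:::round_half_up(8.5), 9L)
  expect_error(lesion_diameter(lesion_mask(matrix(FALSE, 3, 3))), "empty")
})

test_that("GLCM matches hand enumeration and the brute-force oracle", {
  img <- gray_image(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE))
  d <- discretize(img, lesion_mask(matrix(TRUE, 2, 2)), G = 2)
  m <- glcm(d, directions = 0)
  expect_equal(m$P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  gf <- glcm_features(m)
  expect_equal(gf$maximum_probability, 0.5)
  expect_equal(gf$cluster_shade, 0)

  const <- discretize(gray_image(matrix(3, 4, 4)),
                      lesion_mask(matrix(TRUE, 4, 4)), G = 8)
  mc <- glcm(const)
  expect_equal(mc$P[1, 1], 1)
  expect_equal(glcm_features(mc)$maximum_probability, 1)
  expect_equal(glcm_features(mc)$cluster_shade, 0)

  one_px <- lesion_mask(rbind(c(TRUE, FALSE), c(FALSE, FALSE)))
  d1 <- discretize(gray_image(matrix(1:4, 2, 2)), one_px, G = 4)
  expect_error(glcm(d1), "pair")

  set.seed(42)
  for (rep in 1:25) {
    roi <- random_roi(6, 6)
    d <- discretize(roi$image, roi$mask, G = roi$G)
    got <- glcm(d)
    want <- glcm_oracle(d$levels, roi$G)
    expect_lt(max(abs(got$P - want)), 1e-14)
    gf <- glcm_features(got)
    or <- glcm_features_oracle(got$P)
    expect_lt(rel_err(gf$cluster_shade, or$cluster_shade) +
                abs(gf$maximum_probability - or$maximum_probability), 1e-12)
  }
})

test_that("GLRLM matches hand run counts and the scan-line oracle", {
  img <- gray_image(matrix(c(1, 1, 2, 2, 2, 2, 3, 3, 3), 3, 3, byrow = TRUE))
  d <- discretize(img, lesion_mask(matrix(TRUE, 3, 3)), G = 3)
  rl <- glrlm(d, directions = 0)
  m0 <- rl$matrices[["0"]]
  expect_equal(m0$N_r, 4)
  expect_equal(m0$R[1, 2], 1)  # run (level 1, length 2)
  expect_equal(m0$R[2, 1], 1)
  expect_equal(m0$R[2, 3], 1)
  expect_equal(m0$R[3, 3], 1)
  rf <- glrlm_features(rl)
  expect_equal(rf$lre_mean, 5.75)
  expect_equal(rf$longhem, 31.25)

  # single pixel: one run of length 1 in every direction, LRE = 1
  one <- lesion_mask(rbind(c(TRUE, FALSE), c(FALSE, FALSE)))
  d1 <- discretize(gray_image(matrix(c(9, 1, 1, 1), 2, 2)), one, G = 4)
  expect_equal(glrlm_features(glrlm(d1))$lre_mean, 1)

  set.seed(7)
  for (rep in 1:25) {
    roi <- random_roi(6, 6)
    d <- discretize(roi$image, roi$mask, G = roi$G)
    rl <- glrlm(d)
    for (dir in c(0, 45, 90, 135)) {
      want <- glrlm_oracle(d$levels, roi$G, dir)
      got <- rl$matrices[[as.character(dir)]]$R
      expect_equal(got[, seq_len(ncol(want))], want)
    }
  }
})

test_that("wavelet approximation LRE behaves across texture scales", {
  # constant ROI: flat subband, answer equals the oracle run through the
  # subband pipeline by hand
  img <- gray_image(matrix(5, 8, 8))
  mk <- lesion_mask(matrix(TRUE, 8, 8))
  a <- wavelet_approx_lre(img, mk, G = 8)
  # flat 4x4 subband: all levels 1; 0/90 degrees: 4 runs of length 4 each;
  # diagonals: runs of lengths 1..4; LRE mean computable by hand
  lre0 <- 16                                     # (4 * 16) / 4
  lre45 <- (2 * 1 + 2 * 4 + 2 * 9 + 1 * 16) / 7
  expect_equal(a, mean(c(lre0, lre0, lre45, lre45)))

  coarse <- make_lesion_phantom(phantom_config(texture_corr_len = 8,
                                               lesion_radius = 14, seed = 2,
                                               n_inclusions = 0))
  fine <- make_lesion_phantom(phantom_config(texture_corr_len = 1,
                                             lesion_radius = 14, seed = 2,
                                             n_inclusions = 0))
  expect_gt(wavelet_approx_lre(coarse$image, coarse$mask, 32),
            wavelet_approx_lre(fine$image, fine$mask, 32))

  thin <- lesion_mask(matrix(rep(c(TRUE, rep(FALSE, 7)), 8), 8, 8))
  expect_error(wavelet_approx_lre(img, thin, 8), "2 x 2")
})

test_that("extract_all is deterministic and reports failing features", {
  ph <- make_lesion_phantom(phantom_config(seed = 10))
  v1 <- extract_all(ph$image, ph$mask)
  v2 <- extract_all(ph$image, ph$mask)
  expect_identical(v1, v2)
  expect_gte(v1$circularity, 0.95)
  expect_true(all(is.finite(unlist(v1))))

  one <- lesion_mask(matrix(c(TRUE, rep(FALSE, 63)), 8, 8))
  expect_error(extract_all(ph$image$pixels[1:8, 1:8] |> gray_image(), one),
               "feature '")
})

test_that("direction-averaged texture features are invariant to 90-degree rotation", {
  set.seed(11)
  for (rep in 1:5) {
    roi <- random_roi(7, 9)
    rot_img <- gray_image(t(roi$image$pixels)[ncol(roi$image$pixels):1, ])
    rot_msk <- lesion_mask(t(roi$mask$pixels)[ncol(roi$mask$pixels):1, ])
    d <- discretize(roi$image, roi$mask, G = roi$G)
    dr <- discretize(rot_img, rot_msk, G = roi$G)
    expect_equal(glcm_features(glcm(d)), glcm_features(glcm(dr)))
    expect_equal(glrlm_features(glrlm(d)), glrlm_features(glrlm(dr)))
  }
})

test_that("discretized features are invariant to intensity shifts", {
  ph <- make_lesion_phantom(phantom_config(seed = 21))
  shifted <- gray_image(ph$image$pixels + 500, spacing = ph$image$spacing)
  expect_equal(extract_all(ph$image, ph$mask), extract_all(shifted, ph$mask))
})

test_that("features track their generating parameters across a phantom sweep", {
  amps <- seq(0, 0.3, length.out = 10)
  circ <- vapply(seq_along(amps), function(i) {
    ph <- make_lesion_phantom(phantom_config(spiculation_amp = amps[i],
                                             seed = 100 + i))
    shape_circularity(ph$mask)
  }, numeric(1))
  expect_lt(cor(amps, circ, method = "spearman"), -0.8)

  cls <- seq(1, 8, length.out = 20)
  lh <- vapply(seq_along(cls), function(i) {
    ph <- make_lesion_phantom(phantom_config(texture_corr_len = cls[i],
                                             lesion_radius = 14,
                                             n_inclusions = 0,
                                             seed = 200 + i))
    extract_all(ph$image, ph$mask)$longhem
  }, numeric(1))
  expect_gt(cor(cls, lh, method = "spearman"), 0.8)
})
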