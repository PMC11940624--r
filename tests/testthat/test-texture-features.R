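test_that("histogram features follow nearest-rank order statistics", {
  # raw-intensity mode: values 1..100 -> Perc.01. = 1st order statistic
  img <- gray_image(matrix(1:100, 10, 10), 0.1)
  mask <- roi_mask(matrix(TRUE, 10, 10), "tumor")
  q <- normalize_quantize(img, mask, norm_config("none", 64))
  f <- histogram_features(q)
  expect_equal(f[["Perc.01."]], 1)
  expect_equal(f[["Perc.10."]], 10)
  expect_equal(f[["Perc.50."]], 50)
  expect_equal(f[["Perc.99."]], 99)
  expect_equal(f[["Mean"]], mean(1:100))
  expect_equal(f[["Variance"]], mean((1:100 - 50.5)^2))

  # constant ROI: percentiles return the constant, variance 0,
  # skewness/kurtosis undefined
  img2 <- gray_image(matrix(42, 5, 5), 0.1)
  q2 <- normalize_quantize(img2, roi_mask(matrix(TRUE, 5, 5), "tumor"),
                           norm_config("none", 64))
  f2 <- histogram_features(q2)
  expect_equal(f2[["Perc.01."]], 42)
  expect_equal(f2[["Variance"]], 0)
  expect_true(is.na(f2[["Skewness"]]) && is.na(f2[["Kurtosis"]]))
})

test_that("histogram features are shift-invariant under mu3sigma", {
  set.seed(4)
  px <- matrix(sample(10:200, 81, replace = TRUE), 9, 9)
  mask <- roi_mask(matrix(TRUE, 9, 9), "tumor")
  f1 <- histogram_features(normalize_quantize(gray_image(px, 0.1), mask))
  f2 <- histogram_features(normalize_quantize(gray_image(px + 37, 0.1), mask))
  expect_equal(f1, f2)
})

test_that("GLCM matches hand-computable cases", {
  # constant 4x4 ROI: single entry 1 at the (0,0) level pair
  q <- make_qroi(matrix(0L, 4, 4), n_gray = 4)
  m <- glcm(q, 0, 1)
  expect_equal(sum(m), 1)
  expect_equal(m[1, 1], 1)

  # 2x2 checkerboard of levels {0,1}: [[0, .5], [.5, 0]]
  q2 <- make_qroi(matrix(c(0L, 1L, 1L, 0L), 2, 2), n_gray = 2)
  m2 <- glcm(q2, 0, 1)
  expect_equal(unclass(m2)[1:4], c(0, 0.5, 0.5, 0), ignore_attr = TRUE)

  # offset (0,0) rejected; empty-pair offset returns NULL
  expect_error(glcm(q, 0, 0), "offset")
  expect_null(glcm(q, 0, 10))
})

test_that("GLCM features match hand evaluation on degenerate cases", {
  q <- make_qroi(matrix(0L, 4, 4), n_gray = 4)
  f <- glcm_features(glcm(q, 0, 1))
  expect_equal(f[["AngScMom"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["SumEntrp"]], 0)
  expect_equal(f[["Entropy"]], 0)

  chk <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- glcm_features(chk)
  expect_equal(f2[["Contrast"]], 1)
  expect_equal(f2[["AngScMom"]], 0.5)
})

test_that("GLCM/GLRLM normalization and conservation invariants hold", {
  for (s in 1:25) {
    q <- random_qroi(s)
    for (off in list(c(0, 1), c(1, 0), c(2, 2), c(1, -1))) {
      m <- glcm(q, off[1], off[2])
      if (!is.null(m)) expect_equal(sum(m), 1, tolerance = 1e-12)
    }
    npix <- sum(!is.na(q$levels))
    for (ang in c(0, 45, 90, 135)) {
      runs <- gray_level_runs(q, ang)
      expect_equal(sum(runs$length), npix) # every pixel in exactly one run
    }
  }
})

test_that("GLRLM features match hand-computable run patterns", {
  # constant 1x8 line, horizontal: one run of length 8
  q <- make_qroi(matrix(0L, 1, 8), n_gray = 2)
  f <- glrlm_features(q, 0)
  expect_equal(f[["GLevNonU"]], 1)
  expect_equal(f[["RLNonUni"]], 1)
  expect_equal(f[["LngREmph"]], 64)
  expect_equal(f[["Fraction"]], 1 / 8)

  # alternating 1x8 line: 8 runs of length 1
  q2 <- make_qroi(matrix(rep(c(0L, 1L), 4), 1, 8), n_gray = 2)
  f2 <- glrlm_features(q2, 0)
  expect_equal(f2[["ShrtREmp"]], 1)
  expect_equal(f2[["LngREmph"]], 1)
  expect_equal(f2[["Fraction"]], 1)
})

test_that("runs break at mask boundaries", {
  L <- matrix(0L, 1, 7)
  L[1, 4] <- NA # mask hole splits the line
  q <- make_qroi(L, n_gray = 2)
  runs <- gray_level_runs(q, 0)
  expect_equal(nrow(runs), 2L)
  expect_equal(sort(runs$length), c(3L, 3L))
})

test_that("AR model recovers degenerate and null cases", {
  q <- make_qroi(matrix(3L, 10, 10), n_gray = 4)
  expect_warning(f <- ar_model(q), "rank-deficient")
  expect_equal(unname(f[1:4]), rep(0, 4))
  expect_equal(f[["Sigma"]], 0)

  # white noise: all coefficients near zero at n = 1e4
  set.seed(11)
  qn <- make_qroi(matrix(sample(0L:63L, 1e4, TRUE), 100, 100), n_gray = 64)
  fn <- ar_model(qn)
  expect_true(all(abs(fn[1:4]) < 0.1))
  expect_identical(attr(fn, "flag"), "ok")

  # too few usable pixels -> undefined marker
  qs <- make_qroi(matrix(c(1L, 2L, 3L, 0L), 2, 2), n_gray = 4)
  fs <- ar_model(qs)
  expect_true(all(is.na(fs)))
  expect_identical(attr(fs, "flag"), "insufficient")
})

test_that("wavelet energies: constant ROI, step edge, Parseval", {
  # constant ROI: zero detail at every scale
  q <- make_qroi(matrix(5L, 16, 16), n_gray = 8)
  w <- wavelet_energies(q, 4)
  for (k in 1:4) {
    expect_equal(w[[paste0("WavEnLH_s", k)]], 0)
    expect_equal(w[[paste0("WavEnHL_s", k)]], 0)
    expect_equal(w[[paste0("WavEnHH_s", k)]], 0)
  }

  # vertical step edge (left 0, right c, straddling a Haar block):
  # HL responds, LH silent
  L <- cbind(matrix(0L, 8, 3), matrix(6L, 8, 5))
  qs <- make_qroi(L, n_gray = 8)
  ws <- wavelet_energies(qs, 1)
  expect_gt(ws[["WavEnHL_s1"]], 0)
  expect_equal(ws[["WavEnLH_s1"]], 0)
  expect_equal(ws[["WavEnHH_s1"]], 0)

  # Parseval at scale 1 on a full even patch: band energies sum to the
  # patch energy (orthonormal Haar)
  set.seed(12)
  P <- matrix(sample(0L:7L, 64, TRUE), 8, 8)
  qp <- make_qroi(P, n_gray = 8)
  wp <- wavelet_energies(qp, 1)
  n_pos <- 16 # 4x4 coefficient positions
  total <- n_pos * (wp[["WavEnLL_s1"]] + wp[["WavEnLH_s1"]] +
                      wp[["WavEnHL_s1"]] + wp[["WavEnHH_s1"]])
  expect_equal(total, sum(P^2), tolerance = 1e-12)

  # ROI too small for deep scales -> NA markers
  qt <- make_qroi(matrix(1L, 3, 3), n_gray = 4)
  wt <- wavelet_energies(qt, 3)
  expect_true(all(is.na(wt[paste0("WavEn", c("LL", "LH", "HL", "HH"), "_s2")])))
})

test_that("extraction is deterministic and matches the registry manifest", {
  les <- simulate_lesion_image(lesion_params(), seed = 5)
  q <- normalize_quantize(les$image, les$tumor)
  f1 <- extract_roi_features(q)
  f2 <- extract_roi_features(q)
  expect_identical(f1, f2)
  reg <- feature_registry()
  expect_identical(names(f1), reg$name)
  expect_equal(attr(reg, "n_features"), 278L)
  expect_equal(as.numeric(table(reg$family)[c("histogram", "glcm", "glrlm",
                                              "ar", "wavelet")]),
               c(9, 220, 20, 5, 24))
})

test_that("rotating the image by 90 degrees permutes directional features", {
  set.seed(14)
  L <- matrix(sample(0L:7L, 144, TRUE), 12, 12)
  q <- make_qroi(L, n_gray = 8)
  # counter-clockwise rotation: rows <- reversed columns
  Lr <- t(L)[ncol(L):1, ]
  qr <- make_qroi(Lr, n_gray = 8)
  for (d in 1:2) {
    f_0d <- glcm_features(glcm(q, 0, d))
    f_d0_rot <- glcm_features(glcm(qr, d, 0))
    expect_equal(f_0d, f_d0_rot, tolerance = 1e-12)
    f_dd <- glcm_features(glcm(q, d, d))
    f_ddm_rot <- glcm_features(glcm(qr, d, -d))
    expect_equal(f_dd, f_ddm_rot, tolerance = 1e-12)
  }
  expect_equal(glrlm_features(q, 0), glrlm_features(qr, 90))
  expect_equal(glrlm_features(q, 90), glrlm_features(qr, 0))
  expect_equal(glrlm_features(q, 45), glrlm_features(qr, 135))
  expect_equal(glrlm_features(q, 135), glrlm_features(qr, 45))
})

test_that("nested ROIs over stationary texture give close feature values", {
  # one stationary speckle field, two nested masks: features agree up to
  # sampling noise (deterministic fixture, loose tolerances)
  p <- lesion_params(image_size_px = c(96, 96), lesion_center_px = c(48, 48),
                     lesion_radii_px = c(1, 1), margin_irregularity = 0,
                     echogenicity_contrast = 1, # no lesion: pure background
                     texture_correlation_length_px = 1.2)
  les <- simulate_lesion_image(p, seed = 31)
  inner <- outer(1:96, 1:96, function(r, c) (r - 48)^2 + (c - 48)^2 <= 20^2)
  outer_m <- outer(1:96, 1:96, function(r, c) (r - 48)^2 + (c - 48)^2 <= 32^2)
  q_in <- normalize_quantize(les$image, roi_mask(inner, "tumor"))
  q_out <- normalize_quantize(les$image,
                              roi_mask(outer_m, "tumor_plus_peritumoral"))
  f_in <- extract_roi_features(q_in, dmax = 2, max_scale = 3)
  f_out <- extract_roi_features(q_out, dmax = 2, max_scale = 3)
  for (nm in c("S(0,1)Contrast", "S(0,1)Entropy", "Horzl_ShrtREmp")) {
    expect_lt(abs(f_in[[nm]] - f_out[[nm]]) / abs(f_out[[nm]]), 0.15)
  }
})

test_that("canonical_feature_name maps export-mangled names", {
  expect_equal(canonical_feature_name("X.S.0.1.Contrast"), "S(0,1)Contrast")
  expect_equal(canonical_feature_name("X.S.2.2.AngScMom"), "S(2,2)AngScMom")
  expect_equal(canonical_feature_name("X.S.1..1.SumEntrp"), "S(1,-1)SumEntrp")
  expect_equal(canonical_feature_name("X135dr_GLevNonU"), "135dr_GLevNonU")
  expect_equal(canonical_feature_name("ZWavEnLL_s6"), "WavEnLL_s6")
  expect_equal(canonical_feature_name("WavEnHL_s.3"), "WavEnHL_s3")
  expect_equal(canonical_feature_name("Teta2"), "Teta2")
  expect_equal(canonical_feature_name("Perc.01."), "Perc.01.")
  # every mapped name exists in the registry
  reg <- feature_registry()$name
  mapped <- canonical_feature_name(c("X.S.0.1.Contrast", "X.S.2.2.AngScMom",
                                     "X.S.5.5.SumVarnc", "X135dr_GLevNonU",
                                     "Teta2", "ZWavEnLL_s6", "ZWavEnLH_s6",
                                     "Perc.01.", "X.S.5.5.SumEntrp",
                                     "Horzl_RLNonUni", "WavEnHL_s.3",
                                     "WavEnHH_s.6"))
  expect_true(all(mapped %in% reg))
})
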