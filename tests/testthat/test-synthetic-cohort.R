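test_that("noise-free limit gives the exact discrete ellipse and contrast", {
  p <- lesion_params(image_size_px = c(64, 64), lesion_center_px = c(32, 32),
                     lesion_radii_px = c(12, 9), margin_irregularity = 0,
                     speckle_scale = 0, echogenicity_contrast = 0.5)
  les <- simulate_lesion_image(p, seed = 1)
  brute <- outer(1:64, 1:64,
                 function(r, c) ((r - 32) / 12)^2 + ((c - 32) / 9)^2 <= 1)
  expect_identical(les$tumor$mask, brute)
  expect_equal(sum(les$tumor$mask), sum(brute))
  inside <- les$image$pixels[les$tumor$mask]
  outside <- les$image$pixels[!les$tumor$mask]
  expect_lt(mean(inside), mean(outside))
  # piecewise-constant in the noise-free limit
  expect_equal(length(unique(inside)), 1L)
})

test_that("lesion generation is bit-identical under a fixed seed", {
  p <- lesion_params()
  a <- simulate_lesion_image(p, seed = 99)
  b <- simulate_lesion_image(p, seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$tumor$mask, b$tumor$mask)
  c2 <- simulate_lesion_image(p, seed = 100)
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("a lesion that does not fit inside the frame is rejected", {
  expect_error(
    lesion_params(image_size_px = c(32, 32), lesion_center_px = c(16, 16),
                  lesion_radii_px = c(20, 10)),
    "does not fit")
  expect_error(
    lesion_params(lesion_center_px = c(5, 64), lesion_radii_px = c(10, 10)),
    "does not fit")
})

small_cohort_base <- function() {
  lesion_params(image_size_px = c(32, 32), lesion_center_px = c(17, 16),
                lesion_radii_px = c(6, 5), margin_irregularity = 0.1,
                speckle_scale = 0.35)
}

test_that("cohort bookkeeping: sizes, labels, degenerate Ki67 rates", {
  cfg <- cohort_config(n_positive = 7, n_negative = 5,
                       ki67_high_rate_pos = 1, ki67_high_rate_neg = 0,
                       lesion_params_base = small_cohort_base(), seed = 5)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$meta), 12)
  expect_equal(sum(ch$meta$label == 1), 7)
  expect_length(ch$lesions, 12)
  # degenerate rates separate the classes perfectly
  expect_true(all(ch$meta$ki67_high[ch$meta$label == 1] == 1))
  expect_true(all(ch$meta$ki67_high[ch$meta$label == 0] == 0))
  # determinism
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch$meta, ch2$meta)
  expect_identical(ch$lesions[[3]]$image$pixels, ch2$lesions[[3]]$image$pixels)
})

test_that("Ki67-high counts follow the configured binomial rates", {
  # metadata-scale check: replicate cohorts with tiny images, compare the
  # mean Ki67-high count per class with the binomial expectation
  reps <- 200
  pos <- neg <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- cohort_config(n_positive = 50, n_negative = 38,
                         lesion_params_base = small_cohort_base(),
                         seed = 1000 + i)
    # draw only the metadata-level randomness: regenerate via the full
    # generator is exact but slow, so use a 2-lesion base and the rates
    meta <- with(cfg, {
      set.seed(seed)
      label <- rep(c(1L, 0L), c(n_positive, n_negative))
      ifelse(label == 1L, rbinom(88, 1, ki67_high_rate_pos),
             rbinom(88, 1, ki67_high_rate_neg))
    })
    label <- rep(c(1L, 0L), c(50, 38))
    pos[i] <- sum(meta[label == 1]); neg[i] <- sum(meta[label == 0])
  }
  se_pos <- sqrt(50 * (46 / 50) * (4 / 50) / reps)
  se_neg <- sqrt(38 * (26 / 38) * (12 / 38) / reps)
  expect_lt(abs(mean(pos) - 46), 3 * se_pos)
  expect_lt(abs(mean(neg) - 26), 3 * se_neg)
  # and the full generator draws the same metadata for the same seed
  ch <- simulate_cohort(cohort_config(n_positive = 50, n_negative = 38,
                                      lesion_params_base = small_cohort_base(),
                                      seed = 1001))
  expect_equal(sum(ch$meta$ki67_high[ch$meta$label == 1]), pos[1])
})

test_that("machine assignment is independent of class", {
  cfg <- cohort_config(n_positive = 120, n_negative = 120,
                       lesion_params_base = small_cohort_base(), seed = 77)
  ch <- simulate_cohort(cfg)
  tab <- table(ch$meta$label, ch$meta$machine)
  expect_gt(suppressWarnings(chisq.test(tab, correct = FALSE))$p.value, 0.001)
})

test_that("texture correlation length separates classes in GLCM contrast", {
  # two classes differing only in correlation length -> mean GLCM
  # Contrast at offset (0,1) differs with MW p < 0.01
  n <- 30
  contrast <- function(corr_len, seed) {
    p <- lesion_params(image_size_px = c(48, 48), lesion_center_px = c(25, 24),
                       lesion_radii_px = c(10, 9), margin_irregularity = 0,
                       texture_correlation_length_px = corr_len)
    les <- simulate_lesion_image(p, seed = seed)
    q <- normalize_quantize(les$image, les$tumor)
    glcm_features(glcm(q, 0, 1))[["Contrast"]]
  }
  a <- vapply(1:n, function(i) contrast(1.0, 300 + i), numeric(1))
  b <- vapply(1:n, function(i) contrast(3.0, 600 + i), numeric(1))
  expect_lt(mann_whitney(a, b)$p, 0.01)
  expect_gt(mean(a), mean(b)) # finer texture -> higher contrast
})

test_that("feature-table generator plants shifts and honors rho = 1 blocks", {
  cfg <- feattab_config(n_per_class = 200, n_features = 20, k = 3,
                        delta = 1.2, block_sizes = c(4), rho_block = 1,
                        seed = 8)
  tab <- simulate_feature_table(cfg)
  expect_equal(dim(tab$features), c(400L, 20L))
  expect_equal(tab$planted, c("F001", "F002", "F003"))
  # standardized mean shift close to delta at n = 200/class
  for (f in tab$planted) {
    d <- mean(tab$features[tab$labels == 1, f]) -
      mean(tab$features[tab$labels == 0, f])
    expect_lt(abs(d - 1.2), 0.3)
  }
  # rho = 1 block is exactly duplicated
  blk <- tab$features[, tab$blocks[[1]]]
  expect_equal(max(abs(blk - blk[, 1])), 0)
  # pruning keeps exactly one member
  pr <- correlation_prune(tab$features, threshold = 0.9)
  expect_equal(sum(tab$blocks[[1]] %in% pr$kept), 1L)
  # determinism
  tab2 <- simulate_feature_table(cfg)
  expect_identical(tab$features, tab2$features)
})

test_that("correlated blocks achieve the requested correlation in expectation", {
  cfg <- feattab_config(n_per_class = 500, n_features = 10, k = 0,
                        delta = 0, block_sizes = c(5), rho_block = 0.8,
                        seed = 21)
  tab <- simulate_feature_table(cfg)
  blk <- tab$features[, tab$blocks[[1]]]
  rho <- cor(blk)
  off_diag <- rho[upper.tri(rho)]
  expect_lt(abs(mean(off_diag) - 0.8), 0.05)
})
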