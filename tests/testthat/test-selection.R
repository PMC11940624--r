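test_that("Mann-Whitney matches hand-enumerated exact cases", {
  # all tied: U is the midpoint, p = 1
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)
  expect_equal(r$p, 1)
  expect_identical(r$method, "exact")

  # complete separation of 3 vs 3: U = 0, exact two-sided p = 2/20
  r2 <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 0.1)

  # single equal observation each
  expect_equal(mann_whitney(5, 5)$p, 1)
})

test_that("Mann-Whitney agrees with the wilcox.test oracle", {
  set.seed(20)
  # exact path, no ties
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1))
    got <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # normal-approximation path with ties and continuity correction
  for (i in 1:10) {
    a <- sample(1:8, 25, replace = TRUE)
    b <- sample(1:9, 30, replace = TRUE)
    got <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_identical(got$method, "normal")
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  # all values tied across both groups
  expect_equal(mann_whitney(rep(2, 20), rep(2, 25))$p, 1)
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03) # m = 1: unchanged
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(22)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p))            # inflation
    expect_true(all(adj <= 1))            # bounded
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # order-preserving
    # re-adjustment preserves the ordering of the adjusted values
    expect_true(all(diff(bh_adjust(adj)[order(adj)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("univariate filter keeps a strongly planted feature, drops null", {
  tab <- simulate_feature_table(
    feattab_config(n_per_class = 44, n_features = 50, k = 1, delta = 2,
                   seed = 30))
  res <- univariate_filter(tab$features, tab$labels)
  expect_true("F001" %in% res$kept)
  expect_true(all(res$audit$p_adj[res$audit$kept] < 0.05))
  # alpha = 0 -> empty result, still valid
  res0 <- univariate_filter(tab$features, tab$labels, alpha = 0)
  expect_length(res0$kept, 0)
  # undefined features are dropped with a reason
  tab$features[3, 2] <- NA
  res_na <- univariate_filter(tab$features, tab$labels)
  expect_false(colnames(tab$features)[2] %in% res_na$kept)
  expect_match(res_na$audit$reason[2], "undefined")
})

test_that("correlation pruning follows the greedy largest-mean rule", {
  # A duplicated column: exactly one copy kept
  set.seed(33)
  x <- matrix(rnorm(60), 20, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  x[, "B"] <- x[, "A"]
  pr <- correlation_prune(x, threshold = 0.9)
  expect_equal(sum(c("A", "B") %in% pr$kept), 1L)
  expect_true("C" %in% pr$kept)

  # hand-traced: A == B (rho 1), C weakly related -> C always retained,
  # one of A/B dropped (the one with larger mean |rho|; tie -> later)
  expect_true(pr$audit$dropped[pr$audit$feature == "B"])

  # postcondition audit on random inputs
  for (s in 1:5) {
    set.seed(s)
    xr <- matrix(rnorm(30 * 12), 30, 12,
                 dimnames = list(NULL, paste0("f", 1:12)))
    xr[, 2] <- xr[, 1] + rnorm(30, sd = 0.05)
    xr[, 7] <- -xr[, 6] + rnorm(30, sd = 0.05)
    out <- correlation_prune(xr, threshold = 0.9)
    rho <- abs(cor(xr[, out$kept], method = "spearman"))
    diag(rho) <- 0
    expect_lte(max(rho), 0.9)
  }

  # constant feature dropped first with reason
  xc <- cbind(const = rep(1, 20), x[, c("A", "C")])
  prc <- correlation_prune(xc, threshold = 0.9)
  expect_false("const" %in% prc$kept)
  expect_match(prc$audit$reason[prc$audit$feature == "const"], "constant")
})

test_that("LASSO CV is deterministic and recovers a strong planted feature", {
  recovered <- 0L
  for (i in 1:10) {
    tab <- simulate_feature_table(
      feattab_config(n_per_class = 50, n_features = 100, k = 1, delta = 3,
                     seed = 40 + i))
    res <- lasso_logistic_cv(tab$features, tab$labels, k = 10, seed = i)
    if ("F001" %in% res$kept && res$beta[["F001"]] > 0)
      recovered <- recovered + 1L
  }
  expect_gte(recovered, 9L)

  tab <- simulate_feature_table(
    feattab_config(n_per_class = 50, n_features = 40, k = 2, delta = 1.5,
                   seed = 99))
  r1 <- lasso_logistic_cv(tab$features, tab$labels, seed = 7)
  r2 <- lasso_logistic_cv(tab$features, tab$labels, seed = 7)
  expect_identical(r1$lambda, r2$lambda)
  expect_identical(r1$beta, r2$beta)

  # the top of the lambda path carries zero nonzero coefficients, and
  # the survivor count weakly increases as lambda decreases
  xs <- scale(tab$features)
  fit <- glmnet::glmnet(xs, tab$labels, family = "binomial",
                        standardize = FALSE)
  nz <- fit$df
  expect_equal(nz[1], 0)
})

test_that("single-feature input falls back to unpenalized logistic fit", {
  tab <- simulate_feature_table(
    feattab_config(n_per_class = 30, n_features = 1, k = 1, delta = 2,
                   seed = 55))
  res <- lasso_logistic_cv(tab$features, tab$labels, seed = 1)
  expect_equal(res$lambda, 0)
  expect_equal(res$kept, "F001")
  expect_gt(res$beta[["F001"]], 0)
})

test_that("cascade preserves survivor nesting and halts cleanly", {
  tab <- simulate_feature_table(
    feattab_config(n_per_class = 44, n_features = 60, k = 5, delta = 1.5,
                   block_sizes = c(4, 3), rho_block = 1, seed = 61))
  res <- run_cascade(tab$features, tab$labels, seed = 3)
  expect_s3_class(res, "selection_result")
  # nesting: final <= step2 <= step1
  expect_true(all(res$final %in% res$step2$kept))
  expect_true(all(res$step2$kept %in% res$step1$kept))
  expect_equal(unname(res$counts["input"]), 60L)
  # duplicate blocks collapse to at most one member each
  for (blk in tab$blocks)
    expect_lte(sum(blk %in% res$step2$kept), 1L)
  # planted features dominate step 1
  expect_true(all(tab$planted %in% res$step1$kept))
  # model is buildable and scores are finite
  expect_s3_class(res$model, "radscore_model")
  expect_true(all(is.finite(rad_score(tab$features, res$model))))

  # alpha = 0 halts after step 1
  res0 <- run_cascade(tab$features, tab$labels, alpha = 0, seed = 3)
  expect_match(res0$halted, "step1")
  expect_length(res0$final, 0)
})

test_that("train-only selection scope restricts the cascade to train rows", {
  tab <- simulate_feature_table(
    feattab_config(n_per_class = 40, n_features = 30, k = 2, delta = 1.5,
                   seed = 70))
  idx <- split_cohort(tab$labels, seed = 4)
  res <- run_cascade(tab$features, tab$labels, scope = "train_only",
                     train_index = idx$train, seed = 4)
  res_full <- run_cascade(tab$features, tab$labels, seed = 4)
  expect_s3_class(res, "selection_result")
  # the two scopes are genuinely different computations
  expect_false(identical(res$step1$audit$p, res_full$step1$audit$p))
  expect_error(run_cascade(tab$features, tab$labels, scope = "train_only"),
               "train_index")
})
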