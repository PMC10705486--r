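cfg_free <- function(...) {
  gbdt_config(min_child_samples = 1, min_child_weight = 1, ...)
}

test_that("a two-point problem yields the obvious stump", {
  X <- matrix(c(0, 1), 2, 1)
  tree <- fit_tree(X, c(0, 1), cfg_free(max_depth = 1, num_leaves = 2))
  expect_false(tree$is_leaf[1])
  expect_equal(tree$threshold[1], 0.5)
  expect_equal(sort(tree$value[tree$is_leaf]), c(0, 1))
})

test_that("constant residuals produce a single leaf with that value", {
  X <- matrix(runif(20), 20, 1)
  tree <- fit_tree(X, rep(1.7, 20), cfg_free())
  expect_true(tree$is_leaf[1])
  expect_equal(tree$value[1], 1.7)
})

test_that("the chosen split matches an exhaustive (feature, threshold) search", {
  set.seed(41)
  for (k in 1:5) {
    X <- matrix(runif(120), 40, 3)
    r <- rnorm(40)
    tree <- fit_tree(X, r, cfg_free(max_depth = 1, num_leaves = 2))
    ref <- best_stump_bruteforce(X, r)
    expect_equal(tree$feature[1], ref$feature)
    expect_equal(tree$threshold[1], ref$threshold, tolerance = 1e-12)
    # reduction achieved by the split equals the brute-force optimum
    left <- X[, tree$feature[1]] <= tree$threshold[1]
    gain <- sum((r - mean(r))^2) -
      sum((r[left] - mean(r[left]))^2) - sum((r[!left] - mean(r[!left]))^2)
    expect_equal(gain, ref$gain, tolerance = 1e-9)
  }
})

test_that("zero boosting rounds predict the training mean everywhere", {
  set.seed(2)
  X <- matrix(runif(60), 30, 2)
  y <- runif(30, 1, 2)
  m <- fit_gbdt(X, y, cfg_free(n_trees = 0))
  expect_equal(predict(m, X), rep(mean(y), 30))
  expect_length(m$staged_train_mse, 1)
})

test_that("one full-capacity tree with rho 1 interpolates distinct points", {
  X <- matrix(c(0.1, 0.4, 0.7, 0.9), 4, 1)
  y <- c(1.2, 0.3, 2.2, 1.7)
  m <- fit_gbdt(X, y, cfg_free(n_trees = 1, learning_rate = 1,
                               max_depth = 3, num_leaves = 8))
  expect_equal(predict(m, X), y, tolerance = 1e-12)
})

test_that("boosting equals a hand-rolled residual loop of brute-force stumps", {
  set.seed(10)
  X <- matrix(runif(10), 10, 1)
  y <- runif(10, 0.8, 2.4)
  m <- fit_gbdt(X, y, cfg_free(n_trees = 3, learning_rate = 0.5,
                               max_depth = 1, num_leaves = 2))
  ref <- boost_stumps_reference(X, y, K = 3, rho = 0.5)
  expect_equal(predict(m, X), ref, tolerance = 1e-12)
})

test_that("predictions are deterministic and row-duplication consistent", {
  set.seed(3)
  X <- matrix(runif(80), 40, 2)
  y <- X[, 1] * 2 + rnorm(40, 0, 0.05)
  m <- fit_gbdt(X, y, cfg_free(n_trees = 20))
  X2 <- rbind(X[7, , drop = FALSE], X[7, , drop = FALSE])
  p <- predict(m, X2)
  expect_equal(p[1], p[2])
  expect_error(predict(m, X[, 1, drop = FALSE]), "features")
})

test_that("predictions are invariant to monotone feature transforms", {
  set.seed(8)
  X <- matrix(rnorm(120), 40, 3)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(40, 0, 0.1)
  Xt <- X^3                                   # strictly monotone, order preserved
  m1 <- fit_gbdt(X, y, cfg_free(n_trees = 25))
  m2 <- fit_gbdt(Xt, y, cfg_free(n_trees = 25))
  # identical partitions of the observed points, hence identical fits
  expect_equal(predict(m1, X), predict(m2, Xt), tolerance = 1e-12)
  expect_equal(m1$staged_train_mse, m2$staged_train_mse, tolerance = 1e-12)
})

test_that("GBDT results are invariant to min-max rescaling of the features", {
  set.seed(19)
  X <- matrix(runif(200, -3, 7), 50, 4)
  y <- X[, 2] + rnorm(50, 0, 0.1)
  st <- normalize_fit(X)
  m1 <- fit_gbdt(X, y, cfg_free(n_trees = 30))
  m2 <- fit_gbdt(normalize_apply(X, st), y, cfg_free(n_trees = 30))
  Xn <- matrix(runif(40, -3, 7), 10, 4)
  expect_equal(predict(m1, Xn), predict(m2, normalize_apply(Xn, st)),
               tolerance = 1e-12)
})

test_that("the training loss trace starts at the variance and never rises", {
  set.seed(6)
  for (k in 1:50) {
    n <- 25 + k %% 10
    X <- matrix(runif(n * 3), n, 3)
    y <- runif(n, 0.8, 2.4)
    m <- fit_gbdt(X, y, cfg_free(n_trees = 15))
    tr <- staged_loss(m, X, y)
    expect_equal(tr[1], mean((y - mean(y))^2), tolerance = 1e-12)
    expect_true(all(diff(tr) <= 1e-12))
    expect_equal(tr, m$staged_train_mse, tolerance = 1e-12)
  }
})

test_that("subsampled fits are bit-reproducible under a fixed seed", {
  set.seed(4)
  X <- matrix(runif(300), 75, 4)
  y <- X[, 1] + rnorm(75, 0, 0.1)
  cfg <- cfg_free(n_trees = 30, subsample = 0.8, colsample = 0.7, seed = 11)
  m1 <- fit_gbdt(X, y, cfg)
  m2 <- fit_gbdt(X, y, cfg)
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- fit_gbdt(X, y, cfg_free(n_trees = 30, subsample = 0.8,
                                colsample = 0.7, seed = 12))
  expect_false(identical(predict(m1, X), predict(m3, X)))
})

test_that("models survive a JSON save/load round trip", {
  set.seed(5)
  X <- matrix(runif(100), 25, 4)
  y <- runif(25, 1, 2)
  m <- fit_gbdt(X, y, cfg_free(n_trees = 10))
  f <- withr::local_tempfile(fileext = ".json")
  gbdt_save(m, f)
  m2 <- gbdt_load(f)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
})

test_that("config presets honour their stated hyperparameters", {
  lg <- gbdt_preset("lgbm-paper")
  expect_equal(lg$n_trees, 4000L); expect_equal(lg$num_leaves, 15L)
  expect_equal(lg$max_depth, 5L); expect_equal(lg$min_child_samples, 15L)
  xg <- gbdt_preset("xgb-paper")
  expect_equal(xg$n_trees, 2000L); expect_equal(xg$subsample, 0.8)
  expect_equal(xg$colsample, 0.7)
  expect_error(gbdt_config(learning_rate = 0), "learning_rate")
  expect_error(gbdt_config(num_leaves = 1), "num_leaves")
  expect_error(gbdt_config(subsample = 0), "subsample")
})

test_that("a pure-noise learned block does not derail the regression", {
  # features from ground-truth masks of 300 synthetic scenes
  tabs <- lapply(1:300, function(i) {
    sc <- generate_depth_scene(random_scene_spec(9000 + i, weight_sigma_rel = 0.03))
    c(extract_features(sc$depth, sc$masks[[1]]), weight = sc$truth$weight_kg)
  })
  tab <- do.call(rbind, tabs)
  X <- tab[, 1:25]; y <- tab[, 26]
  sp <- train_test_split(300, seed = 77)
  cfg <- gbdt_config(n_trees = 200, max_depth = 5, seed = 77)
  m_base <- fit_gbdt(X[sp$train, ], y[sp$train], cfg)
  mae_base <- mean(abs(predict(m_base, X[sp$test, ]) - y[sp$test]))
  set.seed(123)
  noise <- matrix(rnorm(300 * 2048), 300, 2048)
  Xf <- cbind(X, noise)
  m_fused <- fit_gbdt(Xf[sp$train, ], y[sp$train], cfg)
  mae_fused <- mean(abs(predict(m_fused, Xf[sp$test, ]) - y[sp$test]))
  expect_lte(mae_base / mean(y[sp$test]), 0.06)
  expect_lte(mae_fused, 1.2 * mae_base)
})
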