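test_that("distance correlation matches the explicit double-centering oracle", {
  set.seed(4)
  for (i in 1:15) {
    n <- sample(5:50, 1)
    u <- rnorm(n); v <- rnorm(n)
    expect_equal(distance_correlation(u, v), dc_oracle(u, v),
                 tolerance = 1e-12)
    expect_equal(distance_correlation(u, v), distance_correlation(v, u))
  }
  u <- rnorm(20)
  expect_equal(distance_correlation(u, 3 * u + 1), 1, tolerance = 1e-10)
  expect_warning(dc0 <- distance_correlation(rep(2, 10), rnorm(10)),
                 "constant")
  expect_equal(dc0, 0)
  # invariance under positive affine maps of either argument
  v <- rnorm(20)
  expect_equal(distance_correlation(u, v),
               distance_correlation(2.5 * u + 3, 0.1 * v - 7),
               tolerance = 1e-12)
  # null: independent vectors give small DC
  set.seed(9)
  dcs <- replicate(20, distance_correlation(rnorm(200), rnorm(200)))
  expect_lt(median(dcs), 0.2)
})

test_that("percentile trimming retains the lower 95% of a biased feature", {
  expect_equal(sum(trim_percentile(1:100)), 95L)
  expect_true(all(trim_percentile(rexp(50), enabled = FALSE)))
  expect_true(all(trim_percentile(rep(3, 20))))
})

test_that("median split balances classes and splits ties deterministically", {
  expect_equal(binarize(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  b <- binarize(c(5, 5, 1, 9))
  expect_equal(sort(b[c(1, 2)]), c(0L, 1L))  # the two 5s split across classes
  expect_equal(b[3], 0L); expect_equal(b[4], 1L)
  set.seed(6)
  for (i in 1:20) {
    x <- sample(round(rnorm(sample(3:30, 1)), 1), replace = TRUE)
    if (length(unique(x)) == 1L) next
    cls <- binarize(x)
    expect_lte(abs(sum(cls == 0L) - sum(cls == 1L)), 1L)
  }
  expect_error(binarize(rep(1, 5)), "uninformative")
})

test_that("z-scoring normalizes columns and ignores affine shifts", {
  set.seed(11)
  X <- cbind(m = runif(30, 0.5, 3), beta = runif(30, 0.005, 0.05),
             theta = runif(30, 0.4, 1))
  Z <- zscore(X)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  X2 <- X; X2[, 1] <- 10 * X2[, 1] + 3
  expect_equal(zscore(X2)[, 1], Z[, 1], tolerance = 1e-12)
  expect_error(zscore(cbind(rep(1, 5), rnorm(5))), "zero-variance")
})

test_that("kNN prediction votes among nearest neighbours with deterministic ties", {
  train <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  cls <- c(0L, 0L, 1L, 1L)
  expect_equal(knn_predict(train, cls, rbind(c(0, 0)), k = 1), 0L)
  expect_equal(knn_predict(train, cls, rbind(c(5, 6)), k = 1), 1L)
  expect_equal(knn_predict(train, cls, rbind(c(0, 0.5)), k = 3), 0L)
  # k = n_train with a majority class
  train5 <- rbind(train, c(5, 7)); cls5 <- c(cls, 1L)
  expect_equal(knn_predict(train5, cls5, rbind(c(0, 0), c(9, 9)), k = 5),
               c(1L, 1L))
  # even-k vote tie falls back to the nearest neighbour's class
  expect_equal(knn_predict(train, cls, rbind(c(0.1, 0)), k = 4), 0L)
  expect_equal(knn_predict(train, cls, rbind(c(4.9, 5)), k = 4), 1L)
  expect_error(knn_predict(train, cls, rbind(c(0, 0)), k = 5), "exceeds")
  # k = 1 on its own training set is error-free
  set.seed(12)
  X <- matrix(rnorm(60), ncol = 3)
  c6 <- rep(c(0L, 1L), 10)
  expect_equal(prediction_error(knn_predict(X, c6, X, 1), c6), 0)
})

test_that("kNN agrees with the class package on tie-free data", {
  skip_if_not_installed("class")
  set.seed(13)
  train <- matrix(rnorm(150), ncol = 3)
  cls <- as.integer(train[, 1] + 0.2 * rnorm(50) > 0)
  test <- matrix(rnorm(60), ncol = 3)
  for (k in c(1, 3, 5)) {  # odd k: no vote ties
    ref <- as.integer(as.character(class::knn(train, test, factor(cls), k)))
    expect_equal(knn_predict(train, cls, test, k), ref)
  }
})

test_that("prediction error is the misclassification fraction", {
  expect_equal(prediction_error(c(rep(0, 75), rep(1, 25)), rep(0, 100)), 0.25)
  expect_equal(prediction_error(1:5, 1:5), 0)
  set.seed(14)
  e <- prediction_error(sample(0:1, 1000, replace = TRUE),
                        sample(0:1, 1000, replace = TRUE))
  expect_lt(abs(e - 0.5), 0.05)
})

test_that("significance procedure flags separable features and not noise", {
  set.seed(15)
  X <- cbind(m = runif(200, 0.5, 3), beta = runif(200, 1 / 200, 1 / 20),
             theta = runif(200, 0.4, 1))
  sep <- significance_test(X, X[, "m"], ks = c(5, 10, 20), n_repeats = 20,
                           min_significant_k = 3, seed = 101)
  expect_true(sep$significant)
  expect_equal(sum(sep$per_k$significant_k), 3L)
  noise <- significance_test(X, rnorm(200), ks = c(5, 10, 20),
                             n_repeats = 20, min_significant_k = 3,
                             seed = 102)
  expect_false(noise$significant)
  # identical seed reproduces the result exactly; caller RNG is untouched
  before <- .Random.seed
  again <- significance_test(X, X[, "m"], ks = c(5, 10, 20), n_repeats = 20,
                             min_significant_k = 3, seed = 101)
  expect_identical(sep$per_k, again$per_k)
  expect_identical(before, .Random.seed)
  expect_error(significance_test(X, rnorm(200), ks = 500, n_repeats = 20,
                                 seed = 1), "exceed")
})

test_that("model repair rates track XR-style signals better than the surrogate", {
  cfg <- sim_config(n_cells = 400, n_regions = 60, positions_per_region = 60,
                    noise = "poisson", seed = 21)
  sim <- simulate_cohort(cfg)
  fits <- fit_regions(sim$courses)
  res <- xr_model_correlation(fits, sim$courses, sim$xr)
  expect_gt(res$model_dc, 0.5)
  expect_gt(res$model_dc, res$baseline_dc)
  # noiseless self-consistency: XR values built from the fitted rates give DC 1
  ids <- fits$region_id[fits$passes_filter]
  xr_self <- do.call(rbind, lapply(ids, function(id) {
    row <- fits[fits$region_id == id, ]
    p <- kjma_params(row$m, row$tau, row$theta)
    data.frame(region_id = id, time = c(5, 20, 60),
               value = sqrt(repair_rate(p, c(5, 20, 60))))
  }))
  res_self <- xr_model_correlation(fits, sim$courses, xr_self)
  expect_equal(res_self$model_dc, 1, tolerance = 1e-10)
  # independent-noise XR values decorrelate
  xr_null <- xr_self
  set.seed(22)
  xr_null$value <- rnorm(nrow(xr_null))
  expect_lt(xr_model_correlation(fits, sim$courses, xr_null)$model_dc, 0.25)
})
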