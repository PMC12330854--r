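# shared small design for path tests
path_design <- function(n_time = 60, tes = c(12, 35, 58)) {
  multiecho_design(build_convolution_operator(canonical_hrf(1800), n_time), tes)
}

test_that("all-zero input yields an empty path", {
  X <- path_design(30)
  p <- solve_sparse_path(rep(0, nrow(X)), X)
  expect_true(all(p$support == 0))
  expect_true(all(p$coefficients == 0))
  expect_equal(p$rss, rep(0, length(p$lambda)))
})

test_that("path structure: empty at lambda_max, RSS non-increasing", {
  set.seed(11)
  X <- path_design(60)
  train <- numeric(60)
  train[c(12, 40)] <- c(-2, -1.2)
  y <- as.numeric(X %*% train) + rnorm(nrow(X), 0, 1e-3)
  p <- solve_sparse_path(y, X)
  expect_equal(p$support[1], 0L) # grid starts at lambda_max
  expect_true(all(diff(p$rss) <= 1e-12))
  expect_true(all(p$converged == 1))
  expect_lte(p$rss[length(p$rss)], p$rss[1])
})

test_that("noiseless single event is isolated at the true onset", {
  X <- path_design(40)
  onset <- 14
  train <- numeric(40)
  train[onset] <- -2
  y <- as.numeric(X %*% train)
  p <- solve_sparse_path(y, X)
  # exhaustive single-onset oracle: best-fitting single onset by OLS RSS
  rss1 <- vapply(1:39, function(j) {
    xj <- X[, j]
    sum((y - xj * sum(xj * y) / sum(xj^2))^2)
  }, numeric(1))
  expect_equal(which.min(rss1), onset)
  one <- which(p$support == 1)
  expect_gt(length(one), 0)
  expect_true(all(vapply(one, function(i) {
    which(p$coefficients[, i] != 0) == onset
  }, logical(1))))
})

test_that("path solutions match exhaustive small-support search", {
  # T <= 12: compare the penalised objective with brute force over all
  # supports of size <= 2 wherever the path support is that small
  set.seed(3)
  for (case in 1:3) {
    X <- path_design(10, tes = c(12, 35))
    train <- numeric(10)
    train[sample(1:8, 1)] <- runif(1, -3, -1)
    y <- as.numeric(X %*% train) + rnorm(nrow(X), 0, 0.02 * case)
    p <- solve_sparse_path(y, X)
    for (i in which(p$support <= 2)) {
      mine <- lasso_objective(y, X, p$coefficients[, i], p$lambda[i])
      oracle <- exhaustive_lasso(y, X, p$lambda[i], kmax = 2)
      expect_equal(mine, oracle, tolerance = 1e-8)
    }
  }
})

test_that("path agrees with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  X <- path_design(50)
  train <- numeric(50)
  train[c(10, 30)] <- c(-2.5, -1)
  y <- as.numeric(X %*% train) + rnorm(nrow(X), 0, 5e-3)
  p <- solve_sparse_path(y, X)
  g <- glmnet::glmnet(X, y, lambda = p$lambda / length(y),
                      standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  for (i in seq_along(p$lambda)) {
    mine <- lasso_objective(y, X, p$coefficients[, i], p$lambda[i])
    theirs <- lasso_objective(y, X, as.numeric(stats::coef(g)[-1, i]),
                              p$lambda[i])
    expect_lte(mine, theirs + 1e-10)
  }
})

test_that("scaling covariance: c * y scales the selected coefficients by c", {
  set.seed(5)
  X <- path_design(40)
  train <- numeric(40)
  train[c(9, 25)] <- c(-2, -1.5)
  y <- as.numeric(X %*% train) + rnorm(nrow(X), 0, 0.01)
  p1 <- solve_sparse_path(y, X)
  p2 <- solve_sparse_path(3 * y, X)
  expect_equal(p2$lambda, 3 * p1$lambda)
  expect_equal(p2$coefficients, 3 * p1$coefficients, tolerance = 1e-9)
  s1 <- select_bic(p1)
  s2 <- select_bic(p2)
  expect_equal(s2$coefficients, 3 * s1$coefficients, tolerance = 1e-9)
})

test_that("BIC prefers sparser models on ties and equal RSS", {
  # synthetic path object exercising the selection rule directly
  fake <- structure(list(
    lambda = c(1, 0.5, 0.25),
    coefficients = cbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 0)),
    support = c(1L, 2L, 2L),
    rss = c(4, 4, 4), # equal RSS: penalty must decide
    lambda_max = 1,
    gram = diag(3), xty = c(1, 1, 0), yty = 10, n_obs = 60
  ), class = "reg_path")
  s <- select_bic(fake)
  expect_equal(s$index, 1L)
  expect_equal(length(s$support), 1L)
  # exact ties in BIC resolve to the larger lambda
  fake$support <- c(1L, 1L, 1L)
  fake$coefficients <- cbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  s2 <- select_bic(fake)
  expect_equal(s2$index, 1L)
})

test_that("BIC keeps pure-noise voxels empty and finds strong events", {
  X <- path_design(100)
  n <- nrow(X)
  empty <- 0L
  hits <- 0L
  onset_ok <- 0L
  n_noise <- 200
  n_event <- 100
  for (s in seq_len(n_noise)) {
    set.seed(s)
    y <- rnorm(n, 0, 0.5) / 100
    sel <- select_bic(solve_sparse_path(y, X, max_support = 30))
    if (length(sel$support) == 0) empty <- empty + 1L
  }
  expect_gte(empty / n_noise, 0.9)
  h <- canonical_hrf(1800)
  amp <- amplitude_for_cnr(3, 0.5, h)
  for (s in seq_len(n_event)) {
    set.seed(1000 + s)
    onset <- sample(5:80, 1)
    train <- numeric(100)
    train[onset] <- amp
    y <- as.numeric(X %*% train) + rnorm(n, 0, 0.5) / 100
    sel <- select_bic(solve_sparse_path(y, X, max_support = 30))
    if (length(sel$support) >= 1) {
      hits <- hits + 1L
      if (min(abs(sel$support - onset)) <= 1) onset_ok <- onset_ok + 1L
    }
  }
  expect_gte(hits / n_event, 0.95)
  expect_gte(onset_ok / n_event, 0.95)
})

test_that("deconvolve_run honours the mask, sign convention and determinism", {
  truth <- tiny_truth(noise_sd = 0.3, drift_order = 2)
  ser <- simulate_multiecho_run(truth, seed = 9)
  mask <- array(FALSE, truth$grid)
  mask[1:5, , ] <- TRUE
  d1 <- deconvolve_run(ser, mask = mask)
  d2 <- deconvolve_run(ser, mask = mask)
  expect_identical(d1$estimates, d2$estimates) # seed-free determinism
  expect_true(all(d1$estimates[!as.logical(mask), ] == 0))
  # planted negative events produce negative coefficients at event times
  roi_in_mask <- which(as.integer(truth$roi_labels) == 1 & as.logical(mask))
  ev <- truth$events[truth$events$roi == 1, ]
  found <- vapply(ev$onset_tr, function(o) {
    any(d1$estimates[roi_in_mask, max(1, o - 1):min(100, o + 1)] < 0)
  }, logical(1))
  expect_true(all(found))
})

test_that("batch selection equals the R-level path + BIC route", {
  truth <- tiny_truth(noise_sd = 0.4, drift_order = 1,
                      events_per_roi = 1, seed = 6)
  ser <- simulate_multiecho_run(truth, seed = 10)
  dec <- deconvolve_run(ser, max_support = Inf)
  X <- urgepfm:::residualised_design(canonical_hrf(1800), 100, ser$tes_ms, 4)
  vox <- c(which(as.integer(truth$roi_labels) == 1)[1:2], 1L, 250L)
  for (v in vox) {
    y <- unlist(lapply(ser$echoes, function(e) {
      percent_signal_change(matrix(e, 500, 100), detrend_order = 4)[v, ]
    })) / 100
    sel <- select_bic(solve_sparse_path(y, X))
    expect_equal(dec$estimates[v, ], sel$coefficients, tolerance = 1e-9)
  }
})
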