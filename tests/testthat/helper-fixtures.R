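# shared fixtures and independent oracles, built in code at test time

# small phantom: 2 ROIs of 18 voxels on a 10x10x5 grid
tiny_truth <- function(noise_sd = 0, amplitude = -2, seed = 1,
                       n_time = 100, events_per_roi = 2, drift_order = 0) {
  make_ground_truth(
    grid = c(10, 10, 5), n_time = n_time, n_rois = 2, roi_dim = c(3, 3, 2),
    events_per_roi = events_per_roi, amplitude = amplitude,
    noise_sd = noise_sd, drift_order = drift_order, seed = seed
  )
}

# brute-force discrete causal convolution oracle
brute_convolve <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_len(min(t, length(kernel)))) {
      out[t] <- out[t] + kernel[j] * x[t - j + 1]
    }
  }
  out
}

# penalised lasso objective
lasso_objective <- function(y, X, b, lambda) {
  0.5 * sum((y - X %*% b)^2) + lambda * sum(abs(b))
}

# exact minimiser of the penalised objective restricted to a fixed support,
# by 2-variable coordinate descent iterated to convergence
lasso_on_support <- function(y, X, supp, lambda, iters = 5000) {
  b <- numeric(ncol(X))
  if (!length(supp)) return(b)
  Xs <- X[, supp, drop = FALSE]
  g <- colSums(Xs^2)
  if (any(g <= 1e-12)) return(b) # unidentifiable support
  bs <- numeric(length(supp))
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_along(supp)) {
      r <- y - Xs %*% bs + Xs[, j] * bs[j]
      z <- sum(Xs[, j] * r)
      new <- sign(z) * max(abs(z) - lambda, 0) / g[j]
      delta <- max(delta, abs(new - bs[j]))
      bs[j] <- new
    }
    if (delta < 1e-13) break
  }
  b[supp] <- bs
  b
}

# exhaustive search over all supports of size <= kmax for the lasso problem
exhaustive_lasso <- function(y, X, lambda, kmax = 2) {
  p <- ncol(X)
  best <- lasso_objective(y, X, numeric(p), lambda)
  for (k in seq_len(kmax)) {
    for (supp in utils::combn(p, k, simplify = FALSE)) {
      b <- lasso_on_support(y, X, supp, lambda)
      best <- min(best, lasso_objective(y, X, b, lambda))
    }
  }
  best
}

# a reproducible peri-blink curve tibble for n participants
fake_curves <- function(n, shape = function(lag) pmax(0, 1 - abs(lag) / 5)) {
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(participant = paste0("p", i), lag = -5:5,
                   mean_z = shape(-5:5))
  })
}
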