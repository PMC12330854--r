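#' L1 regularisation path for one stacked voxel
#'
#' Solves the sparse deconvolution problem
#' `min 0.5 * ||y - X b||^2 + lambda * ||b||_1`
#' along a decreasing logarithmic lambda grid from `lambda_max` (the smallest
#' lambda with an empty model) down to `lambda_max * lambda_min_ratio`, by
#' coordinate descent in Gram form with warm starts. Every returned solution
#' satisfies the stationarity (KKT) conditions of the penalised problem within
#' `tol * max(1, lambda_max)`.
#'
#' @param y Stacked percent-change/100 vector of length E*T (one voxel, all
#'   echoes concatenated).
#' @param design The (E*T) x T matrix from [multiecho_design()] (or any design).
#' @param n_lambda Number of grid points (default 50).
#' @param lambda_min_ratio Ratio of the last to the first lambda (default 1e-3).
#' @param tol Stationarity tolerance (default 1e-8).
#' @param max_support Optional cap on the support size: the path stops early
#'   (and is returned truncated) once a solution exceeds it. Default `Inf`.
#' @return Object of class `reg_path`: list with `lambda` (decreasing),
#'   `coefficients` (T x n_lambda), `support`, `rss` (residual sum of squares
#'   of the penalised solutions, non-increasing), `lambda_max`, plus the Gram
#'   quantities (`gram`, `xty`, `yty`, `n_obs`) used by [select_bic()].
#' @export
solve_sparse_path <- function(y, design, n_lambda = 50,
                              lambda_min_ratio = 1e-3, tol = 1e-8,
                              max_support = Inf) {
  y <- as.numeric(y)
  X <- unclass(design)
  if (length(y) != nrow(X)) {
    abort("length(y) does not match the design", class = "urgepfm_parameter_error")
  }
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    abort("inputs must be finite", class = "urgepfm_parameter_error")
  }
  xty <- as.numeric(crossprod(X, y))
  G <- crossprod(X)
  yty <- sum(y^2)
  ms <- if (is.finite(max_support)) as.integer(max_support) else -1L
  res <- lasso_path_gram(xty, G, yty, n_lambda, lambda_min_ratio, tol, ms)
  structure(
    list(
      lambda = as.numeric(res$lambda),
      coefficients = res$beta,
      support = as.integer(res$support),
      rss = as.numeric(res$rss),
      lambda_max = res$lambda_max,
      converged = as.integer(res$converged),
      gram = G, xty = xty, yty = yty, n_obs = nrow(X)
    ),
    class = "reg_path"
  )
}

#' @export
print.reg_path <- function(x, ...) {
  cat(sprintf(
    "<reg_path: %d lambdas in [%.3g, %.3g], support %d..%d>\n",
    length(x$lambda), min(x$lambda), max(x$lambda),
    min(x$support), max(x$support)
  ))
  invisible(x)
}

#' @rdname tidy-urgepfm
#' @method tidy reg_path
#' @export
tidy.reg_path <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    support = x$support,
    rss = x$rss
  )
}

#' BIC selection of the regularisation parameter
#'
#' Scores every model on the path with
#' `BIC(lambda) = n * log(RSS(lambda) / n) + k(lambda) * log(n)`,
#' where `k` is the support size. By default the RSS of the penalised
#' (shrunk) solution is used for scoring - shrinkage keeps the apparent fit
#' improvement of spurious coefficients near `lambda_max` small, which is what
#' makes the criterion conservative on noise - while the *returned*
#' coefficients at the selected lambda are debiased (ordinary least squares on
#' the support), so amplitudes are unbiased. Set `bic_rss = "debiased"` to
#' score debiased fits instead. Ties in BIC resolve to the larger lambda
#' (sparser model). RSS is floored at `y'y * 1e-24` so numerically exact fits
#' compare by sparsity.
#'
#' @param path A [solve_sparse_path()] object.
#' @param n Number of stacked observations (default: taken from the path).
#' @param bic_rss Which RSS enters the criterion: "penalised" (default) or
#'   "debiased".
#' @return List with `lambda` (selected), `coefficients` (debiased, length T),
#'   `bic` (per path lambda), `index`, `support` (selected support indices),
#'   `bic_rss`.
#' @export
select_bic <- function(path, n = path$n_obs,
                       bic_rss = c("penalised", "debiased")) {
  bic_rss <- match.arg(bic_rss)
  if (length(path$lambda) == 0) {
    abort("empty path", class = "urgepfm_parameter_error")
  }
  L <- length(path$lambda)
  floor_rss <- max(path$yty * 1e-24, .Machine$double.xmin)
  rss <- path$rss
  k <- path$support
  if (bic_rss == "debiased") {
    rss <- vapply(seq_len(L), function(i) {
      s <- which(path$coefficients[, i] != 0)
      if (!length(s)) return(path$yty)
      debias_gram(path, s)$rss
    }, numeric(1))
  }
  bic <- n * log(pmax(rss, floor_rss) / n) + k * log(n)
  # strict-improvement scan from the largest lambda: ties keep sparser model
  idx <- 1L
  for (i in seq_len(L)) if (bic[i] < bic[idx] - 1e-12) idx <- i
  s <- which(path$coefficients[, idx] != 0)
  coefs <- numeric(nrow(path$coefficients))
  if (length(s)) coefs[s] <- debias_gram(path, s)$coef
  list(
    lambda = path$lambda[idx], coefficients = coefs, bic = bic,
    index = idx, support = s, bic_rss = bic_rss
  )
}

# OLS on a support through the Gram system
debias_gram <- function(path, supp) {
  Gs <- path$gram[supp, supp, drop = FALSE]
  bs <- path$xty[supp]
  coef <- tryCatch(solve(Gs, bs), error = function(e) {
    as.numeric(MASS_ginv(Gs) %*% bs)
  })
  list(coef = coef, rss = max(0, path$yty - sum(bs * coef)))
}

# tiny pseudo-inverse fallback (avoids a MASS dependency)
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Voxelwise sparse deconvolution of a multi-echo run
#'
#' For every voxel inside the mask: compute percent signal change per echo
#' (Legendre detrending of order `detrend_order`), stack the echoes, solve the
#' L1 regularisation path against the multi-echo design (the design columns
#' are residualised against the same detrending basis so the nuisance
#' projection cannot bias the event amplitudes), and select the model by BIC.
#' Estimates carry units of delta-R2* in 1/s; a negative estimate encodes a
#' positive BOLD event.
#'
#' The procedure is deterministic: identical inputs give identical outputs.
#'
#' @param series A [simulate_multiecho_run()] object (or a compatible list
#'   with `echoes`, `tes_ms`, `tr_ms`, `brain_mask`).
#' @param mask Logical 3D array; defaults to the series brain mask.
#' @param hrf HRF model; defaults to the canonical HRF at the series TR.
#' @param detrend_order Drift order used in the percent-change step (default 4).
#' @param n_lambda,lambda_min_ratio,tol Path parameters, see
#'   [solve_sparse_path()].
#' @param bic_rss Passed to the BIC step, see [select_bic()].
#' @param max_support Stop descending the lambda grid once a voxel's support
#'   exceeds this size (default `n_time %/% 3`): supports that large can
#'   never minimise the BIC, so the expensive tail of the path is skipped.
#'   Set to `Inf` to always solve the full grid.
#' @return Object of class `decon_result`: list with `estimates` (n_voxel x T
#'   matrix, zero outside the mask), `mask`, `grid`, `lambda` and `bic` and
#'   `support` (3D maps), `tes_ms`, `tr_ms`, `hrf`, `detrend_order`,
#'   `bic_rss`.
#' @export
deconvolve_run <- function(series,
                           mask = series$brain_mask,
                           hrf = canonical_hrf(series$tr_ms),
                           detrend_order = 4,
                           n_lambda = 50,
                           lambda_min_ratio = 1e-3,
                           tol = 1e-8,
                           bic_rss = c("penalised", "debiased"),
                           max_support = NULL) {
  bic_rss <- match.arg(bic_rss)
  grid <- dim(series$echoes[[1]])[1:3]
  n_time <- dim(series$echoes[[1]])[4]
  if (!all(dim(mask) == grid)) {
    abort("mask does not match the series grid", class = "urgepfm_parameter_error")
  }
  for (e in series$echoes) {
    if (dim(e)[4] != n_time) {
      abort("echoes disagree on the number of timepoints",
            class = "urgepfm_parameter_error")
    }
  }
  m <- as.logical(mask)
  # voxels whose raw mean is ~0 cannot be expressed in percent change; they
  # are logged, removed from the fit and zero-filled in the output
  flat <- vapply(series$echoes, function(e) {
    rowMeans(matrix(e, prod(grid), n_time))
  }, numeric(prod(grid)))
  degenerate <- m & (rowSums(abs(flat) < .Machine$double.eps^0.5) > 0)
  if (any(degenerate)) {
    warn(sprintf(
      "%d masked voxel(s) with zero mean signal were zero-filled (first: %d)",
      sum(degenerate), which(degenerate)[1]
    ), class = "urgepfm_degenerate_voxel_warning")
    m <- m & !degenerate
  }
  V <- sum(m)

  X <- residualised_design(hrf, n_time, series$tes_ms, detrend_order)
  G <- crossprod(X)

  # stacked percent-change/100 matrix: (E*T) x V
  Ys <- matrix(0, length(series$tes_ms) * n_time, V)
  for (k in seq_along(series$echoes)) {
    Yk <- matrix(series$echoes[[k]], prod(grid), n_time)[m, , drop = FALSE]
    Ys[((k - 1) * n_time + 1):(k * n_time), ] <-
      t(pct_matrix(Yk, detrend_order, voxel_ids = which(m))) / 100
  }
  XtY <- crossprod(X, Ys)
  yty <- colSums(Ys^2)

  # paths are cut short once the support is too large for BIC to ever
  # prefer it (a k-coefficient noise fit gains ~k/n in log-RSS but pays
  # k*log(n)/n > k/n in penalty), which avoids the expensive path tail
  ms <- max_support %||% (n_time %/% 3)
  ms <- if (is.finite(ms)) as.integer(ms) else -1L
  fit <- mespfm_batch(XtY, G, yty, nrow(X), n_lambda, lambda_min_ratio,
                      tol, debias_rss = identical(bic_rss, "debiased"),
                      max_support = ms)

  estimates <- matrix(0, prod(grid), n_time)
  estimates[m, ] <- t(fit$estimates)
  to_map <- function(v) {
    out <- array(NA_real_, grid)
    out[m] <- v
    out
  }
  structure(
    list(
      estimates = estimates, mask = array(m, grid), grid = grid,
      lambda = to_map(as.numeric(fit$lambda)),
      bic = to_map(as.numeric(fit$bic)),
      support = to_map(as.numeric(fit$support)),
      tes_ms = series$tes_ms, tr_ms = series$tr_ms, hrf = hrf,
      detrend_order = detrend_order, bic_rss = bic_rss
    ),
    class = "decon_result"
  )
}

# multi-echo design with columns residualised against the Legendre drift basis
residualised_design <- function(hrf, n_time, tes, detrend_order) {
  H <- unclass(build_convolution_operator(hrf, n_time))
  if (detrend_order >= 0) {
    Q <- legendre_q(n_time, detrend_order)
    H <- H - Q %*% (t(Q) %*% H)
  }
  unclass(multiecho_design(H, tes))
}

#' @export
print.decon_result <- function(x, ...) {
  cat(sprintf(
    "<decon_result: grid %s, T = %d, %d masked voxels, %d with events, BIC on %s RSS>\n",
    paste(x$grid, collapse = "x"), ncol(x$estimates), sum(x$mask),
    sum(x$support > 0, na.rm = TRUE), x$bic_rss
  ))
  invisible(x)
}
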