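#' Legendre polynomial basis on a time grid
#'
#' Basis columns are Legendre polynomials P_0..P_order evaluated on T points
#' equally spaced over `-1..1`; used as the slow-drift nuisance basis for
#' detrending.
#'
#' @param n_time Number of timepoints.
#' @param order Highest polynomial order (>= 0).
#' @return A `n_time x (order + 1)` matrix.
#' @export
legendre_basis <- function(n_time, order) {
  stopifnot(n_time >= 2, order >= 0)
  x <- seq(-1, 1, length.out = n_time)
  B <- matrix(0, n_time, order + 1)
  B[, 1] <- 1
  if (order >= 1) B[, 2] <- x
  if (order >= 2) {
    for (k in 1:(order - 1)) {
      B[, k + 2] <- ((2 * k + 1) * x * B[, k + 1] - k * B[, k]) / (k + 1)
    }
  }
  B
}

# orthonormal column space of the Legendre basis
legendre_q <- function(n_time, order) {
  qr.Q(qr(legendre_basis(n_time, order)))
}

# rows of Y minus their projection on span(Q)
project_out <- function(Y, Q) {
  Y - (Y %*% Q) %*% t(Q)
}

#' Percent signal change with polynomial detrending
#'
#' Converts raw fMRI timeseries to percent signal change: per voxel, a Legendre
#' polynomial trend of order `detrend_order` is removed and the residual is
#' divided by the temporal mean of the raw series and scaled by 100. After
#' detrending (order >= 0 always includes the constant) every voxel timeseries
#' has zero temporal mean.
#'
#' @param x One echo as a 4D array (X x Y x Z x T) or a voxel-by-time matrix.
#' @param detrend_order Polynomial order of the drift model (default 4).
#' @param mask Optional logical/0-1 3D array (for 4D input) or logical vector
#'   (for matrix input); voxels outside the mask are returned as all zeros.
#' @return Object shaped like `x` (class `pct_series` attributes
#'   `detrend_order`), in percent units.
#' @export
percent_signal_change <- function(x, detrend_order = 4, mask = NULL) {
  if (is.array(x) && length(dim(x)) == 4) {
    d <- dim(x)
    Y <- matrix(x, prod(d[1:3]), d[4])
    m <- if (is.null(mask)) rep(TRUE, nrow(Y)) else as.logical(mask)
    out <- matrix(0, nrow(Y), ncol(Y))
    out[m, ] <- pct_matrix(Y[m, , drop = FALSE], detrend_order,
                           voxel_ids = which(m))
    res <- array(out, d)
  } else {
    Y <- as.matrix(x)
    m <- if (is.null(mask)) rep(TRUE, nrow(Y)) else as.logical(mask)
    res <- matrix(0, nrow(Y), ncol(Y))
    res[m, ] <- pct_matrix(Y[m, , drop = FALSE], detrend_order,
                           voxel_ids = which(m))
  }
  structure(res, detrend_order = detrend_order, class = c("pct_series", class(res)))
}

pct_matrix <- function(Y, detrend_order, voxel_ids = seq_len(nrow(Y))) {
  if (nrow(Y) == 0) return(Y)
  mu <- rowMeans(Y)
  bad <- abs(mu) < .Machine$double.eps^0.5
  if (any(bad)) {
    abort(sprintf(
      "voxel(s) with zero temporal mean inside the mask: %s",
      paste(utils::head(voxel_ids[bad], 5), collapse = ", ")
    ), class = "urgepfm_degenerate_voxel_error")
  }
  Q <- legendre_q(ncol(Y), detrend_order)
  resid <- project_out(Y, Q)
  100 * resid / mu
}
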