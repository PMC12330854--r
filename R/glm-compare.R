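#' First-level design matrix with parametric urge and blink regressors
#'
#' Builds the 10-column design: boxcar regressors for the Random, Okay and
#' Suppress blocks; a parametric urge regressor (one 1 s impulse per
#' experimental second, weighted by the standardised urge score); a blink
#' regressor from blink onsets/durations; each convolved with the double-gamma
#' HRF; plus one temporal-derivative column per base regressor (first
#' differences of the convolved regressor, zero prepended). Regressors are
#' constructed on a fine `dt` grid, convolved there, and sampled at the volume
#' acquisition times.
#'
#' @param schedule A [make_block_schedule()] tibble.
#' @param urge_z Standardised urge at 1 Hz, as returned by
#'   [downsample_standardise()]: tibble with `time_s`, `urge_z`, `group`; only
#'   the experimental-group rows enter the parametric regressor (Random-period
#'   ratings are removed).
#' @param blinks A `blink_train` tibble (`onset`, `duration`, seconds).
#' @param tr Repetition time, ms.
#' @param dt Neural-grid resolution in seconds (default 0.1).
#' @param hrf_params Optional list of double-gamma parameters overriding the
#'   canonical defaults (passed to [canonical_hrf()]).
#' @return A T x 10 matrix of class `design_matrix` with column names
#'   `Random`, `Okay`, `Suppress`, `Urge`, `Blink` and `d_*` partners;
#'   attributes `tr_ms`, `times`.
#' @export
build_design_matrix <- function(schedule, urge_z, blinks, tr = 1800,
                                dt = 0.1, hrf_params = list()) {
  run_length <- attr(schedule, "run_length")
  if (nrow(blinks) && any(blinks$onset < 0 |
                          blinks$onset + blinks$duration > run_length)) {
    abort("blink events fall outside the run", class = "urgepfm_event_error")
  }
  tr_s <- tr / 1000
  n_vol <- floor(run_length / tr_s)
  vol_times <- (seq_len(n_vol) - 1) * tr_s
  fine <- seq(0, run_length - dt, by = dt)
  nf <- length(fine)

  box <- function(onsets, durations, weights = 1) {
    x <- numeric(nf)
    w <- rep_len(weights, length(onsets))
    for (i in seq_along(onsets)) {
      a <- onsets[i]
      b <- onsets[i] + max(durations[i], dt)
      sel <- fine >= a & fine < b
      x[sel] <- x[sel] + w[i]
    }
    x
  }

  neural <- list(
    Random = box(schedule$onset[schedule$trial_type == "Random"],
                 schedule$duration[schedule$trial_type == "Random"]),
    Okay = box(schedule$onset[schedule$trial_type == "Okay"],
               schedule$duration[schedule$trial_type == "Okay"]),
    Suppress = box(schedule$onset[schedule$trial_type == "Suppress"],
                   schedule$duration[schedule$trial_type == "Suppress"])
  )
  uz <- urge_z[urge_z$group == "experimental", , drop = FALSE]
  neural$Urge <- box(uz$time_s, rep(1, nrow(uz)), weights = uz$urge_z)
  neural$Blink <- if (nrow(blinks)) box(blinks$onset, blinks$duration) else numeric(nf)

  hrf <- do.call(canonical_hrf, c(list(tr = dt * 1000), hrf_params))
  k <- hrf$kernel
  at_vols <- pmin(nf, round(vol_times / dt) + 1)
  base <- vapply(neural, function(x) {
    conv <- convolve_causal(x, k)
    conv[at_vols]
  }, numeric(n_vol))
  deriv <- apply(base, 2, function(col) c(0, diff(col)))
  colnames(deriv) <- paste0("d_", colnames(base))
  X <- cbind(base, deriv)
  structure(X, tr_ms = tr, times = vol_times,
            class = c("design_matrix", "matrix", "array"))
}

# full causal discrete convolution, truncated to the input length
convolve_causal <- function(x, kernel) {
  nk <- length(kernel)
  xp <- c(numeric(nk - 1), x)
  out <- stats::filter(xp, kernel, method = "convolution", sides = 1)
  as.numeric(out[(nk - 1) + seq_along(x)])
}

#' Voxelwise ordinary least squares with a contrast
#'
#' Fits `y = X b + e` per voxel by OLS, computes the contrast effect
#' `c'b`, its t statistic from the residual variance, converts t to a
#' standard-normal Z (tail-accurate), and binarizes at `threshold`.
#'
#' @param data Voxel-by-time matrix (percent-change units) or 4D array.
#' @param design A [build_design_matrix()] matrix (T x p, full column rank).
#' @param contrast Numeric contrast vector of length p, or a named vector
#'   whose names match design columns (unnamed entries 0).
#' @param threshold Z threshold for the binarized map (default 3.2).
#' @return Object of class `contrast_result`: list with `effect`, `z`
#'   (numeric per voxel), `mask` (logical, `z >= threshold`), `contrast`,
#'   `df`, `threshold`.
#' @export
fit_glm <- function(data, design, contrast, threshold = 3.2) {
  if (is.array(data) && length(dim(data)) == 4) {
    d <- dim(data)
    data <- matrix(data, prod(d[1:3]), d[4])
  }
  X <- unclass(design)
  p <- ncol(X)
  if (ncol(data) != nrow(X)) {
    abort("data and design disagree on the number of timepoints",
          class = "urgepfm_parameter_error")
  }
  contrast <- expand_contrast(contrast, colnames(X), p)
  if (all(contrast == 0)) {
    abort("contrast vector is all zeros", class = "urgepfm_parameter_error")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]] %||%
      qx$pivot[(qx$rank + 1):p]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")),
          class = "urgepfm_design_error")
  }
  XtXi <- chol2inv(qr.R(qx))
  B <- XtXi %*% crossprod(X, t(data)) # p x V
  fitted <- X %*% B
  rss <- colSums((t(data) - fitted)^2)
  df <- nrow(X) - p
  sigma2 <- rss / df
  effect <- as.numeric(crossprod(contrast, B))
  se <- sqrt(as.numeric(crossprod(contrast, XtXi %*% contrast)) * sigma2)
  tstat <- effect / se
  z <- t_to_z(tstat, df)
  structure(
    list(effect = effect, t = tstat, z = z, mask = z >= threshold,
         contrast = contrast, df = df, threshold = threshold),
    class = "contrast_result"
  )
}

expand_contrast <- function(contrast, nms, p) {
  if (!is.null(names(contrast)) && any(names(contrast) != "")) {
    out <- stats::setNames(numeric(p), nms)
    missing <- setdiff(names(contrast), nms)
    if (length(missing)) {
      abort(paste0("unknown contrast columns: ", paste(missing, collapse = ", ")),
            class = "urgepfm_parameter_error")
    }
    out[names(contrast)] <- contrast
    as.numeric(out)
  } else {
    if (length(contrast) != p) {
      abort("contrast length does not match the design",
            class = "urgepfm_parameter_error")
    }
    as.numeric(contrast)
  }
}

# tail-accurate t -> Z conversion; antisymmetric in t by construction
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  neg <- t < 0
  z[neg] <- qnorm(pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -qnorm(pt(-t[!neg], df, log.p = TRUE), log.p = TRUE)
  z
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result: %d voxels, %d with Z >= %.1f, df = %d>\n",
              length(x$z), sum(x$mask), x$threshold, x$df))
  invisible(x)
}

#' Conjunction of two thresholded masks
#'
#' Voxelwise logical AND of two binary maps on the same grid.
#'
#' @param mask_a,mask_b Logical arrays/vectors of identical dimensions.
#' @return Logical array of the same shape.
#' @export
conjunction <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a) %||% length(mask_a),
                 dim(mask_b) %||% length(mask_b))) {
    abort("masks are on different grids", class = "urgepfm_parameter_error")
  }
  mask_a & mask_b
}

#' Overlap metrics between a cluster mask and a GLM mask
#'
#' Reports voxel counts and three set-overlap summaries: the percentage of
#' the GLM mask covered by the intersection (`100 * |A int B| / |B|` with B
#' the GLM mask), the Jaccard index `|A int B| / |A u B)|` and the Dice
#' coefficient `2 |A int B| / (|A| + |B|)` (identically `2J / (1 + J)`).
#'
#' @param mespfm_mask,glm_mask Logical arrays/vectors on the same grid.
#' @return A one-row tibble: `n_mespfm`, `n_glm`, `n_intersect`,
#'   `percent_overlap`, `jaccard`, `dice`.
#' @export
overlap_metrics <- function(mespfm_mask, glm_mask) {
  if (!identical(dim(mespfm_mask) %||% length(mespfm_mask),
                 dim(glm_mask) %||% length(glm_mask))) {
    abort("masks are on different grids", class = "urgepfm_parameter_error")
  }
  a <- sum(mespfm_mask)
  b <- sum(glm_mask)
  i <- sum(mespfm_mask & glm_mask)
  u <- a + b - i
  if (b == 0) {
    warn("empty GLM mask: percent overlap undefined",
         class = "urgepfm_empty_mask_warning")
  }
  tibble(
    n_mespfm = a, n_glm = b, n_intersect = i,
    percent_overlap = if (b > 0) 100 * i / b else NA_real_,
    jaccard = if (u > 0) i / u else NA_real_,
    dice = if (a + b > 0) 2 * i / (a + b) else NA_real_
  )
}

#' Overlap table of cluster maps against GLM maps
#'
#' Crosses every positive cluster mask with every named GLM mask and reports
#' the overlap metrics per pair, mirroring the cluster-by-contrast comparison
#' layout.
#'
#' @param zmaps A [cluster_zmaps()] object.
#' @param glm_masks Named list of logical masks (e.g. Suppression/Urge/Blink).
#' @return Tibble with `cluster`, `glm_map` and the [overlap_metrics()]
#'   columns.
#' @export
overlap_table <- function(zmaps, glm_masks) {
  purrr::map_dfr(zmaps$clusters, function(cl) {
    purrr::imap_dfr(glm_masks, function(gm, nm) {
      dplyr::bind_cols(
        tibble(cluster = cl$cluster, glm_map = nm),
        overlap_metrics(cl$positive_mask, as.logical(gm))
      )
    })
  })
}
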