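#' Sliding-window temporal maximum-magnitude filter
#'
#' Replaces each deconvolved value by the value of largest absolute magnitude
#' (sign retained) within a centred temporal window of `window` samples
#' (default 3: the sample and its two neighbours). Boundary windows are
#' truncated. Applying the filter widens isolated spikes by one sample per
#' side and never changes magnitudes.
#'
#' @param x A voxel-by-time matrix or a `decon_result` (its `estimates` are
#'   filtered).
#' @param window Odd window length (default 3).
#' @return A voxel-by-time matrix of filtered values.
#' @export
temporal_max_filter <- function(x, window = 3) {
  if (inherits(x, "decon_result")) x <- x$estimates
  if (window %% 2 == 0 || window < 1) {
    abort("window must be odd and positive", class = "urgepfm_parameter_error")
  }
  half <- (window - 1) / 2
  n_t <- ncol(x)
  out <- x
  for (s in setdiff(-half:half, 0)) {
    src <- seq_len(n_t) + s
    ok <- src >= 1 & src <= n_t
    cand <- x[, src[ok], drop = FALSE]
    cur <- out[, ok, drop = FALSE]
    swap <- abs(cand) > abs(cur)
    cur[swap] <- cand[swap]
    out[, ok] <- cur
  }
  out
}

#' Minimum-cluster-size spatial mask, per timepoint
#'
#' Labels the connected components of nonzero voxels in every volume of the
#' (temporally filtered) deconvolution and removes components smaller than
#' `min_size` voxels. The surviving spatiotemporal mask is meant to be applied
#' to the *unfiltered* estimates (see [apply_event_mask()]).
#'
#' @param filtered Voxel-by-time matrix (typically from
#'   [temporal_max_filter()]).
#' @param grid Integer grid dimensions (nx, ny, nz).
#' @param min_size Minimum cluster size in voxels (default 10).
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return Logical voxel-by-time matrix.
#' @export
spatial_cluster_mask <- function(filtered, grid, min_size = 10,
                                 connectivity = 6) {
  if (min_size < 1) {
    abort("min_size must be >= 1", class = "urgepfm_parameter_error")
  }
  if (!connectivity %in% c(6, 18, 26)) {
    abort("connectivity must be 6, 18 or 26", class = "urgepfm_parameter_error")
  }
  nz <- matrix(as.integer(filtered != 0), nrow(filtered), ncol(filtered))
  cluster_size_filter(nz, as.integer(grid), as.integer(min_size),
                      as.integer(connectivity))
}

#' Apply a spatiotemporal mask to deconvolution estimates
#'
#' @param decon A `decon_result` or voxel-by-time matrix.
#' @param mask Logical voxel-by-time matrix from [spatial_cluster_mask()].
#' @return Voxel-by-time matrix: estimates where the mask is TRUE, else 0.
#' @export
apply_event_mask <- function(decon, mask) {
  est <- if (inherits(decon, "decon_result")) decon$estimates else decon
  est * mask
}

#' Activation timeseries
#'
#' Counts, per timepoint, the voxels whose deconvolved coefficient is negative
#' (a negative delta-R2* produces a positive BOLD response under the
#' multi-echo model).
#'
#' @param masked Voxel-by-time matrix of (masked) deconvolution estimates.
#' @param threshold Optional count threshold to attach (e.g. the surrogate
#'   median).
#' @return Object of class `ats_series`: list with `counts` (integer, length
#'   T), `threshold` (or NULL) and `peaks` (supra-threshold peak timepoints,
#'   or NULL when no threshold is given).
#' @export
compute_ats <- function(masked, threshold = NULL) {
  counts <- as.integer(colSums(masked < 0))
  peaks <- if (!is.null(threshold)) find_ats_peaks(counts, threshold)
  structure(list(counts = counts, threshold = threshold, peaks = peaks),
            class = "ats_series")
}

#' Supra-threshold peaks of an activation timeseries
#'
#' A peak is the maximum of each maximal segment of timepoints whose counts
#' are strictly above the threshold; if the segment maximum is attained on a
#' plateau, the plateau midpoint is returned (the earlier sample when the
#' plateau has even length).
#'
#' @param counts Integer vector of per-timepoint voxel counts.
#' @param threshold Count threshold (strict comparison).
#' @return Integer vector of peak timepoints (1-based).
#' @export
find_ats_peaks <- function(counts, threshold) {
  supra <- counts > threshold
  if (!any(supra)) return(integer(0))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- which(r$values)
  vapply(segs, function(s) {
    idx <- starts[s]:ends[s]
    m <- max(counts[idx])
    at <- idx[counts[idx] == m]
    # first contiguous plateau of the maximum, resolved to its midpoint
    plateau <- at[seq_len(match(FALSE, diff(at) == 1, nomatch = length(at)))]
    plateau[ceiling(length(plateau) / 2)]
  }, integer(1))
}

#' @export
print.ats_series <- function(x, ...) {
  cat(sprintf(
    "<ats_series: T = %d, max count %d%s%s>\n",
    length(x$counts), max(x$counts),
    if (!is.null(x$threshold)) sprintf(", threshold %.1f", x$threshold) else "",
    if (!is.null(x$peaks)) sprintf(", %d peak(s)", length(x$peaks)) else ""
  ))
  invisible(x)
}

#' @rdname tidy-urgepfm
#' @method tidy ats_series
#' @export
tidy.ats_series <- function(x, ...) {
  tibble(
    t = seq_along(x$counts),
    count = x$counts,
    is_peak = seq_along(x$counts) %in% (x$peaks %||% integer(0))
  )
}

#' @rdname autoplot-urgepfm
#' @method autoplot ats_series
#' @export
autoplot.ats_series <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "volume", y = "positive-BOLD voxels") +
    ggplot2::theme_minimal()
  if (!is.null(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = 2, colour = "red")
  }
  if (length(object$peaks %||% integer(0))) {
    p <- p + ggplot2::geom_point(data = df[df$is_peak, ], colour = "red")
  }
  p
}

#' Surrogate null for the activation timeseries
#'
#' Draws one random permutation of the volume order (shared across voxels and
#' echoes), applies it to the raw data *before* percent-change computation,
#' and reruns the full detection pipeline (percent change, deconvolution,
#' temporal max filter, spatial cluster filter, ATS). The surrogate preserves
#' each voxel's value distribution while destroying temporal structure; the
#' detection threshold is the median of the surrogate ATS counts (zeros
#' included).
#'
#' @param series A `multiecho_series`, already trimmed to the experimental
#'   segment (see [trim_random_pads()]).
#' @param mask Analysis mask (default: series brain mask).
#' @param hrf HRF model (default: canonical at the series TR).
#' @param seed Integer seed for the permutation draw (one draw per run).
#' @param detrend_order,window,min_size,connectivity,... Pipeline settings,
#'   passed to [deconvolve_run()] and the filtering steps.
#' @return Object of class `surrogate_result`: list with `permutation`,
#'   `seed`, `ats` (an `ats_series`), `threshold` (median surrogate count),
#'   `masked` (surrogate masked estimates, voxel x T), `grid`.
#' @export
surrogate_threshold <- function(series, mask = series$brain_mask,
                                hrf = canonical_hrf(series$tr_ms),
                                seed = 1L,
                                detrend_order = 4, window = 3,
                                min_size = 10, connectivity = 6, ...) {
  n_time <- dim(series$echoes[[1]])[4]
  perm <- withr::with_seed(seed, sample.int(n_time))
  shuffled <- series
  shuffled$echoes <- lapply(series$echoes, function(e) {
    e[, , , perm, drop = FALSE]
  })
  decon <- deconvolve_run(shuffled, mask = mask, hrf = hrf,
                          detrend_order = detrend_order, ...)
  filt <- temporal_max_filter(decon, window)
  stmask <- spatial_cluster_mask(filt, decon$grid, min_size, connectivity)
  masked <- apply_event_mask(decon, stmask)
  ats <- compute_ats(masked)
  threshold <- median(ats$counts)
  ats$threshold <- threshold
  ats$peaks <- find_ats_peaks(ats$counts, threshold)
  structure(
    list(permutation = perm, seed = seed, ats = ats, threshold = threshold,
         masked = masked, grid = decon$grid),
    class = "surrogate_result"
  )
}

#' Select event peaks within a region of interest
#'
#' Restricts the activation timeseries to the ROI, thresholds it at the median
#' of the ROI-restricted *surrogate* ATS (strict comparison) and returns one
#' peak per maximal supra-threshold segment (see [find_ats_peaks()]), together
#' with the 3D activation map of estimates at each peak. An empty result is
#' valid: not every run shows ROI activation above the surrogate threshold.
#'
#' @param ats The run's global `ats_series` (kept for provenance; the ROI
#'   counts are recomputed from `masked`).
#' @param masked Voxel-by-time matrix of masked deconvolution estimates.
#' @param roi_mask Logical 3D array (must lie within the brain mask and be
#'   non-empty).
#' @param surrogate A [surrogate_threshold()] result for the same run.
#' @return Object of class `event_set`: list with `peaks` (tibble `peak_tr`,
#'   `roi_count`), `maps` (list of 3D arrays of estimates), `roi_counts`,
#'   `roi_threshold`, `grid`.
#' @export
select_roi_peaks <- function(ats, masked, roi_mask, surrogate) {
  grid <- surrogate$grid
  roi <- as.logical(roi_mask)
  if (!any(roi)) {
    abort("ROI mask is empty", class = "urgepfm_parameter_error")
  }
  roi_counts <- as.integer(colSums(masked[roi, , drop = FALSE] < 0))
  surr_counts <- as.integer(colSums(surrogate$masked[roi, , drop = FALSE] < 0))
  thr <- median(surr_counts)
  pk <- find_ats_peaks(roi_counts, thr)
  maps <- lapply(pk, function(t) array(masked[, t], grid))
  structure(
    list(
      peaks = tibble(peak_tr = pk, roi_count = roi_counts[pk]),
      maps = maps, roi_counts = roi_counts, roi_threshold = thr,
      grid = grid
    ),
    class = "event_set"
  )
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf(
    "<event_set: %d peak(s) above ROI threshold %.1f>\n",
    nrow(x$peaks), x$roi_threshold
  ))
  invisible(x)
}

#' Run the full timing-free event-detection pipeline on one run
#'
#' Convenience wrapper: deconvolve the (trimmed) run, temporally filter,
#' remove sub-threshold spatial clusters, compute the activation timeseries,
#' build the surrogate null, and select ROI peaks.
#'
#' @inheritParams surrogate_threshold
#' @param roi_mask Logical 3D ROI array.
#' @param seed Seed for the surrogate permutation.
#' @return List with `decon`, `masked`, `ats` (thresholded, with peaks),
#'   `surrogate`, `events` (an `event_set`).
#' @export
detect_events <- function(series, roi_mask,
                          mask = series$brain_mask,
                          hrf = canonical_hrf(series$tr_ms),
                          seed = 1L,
                          detrend_order = 4, window = 3,
                          min_size = 10, connectivity = 6, ...) {
  decon <- deconvolve_run(series, mask = mask, hrf = hrf,
                          detrend_order = detrend_order, ...)
  filt <- temporal_max_filter(decon, window)
  stmask <- spatial_cluster_mask(filt, decon$grid, min_size, connectivity)
  masked <- apply_event_mask(decon, stmask)
  surrogate <- surrogate_threshold(series, mask = mask, hrf = hrf, seed = seed,
                                   detrend_order = detrend_order,
                                   window = window, min_size = min_size,
                                   connectivity = connectivity, ...)
  ats <- compute_ats(masked, threshold = surrogate$threshold)
  events <- select_roi_peaks(ats, masked, roi_mask, surrogate)
  list(decon = decon, masked = masked, ats = ats,
       surrogate = surrogate, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
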