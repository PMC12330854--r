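#' Ground truth for a multi-echo phantom
#'
#' Lays out cuboid ROIs on a small voxel grid and plants sparse neuronal
#' events (delta-R2* impulses, negative values = positive BOLD) at random TRs
#' within each ROI. All voxels of an ROI share its event train, so a planted
#' event produces a spatial cluster the size of the ROI.
#'
#' @param grid Integer vector (nx, ny, nz); default 20 x 20 x 10.
#' @param n_time Number of volumes T.
#' @param n_rois Number of cuboid ROIs (1-4).
#' @param roi_dim Cuboid dimensions in voxels (default 4 x 4 x 3 = 48 voxels).
#' @param events_per_roi Events planted in each ROI.
#' @param amplitude Event amplitude, delta-R2* in 1/s (negative = positive
#'   BOLD). Scalar or one value per ROI.
#' @param noise_sd Gaussian noise SD in percent-signal units.
#' @param drift_order,drift_sd Order of the global Legendre drift and the SD
#'   (percent units) of its random coefficients.
#' @param min_onset,max_onset_margin Planted onsets are drawn from TRs
#'   `min_onset .. n_time - max_onset_margin` (1-based), at least
#'   `min_separation` TRs apart within an ROI; the upper margin keeps the
#'   haemodynamic response inside the run.
#' @param min_separation Minimum TR separation of events within an ROI.
#' @param seed Optional integer seed.
#' @return An object of class `ground_truth`: list with `grid`, `roi_labels`
#'   (3D integer array, 0 = background), `events` (tibble `roi`, `onset_tr`
#'   1-based, `amplitude`), `noise_sd`, `drift_order`, `drift_coef`, `n_time`.
#' @export
make_ground_truth <- function(grid = c(20, 20, 10),
                              n_time = 200,
                              n_rois = 4,
                              roi_dim = c(4, 4, 3),
                              events_per_roi = 3,
                              amplitude = -2.5,
                              noise_sd = 0.5,
                              drift_order = 2,
                              drift_sd = 0.15,
                              min_onset = 6,
                              max_onset_margin = 20,
                              min_separation = 12,
                              seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, make_ground_truth(
      grid, n_time, n_rois, roi_dim, events_per_roi, amplitude, noise_sd,
      drift_order, drift_sd, min_onset, max_onset_margin, min_separation
    )))
  }
  stopifnot(length(grid) == 3, n_rois >= 1, n_rois <= 4)
  if (any(roi_dim + 1 > grid)) {
    abort("ROI cuboids do not fit the grid", class = "urgepfm_parameter_error")
  }
  labels <- array(0L, grid)
  lo <- pmax(1L, round(0.15 * grid))
  hi <- pmin(grid - roi_dim + 1L, round(0.62 * grid))
  corners <- list(
    c(lo[1], lo[2], lo[3]), c(hi[1], lo[2], lo[3]),
    c(lo[1], hi[2], hi[3]), c(hi[1], hi[2], hi[3])
  )
  for (r in seq_len(n_rois)) {
    cc <- corners[[r]]
    labels[cc[1]:(cc[1] + roi_dim[1] - 1),
           cc[2]:(cc[2] + roi_dim[2] - 1),
           cc[3]:(cc[3] + roi_dim[3] - 1)] <- r
  }
  amplitude <- rep_len(amplitude, n_rois)
  hi_t <- n_time - max_onset_margin
  if (hi_t < min_onset) {
    abort("run too short for the requested onset margins",
          class = "urgepfm_parameter_error")
  }
  events <- purrr::map_dfr(seq_len(n_rois), function(r) {
    onsets <- draw_separated(min_onset, hi_t, events_per_roi, min_separation)
    tibble(roi = r, onset_tr = onsets, amplitude = amplitude[r])
  })
  if (any(events$onset_tr < 1 | events$onset_tr > n_time)) {
    abort("planted onsets fall outside the run", class = "urgepfm_parameter_error")
  }
  structure(
    list(
      grid = grid, roi_labels = labels, events = events,
      noise_sd = noise_sd, drift_order = drift_order,
      drift_coef = if (drift_order > 0) rnorm(drift_order, 0, drift_sd) else numeric(0),
      n_time = as.integer(n_time)
    ),
    class = "ground_truth"
  )
}

# sample n integers in [lo, hi] pairwise >= sep apart (sequential rejection)
draw_separated <- function(lo, hi, n, sep) {
  if (n == 0) return(integer(0))
  picked <- integer(0)
  for (tries in seq_len(5000)) {
    cand <- sample(lo:hi, 1)
    if (all(abs(cand - picked) >= sep)) picked <- c(picked, cand)
    if (length(picked) == n) return(sort(picked))
  }
  abort("could not place events with the requested separation",
        class = "urgepfm_parameter_error")
}

#' Event amplitude for a target contrast-to-noise ratio
#'
#' Returns the delta-R2* amplitude (negative, 1/s) whose peak percent-signal
#' change at the reference echo equals `cnr * noise_sd`.
#'
#' @param cnr Target peak-amplitude-to-noise ratio.
#' @param noise_sd Noise SD in percent units.
#' @param hrf HRF from [canonical_hrf()].
#' @param te_ms Reference echo time in ms (default 35, the middle echo).
#' @return Negative scalar, delta-R2* in 1/s.
#' @export
amplitude_for_cnr <- function(cnr, noise_sd, hrf, te_ms = 35) {
  peak_pct_per_unit <- (te_ms / 1000) * max(hrf$kernel) * 100
  -cnr * noise_sd / peak_pct_per_unit
}

#' Simulate one multi-echo run from planted ground truth
#'
#' For each echo k the noiseless fractional signal change is
#' `-TE_k * (H s)(t)` where `s` is the planted delta-R2* impulse train and `H`
#' the HRF convolution; the raw signal is the voxel mean image scaled by
#' `1 + (pct + drift + noise) / 100` with drift and noise in percent units.
#' Percent-change traces of any two echoes are therefore proportional with
#' ratio TE_j / TE_i in the noiseless case, and a negative planted delta-R2*
#' yields a positive BOLD deflection.
#'
#' @param truth A [make_ground_truth()] object.
#' @param hrf HRF from [canonical_hrf()]; its TR must match `tr`.
#' @param tes Echo times in ms (strictly increasing; default 12/35/58).
#' @param tr Repetition time in ms (default 1800).
#' @param seed Optional integer seed for noise.
#' @param schedule Optional [make_block_schedule()] attached for later
#'   trimming; when supplied, `truth$n_time` must equal the number of whole
#'   volumes in the run.
#' @return Object of class `multiecho_series`: list with `echoes` (list of 4D
#'   arrays), `tes_ms`, `tr_ms`, `times` (volume acquisition times, s),
#'   `mean_image`, `brain_mask`, `truth`, `schedule`.
#' @export
simulate_multiecho_run <- function(truth,
                                   hrf = canonical_hrf(tr),
                                   tes = c(12, 35, 58),
                                   tr = 1800,
                                   seed = NULL,
                                   schedule = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, simulate_multiecho_run(truth, hrf, tes, tr, schedule = schedule)
    ))
  }
  check_tes(tes)
  tr_s <- tr / 1000
  n_time <- truth$n_time
  if (!is.null(schedule)) {
    n_run <- floor(attr(schedule, "run_length") / tr_s)
    if (n_run != n_time) {
      abort(sprintf(
        "truth has %d volumes but the schedule implies %d", n_time, n_run
      ), class = "urgepfm_parameter_error")
    }
  }
  grid <- truth$grid
  n_vox <- prod(grid)
  H <- build_convolution_operator(hrf, n_time)

  # per-ROI convolved delta-R2* timecourse
  n_rois <- max(truth$roi_labels)
  roi_pct1 <- matrix(0, n_rois, n_time) # percent change per unit TE(s)
  for (r in seq_len(n_rois)) {
    ev <- truth$events[truth$events$roi == r, ]
    if (nrow(ev) == 0) next
    train <- numeric(n_time)
    train[ev$onset_tr] <- ev$amplitude
    roi_pct1[r, ] <- -100 * as.numeric(unclass(H) %*% train)
  }

  mean_image <- array(
    800 + 40 * (slice.index(array(0, grid), 1) / grid[1] +
                slice.index(array(0, grid), 2) / grid[2] +
                slice.index(array(0, grid), 3) / grid[3]),
    grid
  )
  drift <- numeric(n_time)
  if (truth$drift_order > 0) {
    B <- legendre_basis(n_time, truth$drift_order)[, -1, drop = FALSE]
    drift <- as.numeric(B %*% truth$drift_coef)
  }

  lab_vec <- as.integer(truth$roi_labels)
  mu_vec <- as.numeric(mean_image)
  echoes <- lapply(tes, function(te) {
    pct <- matrix(0, n_vox, n_time)
    in_roi <- lab_vec > 0
    if (any(in_roi)) {
      pct[in_roi, ] <- (te / 1000) * roi_pct1[lab_vec[in_roi], , drop = FALSE]
    }
    pct <- sweep(pct, 2, drift, "+")
    if (truth$noise_sd > 0) {
      pct <- pct + matrix(rnorm(n_vox * n_time, 0, truth$noise_sd), n_vox, n_time)
    }
    array(mu_vec * (1 + pct / 100), c(grid, n_time))
  })

  structure(
    list(
      echoes = echoes, tes_ms = tes, tr_ms = tr,
      times = (seq_len(n_time) - 1) * tr_s,
      mean_image = mean_image,
      brain_mask = array(TRUE, grid),
      truth = truth, schedule = schedule
    ),
    class = "multiecho_series"
  )
}

#' @export
print.multiecho_series <- function(x, ...) {
  d <- dim(x$echoes[[1]])
  cat(sprintf(
    "<multiecho_series: %d echoes (TE %s ms), grid %s, T = %d, TR %g ms>\n",
    length(x$echoes), paste(x$tes_ms, collapse = "/"),
    paste(d[1:3], collapse = "x"), d[4], x$tr_ms
  ))
  invisible(x)
}

#' Trim the Random pads from a run
#'
#' Keeps only volumes acquired during the experimental segment (between the
#' opening and closing Random baselines), the input expected by the
#' deconvolution. Planted events are remapped to the trimmed time axis; events
#' in the pads are dropped.
#'
#' @param series A [simulate_multiecho_run()] object with a schedule (or pass
#'   `schedule` explicitly).
#' @param schedule Optional schedule overriding `series$schedule`.
#' @return A `multiecho_series` covering only the experimental volumes, with
#'   attribute `kept_volumes` (indices into the original run).
#' @export
trim_random_pads <- function(series, schedule = series$schedule) {
  if (is.null(schedule)) {
    abort("a block schedule is required to locate the Random pads",
          class = "urgepfm_parameter_error")
  }
  win <- experimental_window(schedule)
  keep <- which(series$times >= win["start"] & series$times < win["end"])
  out <- series
  out$echoes <- lapply(series$echoes, function(e) e[, , , keep, drop = FALSE])
  out$times <- series$times[keep]
  if (!is.null(series$truth)) {
    tr <- series$truth
    remap <- match(tr$events$onset_tr, keep)
    tr$events <- tr$events[!is.na(remap), , drop = FALSE]
    tr$events$onset_tr <- remap[!is.na(remap)]
    tr$n_time <- length(keep)
    out$truth <- tr
  }
  attr(out, "kept_volumes") <- keep
  out
}
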