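#' Write a simulated multi-echo run to disk
#'
#' Writes one 4D NIfTI per echo (`<prefix>_echo-1.nii.gz`, ...), the 3D mean
#' image and ROI label volume, the block schedule and blink train as
#' tab-separated events files (`onset`, `duration`, `trial_type`; seconds,
#' time origin at run start) and the urge trace as TSV (`time_s`, `urge`,
#' `condition`).
#'
#' @param series A [simulate_multiecho_run()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sim").
#' @param urge,blinks Optional behavioural objects from
#'   [simulate_urge_and_blinks()].
#' @return `dir`, invisibly.
#' @export
write_multiecho_run <- function(series, dir, prefix = "sim",
                                urge = NULL, blinks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(dir, paste0(prefix, "_", ...))
  tr_s <- series$tr_ms / 1000
  for (k in seq_along(series$echoes)) {
    RNifti::writeNifti(
      RNifti::asNifti(series$echoes[[k]], pixdim = c(3, 3, 3, tr_s)),
      path(sprintf("echo-%d.nii.gz", k))
    )
  }
  RNifti::writeNifti(RNifti::asNifti(series$mean_image), path("mean.nii.gz"))
  if (!is.null(series$truth)) {
    RNifti::writeNifti(RNifti::asNifti(series$truth$roi_labels + 0),
                       path("roi-labels.nii.gz"))
  }
  if (!is.null(series$schedule)) {
    readr::write_tsv(
      as_tibble(series$schedule)[, c("onset", "duration", "trial_type")],
      path("schedule_events.tsv")
    )
  }
  if (!is.null(blinks)) {
    ev <- as_tibble(blinks)[, c("onset", "duration")]
    ev$trial_type <- "blink"
    readr::write_tsv(ev, path("blink_events.tsv"))
  }
  if (!is.null(urge)) {
    readr::write_tsv(as_tibble(urge)[, c("time_s", "urge", "condition")],
                     path("urge.tsv"))
  }
  invisible(dir)
}

#' Read a multi-echo run from per-echo NIfTI files
#'
#' @param echo_files Character vector of per-echo 4D NIfTI paths, in echo
#'   order.
#' @param tes Echo times in ms.
#' @param tr Repetition time in ms.
#' @param mean_file,mask_file Optional 3D NIfTI paths; the mean image defaults
#'   to the temporal mean of the first echo and the mask to all voxels.
#' @return A `multiecho_series`.
#' @export
read_multiecho_run <- function(echo_files, tes, tr,
                               mean_file = NULL, mask_file = NULL) {
  check_tes(tes)
  if (length(echo_files) != length(tes)) {
    abort("one file per echo time is required", class = "urgepfm_parameter_error")
  }
  echoes <- lapply(echo_files, function(f) {
    a <- as.array(RNifti::readNifti(f))
    if (length(dim(a)) != 4) {
      abort(sprintf("%s is not a 4D volume", f), class = "urgepfm_io_error")
    }
    a
  })
  grid <- dim(echoes[[1]])[1:3]
  mean_image <- if (!is.null(mean_file)) {
    as.array(RNifti::readNifti(mean_file))
  } else {
    array(rowMeans(matrix(echoes[[1]], prod(grid))), grid)
  }
  brain_mask <- if (!is.null(mask_file)) {
    array(as.array(RNifti::readNifti(mask_file)) > 0, grid)
  } else {
    array(TRUE, grid)
  }
  structure(
    list(
      echoes = echoes, tes_ms = tes, tr_ms = tr,
      times = (seq_len(dim(echoes[[1]])[4]) - 1) * tr / 1000,
      mean_image = mean_image, brain_mask = brain_mask,
      truth = NULL, schedule = NULL
    ),
    class = "multiecho_series"
  )
}

#' Read an events TSV (onset, duration, trial_type)
#'
#' @param path File path.
#' @return Tibble with `onset`, `duration` (numeric, seconds) and
#'   `trial_type`.
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    onset = readr::col_double(),
                    duration = readr::col_double(),
                    .default = readr::col_character()
                  ))
}

#' Read an urge trace TSV
#'
#' @param path File path (columns `time_s`, `urge`, `condition`).
#' @param rate Sampling rate in Hz; inferred from the time stamps if omitted.
#' @return An `urge_trace` tibble.
#' @export
read_urge_tsv <- function(path, rate = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          time_s = readr::col_double(),
                          urge = readr::col_double(),
                          condition = readr::col_character()
                        ))
  class(df) <- c("urge_trace", class(df))
  attr(df, "rate") <- rate %||% infer_rate(df$time_s)
  df
}

#' Write deconvolution results as NIfTI maps
#'
#' Writes the voxel-by-time delta-R2* estimates as a 4D volume and the
#' selected-lambda, BIC and support-size maps as 3D volumes.
#'
#' @param decon A [deconvolve_run()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix (default "mespfm").
#' @return `dir`, invisibly.
#' @export
write_decon_nifti <- function(decon, dir, prefix = "mespfm") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(nm) file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
  RNifti::writeNifti(
    RNifti::asNifti(array(decon$estimates, c(decon$grid, ncol(decon$estimates)))),
    path("estimates")
  )
  for (nm in c("lambda", "bic", "support")) {
    m <- decon[[nm]]
    m[is.na(m)] <- 0
    RNifti::writeNifti(RNifti::asNifti(m), path(nm))
  }
  invisible(dir)
}

#' Write a detected event set to disk
#'
#' Peaks as TSV (`peak_tr`, `roi_count`), the ROI activation timeseries and
#' threshold as TSV, and one 3D NIfTI delta-R2* map per event.
#'
#' @param events An `event_set` from [select_roi_peaks()].
#' @param dir Output directory.
#' @param prefix File-name prefix (default "events").
#' @return `dir`, invisibly.
#' @export
write_event_set <- function(events, dir, prefix = "events") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(nm) file.path(dir, paste0(prefix, "_", nm))
  readr::write_tsv(events$peaks, path("peaks.tsv"))
  readr::write_tsv(
    tibble(t = seq_along(events$roi_counts), roi_count = events$roi_counts,
           threshold = events$roi_threshold),
    path("roi_ats.tsv")
  )
  for (i in seq_along(events$maps)) {
    RNifti::writeNifti(
      RNifti::asNifti(events$maps[[i]]),
      path(sprintf("map_t%03d.nii.gz", events$peaks$peak_tr[i]))
    )
  }
  invisible(dir)
}

#' Write an activation timeseries as TSV
#'
#' @param ats An `ats_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ats_tsv <- function(ats, path) {
  readr::write_tsv(tidy(ats), path)
  invisible(path)
}

#' Write cluster Z maps as NIfTI volumes
#'
#' Per cluster: the mean delta-R2* map, the spatial Z map, the sign-flipped
#' Z map and the binarized positive mask.
#'
#' @param zmaps A [cluster_zmaps()] object.
#' @param dir Output directory.
#' @param prefix File-name prefix (default "cluster").
#' @return `dir`, invisibly.
#' @export
write_cluster_zmaps <- function(zmaps, dir, prefix = "cluster") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as.logical(zmaps$mask)
  to_vol <- function(v) {
    out <- array(0, zmaps$grid)
    out[m] <- v
    out
  }
  for (cl in zmaps$clusters) {
    base <- file.path(dir, sprintf("%s%d", prefix, cl$cluster))
    RNifti::writeNifti(RNifti::asNifti(to_vol(cl$mean_map)),
                       paste0(base, "_mean.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(to_vol(cl$flipped_z)),
                       paste0(base, "_zflip.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(to_vol(as.numeric(cl$positive_mask))),
                       paste0(base, "_posmask.nii.gz"))
  }
  invisible(dir)
}
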