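#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: a gamma-density main lobe (response delay 6 s,
#' dispersion 1 s) minus a later gamma-density undershoot (delay 16 s,
#' dispersion 1 s) scaled by `1/ratio`. The kernel is sampled on the scan grid
#' (multiples of TR) and, by default, left unnormalised: its scale is absorbed
#' into the deconvolved R2* amplitudes and recorded in the model metadata.
#'
#' @param tr Repetition time in milliseconds.
#' @param length_s Kernel duration in seconds (default 32).
#' @param delay,undershoot_delay Delays (s) of response and undershoot.
#' @param dispersion,undershoot_dispersion Dispersions (s).
#' @param ratio Response-to-undershoot amplitude ratio.
#' @param normalise One of "none" (default) or "peak" (unit peak).
#' @return An object of class `hrf_model`: list with `kernel` (numeric),
#'   `tr_s`, `times` and the parameters.
#' @examples
#' h <- canonical_hrf(1800)
#' h$times[which.max(h$kernel)] # ~5.4 s on the 1.8 s grid
#' @export
canonical_hrf <- function(tr, length_s = 32,
                          delay = 6, undershoot_delay = 16,
                          dispersion = 1, undershoot_dispersion = 1,
                          ratio = 6,
                          normalise = c("none", "peak")) {
  if (!is.numeric(tr) || tr <= 0) {
    abort("TR must be a positive number of milliseconds",
          class = "urgepfm_parameter_error")
  }
  if (length_s < 20) {
    abort("HRF kernel length must be at least 20 s to contain the undershoot",
          class = "urgepfm_parameter_error")
  }
  normalise <- match.arg(normalise)
  tr_s <- tr / 1000
  times <- seq(0, length_s, by = tr_s)
  kernel <- double_gamma(times, delay, undershoot_delay,
                         dispersion, undershoot_dispersion, ratio)
  if (normalise == "peak") kernel <- kernel / max(kernel)
  structure(
    list(
      kernel = kernel, times = times, tr_s = tr_s,
      parameters = list(
        delay = delay, undershoot_delay = undershoot_delay,
        dispersion = dispersion,
        undershoot_dispersion = undershoot_dispersion,
        ratio = ratio, length_s = length_s, normalise = normalise
      )
    ),
    class = "hrf_model"
  )
}

# difference of gamma densities; vectorised over t (seconds)
double_gamma <- function(t, delay, undershoot_delay,
                         dispersion, undershoot_dispersion, ratio) {
  main <- stats::dgamma(t, shape = delay / dispersion, scale = dispersion)
  under <- stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                         scale = undershoot_dispersion)
  main - under / ratio
}

#' @export
print.hrf_model <- function(x, ...) {
  cat(sprintf(
    "<hrf_model: double-gamma, TR %.3g s, %d samples over %g s, peak %.4g at %g s>\n",
    x$tr_s, length(x$kernel), x$parameters$length_s,
    max(x$kernel), x$times[which.max(x$kernel)]
  ))
  invisible(x)
}

#' @rdname autoplot-urgepfm
#' @method autoplot hrf_model
#' @export
autoplot.hrf_model <- function(object, ...) {
  ggplot2::ggplot(tibble(t = object$times, h = object$kernel)) +
    ggplot2::geom_line(ggplot2::aes(.data$t, .data$h)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "time (s)", y = "response") +
    ggplot2::theme_minimal()
}

#' HRF convolution operator
#'
#' Builds the T x T lower-triangular Toeplitz matrix `H` whose column `j` is
#' the HRF kernel placed at onset `j` (truncated at the run end), so that
#' `H %*% s` is the discrete convolution of the innovation train `s` with the
#' kernel. The operator is strictly causal.
#'
#' @param hrf An [canonical_hrf()] object (or any list with a `kernel` field).
#' @param n_time Number of timepoints T.
#' @return A T x T matrix of class `conv_operator` with the `hrf` attached as
#'   an attribute.
#' @export
build_convolution_operator <- function(hrf, n_time) {
  if (!is.numeric(n_time) || n_time <= 0) {
    abort("n_time must be a positive integer", class = "urgepfm_parameter_error")
  }
  n_time <- as.integer(n_time)
  k <- hrf$kernel
  H <- matrix(0, n_time, n_time)
  nk <- min(length(k), n_time)
  for (j in seq_len(n_time)) {
    len <- min(nk, n_time - j + 1L)
    H[j:(j + len - 1L), j] <- k[seq_len(len)]
  }
  structure(H, hrf = hrf, class = c("conv_operator", "matrix", "array"))
}

#' Stacked multi-echo deconvolution design
#'
#' Vertically stacks `-TE_k * H` blocks (TE converted to seconds) for each
#' echo, expressing the linear dependence of the BOLD percent-signal change on
#' echo time under an R2*-only model: for echo k,
#' `pct_k(t) = -TE_k * (H s)(t) * 100` when `s` is measured in 1/s and the
#' percent-change data are divided by 100 before fitting (the package fits the
#' design against percent/100 so the coefficients carry units of 1/s).
#'
#' @param hconv A [build_convolution_operator()] matrix.
#' @param tes Echo times in milliseconds, strictly increasing, length >= 2.
#' @return An (E*T) x T matrix of class `multiecho_design` with attributes
#'   `tes_ms` and `echo_index` (echo of each stacked row).
#' @export
multiecho_design <- function(hconv, tes) {
  check_tes(tes)
  n_time <- ncol(hconv)
  blocks <- lapply(tes, function(te) -(te / 1000) * unclass(hconv))
  X <- do.call(rbind, blocks)
  structure(X,
    tes_ms = tes,
    echo_index = rep(seq_along(tes), each = n_time),
    class = c("multiecho_design", "matrix", "array")
  )
}

check_tes <- function(tes) {
  if (length(tes) < 2) {
    abort("at least two echoes are required", class = "urgepfm_parameter_error")
  }
  if (any(diff(tes) <= 0)) {
    abort("echo times must be strictly increasing",
          class = "urgepfm_parameter_error")
  }
  # magnitude consistency check: TEs are milliseconds; values below 1 suggest
  # seconds were passed, values above 500 are not echo times at 3T
  if (any(tes < 1) || any(tes > 500)) {
    abort("echo times look inconsistent with milliseconds (expected ~5-150 ms)",
          class = "urgepfm_units_error")
  }
  invisible(tes)
}

#' Export an HRF kernel as TSV
#'
#' @param hrf An [canonical_hrf()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hrf_tsv <- function(hrf, path) {
  readr::write_tsv(tibble(time_s = hrf$times, value = hrf$kernel), path)
  invisible(path)
}
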