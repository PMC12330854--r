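#' Broom-style tidiers for urgepfm objects
#'
#' `tidy()` returns a tibble of per-term or per-step summaries; `glance()`
#' returns a one-row model summary. Methods exist for regularisation paths,
#' activation timeseries, logistic blink models and curvilinear fits.
#'
#' @param x The object to summarise.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-urgepfm
NULL
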