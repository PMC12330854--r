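#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for urgepfm result types
#'
#' `autoplot()` methods returning ggplot objects: the block schedule as a
#' timeline, an urge trace coloured by condition (with optional blink rug),
#' the HRF kernel, an activation timeseries with its surrogate threshold and
#' peaks, a peri-blink curve, and the consensus-versus-k curve.
#'
#' @param object The result object to plot.
#' @param blinks Optional `blink_train` overlaid as a rug (urge traces only).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-urgepfm
NULL
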