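#' Build the blink-suppression block schedule
#'
#' Constructs the task timing used throughout the package: a run that opens and
#' closes with a 30 s "Random" baseline (random trackball movement, no urge
#' rating) and contains six alternating 60 s experimental blocks, three
#' "Okay to blink" and three "Suppress". Whether the first experimental block
#' is a suppression block is counterbalanced across participants via
#' `start_with_suppress`.
#'
#' @param start_with_suppress Logical; if `TRUE` the first experimental block
#'   is "Suppress", otherwise "Okay".
#' @param run_length Total run duration in seconds. Must equal the block plan
#'   (two pads of `pad_length` plus six blocks of `block_length`).
#' @param pad_length Duration of each Random pad in seconds (default 30).
#' @param block_length Duration of each experimental block in seconds
#'   (default 60).
#'
#' @return A tibble of class `block_schedule` with columns `trial_type`
#'   (factor: Random/Okay/Suppress), `onset` and `duration` (seconds), and
#'   attribute `run_length`.
#' @examples
#' sched <- make_block_schedule()
#' sum(sched$duration)
#' @export
make_block_schedule <- function(start_with_suppress = FALSE,
                                run_length = 420,
                                pad_length = 30,
                                block_length = 60) {
  n_exp <- 6L
  expected <- 2 * pad_length + n_exp * block_length
  if (!isTRUE(all.equal(run_length, expected))) {
    abort(sprintf(
      "run_length (%s s) inconsistent with block plan: 2 x %s s pads + %d x %s s blocks = %s s",
      run_length, pad_length, n_exp, block_length, expected
    ), class = "urgepfm_schedule_error")
  }
  pair <- if (start_with_suppress) c("Suppress", "Okay") else c("Okay", "Suppress")
  labels <- c("Random", rep(pair, n_exp / 2), "Random")
  durations <- c(pad_length, rep(block_length, n_exp), pad_length)
  onsets <- cumsum(c(0, durations[-length(durations)]))
  out <- tibble(
    trial_type = factor(labels, levels = c("Random", "Okay", "Suppress")),
    onset = onsets,
    duration = durations
  )
  structure(out,
    run_length = run_length,
    class = c("block_schedule", class(out))
  )
}

#' Condition label at given times
#'
#' Looks up the block label covering each time point (half-open intervals
#' `[onset, onset + duration)`). Times at or beyond the run end return `NA`.
#'
#' @param schedule A [make_block_schedule()] tibble.
#' @param times Numeric vector of times in seconds (0 = run start).
#' @return Character vector of block labels.
#' @export
schedule_condition_at <- function(schedule, times) {
  idx <- findInterval(times, schedule$onset)
  lab <- as.character(schedule$trial_type)[idx]
  ends <- schedule$onset + schedule$duration
  lab[times < 0 | times >= max(ends) | idx == 0] <- NA_character_
  lab
}

#' Experimental segment of a schedule
#'
#' Returns the start and end (seconds) of the contiguous experimental segment,
#' i.e. everything between the opening and closing Random pads.
#' @param schedule A [make_block_schedule()] tibble.
#' @return Named numeric vector `c(start, end)`.
#' @export
experimental_window <- function(schedule) {
  rand <- schedule[schedule$trial_type == "Random", ]
  c(start = rand$onset[1] + rand$duration[1], end = rand$onset[nrow(rand)])
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule: %g s run>\n", attr(x, "run_length")))
  NextMethod()
}

#' @rdname autoplot-urgepfm
#' @method autoplot block_schedule
#' @export
autoplot.block_schedule <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$onset, xmax = .data$onset + .data$duration,
      ymin = 0, ymax = 1, fill = .data$trial_type
    )) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "time (s)", fill = "block") +
    ggplot2::theme_minimal()
}
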