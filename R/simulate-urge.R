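#' Parameters for the urge/blink generator
#'
#' Defaults emulate the qualitative behavioural structure of a blink-suppression
#' task: urge climbs steadily while blinks are suppressed and is relieved by
#' "escape" blinks; when blinking is allowed urge hovers near a low set point
#' and blinks are frequent, with their probability rising with the momentary
#' urge. Relief of urge after a blink is not instantaneous: it begins
#' `post_blink_delay` seconds after the blink (rating/relief latency), so the
#' 1 Hz peri-blink template attains its maximum in the second containing the
#' blink under suppression.
#'
#' @param rate Sampling rate of the urge trace in Hz.
#' @param growth_suppress Urge growth rate under Suppress, rating units per s.
#' @param okay_target,okay_tau Set point and relaxation time (s) of urge when
#'   blinking is allowed.
#' @param random_target,random_tau Set point and relaxation time (s) during the
#'   Random baseline.
#' @param blink_rate_suppress Escape-blink hazard under Suppress, blinks per s.
#' @param blink_rate_okay Baseline blink hazard when blinking is allowed,
#'   blinks per s (realised hazard is modulated by momentary urge).
#' @param reset_frac_suppress Fraction of the momentary urge relieved by an
#'   escape blink.
#' @param reset_drop_okay Absolute urge drop after a blink outside suppression.
#' @param post_blink_delay Seconds between a blink and the onset of relief.
#' @param reset_tau Time constant (s) of the exponential relief.
#' @param refractory Minimum separation between blinks in seconds.
#' @param blink_duration Nominal blink duration in seconds.
#' @param noise_sd SD of white measurement noise added to the reported urge,
#'   rating units per sample.
#' @param start_urge Urge at run start.
#' @return A named list of generator parameters.
#' @export
urge_sim_params <- function(rate = 10,
                            growth_suppress = 3,
                            okay_target = 28,
                            okay_tau = 6,
                            random_target = 5,
                            random_tau = 5,
                            blink_rate_suppress = 5.12 / 60,
                            blink_rate_okay = 38 / 60,
                            reset_frac_suppress = 0.35,
                            reset_drop_okay = 5,
                            post_blink_delay = 0.7,
                            reset_tau = 0.8,
                            refractory = 0.5,
                            blink_duration = 0.2,
                            noise_sd = 3,
                            start_urge = 10) {
  p <- as.list(environment())
  rates <- c(rate, blink_rate_suppress, blink_rate_okay, growth_suppress,
             okay_tau, random_tau, reset_tau, noise_sd)
  if (any(rates < 0)) {
    abort("rates, time constants and noise SDs must be non-negative",
          class = "urgepfm_parameter_error")
  }
  p
}

#' Simulate an urge trace and blink train for one run
#'
#' Generates a continuous urge-to-blink rating (0-100, sampled at
#' `params$rate` Hz) together with blink events, following the block schedule.
#' Urge rises under Suppress and relaxes to a low set point otherwise; blinks
#' are drawn per 0.1 s bin as an inhomogeneous Bernoulli process whose hazard
#' is urge-modulated when blinking is allowed and strongly reduced under
#' Suppress. Each blink schedules an exponential relief of urge beginning
#' `post_blink_delay` s after its onset, so under suppression the peri-blink
#' urge peaks in the second of the blink and falls thereafter.
#'
#' The unclipped latent urge is kept in the output (`latent` column) so that
#' planted-template checks are exact.
#'
#' @param schedule A [make_block_schedule()] tibble.
#' @param params Generator parameters from [urge_sim_params()].
#' @param seed Optional integer seed; the draw is reproducible given the seed.
#' @return A list with elements `urge` (tibble `time_s`, `urge`, `condition`,
#'   `latent`; class `urge_trace`) and `blinks` (tibble `onset`, `duration`;
#'   class `blink_train`).
#' @examples
#' sim <- simulate_urge_and_blinks(make_block_schedule(), seed = 1)
#' range(sim$urge$urge)
#' @export
simulate_urge_and_blinks <- function(schedule,
                                     params = urge_sim_params(),
                                     seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_urge_and_blinks(schedule, params)))
  }
  run_length <- attr(schedule, "run_length")
  dt <- 1 / params$rate
  n <- as.integer(round(run_length * params$rate))
  times <- (seq_len(n) - 1) * dt
  cond <- schedule_condition_at(schedule, times)

  latent <- numeric(n)
  u <- params$start_urge
  blink_onsets <- numeric(0)
  last_blink <- -Inf
  # pending relief events: remaining amount + time relief becomes active
  relief_remaining <- numeric(0)
  relief_start <- numeric(0)
  decay <- 1 - exp(-dt / params$reset_tau)

  for (i in seq_len(n)) {
    t <- times[i]
    ci <- cond[i]
    if (identical(ci, "Suppress")) {
      u <- u + params$growth_suppress * dt
      hazard <- params$blink_rate_suppress
    } else if (identical(ci, "Okay")) {
      u <- u + (params$okay_target - u) * dt / params$okay_tau
      hazard <- params$blink_rate_okay *
        pmax(0, 0.5 + u / (2 * params$okay_target))
    } else {
      u <- u + (params$random_target - u) * dt / params$random_tau
      hazard <- params$blink_rate_okay *
        pmax(0, 0.5 + u / (2 * params$okay_target))
    }
    active <- relief_start <= t
    if (any(active)) {
      step <- relief_remaining[active] * decay
      u <- u - sum(step)
      relief_remaining[active] <- relief_remaining[active] - step
      keep <- relief_remaining > 1e-3
      relief_remaining <- relief_remaining[keep]
      relief_start <- relief_start[keep]
    }
    u <- max(u, 0)
    latent[i] <- u
    if ((t - last_blink) > params$refractory &&
        runif(1) < hazard * dt) {
      onset <- t + runif(1) * dt # onset uniform within the bin
      blink_onsets <- c(blink_onsets, onset)
      last_blink <- onset
      amount <- if (identical(ci, "Suppress")) {
        params$reset_frac_suppress * u
      } else {
        params$reset_drop_okay
      }
      relief_remaining <- c(relief_remaining, amount)
      relief_start <- c(relief_start, onset + params$post_blink_delay)
    }
  }

  reported <- latent
  if (params$noise_sd > 0) {
    reported <- reported + rnorm(n, 0, params$noise_sd)
  }
  reported <- pmin(pmax(reported, 0), 100)

  urge <- tibble(
    time_s = times,
    urge = reported,
    condition = cond,
    latent = latent
  )
  class(urge) <- c("urge_trace", class(urge))
  attr(urge, "rate") <- params$rate
  attr(urge, "run_length") <- run_length

  blinks <- tibble(
    onset = blink_onsets,
    duration = rep(params$blink_duration, length(blink_onsets))
  )
  blinks <- blinks[blinks$onset + blinks$duration <= run_length, , drop = FALSE]
  class(blinks) <- c("blink_train", class(blinks))
  attr(blinks, "run_length") <- run_length

  list(urge = urge, blinks = blinks)
}

#' @rdname autoplot-urgepfm
#' @method autoplot urge_trace
#' @export
autoplot.urge_trace <- function(object, blinks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object)) +
    ggplot2::geom_line(ggplot2::aes(.data$time_s, .data$urge,
                                    colour = .data$condition, group = 1)) +
    ggplot2::labs(x = "time (s)", y = "urge (0-100)", colour = "block") +
    ggplot2::theme_minimal()
  if (!is.null(blinks) && nrow(blinks)) {
    p <- p + ggplot2::geom_rug(
      data = as_tibble(blinks),
      ggplot2::aes(x = .data$onset), inherit.aes = FALSE, sides = "b"
    )
  }
  p
}
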