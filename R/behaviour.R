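#' Down-sample an urge trace to 1 Hz and standardise to Z-scores
#'
#' Each second's value is the mean of the high-rate samples in the half-open
#' bin `[s, s + 1)`. Z-scoring (mean subtraction, division by SD) is then done
#' separately per run for the Random samples and for the experimental
#' (Okay + Suppress) samples, following the two condition sets of the task.
#'
#' @param urge An `urge_trace` tibble (`time_s`, `urge`, `condition`),
#'   optionally with a `run` column for multi-run input.
#' @return Tibble of class `std_urge`: `run`, `time_s` (start of second),
#'   `urge` (1 Hz mean), `condition`, `group` ("random"/"experimental"),
#'   `urge_z`. Within every run x group the z-scores have mean 0, SD 1.
#' @export
downsample_standardise <- function(urge) {
  rate <- attr(urge, "rate") %||% infer_rate(urge$time_s)
  if (abs(rate - round(rate)) > 1e-8 || rate < 1) {
    abort("sampling rate must be a whole number of samples per second",
          class = "urgepfm_parameter_error")
  }
  df <- as_tibble(urge)
  if (!"run" %in% names(df)) df$run <- "run1"
  out <- df |>
    dplyr::mutate(second = floor(.data$time_s)) |>
    dplyr::group_by(.data$run, .data$second) |>
    dplyr::summarise(
      urge = mean(.data$urge),
      condition = .data$condition[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      group = ifelse(.data$condition == "Random", "random", "experimental")
    )
  out <- out |>
    dplyr::group_by(.data$run, .data$group) |>
    dplyr::mutate(urge_z = zscore_strict(.data$urge)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      run = .data$run, time_s = .data$second, urge = .data$urge,
      condition = .data$condition, group = .data$group, urge_z = .data$urge_z
    )
  class(out) <- c("std_urge", class(out))
  out
}

zscore_strict <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardise a zero-variance group",
          class = "urgepfm_degenerate_group_error")
  }
  (x - mean(x)) / s
}

infer_rate <- function(time_s) {
  d <- diff(sort(unique(time_s)))
  1 / min(d[d > 0])
}

#' Binarize a blink train per second
#'
#' Element `s` (1-based, covering `[s - 1, s)` seconds) is 1 iff at least one
#' blink onset falls in that second; multiple blinks in a second count once.
#'
#' @param blinks A `blink_train` tibble (`onset` in seconds).
#' @param n_seconds Length of the output vector.
#' @return Integer 0/1 vector of length `n_seconds`.
#' @export
binarize_blinks <- function(blinks, n_seconds) {
  if (n_seconds < 1) {
    abort("n_seconds must be >= 1", class = "urgepfm_parameter_error")
  }
  onsets <- blinks$onset
  if (any(onsets < 0 | onsets >= n_seconds)) {
    abort("blink onsets beyond the requested window",
          class = "urgepfm_event_error")
  }
  out <- integer(n_seconds)
  out[unique(floor(onsets)) + 1] <- 1L
  out
}

#' Binary logistic regression of blink occurrence on urge
#'
#' Maximum-likelihood fit of `blink ~ urge_z` on per-second data (urge
#' z-scores concatenated across participants within a condition set). Reports
#' the log-odds coefficient B, the odds ratio Exp(B), the Wald statistic, the
#' model chi-square against the intercept-only model, and Cox & Snell R^2.
#'
#' @param urge_z Numeric vector of per-second urge z-scores.
#' @param blinks Integer 0/1 vector of the same length
#'   (see [binarize_blinks()]).
#' @return Object of class `logistic_result` with fields `b`, `exp_b`, `se`,
#'   `wald`, `wald_df`, `p_wald`, `model_chisq`, `chisq_df`, `p_chisq`,
#'   `cox_snell_r2`, `n`.
#' @export
blink_urge_logistic <- function(urge_z, blinks) {
  if (length(urge_z) != length(blinks)) {
    abort("urge and blink vectors differ in length",
          class = "urgepfm_parameter_error")
  }
  y <- as.integer(blinks)
  if (length(unique(y)) < 2) {
    abort("blink outcome has a single class; logistic model not estimable",
          class = "urgepfm_degenerate_outcome_error")
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ urge_z, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  # quiet separation: IRLS can stop with boundary fitted probabilities or a
  # runaway slope without raising the usual warning
  separated <- separated ||
    any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) ||
    abs(coef(fit)[2]) > 15
  if (separated || !fit$converged) {
    abort("perfect separation: logistic estimates are unbounded",
          class = "urgepfm_separation_error")
  }
  s <- summary(fit)
  b <- unname(coef(fit)["urge_z"])
  se <- s$coefficients["urge_z", "Std. Error"]
  wald <- (b / se)^2
  chisq <- fit$null.deviance - fit$deviance
  n <- length(y)
  structure(
    list(
      b = b, exp_b = exp(b), se = se,
      wald = wald, wald_df = 1L,
      p_wald = stats::pchisq(wald, 1, lower.tail = FALSE),
      model_chisq = chisq, chisq_df = 1L,
      p_chisq = stats::pchisq(chisq, 1, lower.tail = FALSE),
      cox_snell_r2 = 1 - exp(-chisq / n),
      n = n, fit = fit
    ),
    class = "logistic_result"
  )
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf(
    "<logistic_result: B = %.3f, Exp(B) = %.3f, Wald(1) = %.2f (p = %.3g), chi2(1) = %.2f, Cox & Snell R2 = %.4f, n = %d>\n",
    x$b, x$exp_b, x$wald, x$p_wald, x$model_chisq, x$cox_snell_r2, x$n
  ))
  invisible(x)
}

#' @rdname tidy-urgepfm
#' @method tidy logistic_result
#' @export
tidy.logistic_result <- function(x, ...) {
  tibble(
    term = "urge_z", estimate = x$b, exp_estimate = x$exp_b,
    std.error = x$se, statistic = x$wald, df = x$wald_df, p.value = x$p_wald
  )
}

#' @rdname tidy-urgepfm
#' @method glance logistic_result
#' @export
glance.logistic_result <- function(x, ...) {
  tibble(
    model_chisq = x$model_chisq, df = x$chisq_df, p.value = x$p_chisq,
    cox_snell_r2 = x$cox_snell_r2, nobs = x$n
  )
}

#' Peri-blink average of the urge z-score
#'
#' Extracts the 11 one-second samples from 5 s before to 5 s after each blink
#' (lags -5..5, the blink's own second at lag 0) and averages them within
#' condition. Blinks in the first or last 5 s of their block are discarded
#' (urge needs time to adjust after a block change, and the window must not
#' straddle the next block), as are blinks outside Okay/Suppress blocks.
#'
#' @param urge_z A [downsample_standardise()] tibble for one participant.
#' @param blinks A `blink_train` tibble; must carry a `run` column matching
#'   `urge_z` when the input spans several runs.
#' @param schedule The run's [make_block_schedule()].
#' @return Tibble of class `periblink_curve`: `condition`, `lag`, `mean_z`,
#'   `n_blinks`. Conditions with no retained blinks are absent; if no blink
#'   at all is retained, a zero-row tibble is returned with a classed warning
#'   (`urgepfm_empty_curve_warning`) so participants without escape blinks can
#'   be excluded upstream.
#' @export
periblink_average <- function(urge_z, blinks, schedule) {
  uz <- as_tibble(urge_z)
  bl <- as_tibble(blinks)
  if (!"run" %in% names(bl)) bl$run <- uz$run[1]
  windows <- retained_blink_windows(bl, schedule)
  lags <- -5:5
  curves <- list()
  if (nrow(windows)) {
    z_lookup <- uz[uz$group == "experimental", ]
    key <- paste(z_lookup$run, z_lookup$time_s)
    samples <- purrr::pmap_dfr(windows, function(run, onset, condition, ...) {
      sec <- floor(onset) + lags
      z <- z_lookup$urge_z[match(paste(run, sec), key)]
      tibble(run = run, condition = condition, lag = lags, z = z)
    })
    curves <- samples |>
      dplyr::filter(!is.na(.data$z)) |>
      dplyr::group_by(.data$condition, .data$lag) |>
      dplyr::summarise(mean_z = mean(.data$z), n_blinks = dplyr::n(),
                       .groups = "drop")
  }
  if (!length(curves) || nrow(curves) == 0) {
    warn("no retained blinks: empty peri-blink curve",
         class = "urgepfm_empty_curve_warning")
    curves <- tibble(condition = character(), lag = integer(),
                     mean_z = numeric(), n_blinks = integer())
  }
  class(curves) <- c("periblink_curve", class(curves))
  curves
}

# blinks surviving the 5 s block-edge rule, with their block condition
retained_blink_windows <- function(blinks, schedule) {
  purrr::pmap_dfr(blinks, function(onset, run = "run1", ...) {
    i <- findInterval(onset, schedule$onset)
    if (i == 0) return(NULL)
    cond <- as.character(schedule$trial_type[i])
    if (!cond %in% c("Okay", "Suppress")) return(NULL)
    b0 <- schedule$onset[i]
    b1 <- b0 + schedule$duration[i]
    if (onset < b0 + 5 || onset >= b1 - 5) return(NULL)
    tibble(run = run, onset = onset, condition = cond)
  })
}

#' @rdname autoplot-urgepfm
#' @method autoplot periblink_curve
#' @export
autoplot.periblink_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$lag, .data$mean_z,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time to blink (s)", y = "mean urge (z)") +
    ggplot2::theme_minimal()
}

#' Temporal-shape statistics of peri-blink curves
#'
#' Per participant, the peri-blink curve is summarised by its peak latency
#' (lag of the maximum; ties resolve to the earliest lag, with a message) and
#' by skewness and kurtosis of the curve treated as a distribution over lags:
#' the curve minimum is subtracted to obtain non-negative weights, which are
#' normalised and used for direct moment summation. Group-level two-tailed
#' one-sample tests compare peak latency against 0, skewness against 0 and
#' kurtosis against 3 (the Gaussian value; excess kurtosis = kurtosis - 3 is
#' reported alongside). A Shapiro-Wilk check at alpha = 0.05 selects the t
#' test, falling back to the Wilcoxon signed-rank test for non-normal data.
#'
#' @param curves Tibble with columns `participant`, `lag`, `mean_z` (one
#'   condition's curves for >= 3 participants).
#' @return Object of class `temporal_stats`: tibble with one row per
#'   statistic (`peak_latency`, `skewness`, `kurtosis`): `mean`, `sd`,
#'   `null_value`, `test`, `statistic`, `df_or_n`, `p.value`; per-participant
#'   values in attribute `participants`.
#' @export
periblink_stats <- function(curves) {
  df <- as_tibble(curves)
  parts <- split(df, df$participant)
  if (length(parts) < 3) {
    abort("at least 3 participants are required", class = "urgepfm_parameter_error")
  }
  per <- purrr::imap_dfr(parts, function(d, id) {
    d <- d[order(d$lag), ]
    mx <- which(d$mean_z == max(d$mean_z))
    if (length(mx) > 1) {
      message(sprintf("participant %s: tied peri-blink maxima; using earliest lag", id))
    }
    shape <- curve_shape_stats(d$lag, d$mean_z)
    tibble(participant = id, peak_latency = d$lag[mx[1]],
           skewness = shape$skewness, kurtosis = shape$kurtosis)
  })
  one <- function(x, null_value, name) {
    x <- x[is.finite(x)]
    if (sd(x) == 0) {
      # no sampling variability: decisive if off the null, uninformative if on
      return(tibble(statistic_name = name, mean = mean(x), sd = 0,
                    null_value = null_value, test = "t",
                    statistic = NA_real_, df_or_n = length(x) - 1,
                    p.value = if (isTRUE(all.equal(mean(x), null_value))) 1 else 0))
    }
    swp <- tryCatch(shapiro.test(x)$p.value, error = function(e) 1)
    if (swp >= 0.05) {
      tt <- t.test(x, mu = null_value)
      tibble(statistic_name = name, mean = mean(x), sd = sd(x),
             null_value = null_value, test = "t",
             statistic = unname(tt$statistic), df_or_n = unname(tt$parameter),
             p.value = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(x, mu = null_value))
      tibble(statistic_name = name, mean = mean(x), sd = sd(x),
             null_value = null_value, test = "wilcoxon",
             statistic = unname(wt$statistic), df_or_n = length(x),
             p.value = wt$p.value)
    }
  }
  out <- dplyr::bind_rows(
    one(per$peak_latency, 0, "peak_latency"),
    one(per$skewness, 0, "skewness"),
    one(per$kurtosis, 3, "kurtosis")
  )
  out$excess <- ifelse(out$statistic_name == "kurtosis", out$mean - 3, NA_real_)
  structure(out, participants = per,
            class = c("temporal_stats", class(out)))
}

# weighted moments of a curve treated as a density over lags
curve_shape_stats <- function(lag, value) {
  w <- value - min(value)
  if (sum(w) <= 0) {
    return(list(skewness = NA_real_, kurtosis = NA_real_))
  }
  p <- w / sum(w)
  mu <- sum(p * lag)
  v <- sum(p * (lag - mu)^2)
  if (v <= 0) {
    return(list(skewness = NA_real_, kurtosis = NA_real_))
  }
  list(
    skewness = sum(p * (lag - mu)^3) / v^1.5,
    kurtosis = sum(p * (lag - mu)^4) / v^2
  )
}

#' Curvilinear (linear vs quadratic) fit of a peri-blink curve
#'
#' Least-squares fits of the group-mean urge z on time-to-blink, linear and
#' quadratic. The quadratic model is chosen when its squared term is
#' significant at `alpha`; otherwise the linear model is preferred. Constant
#' curves return both fits with zero slopes and no chosen model.
#'
#' @param curve Tibble with `lag` and `mean_z` (11 rows for the -5..5 s
#'   window), or two numeric vectors via `lag`/`mean_z` columns.
#' @param alpha Significance level for the quadratic term (default 0.05).
#' @return Object of class `curvilinear_result`: list with `linear` and
#'   `quadratic` sublists (`intercept`, coefficient(s), `f`, `df1`, `df2`,
#'   `adj_r2`, `p`), `p_quadratic_term`, `chosen` ("linear", "quadratic" or
#'   NA).
#' @export
curvilinear_fit <- function(curve, alpha = 0.05) {
  d <- as_tibble(curve)
  t <- d$lag
  y <- d$mean_z
  if (sd(y) == 0) {
    flat <- list(intercept = y[1], f = NA_real_, df1 = NA_real_,
                 df2 = NA_real_, adj_r2 = 0, p = NA_real_)
    return(structure(
      list(linear = c(flat, slope = 0),
           quadratic = c(flat, t_coef = 0, t2_coef = 0),
           p_quadratic_term = NA_real_, chosen = NA_character_),
      class = "curvilinear_result"
    ))
  }
  lin <- lm(y ~ t)
  quad <- lm(y ~ t + I(t^2))
  sl <- summary(lin)
  sq <- summary(quad)
  p_quad <- sq$coefficients["I(t^2)", "Pr(>|t|)"]
  fstat <- function(s) {
    f <- s$fstatistic
    list(f = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
         p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
         adj_r2 = s$adj.r.squared)
  }
  structure(
    list(
      linear = c(list(intercept = unname(coef(lin)[1]),
                      slope = unname(coef(lin)[2])), fstat(sl)),
      quadratic = c(list(intercept = unname(coef(quad)[1]),
                         t_coef = unname(coef(quad)[2]),
                         t2_coef = unname(coef(quad)[3])), fstat(sq)),
      p_quadratic_term = unname(p_quad),
      chosen = if (p_quad <= alpha) "quadratic" else "linear"
    ),
    class = "curvilinear_result"
  )
}

#' @export
print.curvilinear_result <- function(x, ...) {
  cat(sprintf(
    "<curvilinear_result: chosen %s; quadratic term p = %.3g>\n",
    x$chosen %||% "none", x$p_quadratic_term
  ))
  invisible(x)
}

#' @rdname tidy-urgepfm
#' @method tidy curvilinear_result
#' @export
tidy.curvilinear_result <- function(x, ...) {
  tibble(
    model = c("linear", "quadratic"),
    intercept = c(x$linear$intercept, x$quadratic$intercept),
    t_coef = c(x$linear$slope, x$quadratic$t_coef),
    t2_coef = c(NA_real_, x$quadratic$t2_coef),
    f = c(x$linear$f, x$quadratic$f),
    df1 = c(x$linear$df1, x$quadratic$df1),
    df2 = c(x$linear$df2, x$quadratic$df2),
    adj_r2 = c(x$linear$adj_r2, x$quadratic$adj_r2),
    chosen = c("linear", "quadratic") == (x$chosen %||% "")
  )
}

#' Per-condition block summaries for one participant
#'
#' Mean raw urge (0-100 scale) over each experimental condition's samples and
#' the blink rate in blinks per minute of condition time.
#'
#' @param urge An `urge_trace` tibble.
#' @param blinks A `blink_train` tibble.
#' @param schedule The run's schedule.
#' @return Tibble: `condition`, `mean_urge`, `n_blinks`, `minutes`,
#'   `blinks_per_min`.
#' @export
summarise_blocks <- function(urge, blinks, schedule) {
  conds <- c("Okay", "Suppress")
  blink_cond <- schedule_condition_at(schedule, blinks$onset)
  purrr::map_dfr(conds, function(cc) {
    mins <- sum(schedule$duration[schedule$trial_type == cc]) / 60
    tibble(
      condition = cc,
      mean_urge = mean(urge$urge[urge$condition == cc]),
      n_blinks = sum(blink_cond == cc, na.rm = TRUE),
      minutes = mins,
      blinks_per_min = sum(blink_cond == cc, na.rm = TRUE) / mins
    )
  })
}

#' Group-level block comparisons
#'
#' One-tailed paired comparisons of the per-participant condition summaries:
#' a paired t-test on mean urge (directional hypothesis: urge is higher under
#' Suppress) and a paired Wilcoxon signed-rank test on blink rates
#' (directional hypothesis: fewer blinks under Suppress; blink counts are not
#' suited to parametric testing).
#'
#' @param summaries Tibble with columns `participant`, `condition`
#'   ("Okay"/"Suppress"), `mean_urge`, `blinks_per_min` (e.g. rows of
#'   [summarise_blocks()] per participant).
#' @return Tibble of class `block_tests`: `measure`, `mean_okay`,
#'   `mean_suppress`, `test`, `alternative`, `statistic`, `df_or_n`,
#'   `p.value`.
#' @export
block_summary_tests <- function(summaries) {
  wide_u <- tidyr::pivot_wider(summaries[, c("participant", "condition", "mean_urge")],
                               names_from = "condition", values_from = "mean_urge")
  wide_b <- tidyr::pivot_wider(summaries[, c("participant", "condition", "blinks_per_min")],
                               names_from = "condition", values_from = "blinks_per_min")
  for (w in list(wide_u, wide_b)) {
    if (!all(c("Okay", "Suppress") %in% names(w)) ||
        anyNA(w[c("Okay", "Suppress")])) {
      abort("every participant needs both Okay and Suppress summaries",
            class = "urgepfm_parameter_error")
    }
  }
  if (nrow(wide_u) < 2) {
    abort("at least 2 participants are required", class = "urgepfm_parameter_error")
  }
  # zero-difference data carry no directional evidence: report p = 0.5
  tt <- tryCatch(
    t.test(wide_u$Suppress, wide_u$Okay, paired = TRUE,
           alternative = "greater"),
    error = function(e) list(statistic = NA_real_, parameter = NA_real_,
                             p.value = 0.5)
  )
  wt <- tryCatch(
    suppressWarnings(wilcox.test(wide_b$Suppress, wide_b$Okay, paired = TRUE,
                                 alternative = "less")),
    error = function(e) list(statistic = NA_real_, p.value = 0.5)
  )
  out <- tibble(
    measure = c("mean_urge", "blinks_per_min"),
    mean_okay = c(mean(wide_u$Okay), mean(wide_b$Okay)),
    mean_suppress = c(mean(wide_u$Suppress), mean(wide_b$Suppress)),
    test = c("paired t", "wilcoxon signed-rank"),
    alternative = c("Suppress > Okay", "Suppress < Okay"),
    statistic = c(unname(tt$statistic), unname(wt$statistic)),
    df_or_n = c(unname(tt$parameter), nrow(wide_b)),
    p.value = c(tt$p.value, wt$p.value)
  )
  structure(out, class = c("block_tests", class(out)))
}
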