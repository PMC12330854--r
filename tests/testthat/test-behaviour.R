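sched <- make_block_schedule()

test_that("down-sampling bins by second and standardises per run and group", {
  # 70 samples at 10 Hz -> 7 one-second values
  tr <- tibble::tibble(
    time_s = seq(0, 6.9, by = 0.1),
    urge = rep(c(10, 20, 30, 40, 50, 60, 70), each = 10) + rep(0:9, 7) / 100,
    condition = rep(c("Random", "Random", rep("Okay", 5)), each = 10)
  )
  class(tr) <- c("urge_trace", class(tr))
  attr(tr, "rate") <- 10
  z <- downsample_standardise(tr)
  expect_equal(nrow(z), 7)
  expect_equal(z$urge, c(10, 20, 30, 40, 50, 60, 70) + mean(0:9) / 100)
  grp <- split(z$urge_z, z$group)
  expect_equal(mean(grp$experimental), 0, tolerance = 1e-9)
  expect_equal(sd(grp$experimental), 1, tolerance = 1e-9)
  # standardisation is idempotent
  z2 <- z
  z2$urge <- z$urge_z
  class(z2) <- class(tr)
  attr(z2, "rate") <- 1
  restd <- downsample_standardise(z2)
  expect_equal(restd$urge_z, z$urge_z, tolerance = 1e-9)
  # constant group errors
  tr0 <- tr
  tr0$urge <- 5
  expect_error(downsample_standardise(tr0),
               class = "urgepfm_degenerate_group_error")
})

test_that("blink binarization records occurrence, not counts", {
  bl <- tibble::tibble(onset = c(3.1, 3.7, 4.0, 8.5), duration = 0.2)
  v <- binarize_blinks(bl, 10)
  expect_equal(v, c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(sum(binarize_blinks(bl[0, ], 10)), 0)
  expect_error(binarize_blinks(tibble::tibble(onset = 12, duration = 0.2), 10),
               class = "urgepfm_event_error")
})

test_that("logistic blink model recovers a planted coefficient", {
  # simulation oracle: Bernoulli outcomes from the planted logistic model
  b_true <- -0.2
  ests <- purrr::map_dbl(1:40, function(seed) {
    withr::with_seed(seed, {
      z <- rnorm(10000)
      y <- rbinom(10000, 1, plogis(-1 + b_true * z))
      blink_urge_logistic(z, y)$b
    })
  })
  expect_lt(abs(mean(ests) - b_true), 0.02)
  # null model: odds ratio near 1
  withr::with_seed(1, {
    z <- rnorm(5000)
    y <- rbinom(5000, 1, 0.3)
  })
  r <- blink_urge_logistic(z, y)
  expect_equal(r$exp_b, 1, tolerance = 0.1)
  expect_equal(r$exp_b, exp(r$b))
  expect_true(r$cox_snell_r2 >= 0 && r$cox_snell_r2 < 1)
  # degenerate inputs are flagged
  expect_error(blink_urge_logistic(z, rep(0L, 5000)),
               class = "urgepfm_degenerate_outcome_error")
  zs <- c(rep(-2, 50), rep(2, 50))
  expect_error(blink_urge_logistic(zs, as.integer(zs > 0)),
               class = "urgepfm_separation_error")
})

test_that("logistic Wald test is calibrated under the null", {
  rej <- 0
  n_sim <- 1000
  for (seed in seq_len(n_sim)) {
    set.seed(seed)
    z <- rnorm(300)
    y <- rbinom(300, 1, 0.3)
    fit <- suppressWarnings(glm(y ~ z, family = binomial()))
    w <- (coef(fit)[2] / summary(fit)$coefficients[2, 2])^2
    if (pchisq(w, 1, lower.tail = FALSE) <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_sim - 0.05), 0.02)
})

test_that("peri-blink windows follow the retention and averaging rules", {
  # hand-built 1 Hz standardised trace covering the run
  uz <- tibble::tibble(
    run = "run1", time_s = 0:419,
    urge = 0, condition = schedule_condition_at(sched, 0:419),
    group = ifelse(schedule_condition_at(sched, 0:419) == "Random",
                   "random", "experimental"),
    urge_z = sin((0:419) / 20)
  )
  # one retained blink: curve equals the 11 raw samples around it
  bl1 <- tibble::tibble(onset = 50.3, duration = 0.2)
  pc <- periblink_average(uz, bl1, sched)
  expect_equal(nrow(pc), 11)
  expect_equal(pc$mean_z, uz$urge_z[uz$time_s %in% (50 + (-5:5))])
  expect_equal(pc$condition, rep("Okay", 11))
  # blink 3 s after block onset is excluded; so are final-5 s blinks
  bl2 <- tibble::tibble(onset = c(33, 86, 50.3), duration = 0.2)
  pc2 <- periblink_average(uz, bl2, sched)
  expect_equal(unique(pc2$n_blinks), 1L)
  # blinks only in excluded zones signal an empty curve
  bl3 <- tibble::tibble(onset = c(33, 86.2, 12), duration = 0.2)
  expect_warning(pc3 <- periblink_average(uz, bl3, sched),
                 class = "urgepfm_empty_curve_warning")
  expect_equal(nrow(pc3), 0)
})

test_that("window retention count matches brute-force enumeration", {
  for (seed in 1:5) {
    sim <- simulate_urge_and_blinks(sched, seed = seed)
    uz <- downsample_standardise(sim$urge)
    pc <- suppressWarnings(periblink_average(uz, sim$blinks, sched))
    retained <- sum(pc$n_blinks[pc$lag == 0])
    brute <- 0
    for (o in sim$blinks$onset) {
      i <- findInterval(o, sched$onset)
      lab <- as.character(sched$trial_type[i])
      b0 <- sched$onset[i]
      b1 <- b0 + sched$duration[i]
      if (lab %in% c("Okay", "Suppress") && o >= b0 + 5 && o < b1 - 5) {
        brute <- brute + 1
      }
    }
    expect_equal(retained, brute)
  }
})

test_that("temporal-shape statistics match a direct moment oracle", {
  # curves from a discretised Gaussian over lags: moments known by summation
  dens <- function(lag, mu, sig) exp(-(lag - mu)^2 / (2 * sig^2))
  curves <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(participant = paste0("p", i), lag = -5:5,
                   mean_z = dens(-5:5, 0, 2) + i * 1e-9)
  })
  st <- periblink_stats(curves)
  per <- attr(st, "participants")
  # oracle: direct moment summation on the planted density
  w <- dens(-5:5, 0, 2) - min(dens(-5:5, 0, 2))
  p <- w / sum(w)
  mu <- sum(p * (-5:5))
  v <- sum(p * ((-5:5) - mu)^2)
  kurt_oracle <- sum(p * ((-5:5) - mu)^4) / v^2
  skew_oracle <- sum(p * ((-5:5) - mu)^3) / v^1.5
  expect_equal(mean(per$kurtosis), kurt_oracle, tolerance = 1e-6)
  expect_equal(mean(per$skewness), skew_oracle, tolerance = 1e-6)
  expect_equal(unique(per$peak_latency), 0)
  expect_equal(st$excess[st$statistic_name == "kurtosis"],
               kurt_oracle - 3, tolerance = 1e-6)
})

test_that("shifted peaks drive the group latency test negative", {
  curves <- purrr::map_dfr(1:8, function(i) {
    tibble::tibble(participant = paste0("p", i), lag = -5:5,
                   mean_z = dnorm(-5:5, -3 + 0.01 * i, 1.5))
  })
  st <- periblink_stats(curves)
  lat <- st[st$statistic_name == "peak_latency", ]
  expect_lt(lat$mean, 0)
  expect_lt(lat$p.value, 0.01)
  # symmetric triangular curve peaking at 0: latency 0, skewness ~ 0
  tri <- fake_curves(4)
  st2 <- periblink_stats(tri)
  per2 <- attr(st2, "participants")
  expect_equal(unique(per2$peak_latency), 0)
  expect_equal(unique(round(per2$skewness, 10)), 0)
  expect_error(periblink_stats(fake_curves(2)),
               class = "urgepfm_parameter_error")
})

test_that("curvilinear selection recovers planted model shapes", {
  n_seeds <- 60
  quad_sel <- 0
  quad_cov <- 0
  lin_sel <- 0
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    t <- -5:5
    # planted quadratic with small noise
    yq <- 0.948 - 0.038 * t - 0.019 * t^2 + rnorm(11, 0, 0.05)
    fq <- curvilinear_fit(tibble::tibble(lag = t, mean_z = yq))
    if (identical(fq$chosen, "quadratic")) quad_sel <- quad_sel + 1
    sq <- summary(lm(yq ~ t + I(t^2)))$coefficients
    ok <- abs(sq[, "Estimate"] - c(0.948, -0.038, -0.019)) <=
      3 * sq[, "Std. Error"]
    if (all(ok)) quad_cov <- quad_cov + 1
    # planted linear
    yl <- -0.646 - 0.017 * t + rnorm(11, 0, 0.05)
    fl <- curvilinear_fit(tibble::tibble(lag = t, mean_z = yl))
    if (identical(fl$chosen, "linear")) lin_sel <- lin_sel + 1
  }
  expect_gte(quad_sel / n_seeds, 0.95)
  expect_gte(quad_cov / n_seeds, 0.9)
  expect_gte(lin_sel / n_seeds, 0.9)
  # constant curve: zero slopes, no chosen model
  fc <- curvilinear_fit(tibble::tibble(lag = -5:5, mean_z = rep(1, 11)))
  expect_true(is.na(fc$chosen))
  expect_equal(fc$linear$slope, 0)
  expect_equal(fc$quadratic$t2_coef, 0)
  expect_equal(fc$linear$adj_r2, 0)
})

test_that("block summaries and one-tailed group tests", {
  # toy input: 2 blinks in one 60 s Okay block -> 2/3 per minute over 3 blocks
  urge <- tibble::tibble(
    time_s = seq(0, 419.9, by = 0.1),
    urge = ifelse(schedule_condition_at(sched, seq(0, 419.9, 0.1)) == "Suppress",
                  60, 20),
    condition = schedule_condition_at(sched, seq(0, 419.9, 0.1))
  )
  bl <- tibble::tibble(onset = c(40, 55), duration = 0.2)
  su <- summarise_blocks(urge, bl, sched)
  expect_equal(su$mean_urge[su$condition == "Suppress"], 60)
  expect_equal(su$blinks_per_min[su$condition == "Okay"], 2 / 3)
  expect_equal(su$minutes, c(3, 3))
  # planted 6x blink-rate difference rejects; identical data does not
  set.seed(1)
  n_sub <- 20
  summaries <- purrr::map_dfr(seq_len(n_sub), function(i) {
    tibble::tibble(
      participant = paste0("p", i),
      condition = c("Okay", "Suppress"),
      mean_urge = c(rnorm(1, 23, 5), rnorm(1, 56, 5)),
      blinks_per_min = c(rpois(1, 30), rpois(1, 5))
    )
  })
  bt <- block_summary_tests(summaries)
  expect_lt(bt$p.value[bt$measure == "mean_urge"], 0.001)
  expect_lt(bt$p.value[bt$measure == "blinks_per_min"], 0.001)
  flat <- summaries
  flat$mean_urge <- rep(30, nrow(flat))
  flat$blinks_per_min <- rep(10, nrow(flat))
  bt0 <- suppressWarnings(block_summary_tests(flat))
  expect_true(is.na(bt0$p.value[1]) || bt0$p.value[1] >= 0.5)
  # missing condition errors
  expect_error(block_summary_tests(summaries[summaries$condition == "Okay", ]),
               class = "urgepfm_parameter_error")
})
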