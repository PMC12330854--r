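test_that("temporal max filter spreads spikes and keeps signs", {
  x <- matrix(0, 2, 10)
  x[1, 5] <- -0.1
  f <- temporal_max_filter(x)
  expect_equal(which(f[1, ] != 0), 4:6)
  expect_equal(unique(f[1, 4:6]), -0.1)
  expect_equal(f[2, ], rep(0, 10))
  # adjacent (-1, +2): both positions take +2 (largest magnitude, sign kept)
  y <- matrix(c(0, -1, 2, 0), 1)
  fy <- temporal_max_filter(y)
  expect_equal(as.numeric(fy), c(-1, 2, 2, 2))
  expect_error(temporal_max_filter(x, window = 4),
               class = "urgepfm_parameter_error")
})

test_that("repeated filtering widens support by one sample per side only", {
  x <- matrix(0, 1, 20)
  x[1, 10] <- -3
  f1 <- temporal_max_filter(x)
  f2 <- temporal_max_filter(f1)
  expect_equal(which(f1[1, ] != 0), 9:11)
  expect_equal(which(f2[1, ] != 0), 8:12)
  expect_equal(unique(f2[1, 8:12]), -3) # magnitudes unchanged
})

test_that("minimum cluster size is enforced exactly", {
  grid <- c(6, 6, 4)
  V <- prod(grid)
  make_col <- function(idx) {
    v <- numeric(V)
    v[idx] <- -1
    v
  }
  lab <- array(seq_len(V), grid)
  blob10 <- as.integer(lab[1:5, 1:2, 1])  # 10 face-connected voxels
  blob9 <- as.integer(lab[1:3, 1:3, 3])   # 9 voxels
  lone <- as.integer(lab[6, 6, 4])
  x <- cbind(make_col(blob10), make_col(blob9), make_col(lone))
  m <- spatial_cluster_mask(x, grid, min_size = 10)
  expect_equal(which(m[, 1]), sort(blob10)) # retained
  expect_equal(sum(m[, 2]), 0)              # 9-voxel blob removed
  expect_equal(sum(m[, 3]), 0)              # isolated voxel removed
  # monotonicity: raising min_size never adds voxels
  m2 <- spatial_cluster_mask(x, grid, min_size = 11)
  expect_true(all(which(m2) %in% which(m)))
  expect_error(spatial_cluster_mask(x, grid, min_size = 0),
               class = "urgepfm_parameter_error")
  expect_error(spatial_cluster_mask(x, grid, connectivity = 4),
               class = "urgepfm_parameter_error")
})

test_that("connectivity options behave as labelled", {
  grid <- c(3, 3, 1)
  x <- matrix(0, 9, 1)
  x[c(1, 5), 1] <- -1 # diagonal neighbours in-plane
  m6 <- spatial_cluster_mask(x, grid, min_size = 2, connectivity = 6)
  m18 <- spatial_cluster_mask(x, grid, min_size = 2, connectivity = 18)
  expect_equal(sum(m6), 0)  # faces only: two singletons
  expect_equal(sum(m18), 2) # edge connectivity joins them
})

test_that("ATS counts negative voxels and matches a brute-force tally", {
  set.seed(8)
  x <- matrix(sample(c(-1, 0, 2), 60, replace = TRUE), 6, 10)
  a <- compute_ats(x)
  brute <- integer(10)
  for (t in 1:10) for (v in 1:6) if (x[v, t] < 0) brute[t] <- brute[t] + 1L
  expect_equal(a$counts, brute)
  expect_equal(compute_ats(abs(x))$counts, rep(0L, 10))
  x2 <- matrix(0, 3, 9)
  x2[2, 7] <- -5
  expect_equal(compute_ats(x2)$counts[7], 1L)
})

test_that("peak selection: strict threshold, plateau midpoint, segments", {
  counts <- c(0, 3, 5, 5, 5, 3, 0, 0, 4, 6, 2, 0)
  expect_equal(find_ats_peaks(counts, 2), c(4L, 10L)) # odd plateau midpoint
  counts2 <- c(0, 4, 4, 0)
  expect_equal(find_ats_peaks(counts2, 1), 2L) # even plateau: earlier sample
  expect_equal(find_ats_peaks(c(1, 1, 1), 1), integer(0)) # strict comparison
  expect_equal(find_ats_peaks(c(0, 0), 0), integer(0))
})

test_that("surrogate permutation is seeded, shared and value-preserving", {
  truth <- tiny_truth(noise_sd = 0.4, amplitude = -2.5, seed = 3,
                      events_per_roi = 1)
  ser <- simulate_multiecho_run(truth, seed = 12)
  s1 <- surrogate_threshold(ser, seed = 5)
  s2 <- surrogate_threshold(ser, seed = 5)
  expect_identical(s1$permutation, s2$permutation)
  expect_identical(s1$threshold, s2$threshold)
  expect_true(all(sort(s1$permutation) == seq_len(100)))
  s3 <- surrogate_threshold(ser, seed = 6)
  expect_false(identical(s1$permutation, s3$permutation))
  # shuffling preserves each voxel's multiset of raw values
  e1 <- matrix(ser$echoes[[1]], 500, 100)
  expect_equal(apply(e1[, s1$permutation], 1, sort), apply(e1, 1, sort))
  expect_equal(s1$threshold, median(s1$ats$counts))
})

test_that("ROI peak selection recovers planted events and handles empties", {
  h <- canonical_hrf(1800)
  amp <- amplitude_for_cnr(3.5, 0.4, h)
  truth <- make_ground_truth(grid = c(10, 10, 5), n_time = 100, n_rois = 2,
                             roi_dim = c(3, 3, 2), events_per_roi = 3,
                             amplitude = amp, noise_sd = 0.4,
                             drift_order = 1, seed = 21)
  ser <- simulate_multiecho_run(truth, seed = 22)
  roi <- truth$roi_labels == 1
  res <- detect_events(ser, roi, seed = 7, min_size = 6)
  ev <- sort(truth$events$onset_tr[truth$events$roi == 1])
  hit <- vapply(ev, function(o) any(abs(res$events$peaks$peak_tr - o) <= 1),
                logical(1))
  expect_gte(sum(hit), 2) # at least 2 of 3 planted events found
  # empty ROI errors; an all-quiet ROI gives an empty event set
  expect_error(select_roi_peaks(res$ats, res$masked, array(FALSE, truth$grid),
                                res$surrogate),
               class = "urgepfm_parameter_error")
  quiet <- array(FALSE, truth$grid)
  quiet[8:10, 8:10, 5] <- TRUE # background corner away from both ROIs
  expect_equal(sum(truth$roi_labels[quiet]), 0)
  es <- select_roi_peaks(res$ats, res$masked, quiet, res$surrogate)
  expect_equal(nrow(es$peaks), 0)
  expect_length(es$maps, 0)
})
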