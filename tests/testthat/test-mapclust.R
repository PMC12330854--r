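# planted map stack: n_groups well-separated centroids in V dimensions
planted_stack <- function(n_groups, per_group = 20, V = 60, sep = 8,
                          noise = 1, seed = 1) {
  withr::with_seed(seed, {
    centroids <- matrix(rnorm(n_groups * V), n_groups) * sep
    X <- centroids[rep(seq_len(n_groups), each = per_group), ] +
      matrix(rnorm(n_groups * per_group * V, 0, noise), n_groups * per_group)
    list(stack = as_map_stack(X),
         labels = rep(seq_len(n_groups), each = per_group))
  })
}

test_that("consensus selection recovers planted group counts", {
  for (g in 2:3) {
    ok <- 0
    for (seed in 1:5) {
      ps <- planted_stack(g, per_group = 15, seed = seed)
      rep <- consensus_select_k(ps$stack, k_range = 2:6, iters = 30,
                                seed = 100 + seed)
      if (attr(rep, "chosen_k") == g) ok <- ok + 1
      expect_true(all(rep$consensus >= 0 & rep$consensus <= 1, na.rm = TRUE))
      expect_equal(max(rep$consensus, na.rm = TRUE),
                   rep$consensus[rep$k == attr(rep, "chosen_k")])
    }
    expect_gte(ok, 4) # near-perfect recovery on separable stacks
  }
})

test_that("consensus approaches 1 at the true k and is lower elsewhere", {
  ps <- planted_stack(3, per_group = 15, seed = 2)
  rep <- consensus_select_k(ps$stack, k_range = 2:6, iters = 30, seed = 9)
  expect_gt(rep$consensus[rep$k == 3], 0.99)
  expect_gt(rep$consensus[rep$k == 3], max(rep$consensus[rep$k != 3]))
})

test_that("infeasible k values are skipped with a message", {
  ps <- planted_stack(2, per_group = 3, V = 10, seed = 3) # N = 6
  expect_message(
    rep <- consensus_select_k(ps$stack, k_range = c(2, 6, 7), iters = 10,
                              seed = 1),
    "skipped"
  )
  expect_true(all(is.na(rep$consensus[rep$k >= 6])))
})

test_that("k-means restarts recover the planted partition deterministically", {
  ps <- planted_stack(3, per_group = 20, seed = 4)
  km1 <- kmeans_maps(ps$stack, 3, seed = 11)
  km2 <- kmeans_maps(ps$stack, 3, seed = 11)
  expect_identical(km1$assignments, km2$assignments)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(km1$assignments, ps$labels)
  expect_gte(ari, 0.9)
  expect_error(kmeans_maps(ps$stack, 1, seed = 1),
               class = "urgepfm_parameter_error")
  expect_error(kmeans_maps(ps$stack, 60, seed = 1),
               class = "urgepfm_parameter_error")
})

test_that("map order permutation does not change the consensus curve", {
  ps <- planted_stack(2, per_group = 10, V = 30, seed = 5)
  perm <- withr::with_seed(1, sample(20))
  shuffled <- as_map_stack(ps$stack$maps[perm, ])
  r1 <- consensus_select_k(ps$stack, k_range = 2:4, iters = 20, seed = 3)
  r2 <- consensus_select_k(shuffled, k_range = 2:4, iters = 20, seed = 3)
  # same seeded subsample indices act on permuted rows: the consensus value
  # is a pair-exchangeable summary, so the curve shape must agree closely
  expect_equal(attr(r1, "chosen_k"), attr(r2, "chosen_k"))
  expect_equal(r1$consensus, r2$consensus, tolerance = 0.05)
})

test_that("cluster Z maps are normalised, flipped and thresholded", {
  set.seed(6)
  X <- rbind(
    matrix(rnorm(5 * 50), 5),              # cluster 1
    matrix(rnorm(5 * 50, mean = 1), 5)     # cluster 2
  )
  # one voxel with strongly negative delta-R2* in cluster 1
  X[1:5, 7] <- -50
  z <- cluster_zmaps(as_map_stack(X), rep(1:2, each = 5))
  for (cl in z$clusters) {
    expect_equal(mean(cl$z_map), 0, tolerance = 1e-9)
    expect_equal(sd(cl$z_map), 1, tolerance = 1e-9)
    expect_equal(cl$flipped_z, -cl$z_map)
  }
  # negative delta-R2* voxel becomes strongly positive after the flip
  expect_gt(z$clusters[[1]]$flipped_z[7], 3.2)
  expect_true(z$clusters[[1]]$positive_mask[7])
  # threshold monotonicity of the positive map
  z2 <- cluster_zmaps(as_map_stack(X), rep(1:2, each = 5), threshold = 5)
  expect_true(all(which(z2$clusters[[1]]$positive_mask) %in%
                    which(z$clusters[[1]]$positive_mask)))
  # a cluster of identical maps z-normalises the single map
  Xi <- X[rep(1, 4), ]
  zi <- cluster_zmaps(as_map_stack(Xi), rep(1, 4))
  expect_equal(zi$clusters[[1]]$z_map,
               (X[1, ] - mean(X[1, ])) / sd(X[1, ]))
  # zero spatial variance errors
  expect_error(cluster_zmaps(as_map_stack(matrix(1, 3, 10)), rep(1, 3)),
               class = "urgepfm_degenerate_cluster_error")
})

test_that("event maps collect into a stack with provenance", {
  es <- structure(list(
    peaks = tibble::tibble(peak_tr = c(4L, 9L), roi_count = c(5L, 3L)),
    maps = list(array(1, c(2, 2, 2)), array(2, c(2, 2, 2))),
    roi_counts = integer(12), roi_threshold = 0, grid = c(2, 2, 2)
  ), class = "event_set")
  st <- collect_event_maps(list(es, es), provenance = c("runA", "runB"))
  expect_equal(dim(st$maps), c(4, 8))
  expect_equal(st$provenance$run, c("runA", "runA", "runB", "runB"))
  expect_equal(st$provenance$peak_tr, c(4L, 9L, 4L, 9L))
})
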