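#' Stack single-event activation maps
#'
#' Collects the 3D activation maps attached to selected ATS peaks (possibly
#' from several runs) into an N x V matrix over a common voxel mask, the input
#' to clustering.
#'
#' @param event_sets A single `event_set` or a list of them.
#' @param mask Logical 3D array defining the voxel space (default: all voxels
#'   of the maps' grid).
#' @param provenance Optional character vector of run labels (one per event
#'   set).
#' @return Object of class `map_stack`: list with `maps` (N x V matrix),
#'   `mask`, `grid`, `provenance` (tibble `run`, `peak_tr`).
#' @export
collect_event_maps <- function(event_sets, mask = NULL, provenance = NULL) {
  if (inherits(event_sets, "event_set")) event_sets <- list(event_sets)
  grid <- event_sets[[1]]$grid
  if (is.null(mask)) mask <- array(TRUE, grid)
  m <- as.logical(mask)
  runs <- provenance %||% as.character(seq_along(event_sets))
  rows <- list()
  prov <- list()
  for (i in seq_along(event_sets)) {
    es <- event_sets[[i]]
    for (j in seq_along(es$maps)) {
      rows[[length(rows) + 1]] <- as.numeric(es$maps[[j]])[m]
      prov[[length(prov) + 1]] <- tibble(run = runs[i],
                                         peak_tr = es$peaks$peak_tr[j])
    }
  }
  structure(
    list(
      maps = do.call(rbind, rows), mask = array(m, grid), grid = grid,
      provenance = dplyr::bind_rows(prov)
    ),
    class = "map_stack"
  )
}

#' Build a map stack directly from a matrix
#'
#' @param maps N x V numeric matrix (one activation map per row).
#' @param grid Optional grid dims; defaults to a flat 1D geometry.
#' @return A `map_stack`.
#' @export
as_map_stack <- function(maps, grid = c(ncol(maps), 1, 1)) {
  structure(
    list(maps = maps, mask = array(TRUE, grid), grid = grid,
         provenance = tibble(run = NA_character_,
                             peak_tr = seq_len(nrow(maps)))),
    class = "map_stack"
  )
}

#' @export
print.map_stack <- function(x, ...) {
  cat(sprintf("<map_stack: %d maps x %d voxels>\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

#' Choose the number of clusters by consensus
#'
#' For each k in `k_range` and each of `iters` iterations, k-means (squared
#' Euclidean objective on the raw map vectors, which is equivalent to
#' clustering the pairwise Euclidean distances between maps) is run on a
#' random `subsample` fraction of the maps. The co-assignment proportion
#' `m_ij` of every pair - over the iterations in which both members were
#' subsampled - is then summarised into a consensus value:
#'
#' * `method = "agreement"` (default): the mean over pairs of
#'   `m_ij^2 + (1 - m_ij)^2`, the probability that two independent subsampled
#'   clusterings agree about a random pair. It equals 1 exactly when every
#'   pair is either always or never co-clustered, i.e. when the partition is
#'   perfectly reproducible, and peaks at the planted k.
#' * `method = "together"`: the mean fraction of co-subsampled pairs assigned
#'   to the same cluster. This quantity is monotonically inflated for small k
#'   (merging groups always raises it), so it is reported for reference but
#'   not recommended for selection.
#'
#' The chosen k maximises the consensus value; exact ties at the maximum
#' resolve to the larger k (a perfectly reproducible coarse merge tied with
#' its equally reproducible refinement carries less structure). Values of k
#' with too few maps (N <= k) are skipped with a message.
#'
#' @param stack A `map_stack` (or N x V matrix).
#' @param k_range Candidate cluster counts (default 2:15).
#' @param subsample Fraction of maps per iteration (default 0.8).
#' @param iters Iterations per k (default 100).
#' @param seed Integer seed.
#' @param method Consensus summary, see above.
#' @return Object of class `consensus_report`: tibble with columns `k`,
#'   `consensus`, and attributes `chosen_k`, `method`.
#' @export
consensus_select_k <- function(stack, k_range = 2:15, subsample = 0.8,
                               iters = 100, seed = 1L,
                               method = c("agreement", "together")) {
  method <- match.arg(method)
  X <- if (inherits(stack, "map_stack")) stack$maps else as.matrix(stack)
  N <- nrow(X)
  m_sub <- ceiling(subsample * N)
  withr::with_seed(seed, {
    vals <- purrr::map_dbl(k_range, function(k) {
      if (N <= k) {
        message(sprintf("k = %d skipped: only %d maps", k, N))
        return(NA_real_)
      }
      together <- matrix(0, N, N)
      cosub <- matrix(0, N, N)
      frac_sum <- 0
      for (it in seq_len(iters)) {
        idx <- sample.int(N, m_sub)
        cl <- safe_kmeans(X[idx, , drop = FALSE], k)
        eq <- outer(cl, cl, "==")
        together[idx, idx] <- together[idx, idx] + eq
        cosub[idx, idx] <- cosub[idx, idx] + 1
        frac_sum <- frac_sum + (sum(eq) - m_sub) / (m_sub * (m_sub - 1))
      }
      if (method == "together") {
        frac_sum / iters
      } else {
        seen <- upper.tri(cosub) & cosub > 0
        m <- together[seen] / cosub[seen]
        mean(m^2 + (1 - m)^2)
      }
    })
  })
  ok <- !is.na(vals)
  # ties at the maximum resolve to the larger k: when a coarse merge and its
  # refinement are both perfectly reproducible, the finer partition carries
  # the extra structure (exact ties only arise in that fully stable regime)
  tied <- ok & vals >= max(vals[ok]) - 1e-9
  chosen <- max(k_range[tied])
  out <- tibble(k = k_range, consensus = vals)
  structure(out, chosen_k = chosen, method = method,
            class = c("consensus_report", class(out)))
}

# kmeans++ seeding: spread initial centres with probability proportional to
# the squared distance from the centres already chosen
kmeanspp_centers <- function(X, k, xx = rowSums(X^2)) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- pmax(0, xx - 2 * as.numeric(X %*% X[idx[1], ]) + xx[idx[1]])
  for (j in seq_len(k - 1)) {
    idx[j + 1] <- if (all(d2 <= 0)) {
      sample.int(n, 1) # duplicate rows: fall back to uniform
    } else {
      sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, pmax(0, xx - 2 * as.numeric(X %*% X[idx[j + 1], ]) +
                             xx[idx[j + 1]]))
  }
  X[idx, , drop = FALSE]
}

# one k-means run from kmeans++ centres, with retries on degenerate starts;
# the smart seeding keeps local optima from polluting the consensus value
safe_kmeans <- function(X, k, restarts = 1, iter.max = 25) {
  best <- NULL
  for (attempt in seq_len(restarts + 3)) {
    fit <- tryCatch(
      suppressWarnings(kmeans(X, centers = kmeanspp_centers(X, k),
                              iter.max = iter.max)),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
    if (!is.null(best) && attempt >= restarts) break
  }
  if (is.null(best)) {
    abort("k-means failed repeatedly", class = "urgepfm_cluster_error")
  }
  best$cluster
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report: chosen k = %d (%s)>\n",
              attr(x, "chosen_k"), attr(x, "method")))
  NextMethod()
}

#' @rdname autoplot-urgepfm
#' @method autoplot consensus_report
#' @export
autoplot.consensus_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$k, .data$consensus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "k", y = "consensus value") +
    ggplot2::theme_minimal()
}

#' K-means clustering of activation maps with restarts
#'
#' Runs k-means on the raw map vectors with `restarts` random centroid
#' initialisations and keeps the solution with the smallest within-cluster sum
#' of squares. Deterministic given the seed.
#'
#' @param stack A `map_stack` or N x V matrix.
#' @param k Number of clusters, `2 <= k <= N - 1`.
#' @param restarts Number of random restarts (default 50).
#' @param seed Integer seed.
#' @return Object of class `map_clusters`: list with `assignments` (integer
#'   N), `centroids` (k x V), `withinss`, `k`, `stack`.
#' @export
kmeans_maps <- function(stack, k, restarts = 50, seed = 1L) {
  X <- if (inherits(stack, "map_stack")) stack$maps else as.matrix(stack)
  N <- nrow(X)
  if (k < 2 || k > N - 1) {
    abort(sprintf("k must be in [2, %d]", N - 1),
          class = "urgepfm_parameter_error")
  }
  fit <- withr::with_seed(seed, suppressWarnings(
    kmeans(X, centers = k, nstart = restarts, iter.max = 50)
  ))
  structure(
    list(assignments = fit$cluster, centroids = fit$centers,
         withinss = fit$tot.withinss, k = k,
         stack = if (inherits(stack, "map_stack")) stack else as_map_stack(X)),
    class = "map_clusters"
  )
}

#' @export
print.map_clusters <- function(x, ...) {
  cat(sprintf("<map_clusters: k = %d, sizes %s>\n", x$k,
              paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}

#' Spatially Z-normalised cluster maps with BOLD sign flip
#'
#' For each cluster: average the member maps voxelwise, Z-normalise in space
#' (subtract the spatial mean of the delta-R2* values, divide by the spatial
#' SD), multiply by -1 so that positive values encode positive BOLD (the
#' deconvolution estimates R2* changes, whose negative deflections are
#' positive BOLD), and binarize the flipped map at `threshold`.
#'
#' @param stack A `map_stack` or N x V matrix.
#' @param assignments Integer cluster labels, one per map (e.g. from
#'   [kmeans_maps()]).
#' @param threshold Z threshold for the binarized positive map (default 3.2).
#' @return Object of class `cluster_zmaps`: list with per-cluster `mean_map`,
#'   `z_map`, `flipped_z`, `positive_mask` (all V vectors / logical), plus
#'   `threshold`, `grid`, `mask`.
#' @export
cluster_zmaps <- function(stack, assignments, threshold = 3.2) {
  X <- if (inherits(stack, "map_stack")) stack$maps else as.matrix(stack)
  grid <- if (inherits(stack, "map_stack")) stack$grid else c(ncol(X), 1, 1)
  msk <- if (inherits(stack, "map_stack")) stack$mask else array(TRUE, grid)
  ks <- sort(unique(assignments))
  if (length(assignments) != nrow(X)) {
    abort("one assignment per map is required", class = "urgepfm_parameter_error")
  }
  clusters <- lapply(ks, function(k) {
    mean_map <- colMeans(X[assignments == k, , drop = FALSE])
    s <- sd(mean_map)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("cluster %d has zero spatial variance", k),
            class = "urgepfm_degenerate_cluster_error")
    }
    # z map has spatial mean 0 and (sample) SD 1 by construction
    z <- (mean_map - mean(mean_map)) / s
    flipped <- -z
    list(cluster = k, mean_map = mean_map, z_map = z, flipped_z = flipped,
         positive_mask = flipped >= threshold)
  })
  structure(
    list(clusters = clusters, threshold = threshold, grid = grid, mask = msk),
    class = "cluster_zmaps"
  )
}

#' @export
print.cluster_zmaps <- function(x, ...) {
  cat(sprintf("<cluster_zmaps: %d clusters, Z >= %.1f positive voxels: %s>\n",
              length(x$clusters), x$threshold,
              paste(vapply(x$clusters, function(cl) sum(cl$positive_mask),
                           integer(1)), collapse = "/")))
  invisible(x)
}
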