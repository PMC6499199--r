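#' Clustering parameters
#'
#' `d_min` is the dart-throwing rejection distance: no two cluster seeds may
#' lie within `d_min` of each other, which makes `d_min` the nominal cluster
#' diameter under nearest-seed assignment. The defaults (0.15 m seeds, 100
#' point minimum cluster size) suit tree crowns scanned at a few thousand
#' points per square meter.
#'
#' @param d_min Minimum seed separation in meters.
#' @param min_size Smallest cluster size kept by initial clustering (points).
#' @param rng_seed Integer seed driving the dart-throwing permutation.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(d_min = 0.15, min_size = 100L, rng_seed = 1L) {
  stopifnot(d_min > 0, min_size >= 1)
  structure(list(d_min = as.numeric(d_min), min_size = as.integer(min_size),
                 rng_seed = as.integer(rng_seed)),
            class = "cluster_params")
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Poisson-disk seed selection by dart throwing
#'
#' Visits the points of the cloud in a seeded random permutation; a visited
#' point is accepted as a cluster seed iff no already-accepted seed lies
#' within distance `d_min` of it. Neighbor tests run on a 3D spatial index.
#' The accepted set is a maximal Poisson-disk sample: seeds are pairwise
#' `>= d_min` apart and every point of the cloud lies within `d_min` of some
#' seed. Acceptance order defines the label order.
#'
#' @param cloud A non-empty [point_cloud()].
#' @param d_min Rejection distance in meters.
#' @param rng_seed Integer seed for the visiting permutation.
#' @return Integer vector of seed point indices, in acceptance order.
#' @export
poisson_disk_seeds <- function(cloud, d_min = 0.15, rng_seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n == 0L) stop("cannot seed an empty cloud")
  ord <- with_rng_seed(rng_seed, sample.int(n))
  cpp_poisson_disk(cloud$coords, ord, d_min)
}

#' Label every point by its nearest seed
#'
#' Euclidean nearest-neighbor assignment; the label is the 1-based position
#' of the seed in `seed_indices`. Exact distance ties resolve to the lowest
#' seed index.
#'
#' @param cloud A [point_cloud()].
#' @param seed_indices Integer indices of seed points in `cloud`.
#' @return Integer label vector of length `n_points(cloud)`.
#' @export
label_by_nearest_seed <- function(cloud, seed_indices) {
  stopifnot(inherits(cloud, "point_cloud"), length(seed_indices) >= 1L)
  ref <- cloud$coords[seed_indices, , drop = FALSE]
  cpp_nn1(ref, cloud$coords)
}

#' Remove small clusters and relabel their points
#'
#' Clusters with fewer than `min_size` members lose their labels; each
#' orphaned point then takes the label of its nearest remaining labeled
#' point. Surviving cluster ids are renumbered contiguously `1..K'`,
#' preserving their original order. Surviving clusters can only grow, so
#' every final cluster has at least `min_size` members.
#'
#' @param cloud A [point_cloud()].
#' @param labels Integer labels from [label_by_nearest_seed()].
#' @param min_size Minimum surviving cluster size (points).
#' @return Integer label vector, values in `1..K'`.
#' @export
prune_and_relabel <- function(cloud, labels, min_size = 100L) {
  stopifnot(inherits(cloud, "point_cloud"), length(labels) == n_points(cloud))
  if (length(labels) == 0L) return(integer(0))
  K <- max(labels)
  sizes <- tabulate(labels, nbins = K)
  survive <- which(sizes >= min_size)
  if (length(survive) == 0L) stop("no cluster survives pruning")
  orphan <- !(labels %in% survive)
  if (any(orphan)) {
    kept_idx <- which(!orphan)
    nn <- cpp_nn1(cloud$coords[kept_idx, , drop = FALSE],
                  cloud$coords[orphan, , drop = FALSE])
    labels[orphan] <- labels[kept_idx[nn]]
  }
  remap <- integer(K)
  remap[survive] <- seq_along(survive)
  remap[labels]
}

#' Two-phase initial clustering of the first DAI
#'
#' Composition of [poisson_disk_seeds()], [label_by_nearest_seed()] and
#' [prune_and_relabel()]; fully deterministic given `params$rng_seed`.
#' Run on a preprocessed (isolation-filtered) object point cloud.
#'
#' @param cloud A non-empty [point_cloud()].
#' @param params A [cluster_params()].
#' @return A `cluster_labeling`: list with `labels` (1..K), `seed_indices`
#'   (surviving seeds, label order) and `K`.
#' @export
initial_clustering <- function(cloud, params = cluster_params()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "cluster_params"))
  seeds <- poisson_disk_seeds(cloud, params$d_min, params$rng_seed)
  labels0 <- label_by_nearest_seed(cloud, seeds)
  labels <- prune_and_relabel(cloud, labels0, params$min_size)
  sizes0 <- tabulate(labels0, nbins = length(seeds))
  structure(list(labels = labels,
                 seed_indices = seeds[sizes0 >= params$min_size],
                 K = max(labels)),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling> %d points in %d clusters (median size %d)\n",
              length(x$labels), x$K,
              as.integer(stats::median(tabulate(x$labels, x$K)))))
  invisible(x)
}

#' Median cluster centers
#'
#' The cluster center is the per-axis median of the member coordinates (even
#' counts use the midpoint of the two central values), chosen over the mean
#' to blunt the influence of stray points. Cluster ids absent from `labels`
#' get an `NA` center and a `missing` flag.
#'
#' @param cloud A [point_cloud()].
#' @param labels Integer labels (`>= 1`); 0 marks unassigned points, which
#'   are ignored.
#' @param K Number of clusters; defaults to `max(labels)`.
#' @return List with `centers` (`K x 3` matrix, m), `counts` (integer K),
#'   `missing` (logical K).
#' @export
compute_centers <- function(cloud, labels, K = max(labels)) {
  stopifnot(inherits(cloud, "point_cloud"), length(labels) == n_points(cloud))
  centers <- matrix(NA_real_, K, 3, dimnames = list(NULL, c("x", "y", "z")))
  counts <- tabulate(labels[labels > 0L], nbins = K)
  ord <- order(labels)
  ord <- ord[labels[ord] > 0L]
  splits <- split(ord, labels[ord])
  for (nm in names(splits)) {
    k <- as.integer(nm)
    idx <- splits[[nm]]
    centers[k, ] <- apply(cloud$coords[idx, , drop = FALSE], 2, stats::median)
  }
  list(centers = centers, counts = counts, missing = counts == 0L)
}
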