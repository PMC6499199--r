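#' Propagate cluster labels to a new epoch
#'
#' Every point of the new cloud takes the label of its Euclidean
#' nearest labeled reference point (exact ties resolve to the lowest
#' reference index). This is the per-epoch step of the iterative
#' nearest-neighbor clustering cycle: clusters are re-seeded never, so new
#' structure always enters existing clusters.
#'
#' @param ref_cloud Reference [point_cloud()] (previous epoch).
#' @param ref_labels Integer labels (`>= 1`) for `ref_cloud`.
#' @param new_cloud The new epoch's preprocessed [point_cloud()].
#' @return Integer labels for `new_cloud`.
#' @export
propagate_labels <- function(ref_cloud, ref_labels, new_cloud) {
  stopifnot(inherits(ref_cloud, "point_cloud"), inherits(new_cloud, "point_cloud"),
            length(ref_labels) == n_points(ref_cloud))
  if (n_points(ref_cloud) == 0L) stop("empty reference cloud")
  if (any(ref_labels < 1L)) stop("all reference labels must be >= 1")
  nn <- cpp_nn1(ref_cloud$coords, new_cloud$coords)
  ref_labels[nn]
}

#' Track clusters across a DAI sequence
#'
#' Runs the full temporal pipeline: each epoch's cloud is preprocessed
#' ([preprocess_cloud()]), the first epoch is clustered with
#' [initial_clustering()], and labels flow forward by nearest-neighbor
#' propagation. In `"chain"` mode (default) epoch `i` inherits labels from
#' epoch `i-1`'s labeled cloud; in `"anchor-initial"` mode always from epoch
#' 0. Per cluster and epoch the median center and member count are stored;
#' a cluster that receives no points at an epoch is flagged missing there
#' (its center is not carried forward, and in chain mode it cannot recruit
#' points later).
#'
#' @param dais A [dai_sequence()].
#' @param params A [cluster_params()].
#' @param fparams A [filter_params()].
#' @param mode `"chain"` or `"anchor-initial"` label propagation.
#' @param preprocess Logical; set `FALSE` if the clouds are already filtered.
#' @return A `cluster_tracks`: list with `centers` (`K x 3 x n_dai` array,
#'   m), `counts` (`K x n_dai`), `missing` (`K x n_dai` logical),
#'   `timestamps`, `K`, `mode`, `labels0` (first-epoch labeling),
#'   `params`.
#' @export
track_sequence <- function(dais, params = cluster_params(),
                           fparams = filter_params(),
                           mode = c("chain", "anchor-initial"),
                           preprocess = TRUE) {
  stopifnot(inherits(dais, "dai_sequence"))
  mode <- match.arg(mode)
  nd <- length(dais$clouds)
  clouds <- dais$clouds
  if (preprocess) clouds <- lapply(clouds, preprocess_cloud, params = fparams)
  if (n_points(clouds[[1L]]) == 0L) stop("first DAI is empty after filtering")

  lab0 <- initial_clustering(clouds[[1L]], params)
  K <- lab0$K
  centers <- array(NA_real_, c(K, 3, nd))
  counts <- matrix(0L, K, nd)

  ref_cloud <- clouds[[1L]]
  ref_labels <- lab0$labels
  cc <- compute_centers(ref_cloud, ref_labels, K)
  centers[, , 1L] <- cc$centers
  counts[, 1L] <- cc$counts
  anchor_cloud <- ref_cloud
  anchor_labels <- ref_labels

  for (i in seq_len(nd - 1L) + 1L) {
    cl <- clouds[[i]]
    if (n_points(cl) == 0L) {
      warning("DAI ", i - 1L, " is empty after filtering; marked missing wholesale")
      next
    }
    labels <- if (mode == "chain") {
      propagate_labels(ref_cloud, ref_labels, cl)
    } else {
      propagate_labels(anchor_cloud, anchor_labels, cl)
    }
    cc <- compute_centers(cl, labels, K)
    centers[, , i] <- cc$centers
    counts[, i] <- cc$counts
    if (mode == "chain") {
      ref_cloud <- cl
      ref_labels <- labels
    }
  }
  structure(list(centers = centers, counts = counts, missing = counts == 0L,
                 timestamps = dais$timestamps, K = K, mode = mode,
                 labels0 = lab0, cloud0 = clouds[[1L]], params = params),
            class = "cluster_tracks")
}

#' @export
print.cluster_tracks <- function(x, ...) {
  cat(sprintf("<cluster_tracks> %d clusters over %d DAIs (%s propagation); %d cluster-DAI cells missing\n",
              x$K, ncol(x$counts), x$mode, sum(x$missing)))
  invisible(x)
}

#' Per-cluster displacement series
#'
#' Euclidean 3D distance of each cluster center from its reference center:
#' the initial epoch (total displacement, the mode used for result maps) or
#' the previous epoch (inter-epoch movement amplitude). Missing centers
#' propagate `NA`.
#'
#' @param tracks A `cluster_tracks` from [track_sequence()].
#' @param reference `"initial"` or `"previous"`.
#' @return A `displacement_series`: list with `disp` (`K x n_dai` matrix,
#'   m), `reference`, `timestamps`.
#' @export
displacements <- function(tracks, reference = c("initial", "previous")) {
  stopifnot(inherits(tracks, "cluster_tracks"))
  reference <- match.arg(reference)
  K <- tracks$K
  nd <- dim(tracks$centers)[3L]
  disp <- matrix(NA_real_, K, nd)
  for (i in seq_len(nd)) {
    ref_i <- if (reference == "initial") 1L else max(i - 1L, 1L)
    d <- tracks$centers[, , i, drop = FALSE] - tracks$centers[, , ref_i, drop = FALSE]
    disp[, i] <- sqrt(rowSums(matrix(d, K, 3)^2))
  }
  structure(list(disp = disp, reference = reference,
                 timestamps = tracks$timestamps),
            class = "displacement_series")
}

#' Export tracks / displacements as tidy tables
#'
#' @param tracks A `cluster_tracks`.
#' @return `tracks_table()`: data frame (`cluster_id`, `dai`, `timestamp_s`,
#'   `n`, `cx_m`, `cy_m`, `cz_m`, `missing`).
#' @export
tracks_table <- function(tracks) {
  stopifnot(inherits(tracks, "cluster_tracks"))
  nd <- dim(tracks$centers)[3L]
  K <- tracks$K
  data.frame(
    cluster_id = rep(seq_len(K), nd),
    dai = rep(seq_len(nd) - 1L, each = K),
    timestamp_s = rep(tracks$timestamps, each = K),
    n = as.vector(tracks$counts),
    cx_m = as.vector(tracks$centers[, 1L, ]),
    cy_m = as.vector(tracks$centers[, 2L, ]),
    cz_m = as.vector(tracks$centers[, 3L, ]),
    missing = as.vector(tracks$missing)
  )
}

#' @rdname tracks_table
#' @param disp A `displacement_series`.
#' @return `displacement_table()`: data frame (`cluster_id`, `dai`,
#'   `timestamp_s`, `displacement_m`, `reference_mode`).
#' @export
displacement_table <- function(disp) {
  stopifnot(inherits(disp, "displacement_series"))
  K <- nrow(disp$disp)
  nd <- ncol(disp$disp)
  data.frame(
    cluster_id = rep(seq_len(K), nd),
    dai = rep(seq_len(nd) - 1L, each = K),
    timestamp_s = rep(disp$timestamps, each = K),
    displacement_m = as.vector(disp$disp),
    reference_mode = disp$reference
  )
}
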