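#' Construct a point cloud
#'
#' The universal container of the pipeline: an `n x 3` coordinate matrix in
#' meters (right-handed, z-up) with optional per-point raw scanner intensity,
#' a scanner label, and a timestamp in seconds since sequence start.
#'
#' @param coords Numeric `n x 3` matrix of x, y, z coordinates in meters.
#' @param intensity Optional numeric vector of raw intensity counts, length `n`.
#' @param scanner_id Optional scanner label (scalar character).
#' @param timestamp Optional acquisition time in seconds since sequence start.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(coords, intensity = NULL, scanner_id = NULL,
                        timestamp = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) {
    coords <- matrix(numeric(0), ncol = 3)
  }
  if (ncol(coords) != 3L) {
    stop("coords must have exactly 3 columns (x, y, z)")
  }
  storage.mode(coords) <- "double"
  if (nrow(coords) > 0L && !all(is.finite(coords))) {
    stop("all coordinates must be finite")
  }
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != nrow(coords)) {
      stop("intensity must have one value per point")
    }
  }
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(coords = coords, intensity = intensity,
         scanner_id = scanner_id, timestamp = timestamp),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s%s\n", n_points(x),
              if (!is.null(x$intensity)) ", with intensity" else "",
              if (!is.null(x$scanner_id)) paste0(", scanner ", x$scanner_id) else "",
              if (!is.null(x$timestamp)) sprintf(", t = %.0f s", x$timestamp) else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A `point_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$coords)
}

#' Subset a point cloud by point index
#'
#' Keeps coordinate/intensity alignment; point order follows `idx`. Any
#' additional per-point atomic field attached to the cloud (e.g. `scanner`,
#' or the synthetic generator's `component` and `true_disp_m`) is subset
#' alongside the coordinates.
#'
#' @param cloud A `point_cloud`.
#' @param idx Integer or logical index vector.
#' @return A `point_cloud` restricted to `idx`.
#' @export
subset_cloud <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  out <- point_cloud(cloud$coords[idx, , drop = FALSE],
                     intensity = if (!is.null(cloud$intensity)) cloud$intensity[idx],
                     scanner_id = cloud$scanner_id,
                     timestamp = cloud$timestamp)
  extras <- setdiff(names(cloud), c("coords", "intensity", "scanner_id", "timestamp"))
  for (nm in extras) {
    v <- cloud[[nm]]
    if (is.atomic(v) && length(v) == n) out[[nm]] <- v[idx]
  }
  out
}

#' Merge co-registered point clouds
#'
#' Concatenates clouds that already share one coordinate frame (merging is
#' meaningful only after co-registration). Point order is the concatenation
#' order of the input list; per-point scanner labels are retained.
#'
#' @param clouds A non-empty list of `point_cloud` objects.
#' @return A `point_cloud` with `sum(n)` points and a per-point `scanner`
#'   attribute (character vector) recording provenance.
#' @export
merge_clouds <- function(clouds) {
  if (!is.list(clouds) || length(clouds) == 0L) {
    stop("merge_clouds() needs a non-empty list of point clouds")
  }
  lapply(clouds, function(c) stopifnot(inherits(c, "point_cloud")))
  coords <- do.call(rbind, lapply(clouds, function(c) c$coords))
  if (is.null(coords)) coords <- matrix(numeric(0), ncol = 3)
  has_int <- vapply(clouds, function(c) !is.null(c$intensity), logical(1))
  intensity <- NULL
  if (all(has_int)) {
    intensity <- unlist(lapply(clouds, function(c) c$intensity), use.names = FALSE)
  }
  scanner <- unlist(lapply(clouds, function(c) {
    rep(if (is.null(c$scanner_id)) NA_character_ else as.character(c$scanner_id),
        n_points(c))
  }), use.names = FALSE)
  out <- point_cloud(coords, intensity = intensity,
                     timestamp = clouds[[1L]]$timestamp)
  out$scanner <- scanner
  out
}

#' Assemble a DAI sequence
#'
#' A Data Acquisition Interval (DAI) is one epoch of the time series: the
#' merged point cloud captured in one scanning window. Timestamps must be
#' strictly increasing.
#'
#' @param clouds List of `point_cloud` objects, one per DAI, in time order.
#' @param timestamps Numeric vector of epoch times (seconds since sequence
#'   start); defaults to each cloud's own `timestamp`.
#' @return A `dai_sequence`: list with `clouds`, `timestamps` and 0-based
#'   `dai_index`.
#' @export
dai_sequence <- function(clouds, timestamps = NULL) {
  stopifnot(is.list(clouds), length(clouds) >= 1L)
  lapply(clouds, function(c) stopifnot(inherits(c, "point_cloud")))
  if (is.null(timestamps)) {
    timestamps <- vapply(clouds, function(c) {
      if (is.null(c$timestamp)) NA_real_ else c$timestamp
    }, numeric(1))
  }
  if (anyNA(timestamps)) stop("every DAI needs a timestamp")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(
    list(clouds = clouds, timestamps = as.numeric(timestamps),
         dai_index = seq_along(clouds) - 1L),
    class = "dai_sequence"
  )
}

#' @export
print.dai_sequence <- function(x, ...) {
  cat(sprintf("<dai_sequence> %d DAIs, %.0f-%.0f s, %s points/DAI (median)\n",
              length(x$clouds), min(x$timestamps), max(x$timestamps),
              format(stats::median(vapply(x$clouds, n_points, numeric(1))))))
  invisible(x)
}
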