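#' Point-filter parameters
#'
#' Defaults follow common TLS practice for phase-based scanners at a few tens
#' of meters: a 3x3 stray-point window with a 0.02 m range gate and a 50%
#' allocation threshold, a raw-intensity floor of 650 counts, and an isolated
#' point rule of at least two neighbors within 0.01 m.
#'
#' @param stray_window Odd window edge length in cells (>= 3).
#' @param stray_range_thresh Range-agreement gate in meters.
#' @param stray_alloc_thresh Minimum fraction of range-consistent neighbors,
#'   in (0, 1].
#' @param min_intensity Raw-intensity floor (counts); points below it are
#'   removed.
#' @param iso_radius Isolation-filter neighborhood radius in meters.
#' @param iso_min_neighbors Minimum neighbor count within `iso_radius`.
#' @return A `filter_params` list.
#' @export
filter_params <- function(stray_window = 3L, stray_range_thresh = 0.02,
                          stray_alloc_thresh = 0.5, min_intensity = 650,
                          iso_radius = 0.01, iso_min_neighbors = 2L) {
  stray_window <- as.integer(stray_window)
  if (stray_window < 3L || stray_window %% 2L == 0L) {
    stop("stray_window must be an odd integer >= 3")
  }
  stopifnot(stray_range_thresh > 0, stray_alloc_thresh > 0,
            stray_alloc_thresh <= 1, min_intensity > 0,
            iso_radius > 0, iso_min_neighbors >= 1)
  structure(list(stray_window = stray_window,
                 stray_range_thresh = stray_range_thresh,
                 stray_alloc_thresh = stray_alloc_thresh,
                 min_intensity = min_intensity,
                 iso_radius = iso_radius,
                 iso_min_neighbors = as.integer(iso_min_neighbors)),
            class = "filter_params")
}

#' Structured scan grid
#'
#' A scanner's range image: a `rows x cols` array of range values (meters)
#' with a validity mask, as produced by a rotating-mirror TLS. Only needed by
#' [stray_filter()]; unstructured clouds skip that filter.
#'
#' @param ranges Numeric matrix of ranges (m); `NA` where no return.
#' @param valid Optional logical matrix; defaults to `!is.na(ranges)`.
#' @return A `scan_grid`.
#' @export
scan_grid <- function(ranges, valid = NULL) {
  ranges <- as.matrix(ranges)
  if (is.null(valid)) valid <- !is.na(ranges)
  valid <- as.matrix(valid)
  if (!all(dim(valid) == dim(ranges))) stop("mask dimensions must match ranges")
  valid <- valid & !is.na(ranges)
  if (any(ranges[valid] <= 0)) stop("ranges must be positive where valid")
  structure(list(ranges = ranges, valid = valid), class = "scan_grid")
}

#' Stray-point filter on a structured scan
#'
#' Single-pass range-image filter: a cell survives iff, among the valid cells
#' of its centered `w x w` neighborhood (the cell itself excluded, windows
#' truncated at the image border), the fraction whose range differs from the
#' center range by at most `stray_range_thresh` is at least
#' `stray_alloc_thresh`. Cells with no valid neighbor are removed. Removals
#' do not cascade: every cell is judged against the input mask.
#'
#' @param grid A [scan_grid()].
#' @param params A [filter_params()].
#' @return Logical matrix: `TRUE` where the cell is kept.
#' @export
stray_filter <- function(grid, params = filter_params()) {
  stopifnot(inherits(grid, "scan_grid"), inherits(params, "filter_params"))
  r <- grid$ranges
  v <- grid$valid
  nr <- nrow(r); nc <- ncol(r)
  keep <- matrix(FALSE, nr, nc)
  if (nr == 0L || nc == 0L) return(keep)
  half <- (params$stray_window - 1L) %/% 2L

  n_valid <- matrix(0L, nr, nc)
  n_close <- matrix(0L, nr, nc)
  rz <- r
  rz[!v] <- 0
  for (di in -half:half) {
    for (dj in -half:half) {
      if (di == 0L && dj == 0L) next
      sv <- shift_matrix(v, di, dj, FALSE)
      sr <- shift_matrix(rz, di, dj, 0)
      n_valid <- n_valid + sv
      n_close <- n_close + (sv & abs(sr - rz) <= params$stray_range_thresh)
    }
  }
  ok <- n_valid > 0L & n_close >= params$stray_alloc_thresh * n_valid
  keep <- v & ok
  keep
}

# Shift a matrix by (di, dj), filling vacated cells with `fill`.
shift_matrix <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) + di
  cj <- seq_len(nc) + dj
  okr <- ri >= 1L & ri <= nr
  okc <- cj >= 1L & cj <= nc
  out[okr, okc] <- m[ri[okr], cj[okc], drop = FALSE]
  out
}

#' Raw-intensity filter
#'
#' Removes points whose raw scanner intensity falls below the floor; a point
#' with intensity exactly at the floor is kept. Order-preserving.
#'
#' @param cloud A [point_cloud()] carrying intensity.
#' @param min_intensity Intensity floor in raw counts.
#' @return The filtered `point_cloud`.
#' @export
intensity_filter <- function(cloud, min_intensity = 650) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$intensity)) {
    stop("cloud has no intensity attribute; skip the intensity filter for this input")
  }
  subset_cloud(cloud, cloud$intensity >= min_intensity)
}

#' Isolated-point filter
#'
#' Keeps exactly the points that have at least `iso_min_neighbors` other
#' points within Euclidean distance `iso_radius` (closed ball). Neighbor
#' counts are taken on the input cloud in a single pass; the filter is
#' applied once per DAI, not iterated.
#'
#' @param cloud A [point_cloud()].
#' @param iso_radius Neighborhood radius in meters.
#' @param iso_min_neighbors Minimum neighbor count.
#' @return The filtered `point_cloud` (order preserved).
#' @export
isolation_filter <- function(cloud, iso_radius = 0.01, iso_min_neighbors = 2L) {
  stopifnot(inherits(cloud, "point_cloud"), iso_radius > 0, iso_min_neighbors >= 0)
  if (n_points(cloud) == 0L) return(cloud)
  counts <- cpp_radius_count(cloud$coords, iso_radius)
  subset_cloud(cloud, counts >= iso_min_neighbors)
}

#' Per-DAI preprocessing
#'
#' Applies the filter cascade used throughout the pipeline, in order:
#' intensity floor (only when the cloud carries intensity), then isolated
#' point removal. The structured stray filter runs upstream on each
#' scanner's range image, before clouds are merged, and is therefore not
#' part of this unstructured-cloud cascade.
#'
#' @param cloud A [point_cloud()].
#' @param params A [filter_params()].
#' @return The filtered `point_cloud`.
#' @export
preprocess_cloud <- function(cloud, params = filter_params()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "filter_params"))
  if (!is.null(cloud$intensity)) {
    cloud <- intensity_filter(cloud, params$min_intensity)
  }
  isolation_filter(cloud, params$iso_radius, params$iso_min_neighbors)
}
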