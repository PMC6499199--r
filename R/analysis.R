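#' Principal axis for cylindrical projection
#'
#' An operator-chosen vertical line through the target's stem. The azimuth
#' origin is fixed by projecting the global +x axis onto the plane normal to
#' `direction` (falling back to +y when they are parallel), so angles are
#' reproducible.
#'
#' @param origin 3-vector, a point on the stem (m).
#' @param direction 3-vector, near-vertical axis direction (normalized
#'   internally).
#' @return A `principal_axis`.
#' @export
principal_axis <- function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("axis direction must be nonzero")
  d <- direction / nrm
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * d) * d
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
          d[3L] * e1[1L] - d[1L] * e1[3L],
          d[1L] * e1[2L] - d[2L] * e1[1L])
  structure(list(origin = origin, direction = d, e1 = e1, e2 = e2),
            class = "principal_axis")
}

#' Project points into cylindrical coordinates
#'
#' `z` is the signed distance along the axis, `r` the perpendicular distance
#' from it, `phi` the azimuth in the axis-normal frame; `r^2 + z^2` equals
#' the squared distance from the axis origin.
#'
#' @param centers `K x 3` matrix of positions (m), e.g. cluster centers.
#' @param axis A [principal_axis()].
#' @return `K x 3` matrix with columns `r`, `phi`, `z`.
#' @export
cylindrical_project <- function(centers, axis) {
  stopifnot(inherits(axis, "principal_axis"))
  centers <- matrix(as.numeric(centers), ncol = 3)
  rel <- sweep(centers, 2, axis$origin)
  z <- as.numeric(rel %*% axis$direction)
  tv <- rel - outer(z, axis$direction)
  r <- sqrt(rowSums(tv^2))
  phi <- atan2(as.numeric(tv %*% axis$e2), as.numeric(tv %*% axis$e1))
  cbind(r = r, phi = phi, z = z)
}

#' Height-normalize cylindrical coordinates
#'
#' Scales `(r, z)` by `100 / z_max` so targets of different heights share a
#' comparable `[0, 100]^2` frame.
#'
#' @param r,z Cylindrical coordinates (m).
#' @param z_max Target height along the axis (m), `> 0`.
#' @return List with `r_norm`, `z_norm`.
#' @export
normalize_rz <- function(r, z, z_max) {
  if (!is.numeric(z_max) || length(z_max) != 1L || z_max <= 0) {
    stop("z_max must be a positive scalar")
  }
  list(r_norm = r * 100 / z_max, z_norm = z * 100 / z_max)
}

#' Per-cell maximum-displacement map
#'
#' Bins every cluster's initial-epoch center into a height-normalized
#' `(r_norm, z_norm)` grid (so a cluster's cell is fixed over time) and
#' colors each cell with the maximum displacement over the clusters it
#' contains, either at the requested epoch or as a running maximum up to it.
#' Empty cells are `NA`.
#'
#' @param tracks A `cluster_tracks`.
#' @param disp A `displacement_series` with `reference = "initial"`.
#' @param axis A [principal_axis()].
#' @param dai Epoch index (0-based) to map.
#' @param cell Cell edge length in normalized units (default 2: a 50x50
#'   grid over `[0, 100]^2`).
#' @param z_max Height used for normalization (m); defaults to the maximum
#'   projected `z` of the initial cluster centers.
#' @param running_max If `TRUE`, map the running maximum displacement up to
#'   `dai` instead of the displacement at `dai`.
#' @return A `cylindrical_map`: list with `values` (matrix, rows = r bins,
#'   cols = z bins), `r_breaks`, `z_breaks`, `cell`, `z_max`, `dai`,
#'   `cluster_cells` (per-cluster bin assignment).
#' @export
max_displacement_map <- function(tracks, disp, axis, dai, cell = 2,
                                 z_max = NULL, running_max = FALSE) {
  stopifnot(inherits(tracks, "cluster_tracks"),
            inherits(disp, "displacement_series"),
            inherits(axis, "principal_axis"), cell > 0)
  if (disp$reference != "initial") {
    stop("max_displacement_map needs displacements in initial-reference mode")
  }
  nd <- ncol(disp$disp)
  if (dai < 0 || dai > nd - 1L) stop("dai out of range [0, ", nd - 1L, "]")
  cz <- cylindrical_project(tracks$centers[, , 1L], axis)
  if (is.null(z_max)) z_max <- max(cz[, "z"], na.rm = TRUE)
  nz <- normalize_rz(cz[, "r"], cz[, "z"], z_max)

  # bins over [0, 100]; cells index from the origin, values at exactly 100
  # fall in the last covered cell
  ncell <- ceiling(100 / cell)
  bin <- function(v) pmin(pmax(floor(v / cell), 0), ncell - 1L) + 1L
  ri <- bin(nz$r_norm)
  zi <- bin(nz$z_norm)

  vals <- if (running_max) {
    apply(disp$disp[, seq_len(dai + 1L), drop = FALSE], 1, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  } else {
    disp$disp[, dai + 1L]
  }

  grid <- matrix(NA_real_, ncell, ncell)
  ok <- which(!is.na(vals) & !is.na(ri) & !is.na(zi))
  for (k in ok) {
    cur <- grid[ri[k], zi[k]]
    if (is.na(cur) || vals[k] > cur) grid[ri[k], zi[k]] <- vals[k]
  }
  structure(list(values = grid,
                 r_breaks = seq(0, by = cell, length.out = ncell + 1L),
                 z_breaks = seq(0, by = cell, length.out = ncell + 1L),
                 cell = cell, z_max = z_max, dai = dai,
                 running_max = running_max,
                 cluster_cells = data.frame(cluster_id = seq_len(tracks$K),
                                            r_bin = ri, z_bin = zi,
                                            r_norm = nz$r_norm,
                                            z_norm = nz$z_norm)),
            class = "cylindrical_map")
}

#' Write a cylindrical map as a CSV grid
#'
#' Long format (`r_bin`, `z_bin`, `r_norm_lo`, `z_norm_lo`,
#' `max_displacement_m`) with a `#` header recording `z_max`, cell size and
#' epoch; empty cells are omitted.
#'
#' @param map A `cylindrical_map`.
#' @param path Output CSV path.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "cylindrical_map"))
  idx <- which(!is.na(map$values), arr.ind = TRUE)
  df <- data.frame(r_bin = idx[, 1L], z_bin = idx[, 2L],
                   r_norm_lo = map$r_breaks[idx[, 1L]],
                   z_norm_lo = map$z_breaks[idx[, 2L]],
                   max_displacement_m = map$values[idx])
  df <- df[order(df$r_bin, df$z_bin), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# height-normalized displacement map: z_max_m=%s cell=%s dai=%d running_max=%s",
                     format_full(map$z_max), format_full(map$cell), map$dai,
                     map$running_max), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Percentile summary of cluster displacements
#'
#' Percentiles (linear interpolation between order statistics, R quantile
#' type 7) of either the per-epoch displacement distribution across clusters
#' or of each cluster's maximum displacement over all epochs (`overall-max`,
#' the scope used for headline displacement figures). Missing values are
#' excluded.
#'
#' @param disp A `displacement_series`.
#' @param q Percentile(s) in `[0, 100]`.
#' @param scope `"overall-max"` or `"per-DAI"`.
#' @param dai Epoch (0-based) for `scope = "per-DAI"`.
#' @return Named numeric vector of displacement percentiles (m).
#' @export
percentile_summary <- function(disp, q = 99, scope = c("overall-max", "per-DAI"),
                               dai = NULL) {
  stopifnot(inherits(disp, "displacement_series"), all(q >= 0 & q <= 100))
  scope <- match.arg(scope)
  vals <- if (scope == "overall-max") {
    v <- apply(disp$disp, 1, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    v[!is.na(v)]
  } else {
    if (is.null(dai)) stop("per-DAI scope needs a dai")
    v <- disp$disp[, dai + 1L]
    v[!is.na(v)]
  }
  if (!length(vals)) stop("all displacement values are missing")
  stats::quantile(vals, probs = q / 100, type = 7, names = FALSE, na.rm = FALSE) ->
    out
  names(out) <- paste0("p", q)
  out
}

#' Displacement time series for selected clusters
#'
#' Tidy table for plotting individual cluster trajectories, with optional
#' sunset/sunrise annotation times carried through for figure scripts.
#'
#' @param tracks A `cluster_tracks`.
#' @param disp A `displacement_series`.
#' @param cluster_ids Integer cluster ids to extract.
#' @param annotations Optional named numeric vector of annotation times
#'   (seconds since sequence start), e.g. `c(sunset = 2280, sunrise = 35400)`.
#' @return Data frame (`cluster_id`, `dai`, `timestamp_s`,
#'   `displacement_m`), with `annotations` attached as an attribute.
#' @export
cluster_timeseries <- function(tracks, disp, cluster_ids, annotations = NULL) {
  stopifnot(inherits(tracks, "cluster_tracks"), inherits(disp, "displacement_series"))
  bad <- setdiff(cluster_ids, seq_len(tracks$K))
  if (length(bad)) stop("unknown cluster id(s): ", paste(bad, collapse = ", "))
  nd <- ncol(disp$disp)
  out <- do.call(rbind, lapply(cluster_ids, function(k) {
    data.frame(cluster_id = k, dai = seq_len(nd) - 1L,
               timestamp_s = disp$timestamps,
               displacement_m = disp$disp[k, ])
  }))
  out <- out[!is.na(out$displacement_m), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annotations") <- annotations
  out
}
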