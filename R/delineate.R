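#' Define an object delineation boundary
#'
#' An object (a tree, a lamppost, a sphere cluster) is delineated from the
#' scene cloud by one or more 2D polygons drawn in axis-aligned projections.
#' A point is kept only if every listed projection places it inside its
#' polygon, optionally dilated by a buffer. The same boundary, drawn once on
#' the first DAI, is reused for the whole sequence; the buffer absorbs the
#' systematic object movement expected during the night.
#'
#' @param polygons A list of entries, each `list(projection =, vertices =)`
#'   where `projection` is one of `"xy"`, `"xz"`, `"yz"` and `vertices` a
#'   `k x 2` matrix (`k >= 3`) of polygon vertices in meters.
#' @param buffer Nonnegative buffer width in meters (Minkowski dilation,
#'   implemented as distance-to-polygon `<= buffer`).
#' @return An `object_boundary`.
#' @export
object_boundary <- function(polygons, buffer = 0) {
  stopifnot(is.list(polygons), length(polygons) >= 1L, buffer >= 0)
  polygons <- lapply(polygons, function(p) {
    proj <- match.arg(p$projection, c("xy", "xz", "yz"))
    v <- as.matrix(p$vertices)
    storage.mode(v) <- "double"
    if (nrow(v) < 3L || ncol(v) != 2L) {
      stop("each polygon needs >= 3 two-dimensional vertices")
    }
    if (polygon_self_intersects(v)) stop("polygon must be simple (non-self-intersecting)")
    if (polygon_area2(v) == 0) stop("degenerate polygon (zero area)")
    list(projection = proj, vertices = v)
  })
  structure(list(polygons = polygons, buffer = as.numeric(buffer)),
            class = "object_boundary")
}

#' Crop an object point cloud with a boundary
#'
#' Keeps a point iff, for every `(projection, polygon)` of the boundary, its
#' 2D projection lies inside the polygon dilated by the buffer. Containment
#' uses the even-odd rule; points exactly on an edge are kept. Idempotent,
#' and monotone in the buffer (a larger buffer keeps a superset).
#'
#' @param cloud A [point_cloud()].
#' @param boundary An [object_boundary()].
#' @return The delineated `point_cloud` (original point order).
#' @export
delineate <- function(cloud, boundary) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(boundary, "object_boundary"))
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  keep <- rep(TRUE, n)
  for (p in boundary$polygons) {
    idx <- switch(p$projection, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
    pts2 <- cloud$coords[, idx, drop = FALSE]
    inside <- points_in_polygon(pts2, p$vertices)
    if (boundary$buffer > 0) {
      out <- which(!inside & keep)
      if (length(out)) {
        d <- dist_to_polygon_edges(pts2[out, , drop = FALSE], p$vertices)
        inside[out] <- d <= boundary$buffer
      }
    }
    keep <- keep & inside
  }
  subset_cloud(cloud, keep)
}

#' Read / write boundary files
#'
#' Plain-text format: a `buffer <meters>` line followed by one `polygon
#' <projection>` line per polygon, then its vertices as `x y` pairs, one per
#' line. `#` comments allowed.
#'
#' @param path File path.
#' @return An [object_boundary()].
#' @export
read_boundary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  buffer <- 0
  polys <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur$rows)) {
      polys[[length(polys) + 1L]] <<- list(
        projection = cur$projection,
        vertices = do.call(rbind, cur$rows))
    }
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "buffer") {
      buffer <- as.numeric(tok[2L])
    } else if (tok[1L] == "polygon") {
      flush()
      cur <- list(projection = tok[2L], rows = list())
    } else {
      if (is.null(cur)) stop("boundary file: vertex line before any 'polygon' header")
      cur$rows[[length(cur$rows) + 1L]] <- as.numeric(tok[1:2])
    }
  }
  flush()
  object_boundary(polys, buffer = buffer)
}

#' @rdname read_boundary
#' @param boundary An [object_boundary()] to serialize.
#' @export
write_boundary <- function(boundary, path) {
  stopifnot(inherits(boundary, "object_boundary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# object delineation boundary (meters)",
               sprintf("buffer %s", format_full(boundary$buffer))), con)
  for (p in boundary$polygons) {
    writeLines(sprintf("polygon %s", p$projection), con)
    writeLines(paste(format_full(p$vertices[, 1L]), format_full(p$vertices[, 2L])), con)
  }
  invisible(NULL)
}

# Even-odd point-in-polygon; points exactly on an edge count as inside.
points_in_polygon <- function(pts, verts) {
  n <- nrow(pts)
  if (n == 0L) return(logical(0))
  k <- nrow(verts)
  xs <- verts[, 1L]; ys <- verts[, 2L]
  xe <- xs[c(2:k, 1L)]; ye <- ys[c(2:k, 1L)]
  px <- pts[, 1L]; py <- pts[, 2L]
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  for (e in seq_len(k)) {
    x1 <- xs[e]; y1 <- ys[e]; x2 <- xe[e]; y2 <- ye[e]
    # edge-inclusion: point collinear with the segment and within its bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- cross == 0 &
      px >= pmin(x1, x2) & px <= pmax(x1, x2) &
      py >= pmin(y1, y2) & py <= pmax(y1, y2)
    on_edge <- on_edge | on_seg
    # even-odd ray cast toward +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Minimum Euclidean distance from each point to the polygon outline.
dist_to_polygon_edges <- function(pts, verts) {
  n <- nrow(pts)
  if (n == 0L) return(numeric(0))
  k <- nrow(verts)
  best <- rep(Inf, n)
  px <- pts[, 1L]; py <- pts[, 2L]
  for (e in seq_len(k)) {
    a <- verts[e, ]; b <- verts[if (e == k) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, ((px - a[1L]) * ab[1L] + (py - a[2L]) * ab[2L]) / len2))
    dx <- px - (a[1L] + t * ab[1L])
    dy <- py - (a[2L] + t * ab[2L])
    best <- pmin(best, sqrt(dx * dx + dy * dy))
  }
  best
}

polygon_area2 <- function(v) {
  k <- nrow(v)
  j <- c(2:k, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])
}

polygon_self_intersects <- function(v) {
  k <- nrow(v)
  segs <- cbind(v, v[c(2:k, 1L), , drop = FALSE])
  for (i in seq_len(k - 2L)) {
    for (j in (i + 2L):k) {
      if (i == 1L && j == k) next  # adjacent through the wrap-around
      if (segments_cross(segs[i, 1:2], segs[i, 3:4], segs[j, 1:2], segs[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
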