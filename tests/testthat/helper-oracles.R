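# Brute-force reference implementations used as independent oracles.
# All are O(n^2) or worse on purpose; they share no code with the package.

bf_nn1 <- function(ref, query) {
  apply(query, 1, function(p) {
    d2 <- colSums((t(ref) - p)^2)
    which(d2 == min(d2))[1L]   # lowest index on ties
  })
}

bf_radius_count <- function(pts, radius) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  D <- as.matrix(dist(pts))
  diag(D) <- Inf
  as.integer(rowSums(D <= radius))
}

bf_stray_mask <- function(ranges, valid, window, range_thresh, alloc_thresh) {
  nr <- nrow(ranges); nc <- ncol(ranges)
  half <- (window - 1L) %/% 2L
  keep <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j]) next
    nv <- 0L; ncl <- 0L
    for (di in -half:half) for (dj in -half:half) {
      if (di == 0L && dj == 0L) next
      a <- i + di; b <- j + dj
      if (a < 1L || a > nr || b < 1L || b > nc || !valid[a, b]) next
      nv <- nv + 1L
      if (abs(ranges[a, b] - ranges[i, j]) <= range_thresh) ncl <- ncl + 1L
    }
    keep[i, j] <- nv > 0L && ncl >= alloc_thresh * nv
  }
  keep
}

# two-stage prune/relabel replay, sharing no code with the package
bf_prune_relabel <- function(coords, labels, min_size) {
  sizes <- tabulate(labels, max(labels))
  survive <- which(sizes >= min_size)
  stopifnot(length(survive) > 0L)
  orphan <- !(labels %in% survive)
  if (any(orphan)) {
    kept <- which(!orphan)
    nn <- bf_nn1(coords[kept, , drop = FALSE], coords[orphan, , drop = FALSE])
    labels[orphan] <- labels[kept[nn]]
  }
  match(labels, survive)
}

random_cloud <- function(n, scale = 1, intensity = FALSE) {
  point_cloud(matrix(runif(3 * n, 0, scale), ncol = 3),
              intensity = if (intensity) runif(n, 0, 2000))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

sphere_points <- function(n, center, radius, hemisphere = FALSE) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  if (hemisphere) v[, 3] <- abs(v[, 3])
  sweep(radius * v, 2, center, "+")
}

# build a cluster_tracks object directly from a list of K x 3 center matrices
make_tracks <- function(centers_list, timestamps = NULL) {
  K <- nrow(centers_list[[1]])
  nd <- length(centers_list)
  centers <- array(NA_real_, c(K, 3, nd))
  counts <- matrix(0L, K, nd)
  for (i in seq_len(nd)) {
    centers[, , i] <- centers_list[[i]]
    counts[, i] <- ifelse(rowSums(is.na(centers_list[[i]])) > 0, 0L, 10L)
  }
  if (is.null(timestamps)) timestamps <- (seq_len(nd) - 1) * 1200
  structure(list(centers = centers, counts = counts, missing = counts == 0L,
                 timestamps = timestamps,
                 K = K, mode = "chain", labels0 = NULL, cloud0 = NULL,
                 params = NULL),
            class = "cluster_tracks")
}
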