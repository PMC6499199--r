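#' Least-squares sphere fit
#'
#' Geometric (orthogonal-distance) fit minimizing
#' \eqn{\sum_i (\|p_i - c\| - r)^2} by Gauss-Newton, initialized from the
#' algebraic closed-form solution of \eqn{\|p\|^2 = 2 c \cdot p + (r^2 -
#' \|c\|^2)}. With `fixed_radius` the radius is held at the given value
#' (the usual case for manufactured reference spheres of known radius) and
#' only the center is optimized. The geometric fit matters for TLS targets:
#' only part of the sphere faces the scanner, and algebraic fits are biased
#' on such partial arcs.
#'
#' @param points `n x 3` matrix of sphere-surface samples (m); `n >= 4`
#'   (free fit) or `n >= 3` (fixed radius).
#' @param fixed_radius Known radius in meters, or `NULL` for a free fit.
#' @param tol Convergence threshold on the center update (m).
#' @param max_iter Iteration cap.
#' @return List with `center` (3-vector, m), `radius` (m), `rms` (m,
#'   root-mean-square orthogonal residual), `iterations`, `n`.
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' fit_sphere(sweep(0.099 * u, 2, c(1, 2, 3), "+"))$center
#' @export
fit_sphere <- function(points, fixed_radius = NULL, tol = 1e-10, max_iter = 100L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  need <- if (is.null(fixed_radius)) 4L else 3L
  if (n < need) stop("sphere fit needs at least ", need, " points")
  if (qr(sweep(points, 2, colMeans(points)))$rank < 2L) {
    stop("degenerate point configuration: points are collinear")
  }

  # Algebraic start: ||p||^2 = 2 c.p + (r^2 - ||c||^2), linear in (c, k).
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qa <- qr(A)
  if (qa$rank < 4L) {
    # coplanar points: fall back to centroid start (fixed-radius fits on a
    # hemisphere rim etc.); Gauss-Newton refines from there
    c0 <- colMeans(points)
  } else {
    sol <- qr.coef(qa, b)
    c0 <- sol[1:3]
  }

  free_r <- is.null(fixed_radius)
  cc <- c0
  r <- if (free_r) mean(sqrt(rowSums(sweep(points, 2, cc)^2))) else fixed_radius
  if (!free_r && r <= 0) stop("fixed_radius must be positive")

  it <- 0L
  repeat {
    it <- it + 1L
    d <- sweep(points, 2, cc)
    rho <- sqrt(rowSums(d^2))
    rho[rho < 1e-300] <- 1e-300
    res <- rho - r
    J <- -d / rho                       # d res_i / d c
    if (free_r) J <- cbind(J, -1)       # d res_i / d r
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) {
      stop("sphere fit failed: rank-deficient normal equations")
    }
    cc <- cc + step[1:3]
    if (free_r) r <- r + step[4L]
    if (sqrt(sum(step[1:3]^2)) < tol) break
    if (it >= max_iter) {
      stop(sprintf(
        "sphere fit did not converge in %d iterations (last rms %.3g m)",
        max_iter, sqrt(mean(res^2))))
    }
  }
  d <- sweep(points, 2, cc)
  res <- sqrt(rowSums(d^2)) - r
  list(center = as.numeric(cc), radius = r, rms = sqrt(mean(res^2)),
       iterations = it, n = n)
}

#' Rigid transform between corresponding point sets
#'
#' Least-squares rotation + translation minimizing
#' \eqn{\sum_i \|R s_i + t - d_i\|^2} over proper rotations, via SVD of the
#' cross-covariance matrix with reflection correction (the Kabsch/Umeyama
#' solution). Correspondences are positional: row `i` of `src` matches row
#' `i` of `dst` (sphere targets are matched by their ids upstream).
#'
#' @param src_centers,dst_centers `k x 3` matrices, `k >= 3`, not collinear.
#' @return A `rigid_transform`: list with `rotation` (3x3, det +1),
#'   `translation` (3-vector, m), `residuals` (per-pair distances after
#'   alignment, m), `rms`.
#' @export
register_rigid <- function(src_centers, dst_centers) {
  S <- as.matrix(src_centers); D <- as.matrix(dst_centers)
  storage.mode(S) <- storage.mode(D) <- "double"
  if (nrow(S) != nrow(D)) stop("correspondence sets differ in size")
  k <- nrow(S)
  if (k < 3L) stop("rigid registration needs at least 3 correspondences")
  sc <- colMeans(S); dc <- colMeans(D)
  S0 <- sweep(S, 2, sc); D0 <- sweep(D, 2, dc)
  if (qr(S0)$rank < 2L) stop("correspondences are collinear; rotation is not determined")
  H <- crossprod(S0, D0)
  sv <- svd(H)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  t <- dc - as.numeric(R %*% sc)
  res <- sqrt(rowSums((D - (S %*% t(R) + matrix(t, k, 3, byrow = TRUE)))^2))
  structure(list(rotation = R, translation = t,
                 residuals = res, rms = sqrt(mean(res^2))),
            class = "rigid_transform")
}

#' Apply a rigid transform to a point cloud
#'
#' Maps every coordinate `p -> R p + t`; intensity and metadata untouched.
#'
#' @param tf A `rigid_transform` (or list with `rotation`, `translation`).
#' @param cloud A [point_cloud()].
#' @return The transformed `point_cloud`.
#' @export
apply_rigid <- function(tf, cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  co <- cloud$coords %*% t(tf$rotation)
  co <- sweep(co, 2, tf$translation, "+")
  out <- point_cloud(co, intensity = cloud$intensity,
                     scanner_id = cloud$scanner_id, timestamp = cloud$timestamp)
  out$scanner <- cloud$scanner
  out
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  Rt <- t(tf$rotation)
  structure(list(rotation = Rt, translation = as.numeric(-Rt %*% tf$translation)),
            class = "rigid_transform")
}

#' Serialize a rigid transform as 12 numbers
#'
#' Row-major rotation followed by translation, one value per line.
#' @param tf A `rigid_transform`.
#' @param path Output file.
#' @export
write_transform <- function(tf, path) {
  writeLines(format_full(c(t(tf$rotation), tf$translation)), path)
  invisible(NULL)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- as.numeric(readLines(path, warn = FALSE))
  if (length(v) != 12L || anyNA(v)) stop("transform file must hold 12 numbers")
  structure(list(rotation = matrix(v[1:9], 3, 3, byrow = TRUE),
                 translation = v[10:12]),
            class = "rigid_transform")
}

#' Reference-sphere measurement stability
#'
#' Scene-stability QA on static reference spheres: per sphere, the relative
#' standard deviation of the per-scan point count (std/mean, percent) and the
#' Euclidean displacement of the fitted center at every scan from its first
#' scan. Both should stay at the scanner's precision floor if the scene and
#' registration are stable.
#'
#' @param observations Data frame with columns `sphere_id`, `dai`,
#'   `n_points`, `cx`, `cy`, `cz` (one row per sphere per scan).
#' @return List with `per_sphere` (data frame: `sphere_id`,
#'   `count_rsd_pct`, `mean_disp_m`, `max_disp_m`, `n_scans`),
#'   `displacements` (data frame: `sphere_id`, `dai`, `disp_m`), and
#'   summary scalars `mean_count_rsd_pct`, `max_count_rsd_pct`,
#'   `mean_disp_m`, `max_disp_m`.
#' @export
stability_report <- function(observations) {
  obs <- as.data.frame(observations)
  need <- c("sphere_id", "dai", "n_points", "cx", "cy", "cz")
  if (!all(need %in% names(obs))) {
    stop("observations need columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(obs$sphere_id)
  per <- list()
  disp_rows <- list()
  for (id in ids) {
    o <- obs[obs$sphere_id == id, , drop = FALSE]
    o <- o[order(o$dai), , drop = FALSE]
    if (nrow(o) < 2L) {
      warning("sphere ", id, " observed in fewer than 2 scans; flagged, not summarised")
      next
    }
    rsd <- stats::sd(o$n_points) / mean(o$n_points) * 100
    c0 <- as.numeric(o[1L, c("cx", "cy", "cz")])
    d <- sqrt(rowSums(sweep(as.matrix(o[, c("cx", "cy", "cz")]), 2, c0)^2))
    per[[length(per) + 1L]] <- data.frame(
      sphere_id = id, count_rsd_pct = rsd,
      mean_disp_m = mean(d[-1L]), max_disp_m = max(d),
      n_scans = nrow(o))
    disp_rows[[length(disp_rows) + 1L]] <- data.frame(
      sphere_id = id, dai = o$dai, disp_m = d)
  }
  if (!length(per)) stop("no sphere with >= 2 observations")
  per <- do.call(rbind, per)
  disp <- do.call(rbind, disp_rows)
  list(per_sphere = per, displacements = disp,
       mean_count_rsd_pct = mean(per$count_rsd_pct),
       max_count_rsd_pct = max(per$count_rsd_pct),
       mean_disp_m = mean(per$mean_disp_m),
       max_disp_m = max(per$max_disp_m))
}
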