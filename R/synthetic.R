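#' Parametric synthetic scene
#'
#' Builds a ground-truthed stand-in for a night-long TLS campaign at close
#' range: a deforming sapling-scale tree (short stem, whorls of branches
#' carrying granular leaf blobs), a static lamppost (pole plus head box),
#' and five reference spheres of 0.099 m radius. Geometry is stored as
#' parametric surfaces with areas, so scans of any density can be drawn
#' from it.
#'
#' Two properties of real TLS targets matter for the tracking method and
#' are built in deliberately:
#' \itemize{
#'   \item Foliage is granular. Each leaf blob is a field of small clumps
#'     (spherelets) rather than one smooth surface; nearest-neighbor label
#'     propagation then follows the moving material, as it does on real
#'     leaves and twigs, instead of sliding over a featureless surface.
#'   \item Branch whorls get longer toward the top, so the topmost branch
#'     tips attain both the maximum radial distance `r_max` and the crown
#'     height `z_crown`, making the deformation amplitude exactly `A_tip`
#'     there (see [deformation_config()]).
#' }
#'
#' @param stem_height Stem height (m).
#' @param stem_radius Stem radius (m). The default is small enough that one
#'   Poisson-disk seed claims a full ring of stem surface, which keeps stem
#'   cluster centers well determined.
#' @param whorl_heights Attachment heights of branch whorls on the stem (m).
#' @param whorl_lengths Branch length per whorl (m), same length as
#'   `whorl_heights`.
#' @param branches_per_whorl Branches per whorl.
#' @param branch_radius Branch cylinder radius (m).
#' @param branch_pitch Vertical rise per unit horizontal run of a branch.
#' @param blob_radius Radius of the region holding one blob's leaf clumps (m).
#' @param clump_radius Radius of an individual leaf clump (m).
#' @param clumps_per_blob Number of clumps per leaf blob.
#' @param blob_fracs Positions of leaf blobs along each branch (fractions of
#'   branch length; 1 is the tip blob).
#' @param lamppost Logical: include the static control target.
#' @param tree Logical: include the tree.
#' @param spheres Logical: include the five reference spheres.
#' @param sphere_radius Reference-sphere radius (m).
#' @param scene_seed Integer seed fixing the clump layout (scene geometry is
#'   deterministic given this seed).
#' @return A `scene_model`: list with `surfaces`, `tips` (per-branch tip
#'   positions), `r_max`, `z_crown`.
#' @export
scene_model <- function(stem_height = 0.25, stem_radius = 0.02,
                        whorl_heights = c(0.15, 0.23),
                        whorl_lengths = c(0.8, 1.3),
                        branches_per_whorl = 3L,
                        branch_radius = 0.012,
                        branch_pitch = 0.25,
                        blob_radius = 0.06,
                        clump_radius = 0.025,
                        clumps_per_blob = 14L,
                        blob_fracs = c(0.55, 1.0),
                        lamppost = TRUE, tree = TRUE, spheres = TRUE,
                        sphere_radius = 0.099,
                        scene_seed = 42L) {
  stopifnot(length(whorl_heights) == length(whorl_lengths),
            all(whorl_heights < stem_height) || !tree)
  surfaces <- list()
  tips <- NULL
  r_max <- NA_real_
  z_crown <- NA_real_

  add <- function(s) surfaces[[length(surfaces) + 1L]] <<- s

  if (tree) {
    add(list(id = "stem", component = "stem", dclass = "solid",
             type = "cylinder",
             p0 = c(0, 0, 0), dir = c(0, 0, 1), len = stem_height,
             radius = stem_radius,
             area = 2 * pi * stem_radius * stem_height,
             droop = c(0, 0, 0)))
    clump_offsets <- with_rng_seed(scene_seed, {
      # uniform directions, radius biased outward; fixed per scene
      n_all <- clumps_per_blob * branches_per_whorl *
        length(whorl_heights) * length(blob_fracs)
      v <- matrix(stats::rnorm(3L * n_all), ncol = 3L)
      v <- v / sqrt(rowSums(v^2))
      v * (blob_radius * stats::runif(n_all)^(1 / 3))
    })
    off_i <- 0L
    tip_rows <- list()
    bi <- 0L
    for (w in seq_along(whorl_heights)) {
      h <- whorl_heights[w]
      L <- whorl_lengths[w]
      for (b in seq_len(branches_per_whorl)) {
        bi <- bi + 1L
        az <- 2 * pi * (b - 1) / branches_per_whorl + 0.35 * w
        dir <- c(cos(az), sin(az), branch_pitch)
        dir <- dir / sqrt(sum(dir^2))
        attach <- c(0, 0, h)
        tip <- attach + L * dir
        droop <- c(0.35 * cos(az), 0.35 * sin(az), -1)
        droop <- droop / sqrt(sum(droop^2))
        id <- sprintf("branch_%02d", bi)
        add(list(id = id, component = "branch", dclass = "foliage",
                 type = "cylinder",
                 p0 = attach, dir = dir, len = L, radius = branch_radius,
                 area = 2 * pi * branch_radius * L, droop = droop))
        for (f in blob_fracs) {
          ctr <- attach + f * L * dir
          for (cl in seq_len(clumps_per_blob)) {
            off_i <- off_i + 1L
            add(list(id = sprintf("%s_blob%.2f_c%02d", id, f, cl),
                     component = if (f >= 1) "tip_blob" else "blob",
                     dclass = "foliage",
                     type = "sphere",
                     center = ctr + clump_offsets[off_i, ],
                     radius = clump_radius,
                     area = 4 * pi * clump_radius^2, droop = droop,
                     parent = id))
          }
        }
        tip_rows[[bi]] <- data.frame(branch_id = id,
                                     x = tip[1L], y = tip[2L], z = tip[3L],
                                     r = sqrt(sum(tip[1:2]^2)))
      }
    }
    tips <- do.call(rbind, tip_rows)
    r_max <- max(tips$r)
    z_crown <- max(tips$z)
  }

  if (lamppost) {
    add(list(id = "lamppost_pole", component = "lamppost", dclass = "foliage",
             type = "cylinder",
             p0 = c(3, 0, 0), dir = c(0, 0, 1), len = 1.2, radius = 0.04,
             area = 2 * pi * 0.04 * 1.2, droop = c(0, 0, 0)))
    add(list(id = "lamppost_head", component = "lamppost", dclass = "foliage",
             type = "box",
             center = c(3.08, 0, 1.28), dims = c(0.25, 0.15, 0.15),
             area = 2 * (0.25 * 0.15 + 0.25 * 0.15 + 0.15 * 0.15),
             droop = c(0, 0, 0)))
  }

  if (spheres) {
    ctrs <- rbind(c(1.8, 1.8, 0.15), c(-1.8, 1.5, 0.25), c(2.2, -1.5, 0.10),
                  c(-1.5, -1.8, 0.50), c(0.0, 2.4, 0.20))
    for (s in seq_len(nrow(ctrs))) {
      add(list(id = sprintf("sphere_%d", s), component = "sphere",
               dclass = "sphere", type = "sphere",
               center = ctrs[s, ], radius = sphere_radius,
               area = 4 * pi * sphere_radius^2, droop = c(0, 0, 0)))
    }
  }

  structure(list(surfaces = surfaces, tips = tips,
                 r_max = r_max, z_crown = z_crown),
            class = "scene_model")
}

#' Single static cylinder scene
#'
#' A minimal scene holding one motionless vertical cylinder, used for
#' measurement-stability QA of the full pipeline (the lamppost analog): any
#' displacement the tracker reports on it is method noise.
#'
#' @param radius Cylinder radius (m).
#' @param length Cylinder length (m).
#' @param base Base point of the axis.
#' @return A `scene_model` with a single `static` surface of density class
#'   `"solid"`.
#' @export
cylinder_scene <- function(radius = 0.02, length = 0.4, base = c(0, 0, 0)) {
  structure(list(surfaces = list(
    list(id = "cylinder", component = "static", dclass = "solid",
         type = "cylinder", p0 = base, dir = c(0, 0, 1),
         len = length, radius = radius,
         area = 2 * pi * radius * length, droop = c(0, 0, 0))),
    tips = NULL, r_max = NA_real_, z_crown = NA_real_),
    class = "scene_model")
}

#' Deformation schedule and amplitude
#'
#' The imposed movement is separable in space and time. In time, a
#' piecewise-linear profile `s(t)`: zero until `t_onset`, a linear ramp to 1
#' at `t_peak`, then a linear fall back to 0 at `t_return` (the ramp-then-
#' rapid-return shape characteristic of nocturnal crown movement, with the
#' peak shortly after sunrise; with the default breakpoints the 41-epoch
#' night ends mid-return, as a real monitoring window tends to). In space,
#' each tree surface point moves by
#' `s(t) * amplitude(p)` along its branch's fixed droop direction (downward-
#' outward unit vector), with
#' `amplitude(p) = A_tip * min(1, (r/r_max) * (z/z_crown))`
#' where `r` is radial distance from the stem axis and `z` height: zero on
#' the stem, maximal (`A_tip`, exactly) at the topmost branch tips.
#' Lamppost and spheres never move.
#'
#' Defaults place sequence start at 20:10, onset three hours in (about
#' 23:10), the peak one hour after a 06:00 sunrise, and the return at the
#' end of the 41-epoch night.
#'
#' @param t_onset,t_peak,t_return Profile breakpoints (s since start).
#' @param A_tip Maximum tip displacement amplitude (m).
#' @return A `deformation_config`.
#' @export
deformation_config <- function(t_onset = 10800, t_peak = 39000,
                               t_return = 57000, A_tip = 0.15) {
  stopifnot(t_onset < t_peak, t_peak <= t_return, A_tip >= 0)
  structure(list(t_onset = t_onset, t_peak = t_peak, t_return = t_return,
                 A_tip = A_tip),
            class = "deformation_config")
}

#' Temporal deformation profile
#'
#' @param t Time(s) in seconds since sequence start.
#' @param config A [deformation_config()].
#' @return `s` in `[0, 1]` (vectorized over `t`): 0 up to `t_onset`, linear
#'   to 1 at `t_peak`, linear back to 0 at `t_return`.
#' @export
temporal_profile <- function(t, config = deformation_config()) {
  stopifnot(inherits(config, "deformation_config"))
  s <- ifelse(t <= config$t_onset, 0,
       ifelse(t <= config$t_peak,
              (t - config$t_onset) / (config$t_peak - config$t_onset),
       ifelse(t <= config$t_return,
              1 - (t - config$t_peak) / (config$t_return - config$t_peak),
              0)))
  pmin(pmax(s, 0), 1)
}

#' Deformation amplitude field
#'
#' Evaluates the spatial amplitude law at arbitrary positions (used both by
#' the generator and as the analytic ground truth for tracked cluster
#' centers on moving tree parts).
#'
#' @param scene A [scene_model()] containing a tree.
#' @param deform A [deformation_config()].
#' @param points `n x 3` positions (m).
#' @return Amplitude in meters for each position.
#' @export
deformation_amplitude <- function(scene, deform, points) {
  stopifnot(inherits(scene, "scene_model"), inherits(deform, "deformation_config"))
  if (!is.finite(scene$r_max)) stop("scene has no tree; amplitude undefined")
  points <- matrix(as.numeric(points), ncol = 3)
  r <- sqrt(points[, 1L]^2 + points[, 2L]^2)
  z <- points[, 3L]
  deform$A_tip * pmin(1, pmax(0, r / scene$r_max) * pmax(0, z / scene$z_crown))
}

# Draw n points uniformly on one parametric surface (noise-free, undeformed).
sample_surface <- function(surf, n) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  switch(surf$type,
    cylinder = {
      d <- surf$dir
      e1 <- if (abs(d[3L]) < 0.9) c(-d[2L], d[1L], 0) else c(1, 0, 0) - d[1L] * d
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
              d[3L] * e1[1L] - d[1L] * e1[3L],
              d[1L] * e1[2L] - d[2L] * e1[1L])
      u <- stats::runif(n, 0, surf$len)
      th <- stats::runif(n, 0, 2 * pi)
      outer(u, d) + surf$radius * (outer(cos(th), e1) + outer(sin(th), e2)) +
        matrix(surf$p0, n, 3, byrow = TRUE)
    },
    sphere = {
      v <- matrix(stats::rnorm(3 * n), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      surf$radius * v + matrix(surf$center, n, 3, byrow = TRUE)
    },
    box = {
      dm <- surf$dims
      areas <- c(dm[1] * dm[2], dm[1] * dm[2], dm[1] * dm[3],
                 dm[1] * dm[3], dm[2] * dm[3], dm[2] * dm[3])
      f <- sample.int(6L, n, replace = TRUE, prob = areas)
      pts <- matrix(0, n, 3)
      for (ax in 1:3) pts[, ax] <- stats::runif(n, -dm[ax] / 2, dm[ax] / 2)
      fixed_axis <- c(3L, 3L, 2L, 2L, 1L, 1L)
      fixed_sign <- c(1, -1, 1, -1, 1, -1)
      for (ff in 1:6) {
        sel <- f == ff
        pts[sel, fixed_axis[ff]] <- fixed_sign[ff] * dm[fixed_axis[ff]] / 2
      }
      pts + matrix(surf$center, n, 3, byrow = TRUE)
    },
    stop("unknown surface type: ", surf$type))
}

#' Simulate one TLS scan of the scene
#'
#' Draws surface points with expected count `density * area` per surface
#' (Poisson counts), displaces tree points according to the deformation
#' state `s`, adds independent isotropic Gaussian range noise, and applies
#' optional random dropout and a contiguous angular occlusion sector (a
#' crude stand-in for self-occlusion). Deterministic given `rng_seed`.
#'
#' Densities are per surface class: solid close-range targets (stem, the
#' static QA cylinder) return far denser sampling than foliage in real
#' scans, and the mm-level stability of median cluster centers depends
#' directly on density, so the two are controlled separately.
#'
#' @param scene A [scene_model()].
#' @param deform A [deformation_config()], or `NULL` for a motion-free scan.
#' @param s Deformation state in `[0, 1]` (from [temporal_profile()]).
#' @param density Sampling density for foliage-class surfaces (branches,
#'   leaf clumps, lamppost), points per m^2.
#' @param stem_density Sampling density for solid-class surfaces (stem,
#'   static cylinder), points per m^2.
#' @param sphere_density Sampling density for reference spheres (pts/m^2).
#' @param noise_sigma Per-coordinate Gaussian noise (m).
#' @param dropout Fraction of points removed at random, in `[0, 1)`.
#' @param occlusion Optional `c(start, width)` azimuth sector (radians,
#'   about the vertical axis through the origin) whose tree points are
#'   removed.
#' @param intensity Optional constant raw intensity attached to all points.
#' @param rng_seed Integer seed.
#' @param timestamp Timestamp carried on the returned cloud (s).
#' @return A [point_cloud()] with per-point fields `component` (surface
#'   class), `surface_id`, and `true_disp_m` (imposed displacement
#'   magnitude; the ground truth).
#' @export
sample_scan <- function(scene, deform = deformation_config(), s = 0,
                        density = 120000, stem_density = 2e6,
                        sphere_density = 150000,
                        noise_sigma = 0.001, dropout = 0,
                        occlusion = NULL, intensity = NULL,
                        rng_seed = 1L, timestamp = NULL) {
  stopifnot(inherits(scene, "scene_model"), s >= 0, s <= 1,
            density > 0, dropout >= 0, dropout < 1)
  moving_comp <- c("branch", "blob", "tip_blob")
  with_rng_seed(rng_seed, {
    parts <- lapply(scene$surfaces, function(surf) {
      dens <- switch(surf$dclass, solid = stem_density,
                     sphere = sphere_density, density)
      n <- stats::rpois(1L, dens * surf$area)
      base <- sample_surface(surf, n)
      moving <- surf$component %in% moving_comp
      disp <- if (moving && s > 0) {
        s * deformation_amplitude(scene, deform, base)
      } else rep(0, n)
      pts <- if (any(disp > 0)) base + outer(disp, surf$droop) else base
      list(pts = pts, component = rep(surf$component, n),
           surface_id = rep(surf$id, n), true_disp = disp)
    })
    coords <- do.call(rbind, lapply(parts, `[[`, "pts"))
    component <- unlist(lapply(parts, `[[`, "component"), use.names = FALSE)
    surface_id <- unlist(lapply(parts, `[[`, "surface_id"), use.names = FALSE)
    true_disp <- unlist(lapply(parts, `[[`, "true_disp"), use.names = FALSE)
    n <- nrow(coords)
    if (noise_sigma > 0) {
      coords <- coords + matrix(stats::rnorm(3 * n, 0, noise_sigma), n, 3)
    }
    keep <- rep(TRUE, n)
    if (!is.null(occlusion)) {
      az <- atan2(coords[, 2L], coords[, 1L]) %% (2 * pi)
      rel <- (az - occlusion[1L]) %% (2 * pi)
      keep <- keep & !(rel < occlusion[2L] &
                         component %in% c("stem", moving_comp))
    }
    if (dropout > 0) keep <- keep & (stats::runif(n) >= dropout)
    cloud <- point_cloud(coords[keep, , drop = FALSE],
                         intensity = if (!is.null(intensity))
                           rep(intensity, sum(keep)),
                         timestamp = timestamp)
    cloud$component <- component[keep]
    cloud$surface_id <- surface_id[keep]
    cloud$true_disp_m <- true_disp[keep]
    cloud
  })
}

#' Generate a ground-truthed DAI time series
#'
#' The default schedule emulates a night-long campaign: 41 epochs at 20 min
#' spacing, deformation following [temporal_profile()]. Each epoch is an
#' independent resample of the scene (a TLS scan never revisits the same
#' physical surface points), with per-epoch child seeds derived from one
#' master seed.
#'
#' @param scene A [scene_model()].
#' @param deform A [deformation_config()].
#' @param n_dai Number of epochs.
#' @param interval_s Epoch spacing (s).
#' @param master_seed One integer seed controlling the whole series.
#' @param ... Passed to [sample_scan()] (density, noise_sigma, dropout, ...).
#' @return List with `dais` (a [dai_sequence()]; clouds carry per-point
#'   ground truth), `s` (per-epoch deformation state), `timestamps`,
#'   `scene`, `deform`, `tip_truth` (data frame: per branch and epoch, the
#'   true tip displacement magnitude).
#' @export
generate_time_series <- function(scene = scene_model(),
                                 deform = deformation_config(),
                                 n_dai = 41L, interval_s = 1200,
                                 master_seed = 1L, ...) {
  stopifnot(n_dai >= 1L, interval_s > 0)
  timestamps <- (seq_len(n_dai) - 1L) * interval_s
  s <- if (is.null(deform)) rep(0, n_dai) else temporal_profile(timestamps, deform)
  child <- with_rng_seed(master_seed, sample.int(.Machine$integer.max - 1L, n_dai))
  clouds <- vector("list", n_dai)
  for (i in seq_len(n_dai)) {
    clouds[[i]] <- sample_scan(scene, deform, s = s[i], rng_seed = child[i],
                               timestamp = timestamps[i], ...)
  }
  tip_truth <- NULL
  if (!is.null(scene$tips) && !is.null(deform)) {
    amp <- deformation_amplitude(scene, deform,
                                 as.matrix(scene$tips[, c("x", "y", "z")]))
    tip_truth <- do.call(rbind, lapply(seq_len(n_dai), function(i) {
      data.frame(branch_id = scene$tips$branch_id, dai = i - 1L,
                 timestamp_s = timestamps[i], true_disp_m = s[i] * amp)
    }))
  }
  list(dais = dai_sequence(clouds, timestamps), s = s, timestamps = timestamps,
       scene = scene, deform = deform, tip_truth = tip_truth,
       master_seed = master_seed)
}
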