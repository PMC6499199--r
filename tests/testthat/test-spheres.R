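test_that("noise-free sphere samples recover the exact center", {
  set.seed(20)
  pts <- sphere_points(500, c(1, 2, 3), 0.099)
  for (fr in list(NULL, 0.099)) {
    f <- fit_sphere(pts, fixed_radius = fr)
    expect_lt(sqrt(sum((f$center - c(1, 2, 3))^2)), 1e-9)
    expect_lt(abs(f$radius - 0.099), 1e-9)
    expect_lt(f$rms, 1e-10)
  }
})

test_that("a free fit of 4 non-coplanar points equals the circumsphere", {
  set.seed(21)
  repeat {
    p <- matrix(runif(12), 4, 3)
    if (abs(det(cbind(p[2:4, ] - rep(1, 3) %o% p[1, ]))) > 1e-3) break
  }
  # closed-form circumcenter: solve |x-c| equal for all 4 points
  A <- 2 * (p[2:4, ] - rep(1, 3) %o% p[1, ])
  b <- rowSums(p[2:4, ]^2) - sum(p[1, ]^2)
  ctr <- solve(A, b)
  f <- fit_sphere(p)
  expect_equal(f$center, as.numeric(ctr), tolerance = 1e-7)
  expect_equal(f$radius, sqrt(sum((p[1, ] - ctr)^2)), tolerance = 1e-7)
  expect_lt(f$rms, 1e-9)
})

test_that("hemisphere fits with fixed radius stay within 1 mm (Monte Carlo)", {
  set.seed(22)
  hits <- 0L
  runs <- 200L
  for (i in seq_len(runs)) {
    ctr <- runif(3, -1, 1)
    pts <- sphere_points(1000, ctr, 0.099, hemisphere = TRUE) +
      matrix(rnorm(3000, 0, 0.001), ncol = 3)
    f <- fit_sphere(pts, fixed_radius = 0.099)
    if (sqrt(sum((f$center - ctr)^2)) < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * runs)
})

test_that("sphere fitting is equivariant under rigid motion and rejects degeneracy", {
  set.seed(23)
  pts <- sphere_points(300, c(0.3, -0.1, 0.9), 0.099) +
    matrix(rnorm(900, 0, 5e-4), ncol = 3)
  R <- random_rotation(); t <- c(2, 1, -1)
  f0 <- fit_sphere(pts, fixed_radius = 0.099)
  f1 <- fit_sphere(sweep(pts %*% t(R), 2, t, "+"), fixed_radius = 0.099)
  expect_equal(f1$center, as.numeric(R %*% f0$center + t), tolerance = 1e-8)

  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_sphere(collinear), "collinear")
  expect_error(fit_sphere(pts[1:3, ]), "at least 4")
})

test_that("rigid registration recovers a known transform exactly", {
  set.seed(24)
  src <- matrix(runif(15, -2, 2), 5, 3)
  expect_equal(register_rigid(src, src)$rotation, diag(3), tolerance = 1e-12)
  expect_equal(register_rigid(src, src)$translation, c(0, 0, 0), tolerance = 1e-12)

  R0 <- random_rotation(); t0 <- c(0.3, -5, 2.2)
  dst <- sweep(src %*% t(R0), 2, t0, "+")
  tf <- register_rigid(src, dst)
  expect_lt(max(abs(tf$rotation - R0)), 1e-9)
  expect_lt(max(abs(tf$translation - t0)), 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-9)

  expect_error(register_rigid(src[1:2, ], dst[1:2, ]), "at least 3")
  line <- cbind(1:4, 1:4, 1:4)
  expect_error(register_rigid(line, line), "collinear")
})

test_that("registration residuals scale with the injected noise", {
  set.seed(25)
  sigma <- 0.002
  ratios <- replicate(100, {
    src <- matrix(runif(15, -2, 2), 5, 3)
    R0 <- random_rotation()
    dst <- sweep(src %*% t(R0), 2, runif(3), "+") +
      matrix(rnorm(15, 0, sigma), 5, 3)
    register_rigid(src, dst)$rms / sigma
  })
  # rms residual per pair is of order sigma (dof-adjusted below sqrt(3))
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), sqrt(3))
})

test_that("apply_rigid is an isometry with an exact inverse", {
  set.seed(26)
  cl <- random_cloud(100, intensity = TRUE)
  tf <- structure(list(rotation = random_rotation(), translation = c(1, 2, 3)),
                  class = "rigid_transform")
  idt <- structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                   class = "rigid_transform")
  expect_equal(apply_rigid(idt, cl)$coords, cl$coords)
  back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, cl))
  expect_equal(back$coords, cl$coords, tolerance = 1e-12)
  d0 <- dist(cl$coords[1:20, ])
  d1 <- dist(apply_rigid(tf, cl)$coords[1:20, ])
  expect_equal(as.numeric(d0), as.numeric(d1), tolerance = 1e-12)
})

test_that("transform files round-trip", {
  tf <- structure(list(rotation = random_rotation(), translation = c(0.1, -0.2, 5)),
                  class = "rigid_transform")
  f <- withr::local_tempfile(fileext = ".txt")
  write_transform(tf, f)
  back <- read_transform(f)
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-14)
  expect_equal(back$translation, tf$translation, tolerance = 1e-14)
})

test_that("stability report reproduces hand-computed metrics", {
  obs <- data.frame(
    sphere_id = rep(c("a", "b"), each = 3),
    dai = rep(0:2, 2),
    n_points = c(100, 101, 99, 500, 500, 500),
    cx = c(0, 0.003, 0.004, 1, 1, 1),
    cy = c(0, 0.004, 0, 2, 2, 2),
    cz = c(0, 0, 0.003, 3, 3, 3))
  rep_ <- stability_report(obs)
  a <- rep_$per_sphere[rep_$per_sphere$sphere_id == "a", ]
  expect_equal(a$count_rsd_pct, sd(c(100, 101, 99)) / 100 * 100)
  expect_equal(a$max_disp_m, 0.005)
  expect_equal(a$mean_disp_m, 0.005)
  b <- rep_$per_sphere[rep_$per_sphere$sphere_id == "b", ]
  expect_equal(b$count_rsd_pct, 0)
  expect_equal(b$max_disp_m, 0)
  expect_equal(rep_$displacements$disp_m[rep_$displacements$sphere_id == "a"],
               c(0, 0.005, 0.005))
})

test_that("center jitter displacement matches the chi-distribution mean", {
  set.seed(27)
  sigma <- 5e-4
  n_scan <- 400
  ctr <- matrix(rnorm(3 * n_scan, 0, sigma), ncol = 3)
  ctr[1, ] <- 0  # reference scan at the true center
  obs <- data.frame(sphere_id = "s", dai = seq_len(n_scan) - 1,
                    n_points = 1000, cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3])
  rep_ <- stability_report(obs)
  expected <- sigma * sqrt(2) * gamma(2) / gamma(1.5)  # E of chi(3) * sigma
  expect_equal(rep_$per_sphere$mean_disp_m, expected, tolerance = 0.15)
})

test_that("stability displacements are invariant under a global rigid motion", {
  set.seed(28)
  ctr <- matrix(rnorm(9, 0, 0.001), 3, 3)
  obs <- data.frame(sphere_id = "s", dai = 0:2, n_points = 10,
                    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3])
  R <- random_rotation(); t <- c(10, -3, 7)
  moved <- t(R %*% t(ctr) + t)
  obs2 <- obs
  obs2[, c("cx", "cy", "cz")] <- moved
  expect_equal(stability_report(obs)$displacements$disp_m,
               stability_report(obs2)$displacements$disp_m, tolerance = 1e-12)
})
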