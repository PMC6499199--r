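test_that("dart throwing handles the two degenerate extremes", {
  far <- point_cloud(diag(3) * 10)           # pairwise distances >> d_min
  expect_setequal(poisson_disk_seeds(far, 0.15, 1), 1:3)

  close_ <- point_cloud(matrix(runif(30, 0, 0.01), ncol = 3))
  expect_length(poisson_disk_seeds(close_, 0.15, 1), 1)

  expect_error(poisson_disk_seeds(point_cloud(matrix(numeric(0), ncol = 3)),
                                  0.15, 1), "empty")
})

test_that("dart throwing yields a maximal Poisson-disk sample", {
  set.seed(30)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    cl <- random_cloud(n, scale = runif(1, 0.3, 1.5))
    d_min <- runif(1, 0.1, 0.3)
    seeds <- poisson_disk_seeds(cl, d_min, rep)
    sc <- cl$coords[seeds, , drop = FALSE]
    if (length(seeds) > 1) {
      D <- as.matrix(dist(sc)); diag(D) <- Inf
      expect_gte(min(D), d_min)
    }
    cover <- apply(cl$coords, 1, function(p) min(sqrt(colSums((t(sc) - p)^2))))
    expect_lte(max(cover), d_min)
  }
})

test_that("nearest-seed labels match the exhaustive oracle and tie rule", {
  set.seed(31)
  cl <- random_cloud(500)
  seeds <- poisson_disk_seeds(cl, 0.25, 7)
  labels <- label_by_nearest_seed(cl, seeds)
  expect_equal(labels, unname(bf_nn1(cl$coords[seeds, , drop = FALSE], cl$coords)))

  one <- label_by_nearest_seed(cl, seeds[1])
  expect_true(all(one == 1L))

  # exact tie between two seeds resolves to the lower seed index
  tie_cloud <- point_cloud(rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 5, 0),
                                 c(0, 0, 0)))
  lab <- label_by_nearest_seed(tie_cloud, c(1L, 2L, 3L))
  expect_equal(lab[4], 1L)
})

test_that("pruning removes small clusters and relabeling grows survivors", {
  # forced outcome: clusters of 10 and 3 with min_size 6 merge into one of 13
  set.seed(32)
  big <- matrix(rnorm(30, 0, 0.01), 10, 3)
  small <- sweep(matrix(rnorm(9, 0, 0.01), 3, 3), 2, c(1, 0, 0), "+")
  cl <- point_cloud(rbind(big, small))
  labels <- rep(c(1L, 2L), c(10, 3))
  out <- prune_and_relabel(cl, labels, 6)
  expect_true(all(out == 1L))
  expect_length(out, 13)

  # all clusters large enough: identity after renumbering
  ok <- prune_and_relabel(cl, labels, 3)
  expect_equal(ok, labels)

  expect_error(prune_and_relabel(cl, labels, 100), "no cluster survives")
})

test_that("prune_and_relabel matches the two-stage oracle replay", {
  set.seed(33)
  for (rep in 1:8) {
    cl <- random_cloud(400, scale = 1)
    seeds <- poisson_disk_seeds(cl, 0.2, rep)
    labels <- label_by_nearest_seed(cl, seeds)
    min_size <- sample(5:40, 1)
    sizes <- tabulate(labels, length(seeds))
    if (!any(sizes >= min_size)) next
    expect_identical(prune_and_relabel(cl, labels, min_size),
                     bf_prune_relabel(cl$coords, labels, min_size))
  }
})

test_that("initial clustering is deterministic and finds separated blobs", {
  set.seed(34)
  blob1 <- matrix(rnorm(600, 0, 0.02), ncol = 3)
  blob2 <- sweep(matrix(rnorm(600, 0, 0.02), ncol = 3), 2, c(1, 1, 0), "+")
  cl <- point_cloud(rbind(blob1, blob2))
  p <- cluster_params(d_min = 0.15, min_size = 50, rng_seed = 99)
  lab <- initial_clustering(cl, p)
  expect_equal(lab$K, 2)
  expect_length(unique(lab$labels[1:200]), 1)
  expect_length(unique(lab$labels[201:400]), 1)

  again <- initial_clustering(cl, p)
  expect_identical(lab$labels, again$labels)
  expect_identical(lab$seed_indices, again$seed_indices)
})

test_that("every final cluster respects min_size and labels are contiguous", {
  set.seed(35)
  cl <- random_cloud(2000, scale = 1)
  lab <- initial_clustering(cl, cluster_params(d_min = 0.3, min_size = 30,
                                               rng_seed = 3))
  sizes <- tabulate(lab$labels, lab$K)
  expect_true(all(sizes >= 30))
  expect_setequal(unique(lab$labels), seq_len(lab$K))
  expect_equal(length(lab$seed_indices), lab$K)
})

test_that("clustering is equivariant under rigid motion of the cloud", {
  set.seed(36)
  cl <- random_cloud(800, scale = 1)
  p <- cluster_params(d_min = 0.2, min_size = 20, rng_seed = 5)
  R <- random_rotation(); t <- c(5, -1, 2)
  moved <- point_cloud(sweep(cl$coords %*% t(R), 2, t, "+"))
  a <- initial_clustering(cl, p)
  b <- initial_clustering(moved, p)
  expect_identical(a$labels, b$labels)
  expect_identical(a$seed_indices, b$seed_indices)

  # per-axis medians commute with translations (and axis permutations),
  # but not with general rotations: under rotation the centers agree only
  # to within the intra-cluster spread
  shifted <- point_cloud(sweep(cl$coords, 2, t, "+"))
  cs <- compute_centers(shifted, initial_clustering(shifted, p)$labels)
  ca <- compute_centers(cl, a$labels)
  expect_equal(cs$centers, sweep(ca$centers, 2, t, "+"),
               tolerance = 1e-12, ignore_attr = TRUE)
  cb <- compute_centers(moved, b$labels)
  expect_lt(max(abs(cb$centers - sweep(ca$centers %*% t(R), 2, t, "+"))),
            p$d_min)
})

test_that("median centers follow the documented conventions", {
  cl <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),
                          c(0, 0, 0), c(1, 0, 0)))
  cc <- compute_centers(cl, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(cc$centers[1, ], c(x = 1, y = 1, z = 1))
  expect_equal(cc$centers[2, ], c(x = 0.5, y = 0, z = 0))
  expect_equal(cc$counts, c(3L, 2L))

  # robustness to one outlier, versus the mean
  pts <- cbind(seq(0, 1, length.out = 101), 0, 0)
  pts <- rbind(pts, c(10, 0, 0))
  cc2 <- compute_centers(point_cloud(pts), rep(1L, 102))
  expect_lt(abs(cc2$centers[1, 1] - 0.5), 0.02)
  expect_gt(mean(pts[, 1]) - 0.5, 0.09)

  # permutation invariance
  set.seed(37)
  cl3 <- random_cloud(100)
  lab3 <- sample(1:3, 100, replace = TRUE)
  perm <- sample(100)
  a <- compute_centers(cl3, lab3)
  b <- compute_centers(subset_cloud(cl3, perm), lab3[perm])
  expect_equal(a$centers, b$centers)

  # absent cluster id flagged missing
  cc4 <- compute_centers(cl3, ifelse(lab3 == 2, 3L, lab3), K = 3)
  expect_true(cc4$missing[2])
  expect_true(all(is.na(cc4$centers[2, ])))
})
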