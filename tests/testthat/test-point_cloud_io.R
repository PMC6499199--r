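test_that("XYZ and PLY round-trips preserve coordinates and intensity", {
  set.seed(1)
  for (fmt in c("xyz", "ply")) {
    cl <- random_cloud(1000, scale = 50, intensity = TRUE)
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cloud(cl, f)
    back <- read_cloud(f)
    expect_equal(n_points(back), 1000)
    expect_lt(max(abs(back$coords - cl$coords)), 1e-12)
    expect_identical(back$intensity, cl$intensity)
  }
})

test_that("degenerate clouds survive the round-trip", {
  empty <- point_cloud(matrix(numeric(0), ncol = 3))
  zeros <- point_cloud(matrix(1:9, ncol = 3), intensity = c(0, 0, 0))
  for (fmt in c("xyz", "ply")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cloud(empty, f)
    expect_equal(n_points(read_cloud(f)), 0)
    write_cloud(zeros, f)
    back <- read_cloud(f)
    expect_identical(back$intensity, c(0, 0, 0))
    expect_equal(back$coords, zeros$coords, ignore_attr = TRUE)
  }
})

test_that("cross-format reads agree on the same points", {
  set.seed(2)
  cl <- random_cloud(200, intensity = TRUE)
  fx <- withr::local_tempfile(fileext = ".xyz")
  fp <- withr::local_tempfile(fileext = ".ply")
  write_cloud(cl, fx)
  write_cloud(cl, fp)
  a <- read_cloud(fx)
  b <- read_cloud(fp)
  expect_equal(a$coords, b$coords)
  expect_equal(a$intensity, b$intensity)
})

test_that("malformed records are rejected with the record index", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 1", "2 2 2"), f)
  expect_error(read_cloud(f), "point 2")
  writeLines(c("0 0 0", "1 1 bad"), f)
  expect_error(read_cloud(f), "point")
  expect_error(read_cloud("no/such/file.xyz"), "no such file")
})

test_that("merge_clouds concatenates in order and keeps provenance", {
  a <- point_cloud(matrix(runif(6), ncol = 3), scanner_id = "s1")
  b <- point_cloud(matrix(runif(9), ncol = 3), scanner_id = "s2")
  m <- merge_clouds(list(a, b))
  expect_equal(n_points(m), 5)
  expect_equal(m$coords, rbind(a$coords, b$coords), ignore_attr = TRUE)
  expect_equal(m$scanner, c("s1", "s1", "s2", "s2", "s2"))
  expect_equal(merge_clouds(list(a))$coords, a$coords)
  expect_error(merge_clouds(list()), "non-empty")
})

test_that("merged multi-view sphere scans fit the same center as one view", {
  set.seed(3)
  ctr <- c(1, -2, 0.5)
  views <- lapply(1:3, function(i) {
    point_cloud(sphere_points(400, ctr, 0.099) +
                  matrix(rnorm(1200, 0, 5e-4), ncol = 3))
  })
  single <- fit_sphere(views[[1]]$coords, fixed_radius = 0.099)
  merged <- fit_sphere(merge_clouds(views)$coords, fixed_radius = 0.099)
  expect_lt(sqrt(sum((single$center - merged$center)^2)), 1e-4)
})

test_that("delineation keeps points inside buffered polygons", {
  sq <- list(projection = "xy", vertices = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  b0 <- object_boundary(list(sq), buffer = 0)
  cl <- point_cloud(rbind(c(0.5, 0.5, 3), c(2, 2, 3)))
  kept <- delineate(cl, b0)
  expect_equal(n_points(kept), 1)
  expect_equal(kept$coords[1, ], c(x = 0.5, y = 0.5, z = 3))

  b05 <- object_boundary(list(sq), buffer = 0.5)
  near <- point_cloud(rbind(c(1.3, 0.5, -1), c(1.6, 0.5, -1)))
  expect_equal(n_points(delineate(near, b05)), 1)

  on_edge <- point_cloud(rbind(c(1, 0.5, 0)))
  expect_equal(n_points(delineate(on_edge, b0)), 1)
})

test_that("multi-projection delineation equals intersection of single crops", {
  set.seed(4)
  cl <- random_cloud(500, scale = 2)
  p1 <- list(projection = "xy", vertices = rbind(c(0.2, 0.2), c(1.5, 0.3),
                                                 c(1.4, 1.6), c(0.1, 1.2)))
  p2 <- list(projection = "xz", vertices = rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
  both <- delineate(cl, object_boundary(list(p1, p2), buffer = 0.1))
  only1 <- delineate(cl, object_boundary(list(p1), buffer = 0.1))
  only2 <- delineate(cl, object_boundary(list(p2), buffer = 0.1))
  key <- function(c) apply(c$coords, 1, paste, collapse = "|")
  expect_setequal(key(both), intersect(key(only1), key(only2)))
})

test_that("delineation is idempotent and monotone in the buffer", {
  set.seed(5)
  cl <- random_cloud(400, scale = 2)
  poly <- list(projection = "xy",
               vertices = rbind(c(0.3, 0.1), c(1.7, 0.4), c(1.2, 1.8), c(0.2, 1.1)))
  for (buf in c(0, 0.25)) {
    b <- object_boundary(list(poly), buffer = buf)
    once <- delineate(cl, b)
    expect_equal(delineate(once, b)$coords, once$coords)
  }
  small <- delineate(cl, object_boundary(list(poly), buffer = 0.05))
  big <- delineate(cl, object_boundary(list(poly), buffer = 0.4))
  key <- function(c) apply(c$coords, 1, paste, collapse = "|")
  expect_true(all(key(small) %in% key(big)))
})

test_that("boundary files round-trip", {
  b <- object_boundary(list(
    list(projection = "xy", vertices = rbind(c(0, 0), c(2, 0), c(1, 2))),
    list(projection = "yz", vertices = rbind(c(-1, 0), c(1, 0), c(0, 3)))),
    buffer = 0.35)
  f <- withr::local_tempfile(fileext = ".txt")
  write_boundary(b, f)
  back <- read_boundary(f)
  expect_equal(back$buffer, 0.35)
  expect_equal(length(back$polygons), 2)
  expect_equal(back$polygons[[2]]$vertices, b$polygons[[2]]$vertices)
})

test_that("degenerate polygons are rejected", {
  line <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(object_boundary(list(list(projection = "xy", vertices = line))),
               "degenerate")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(object_boundary(list(list(projection = "xy", vertices = bowtie))),
               "simple")
})
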