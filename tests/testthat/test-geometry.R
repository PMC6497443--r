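test_that("standard nest layouts have the documented areas and connectivity", {
  n1 <- nest_one_chamber()
  expect_equal(nest_area(n1, include_corridors = FALSE), 65 * 40)
  expect_equal(nest_area(n1), 65 * 40 + 2 * 6)

  n4 <- nest_four_chamber()
  expect_equal(nest_area(n4, include_corridors = FALSE), 4 * 65 * 40)
  # polygon-union oracle: rectangles are disjoint by construction, so the
  # union area is the sum: 4 chambers + entrance corridor + 3 openings
  expect_equal(nest_area(n4), 4 * 2600 + 4 * (2 * 6))
  expect_true(all(in_nest(c(0, 66, 100, 200.5), c(0, 0, 10, 0), n4)))
})

test_that("degenerate and inconsistent nest configs are rejected", {
  expect_error(
    nest_geometry(tibble::tibble(x0 = 0, y0 = 0, width = 65, height = 40),
                  tibble::tibble(a = 1L, b = 0L, center = 20, width = 0,
                                 side = "left")),
    class = "antnest_config_error")
  expect_error(
    nest_geometry(tibble::tibble(x0 = c(0, 10), y0 = 0, width = 65,
                                 height = 40),
                  tibble::tibble(a = 1L, b = 0L, center = 20, width = 6,
                                 side = "left")),
    class = "antnest_config_error")
  # two chambers with no opening between them: disconnected
  expect_error(
    nest_geometry(tibble::tibble(x0 = c(0, 100), y0 = 0, width = 20,
                                 height = 16),
                  tibble::tibble(a = 1L, b = 0L, center = 8, width = 3,
                                 side = "left")),
    class = "antnest_config_error")
  expect_error(
    nest_geometry(tibble::tibble(x0 = 0, y0 = 0, width = -5, height = 40),
                  tibble::tibble(a = 1L, b = 0L, width = 6, side = "left")),
    class = "antnest_config_error")
})

test_that("build_nest accepts list configs and rejects incomplete ones", {
  cfg <- list(
    chambers = list(list(x0 = 0, y0 = -20, width = 65, height = 40)),
    openings = list(list(a = 1, b = 0, center = 0, width = 6, side = "left"))
  )
  nest <- build_nest(cfg)
  expect_s3_class(nest, "nest_geometry")
  expect_equal(nest_area(nest, include_corridors = FALSE), 2600)
  expect_error(build_nest(list()), class = "antnest_config_error")
})

test_that("geodesic distance is Euclidean within a chamber and zero at p = q", {
  n1 <- nest_one_chamber()
  expect_equal(geodesic_distance(c(10, 5), c(10, 5), n1), 0)
  expect_equal(geodesic_distance(c(10, 0), c(40, 10), n1),
               sqrt(30^2 + 10^2))
})

test_that("cross-chamber geodesic distances match a fine-grid Dijkstra oracle", {
  nest <- small_two_chamber()
  res <- 0.5
  set.seed(71)
  # points on both sides of the dividing wall
  p <- cbind(runif(6, 2, 18), runif(6, -7, 7))
  q <- cbind(runif(6, 24, 40), runif(6, -7, 7))
  d_pkg <- geodesic_distance(p, q, nest, res = res)
  for (k in seq_len(nrow(p))) {
    d_oracle <- oracle_grid_distance(nest, p[k, ], q[k, ], res = res,
                                     connectivity = 8)
    expect_lt(abs(d_pkg[k] - d_oracle), 2 * res * sqrt(2))
  }
})

test_that("geodesic distance is a metric and dominates Euclidean distance", {
  nest <- small_two_chamber()
  set.seed(5)
  pts <- cbind(runif(9, 0, 42), runif(9, -7, 7))
  pr <- project_into_nest(pts[, 1], pts[, 2], nest)
  D <- antnest:::geodesic_distance_matrix(pr$x, pr$y, nest, res = 0.5)
  E <- as.matrix(dist(cbind(pr$x, pr$y)))
  expect_true(all(D >= E - 1e-9))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  tol <- 2 * 0.5 * sqrt(2)  # grid discretisation slack
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + tol)
  }
})

test_that("points outside the walkable region are a domain error", {
  n1 <- nest_one_chamber()
  expect_error(geodesic_distance(c(-10, 0), c(10, 0), n1),
               class = "antnest_domain_error")
  expect_error(distance_to_entrance(80, 0, n1),
               class = "antnest_domain_error")
})

test_that("entrance distance is L1 in the entrance chamber and 0 at the entrance", {
  n1 <- nest_one_chamber()
  ep <- n1$entrance_point
  expect_equal(distance_to_entrance(ep[1], ep[2], n1), 0)
  expect_equal(distance_to_entrance(10, 5, n1), 15)
  expect_equal(distance_to_entrance(c(3, 60), c(-4, 19), n1), c(7, 79))
})

test_that("entrance distance deep in the nest matches a 4-connected BFS oracle", {
  nest <- small_four_chamber()
  res <- 0.5
  g <- oracle_grid(nest, res)
  fld <- oracle_dijkstra_field(g, oracle_cell(g, nest$entrance_point),
                               connectivity = 4)
  set.seed(12)
  xs <- runif(8, 40, 70)  # queen-end chambers
  ys <- runif(8, -4, 4)
  pr <- project_into_nest(xs, ys, nest)
  d_pkg <- distance_to_entrance(pr$x, pr$y, nest, res = res)
  for (k in seq_along(xs)) {
    cc <- oracle_cell(g, c(pr$x[k], pr$y[k]))
    expect_lt(abs(d_pkg[k] - fld[cc[1], cc[2]]), 3 * res)
  }
  # rectilinear distance never beats the unconstrained L1 distance
  ep <- nest$entrance_point
  expect_true(all(d_pkg >= abs(pr$x - ep[1]) + abs(pr$y - ep[2]) - 1e-9))
})

test_that("projection returns interior points unchanged and is idempotent", {
  n1 <- nest_one_chamber()
  p <- project_into_nest(c(10, 30), c(0, 19), n1)
  expect_equal(p$x, c(10, 30))
  expect_equal(p$y, c(0, 19))
  # 1 mm outside the middle of the top edge -> foot of the perpendicular
  p2 <- project_into_nest(32, 21, n1)
  expect_equal(c(p2$x, p2$y), c(32, 20))
  # diagonally outside a corner -> the corner vertex
  p3 <- project_into_nest(70, 25, n1)
  expect_equal(c(p3$x, p3$y), c(65, 20))
  set.seed(3)
  xs <- runif(50, -20, 300); ys <- runif(50, -30, 30)
  n4 <- nest_four_chamber()
  pr <- project_into_nest(xs, ys, n4)
  pr2 <- project_into_nest(pr$x, pr$y, n4)
  expect_equal(pr, pr2)
  expect_true(all(in_nest(pr$x, pr$y, n4)))
})

test_that("affine alignment recovers exact and randomly generated transforms", {
  corners <- cbind(c(0, 100, 0, 100), c(0, 0, 80, 80))
  tf_id <- fit_affine(corners, corners)
  expect_equal(tf_id$A, diag(2), tolerance = 1e-12)
  expect_equal(tf_id$b, c(0, 0), tolerance = 1e-12)

  tf_shift <- fit_affine(corners, corners + rep(c(5, -3), each = 4))
  expect_equal(tf_shift$A, diag(2), tolerance = 1e-12)
  expect_equal(tf_shift$b, c(5, -3), tolerance = 1e-12)

  set.seed(42)
  A <- matrix(rnorm(4, sd = 2), 2); b <- rnorm(2, sd = 10)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(4, sd = 2), 2)
  dst <- t(A %*% t(corners) + b)
  tf <- fit_affine(corners, dst)
  expect_equal(tf$A, A, tolerance = 1e-9)
  expect_equal(tf$b, b, tolerance = 1e-9)
  expect_true(all(tf$residuals < 1e-9))
  expect_equal(as.matrix(apply_affine(corners, tf)), dst,
               tolerance = 1e-9, ignore_attr = TRUE)

  collinear <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(fit_affine(collinear, collinear), class = "antnest_rank_error")
})
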