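test_that("carbon range and variance follow their definitions", {
  expect_equal(carbon_range(c(-20, -20, -20)), 0)
  expect_equal(carbon_range(c(-22.5, -18.0, -20.1)), 4.5)
  expect_error(carbon_range(numeric(0)))
  set.seed(1)
  u <- runif(100, -25, -15)
  expect_lte(carbon_range(u), 10)

  expect_equal(carbon_variance(c(1, 1, 1)), 0)
  expect_equal(carbon_variance(c(0, 2)), 2.0)
  expect_error(carbon_variance(1))
  set.seed(2)
  g <- rnorm(2e4, sd = 1)
  se_var <- sqrt(2 / (length(g) - 1))  # var of sample variance of N(0,1)
  expect_lt(abs(carbon_variance(g) - 1), 3 * se_var)
})

test_that("convex hull area matches hand values and a brute-force oracle", {
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                                      c(0.5, 0.5))), 1.0)
  expect_warning(a0 <- convex_hull_area(rbind(c(0, 0), c(1, 1))), "fewer")
  expect_equal(a0, 0)
  expect_warning(ac <- convex_hull_area(rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "collinear")
  expect_equal(ac, 0)
  set.seed(3)
  for (rep in 1:5) {
    pts <- matrix(rnorm(100), ncol = 2)
    expect_equal(convex_hull_area(pts), brute_hull_area(pts),
                 tolerance = 1e-10)
  }
})

test_that("standard ellipse area and small-sample correction", {
  # whiten points so the sample covariance is exactly the identity
  set.seed(4)
  raw <- matrix(rnorm(20), ncol = 2)
  raw <- scale(raw, scale = FALSE)
  W <- chol(solve(cov(raw)))
  pts <- raw %*% t(W)
  e <- standard_ellipse(pts)
  expect_equal(e$sea, pi, tolerance = 1e-10)
  expect_equal(e$seac, pi * 9 / 8, tolerance = 1e-10)  # n = 10
  expect_error(standard_ellipse(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               "degenerate")
  expect_error(standard_ellipse(matrix(rnorm(6), ncol = 2)), "at least 4")
})

test_that("standard ellipse contains ~39.3% of bivariate normal points", {
  set.seed(5)
  n <- 1e4
  pts <- cbind(rnorm(n, 2, 1.5), rnorm(n, -1, 0.8) + 0.4 * rnorm(n))
  e <- standard_ellipse(pts)
  S_inv <- solve(e$cov)
  d <- sweep(pts, 2, e$centroid)
  maha2 <- rowSums((d %*% S_inv) * d)
  frac <- mean(maha2 <= 1)
  p <- 1 - exp(-0.5)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("hull overlap matches hand cases and Monte-Carlo containment", {
  set.seed(6)
  A <- matrix(rnorm(40), ncol = 2)
  same <- hull_overlap(A, A)
  expect_equal(same$pct_of_i, 100, tolerance = 1e-9)
  expect_equal(same$pct_of_j, 100, tolerance = 1e-9)
  B <- A + 100
  expect_equal(hull_overlap(A, B)$area_overlap, 0)
  expect_error(hull_overlap(rbind(c(0, 0), c(1, 1), c(2, 2)), A),
               "degenerate")

  # MC oracle: overlapping random hulls
  C <- matrix(rnorm(40), ncol = 2) + 0.8
  ov <- hull_overlap(A, C)
  box_lo <- pmin(apply(A, 2, min), apply(C, 2, min))
  box_hi <- pmax(apply(A, 2, max), apply(C, 2, max))
  mc <- cbind(runif(2e5, box_lo[1], box_hi[1]),
              runif(2e5, box_lo[2], box_hi[2]))
  hull_a <- isocompete:::.hull_vertices(A)
  hull_c <- isocompete:::.hull_vertices(C)
  est <- mean(in_convex(mc, hull_a) & in_convex(mc, hull_c)) *
    prod(box_hi - box_lo)
  expect_equal(ov$area_overlap, est, tolerance = 0.02)
  # absolute overlap is symmetric; percentages need not be
  expect_equal(hull_overlap(C, A)$area_overlap, ov$area_overlap,
               tolerance = 1e-9)
})

test_that("ellipse overlap matches identity, disjoint and MC cases", {
  set.seed(7)
  e1 <- standard_ellipse(matrix(rnorm(60), ncol = 2))
  same <- ellipse_overlap(e1, e1)
  expect_equal(same$pct_of_i, 100, tolerance = 0.5)
  far <- e1
  far$centroid <- e1$centroid + 100
  expect_equal(ellipse_overlap(e1, far)$area_overlap, 0)

  e2 <- standard_ellipse(matrix(rnorm(60), ncol = 2) * 1.4 + 0.5)
  ov <- ellipse_overlap(e1, e2)
  # MC containment oracle on a bounding box
  ctr <- rbind(e1$centroid, e2$centroid)
  lo <- apply(ctr, 2, min) - 6
  hi <- apply(ctr, 2, max) + 6
  mc <- cbind(runif(4e5, lo[1], hi[1]), runif(4e5, lo[2], hi[2]))
  inside <- function(e, p) {
    d <- sweep(p, 2, e$centroid)
    rowSums((d %*% solve(e$cov)) * d) <= 1
  }
  est <- mean(inside(e1, mc) & inside(e2, mc)) * prod(hi - lo)
  expect_equal(ov$area_overlap, est, tolerance = 0.03)
  expect_equal(ellipse_overlap(e2, e1)$area_overlap, ov$area_overlap,
               tolerance = 1e-6)
})

test_that("resource-centroid standardization is a per-location translation", {
  specs <- data.frame(
    specimen_id = paste0("s", 1:6),
    species = "sp", location = rep(c("H", "L"), each = 3),
    site = "S1", litterbag = "B1",
    d13c = c(-15, -16, -17, -18, -19, -20),
    d15n = c(3, 4, 5, 6, 7, 8), stringsAsFactors = FALSE)
  res <- data.frame(resource = rep(c("a", "b"), 2),
                    location = rep(c("H", "L"), each = 2),
                    d13c_mean = c(-14, -16, -18, -20),
                    d15n_mean = c(2, 4, 5, 7),
                    d13c_sd = 0.5, d15n_sd = 0.5, n = 5L,
                    stringsAsFactors = FALSE)
  std <- standardize_to_resource_centroid(specs, res)
  # hand subtraction: H centroid (-15, 3), L centroid (-19, 6)
  expect_equal(std$d13c, c(0, -1, -2, 1, 0, -1))
  expect_equal(std$d15n, c(0, 1, 2, 0, 1, 2))

  # specimen exactly at its centroid maps to the origin
  at_centroid <- specs[1, ]; at_centroid$d13c <- -15; at_centroid$d15n <- 3
  std1 <- standardize_to_resource_centroid(at_centroid, res)
  expect_equal(c(std1$d13c, std1$d15n), c(0, 0))

  # joint translation of resources and specimens leaves output unchanged
  specs2 <- specs; specs2$d13c <- specs2$d13c + 5; specs2$d15n <- specs2$d15n + 5
  res2 <- res; res2$d13c_mean <- res2$d13c_mean + 5
  res2$d15n_mean <- res2$d15n_mean + 5
  std2 <- standardize_to_resource_centroid(specs2, res2)
  expect_equal(std2$d13c, std$d13c)
  expect_equal(std2$d15n, std$d15n)

  expect_error(standardize_to_resource_centroid(specs, res[res$location == "H", ]),
               "no resources")
})

test_that("specimen distance summaries follow their definitions", {
  one_point <- rbind(c(1, 1), c(1, 1), c(1, 1))
  nd <- nd_distances(one_point)
  expect_equal(nd$nd, c(0, 0, 0))

  pair <- rbind(c(0, 0), c(1, 0))
  nd2 <- nd_distances(pair)
  expect_equal(nd2$nd, c(1, 1))
  expect_equal(nd2$mnd, 1)

  j <- rbind(c(0, 1), c(1, 1))
  ndij <- nd_distances(pair, j)
  expect_equal(ndij$nd[1], (1 + sqrt(2)) / 2)

  expect_warning(single <- nd_distances(rbind(c(0, 0))), "singleton")
  expect_null(single)

  # MND_ij == MND_ji: both equal the grand mean of the distance matrix
  set.seed(8)
  A <- matrix(rnorm(24), ncol = 2)
  B <- matrix(rnorm(14, 1), ncol = 2)
  expect_equal(nd_distances(A, B)$mnd, nd_distances(B, A)$mnd,
               tolerance = 1e-12)
})

test_that("niche geometry is invariant under rigid motions", {
  set.seed(9)
  pts <- matrix(rnorm(50), ncol = 2)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- pts %*% t(R) + rep(c(3, -2), each = nrow(pts))
  expect_equal(convex_hull_area(moved), convex_hull_area(pts),
               tolerance = 1e-10)
  expect_equal(standard_ellipse(moved)$sea, standard_ellipse(pts)$sea,
               tolerance = 1e-10)
  # ellipse centroid lies inside the hull
  e <- standard_ellipse(pts)
  hull <- isocompete:::.hull_vertices(pts)
  expect_true(in_convex(rbind(e$centroid), hull))
})

test_that("Pielou evenness spans its range", {
  expect_equal(pielou_evenness(c(5, 5, 5, 5)), 1.0)
  expect_equal(pielou_evenness(c(9, 0, 0)), 0.0)
  expect_equal(pielou_evenness(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2))
  expect_error(pielou_evenness(c(0, 0)), "zero total")
  expect_error(pielou_evenness(5), "two litterbags")
})

test_that("bootstrap SEAc comparison detects scaling and is seeded", {
  set.seed(10)
  A <- matrix(rnorm(60), ncol = 2)
  scaled <- compare_seac(A, A * 3, B = 400L, seed = 11L)
  expect_lt(scaled$p, 0.01)  # scaling x3 multiplies SEAc by 9
  expect_equal(scaled$seac_j / scaled$seac_i, 9, tolerance = 1e-9)

  null1 <- compare_seac(A, A, B = 300L, seed = 12L)
  null2 <- compare_seac(A, A, B = 300L, seed = 12L)
  expect_identical(null1$t, null2$t)
  expect_identical(null1$p, null2$p)

  # under the null (identical point sets) non-significance holds in the
  # vast majority of seeded runs
  null_ps <- vapply(1:20, function(s) {
    compare_seac(A, A, B = 200L, seed = s)$p
  }, numeric(1))
  expect_gte(mean(null_ps > 0.05), 0.85)

  expect_warning(compare_seac(A, A, B = 50L, seed = 1L), "crude")
})
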