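test_that("unit-square corners plus center give one bounded cell of area 0.5", {
  xy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  t <- tessellate(sites_map(xy))
  expect_equal(t$n_finite, 1L)
  expect_true(t$cells$bounded[5])
  expect_false(any(t$cells$bounded[1:4]))
  # exact: the center cell is the diamond with vertices at the edge midpoints
  expect_equal(t$cells$area[5], 0.5, tolerance = 1e-9)
  # Monte-Carlo oracle over the unit square
  mc <- mc_cell_areas(xy, n_samples = 1e6, box = c(0, 1, 0, 1))
  expect_equal(mc[5], 0.5, tolerance = 0.01)
})

test_that("three sites have only unbounded cells and cannot be normalized", {
  t <- tessellate(sites_map(rbind(c(0, 0), c(1, 0), c(0.4, 1))))
  expect_equal(t$n_finite, 0L)
  expect_true(all(is.na(t$cells$area)))
  expect_error(normalize_densities(t), "no bounded cells")
})

test_that("areas and edges are invariant under translation", {
  xy <- random_sites(40, seed = 2)
  t1 <- tessellate(sites_map(xy))
  t2 <- tessellate(sites_map(sweep(xy, 2, c(10, -7), "+")))
  expect_equal(t1$cells$area, t2$cells$area, tolerance = 1e-9)
  expect_equal(t1$edges[c("site_a", "site_b")], t2$edges[c("site_a", "site_b")])
  expect_equal(t1$cells$bounded, t2$cells$bounded)
})

test_that("normalized densities are invariant under rotation and scaling", {
  xy <- random_sites(60, seed = 8)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  f1 <- normalize_densities(tessellate(sites_map(xy)))$cells$normalized_density
  f2 <- normalize_densities(tessellate(sites_map(3.2 * xy %*% rot)))$cells$normalized_density
  # circumcenters of near-degenerate Delaunay triangles move at ~1e-4
  # relative under reordered floating-point arithmetic
  expect_equal(f1, f2, tolerance = 1e-4)
})

test_that("degenerate inputs are rejected with informative errors", {
  xy <- rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.9, 0.9), c(0.1, 0.1))
  expect_error(tessellate(sites_map(xy, c("AA", "BB", "CC", "DD"))), "AA.*DD")
  col <- cbind(seq(0, 1, length.out = 5), seq(0, 2, length.out = 5))
  expect_error(tessellate(sites_map(col)), "collinear")
  expect_error(tessellate(sites_map(xy[1:2, , drop = FALSE])), "at least 3")
  # jitter with a seed resolves duplicates deterministically
  t1 <- tessellate(sites_map(xy, c("AA", "BB", "CC", "DD")), jitter = 1e-6, seed = 4)
  t2 <- tessellate(sites_map(xy, c("AA", "BB", "CC", "DD")), jitter = 1e-6, seed = 4)
  expect_equal(t1$cells, t2$cells)
})

test_that("perturbed-grid densities match the Monte-Carlo oracle within 1%", {
  g <- seq(0, 1, length.out = 7)
  xy <- as.matrix(expand.grid(x = g, y = g))
  # displace one interior site 30% of a grid step toward its right neighbor
  i <- which(xy[, 1] == g[4] & xy[, 2] == g[4])
  xy[i, 1] <- xy[i, 1] + 0.3 * diff(g)[1]
  t <- normalize_densities(tessellate(sites_map(xy)))
  mc_area <- mc_cell_areas(xy, n_samples = 4e6, box = c(-0.5, 1.5, -0.5, 1.5),
                           seed = 42)
  b <- t$cells$bounded
  mc_fnorm <- mean(mc_area[b]) / mc_area[b]
  expect_equal(t$cells$normalized_density[b], mc_fnorm, tolerance = 0.01)
})

test_that("harmonic identity and area sanity hold on random instances", {
  for (seed in 1:6) {
    n <- sample(20:120, 1)
    xy <- random_sites(n, seed = seed)
    t <- normalize_densities(tessellate(sites_map(xy)))
    f <- t$cells$normalized_density[t$cells$bounded]
    expect_true(all(t$cells$area[t$cells$bounded] > 0))
    expect_equal(sum(1 / f), t$n_finite, tolerance = 1e-9)
    # bounded cells tile part of the padded clipping region around the data
    pad <- 10 * max(diff(range(xy[, 1])), diff(range(xy[, 2])))
    region <- prod(diff(range(xy[, 1])) + 2 * pad,
                   diff(range(xy[, 2])) + 2 * pad)
    expect_lte(sum(t$cells$area[t$cells$bounded]), region)
  }
})

test_that("midpoint rule disqualifies blocked edges and keeps isolated pairs", {
  # third site 0.4 from the midpoint of the base edge, closer than 0.5
  t <- qualified_neighbors(tessellate(sites_map(
    rbind(c(0, 0), c(1, 0), c(0.5, 0.4)))))
  e <- t$edges
  base <- e$site_a == 1 & e$site_b == 2
  expect_false(e$qualified[base])
  expect_true(all(e$qualified[!base]))

  # two isolated distant pairs: no blocking site, both pair edges qualify,
  # and the full qualified set matches the all-pairs disk test
  xy2 <- rbind(c(0, 0), c(0, 0.1), c(5, 5), c(5, 5.1))
  t2 <- qualified_neighbors(tessellate(sites_map(xy2)))
  e2 <- t2$edges
  pair <- (e2$site_a == 1 & e2$site_b == 2) | (e2$site_a == 3 & e2$site_b == 4)
  expect_true(all(e2$qualified[pair]))
  got <- e2[e2$qualified, c("site_a", "site_b")]
  expect_equal(unname(as.matrix(got[order(got$site_a), ])),
               unname(brute_gabriel(xy2)))
})

test_that("qualified edges equal the brute-force Gabriel graph", {
  for (seed in 1:5) {
    xy <- random_sites(100, seed = 100 + seed)
    t <- qualified_neighbors(tessellate(sites_map(xy)))
    got <- t$edges[t$edges$qualified, c("site_a", "site_b")]
    got <- got[order(got$site_a, got$site_b), ]
    want <- brute_gabriel(xy)
    expect_equal(unname(as.matrix(got)), unname(want))
  }
})

test_that("bounding-box mode clips every cell to a finite polygon", {
  xy <- random_sites(30, seed = 12)
  t <- tessellate(sites_map(xy), bounding_box = c(0, 1, 0, 1))
  expect_equal(t$n_finite, 30L)
  expect_true(all(t$cells$bounded))
  expect_equal(sum(t$cells$area), 1, tolerance = 1e-9)  # cells tile the box
})
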