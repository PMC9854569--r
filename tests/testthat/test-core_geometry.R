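test_that("ray directions follow the angular convention", {
  d4 <- ray_directions(4)
  expect_equal(unname(d4),
               rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0)),
               tolerance = 1e-12)
  d32 <- ray_directions(32)
  ang <- atan2(d32[, 1], d32[, 2]) %% (2 * pi)
  expect_equal(diff(ang)[1:15], rep(2 * pi / 32, 15), tolerance = 1e-12)
  expect_true(all(abs(rowSums(d32^2) - 1) < 1e-12))
  # symmetry: directions cancel
  for (n in c(3, 5, 8, 32, 57))
    expect_lt(sqrt(sum(colSums(ray_directions(n))^2)), 1e-9)
  expect_error(ray_directions(2), "n_rays")
})

test_that("polygon vertices match direct trigonometric evaluation", {
  p <- star_polygon(c(0, 0), rep(3, 4))
  expect_equal(unname(polygon_vertices(p)),
               rbind(c(0, 3), c(3, 0), c(0, -3), c(-3, 0)),
               tolerance = 1e-12)
  p0 <- star_polygon(c(5, 7), rep(0, 8))
  expect_true(all(abs(sweep(polygon_vertices(p0), 2, c(5, 7))) < 1e-12))
  set.seed(42)
  pr <- random_polygon(32, center = c(10, 10))
  expect_equal(unname(polygon_vertices(pr)), unname(oracle_vertices(pr)),
               tolerance = 1e-12)
})

test_that("polygon area: closed form, degenerate, raster oracle", {
  for (n in c(4, 8, 32)) {
    p <- star_polygon(c(0, 0), rep(5, n))
    expect_equal(polygon_area(p), (n / 2) * 25 * sin(2 * pi / n),
                 tolerance = 1e-12)
  }
  expect_equal(polygon_area(star_polygon(c(1, 1), rep(0, 8))), 0)
  set.seed(7)
  p <- random_polygon(16, rmin = 4, rmax = 12)
  expect_equal(polygon_area(p), oracle_area_raster(p, 0.05),
               tolerance = 0.01)
  # 32-gon area converges to the disk area (< 1% off at n = 32)
  p32 <- star_polygon(c(0, 0), rep(10, 32))
  expect_lt(abs(polygon_area(p32) - pi * 100) / (pi * 100), 0.01)
})

test_that("polygon IoU: exact values and raster agreement", {
  set.seed(3)
  a <- random_polygon(32)
  expect_equal(polygon_iou(a, a), 1.0, tolerance = 1e-9)
  far <- star_polygon(c(200, 200), a$distances)
  expect_equal(polygon_iou(a, far), 0)
  # two degenerate polygons
  z <- star_polygon(c(5, 5), rep(0, 8))
  expect_equal(polygon_iou(z, z), 0)
  # unit squares offset by 0.5: intersection 0.5, union 1.5
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  sq2 <- sq + 0.5 * cbind(rep(0, 4), rep(1, 4))
  expect_equal(starseg:::cpp_clip_iou(sq, sq2, 0.5, 0.5, 0.5, 1.0), 1 / 3,
               tolerance = 1e-9)
  # diamonds (4-ray stars) with a closed-form overlap
  d1 <- star_polygon(c(0, 0), rep(1, 4))
  d2 <- star_polygon(c(0, 1), rep(1, 4))  # shifted one half-diagonal
  inter <- 0.5  # squares of side sqrt(2) overlapping in half
  expect_equal(polygon_iou(d1, d2), inter / (2 + 2 - inter),
               tolerance = 1e-9)
  # raster backend agreement on random pairs
  for (i in 1:30) {
    a <- random_polygon(32, center = c(20, 20))
    b <- random_polygon(32, center = c(20, 20) + runif(2, -10, 10))
    expect_lt(abs(polygon_iou(a, b) - oracle_iou_raster(a, b)), 0.01)
  }
})

test_that("polygon IoU invariants: symmetry, bounds, scale invariance", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_polygon(16)
    b <- random_polygon(16, center = c(20, 20) + runif(2, -12, 12))
    iab <- polygon_iou(a, b)
    expect_equal(iab, polygon_iou(b, a), tolerance = 1e-9)
    expect_gte(iab, 0); expect_lte(iab, 1)
    s <- 3.7
    as <- star_polygon(a$center * s, a$distances * s)
    bs <- star_polygon(b$center * s, b$distances * s)
    expect_equal(polygon_iou(as, bs), iab, tolerance = 1e-9)
  }
})

test_that("rasterization matches polygon area and drops out-of-image parts", {
  z <- star_polygon(c(10, 10), rep(0, 8))
  expect_equal(sum(rasterize_polygon(z, c(32, 32))), 0)
  p <- star_polygon(c(31.5, 31.5), rep(20, 32))
  m <- rasterize_polygon(p, c(64, 64))
  expect_lt(abs(sum(m) - polygon_area(p)) / polygon_area(p), 0.03)
  # partially outside the image never gains pixels
  pout <- star_polygon(c(5, 5), rep(20, 32))
  expect_lte(sum(rasterize_polygon(pout, c(64, 64))), sum(m))
})

test_that("polygon CSV and GeoJSON round trips", {
  set.seed(8)
  polys <- lapply(1:3, function(i) random_polygon(8))
  f <- tempfile(fileext = ".csv")
  write_polygons_csv(polys, f)
  back <- read_polygons_csv(f)
  for (i in 1:3) {
    expect_equal(back[[i]]$center, polys[[i]]$center)
    expect_equal(back[[i]]$distances, polys[[i]]$distances)
    expect_equal(back[[i]]$score, polys[[i]]$score)
  }
  gj <- polygon_geojson(polys[[1]])
  expect_equal(gj$type, "Polygon")
  expect_equal(nrow(gj$coordinates[[1]]), 9)  # closed ring
})

test_that("star_polygon validates its inputs", {
  expect_error(star_polygon(c(0, 0), c(1, 2)), "3 rays")
  expect_error(star_polygon(c(0, 0), c(1, -1, 2)), "non-negative")
  expect_error(star_polygon(c(0, 0), rep(1, 4), score = 2), "score")
})
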