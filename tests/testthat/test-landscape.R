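test_that("classical MDS recovers exactly embeddable configurations", {
  set.seed(61)
  pts <- matrix(rnorm(30), ncol = 2)
  d <- as.matrix(dist(pts))
  co <- mds_embed(d, 2)
  expect_equal(as.matrix(dist(co)), d, ignore_attr = TRUE,
               tolerance = 1e-9)
  sh <- shepard_stats(d, co)
  expect_equal(sh$pearson, 1, tolerance = 1e-9)

  # three equidistant points form a unit equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  co3 <- mds_embed(d3, 2)
  expect_equal(as.vector(dist(co3)), rep(1, 3), tolerance = 1e-9)

  # duplicated point lands on coincident coordinates
  d4 <- as.matrix(dist(pts[c(1, 1, 2, 3, 4), ]))
  co4 <- mds_embed(d4, 2)
  expect_equal(co4[1, ], co4[2, ], tolerance = 1e-9)

  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(mds_embed(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("mds_embed is deterministic including axis orientation", {
  set.seed(62)
  pts <- matrix(rnorm(40), ncol = 2)
  d <- as.matrix(dist(pts))
  a <- mds_embed(d); b <- mds_embed(d)
  expect_identical(a, b)
  for (j in 1:2) expect_gt(a[which.max(abs(a[, j])), j], 0)
})

test_that("hull vertices are the CCW extreme points", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- hull_vertices(sq)
  expect_setequal(h, 1:4)
  # counter-clockwise: positive signed area
  x <- sq[h, 1]; y <- sq[h, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y), 0)

  # points on a segment plus one off-line point give a triangle
  line <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(1, 2))
  expect_setequal(hull_vertices(line), c(1, 4, 5))

  expect_error(hull_vertices(rbind(c(0, 0), c(1, 0), c(2, 0))),
               "collinear")

  # support-function oracle: hull vertices are exactly the points that are
  # maximal in some direction
  set.seed(67)
  th <- runif(500) * 2 * pi; r <- sqrt(runif(500))
  disk <- cbind(r * cos(th), r * sin(th))
  h2 <- hull_vertices(disk)
  dirs <- seq(0, 2 * pi, length.out = 721)[-721]
  sup <- unique(vapply(dirs, function(a) {
    which.max(disk %*% c(cos(a), sin(a)))
  }, integer(1)))
  expect_setequal(h2, sup)

  # adding an interior point never changes the hull set
  h3 <- hull_vertices(rbind(disk, c(0.01, 0.02)))
  expect_setequal(h3, h2)
})

test_that("shepard statistics respond to order and rigid motion", {
  # distances 1,2,3 against embedded 3,2,1: perfect anti-correlation
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 2; d[2, 3] <- d[3, 2] <- 3
  co <- cbind(c(0, 3, 2), 0)
  sh <- shepard_stats(d, co)
  expect_equal(sh$kendall, -1)
  expect_equal(sh$spearman, -1)

  # adding a constant preserves Pearson and rank correlations
  set.seed(71)
  pts <- matrix(rnorm(20), ncol = 2)
  dd <- as.matrix(dist(pts))
  sh1 <- shepard_stats(dd + 0.5 - diag(rep(0.5, 10)), pts)
  expect_equal(sh1$pearson, 1, tolerance = 1e-9)
  expect_equal(sh1$spearman, 1, tolerance = 1e-9)

  # rigid motions of the embedding leave all statistics unchanged
  base <- shepard_stats(dd, pts)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% rot, 2, c(3, -1), "+")
  refl <- cbind(-pts[, 1], pts[, 2])
  for (coords in list(moved, refl)) {
    sh2 <- shepard_stats(dd, coords)
    expect_equal(sh2$pearson, base$pearson, tolerance = 1e-12)
    expect_equal(sh2$spearman, base$spearman, tolerance = 1e-12)
    expect_equal(sh2$kendall, base$kendall, tolerance = 1e-12)
  }
})

test_that("both interpolators reproduce data, constants and planes", {
  set.seed(73)
  co <- matrix(runif(100), ncol = 2)
  for (method in c("tps", "cubic")) {
    # constant field stays constant
    s <- interpolate_surface(co, rep(5, 50), method, grid = 25)
    expect_equal(range(s$z, na.rm = TRUE), c(5, 5), tolerance = 1e-8)
    # interpolation property at the data sites
    z <- rnorm(50)
    s2 <- interpolate_surface(co, z, method, grid = 10)
    expect_equal(s2$predict(co), z, tolerance = 1e-6)
    # affine fields are reproduced exactly
    plane <- 2 * co[, 1] - co[, 2] + 3
    s3 <- interpolate_surface(co, plane, method, grid = 20)
    grid_pts <- cbind(rep(s3$x, times = 20), rep(s3$y, each = 20))
    expect_equal(s3$predict(grid_pts),
                 2 * grid_pts[, 1] - grid_pts[, 2] + 3, tolerance = 1e-6)
  }
  # cells outside the hull are masked
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0.2, 0.2))
  sm <- interpolate_surface(tri, c(1, 2, 3, 4), "tps", grid = 30)
  expect_true(is.na(sm$z[30, 30]))  # far corner, outside the triangle
  expect_true(any(is.finite(sm$z)))
  # collinear points are rejected with advice
  lin <- cbind(0:3, 0)
  expect_error(interpolate_surface(lin, 1:4, "cubic"), "collinear")
  # coincident duplicate sites are averaged, not fatal
  dup <- rbind(co[1:10, ], co[1, ])
  expect_silent(interpolate_surface(dup, c(1:10, 3), "tps", grid = 5))
})

test_that("landscape assembly and plots expose the annotated best tree", {
  set.seed(79)
  trees <- lapply(1:15, function(i) random_tree(6, branch_pars = 0.2))
  ll <- rnorm(15, -100, 3)
  l <- tree_landscape(trees, ll, metric = "wrf", grid = 25)
  expect_equal(dim(l$coords), c(15, 2))
  expect_true(all(l$hull %in% 1:15))
  expect_equal(l$dist, t(l$dist))

  f1 <- file.path(tempdir(), "ls_contour.png")
  pl <- plot_landscape(l, "contour", file = f1,
                       annotations = list(best = 7, starting = 1:3,
                                          optimized = 10:12))
  expect_gt(file.size(f1), 1000)
  shapes <- vapply(pl$plot$layers, function(L) {
    if (!is.null(L$aes_params$shape)) L$aes_params$shape else NA_real_
  }, numeric(1))
  k <- which(shapes == 15)
  expect_length(k, 1)
  expect_identical(pl$plot$layers[[k]]$aes_params$colour, "red")
  expect_equal(unlist(pl$plot$layers[[k]]$data[1, c("x", "y")]),
               l$coords[7, ], ignore_attr = TRUE)

  f2 <- file.path(tempdir(), "ls_surface.png")
  p3 <- plot_landscape(l, "surface3d", file = f2)
  expect_identical(p3$mode, "surface3d")
  expect_gt(file.size(f2), 1000)

  expect_error(plot_landscape(list(), "contour"), "empty or invalid")

  tsv <- file.path(tempdir(), "ls.tsv")
  write_landscape_tsv(l, tsv)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 15)
  expect_equal(sum(tab$is_hull_vertex), length(l$hull))
})
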