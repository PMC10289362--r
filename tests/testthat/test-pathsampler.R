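test_that("path endpoints reproduce the input trees exactly", {
  set.seed(41)
  for (i in 1:15) {
    t1 <- random_tree(7, branch_pars = 0.2)
    t2 <- random_tree(7, branch_pars = 0.2)
    g <- geodesic(t1, t2)
    expect_equal(bhv_distance(tree_at(g, 0)$tree, t1), 0, tolerance = 1e-12)
    expect_equal(bhv_distance(tree_at(g, 1)$tree, t2), 0, tolerance = 1e-12)
  }
  expect_error(tree_at(g, 1.2), "lambda")
  expect_error(tree_at(g, -0.1), "lambda")
})

test_that("single-leg branch lengths follow the closed form", {
  # AB|CD with length a against AC|BD with length b, identical pendants:
  # before the orthant boundary at a/(a+b) the tree keeps AB|CD with
  # length (1-lam)*a - lam*b
  a <- 2; b <- 1.2
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")     # a = 2 after merge
  t2 <- parse_newick("((A:1,C:1):0.5,(B:1,D:1):0.7);") # b = 1.2
  g <- geodesic(t1, t2)
  lam <- 0.3  # below the boundary 2/3.2 = 0.625
  pt <- tree_at(g, lam)
  expect_equal(pt$orthant, 0)
  sp <- tree_splits(pt$tree)
  expect_equal(unname(sp$length[sp$split == "0011"]),
               (1 - lam) * a - lam * b, tolerance = 1e-12)
  # past the boundary the AC|BD split grows
  lam2 <- 0.8
  pt2 <- tree_at(g, lam2)
  expect_equal(pt2$orthant, 1)
  sp2 <- tree_splits(pt2$tree)
  expect_equal(unname(sp2$length[sp2$split == "0101"]),
               (lam2 * b - (1 - lam2) * a) / b * 1.2, tolerance = 1e-12)
  # at the boundary the tree is the star tree on the internal splits
  pb <- tree_at(g, a / (a + b))
  expect_equal(sum(!tree_splits(pb$tree)$trivial &
                     tree_splits(pb$tree)$length > 0), 0)
})

test_that("same-topology paths interpolate lengths linearly", {
  t1 <- parse_newick("((A:1,B:2):1.5,(C:1,D:1):1);")
  t2 <- parse_newick("((A:2,B:1):0.5,(C:3,D:1):2);")
  g <- geodesic(t1, t2)
  s1 <- stats::setNames(tree_splits(t1)$length, tree_splits(t1)$split)
  s2 <- stats::setNames(tree_splits(t2)$length, tree_splits(t2)$split)
  for (lam in c(0.25, 0.5, 0.9)) {
    sp <- tree_splits(tree_at(g, lam)$tree)
    expect_equal(unname(stats::setNames(sp$length, sp$split)[names(s1)]),
                 unname((1 - lam) * s1 + lam * s2), tolerance = 1e-12)
  }
})

test_that("BHV distances telescope along sampled paths", {
  set.seed(43)
  for (i in 1:10) {
    t1 <- random_tree(7, branch_pars = 0.2)
    t2 <- random_tree(7, branch_pars = 0.2)
    p <- sample_path(t1, t2, 4)
    chain <- c(list(t1), unclass(p), list(t2))
    tot <- sum(vapply(seq_len(length(chain) - 1), function(j) {
      bhv_distance(chain[[j]], chain[[j + 1]])
    }, numeric(1)))
    expect_equal(tot, bhv_distance(t1, t2), tolerance = 1e-8)
  }
  # interior additivity at arbitrary positions
  t1 <- random_tree(8, branch_pars = 0.2, seed = 2)
  t2 <- random_tree(8, branch_pars = 0.2, seed = 3)
  g <- geodesic(t1, t2)
  lams <- sort(runif(3))
  p <- lapply(lams, function(l) tree_at(g, l)$tree)
  expect_equal(bhv_distance(p[[1]], p[[2]]) + bhv_distance(p[[2]], p[[3]]),
               bhv_distance(p[[1]], p[[3]]), tolerance = 1e-8)
})

test_that("pathtree splits stay within the endpoint split union", {
  set.seed(47)
  for (i in 1:10) {
    t1 <- random_tree(7, branch_pars = 0.2)
    t2 <- random_tree(7, branch_pars = 0.2)
    u <- union(tree_splits(t1)$split, tree_splits(t2)$split)
    common <- intersect(tree_splits(t1)$split, tree_splits(t2)$split)
    g <- geodesic(t1, t2)
    for (lam in c(0.2, 0.5, 0.8)) {
      sp <- tree_splits(tree_at(g, lam)$tree)
      present <- sp$split[sp$length > 0]
      expect_true(all(present %in% u))
      expect_true(all(common %in% sp$split))
      expect_true(all(sp$length >= 0))
    }
  }
})

test_that("pathtree counts follow m * s * (s-1) / 2", {
  set.seed(53)
  cloud <- lapply(1:5, function(i) random_tree(5, branch_pars = 0.2))
  pt <- all_pairs_pathtrees(cloud, 3)
  expect_length(pt$trees, 3 * 5 * 4 / 2)
  expect_equal(nrow(pt$info), length(pt$trees))
  expect_true(all(pt$info$lambda > 0 & pt$info$lambda < 1))
  # m = 1 gives the midpoint only
  p1 <- sample_path(cloud[[1]], cloud[[2]], 1)
  expect_length(p1, 1)
  expect_equal(attr(p1, "info")$lambda, 0.5)
  # two starting trees, m = 4
  p2 <- all_pairs_pathtrees(cloud[1:2], 4)
  expect_length(p2$trees, 4)
})

test_that("pathtree sidecar files round-trip", {
  set.seed(59)
  cloud <- lapply(1:3, function(i) random_tree(5, branch_pars = 0.2))
  pt <- all_pairs_pathtrees(cloud, 2)
  stem <- file.path(tempdir(), "pt_test")
  write_pathtrees(pt, stem)
  trees <- read_newick_file(paste0(stem, ".nwk"))
  expect_length(trees, length(pt$trees))
  info <- utils::read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(info), length(pt$trees))
  expect_identical(colnames(info), c("pair_id", "lambda", "topology"))
})
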