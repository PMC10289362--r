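test_that("RF distance counts the symmetric split difference", {
  a <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  b <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(a, a), 0)
  expect_equal(rf_distance(a, b), 2)

  # 6-leaf pair differing by one NNI across the ABCD|EF edge: exchanges
  # the (C,D) clade with E, replacing split ABCD by ABE
  t1 <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  t2 <- parse_newick("(((A:1,B:1):1,E:1):1,((C:1,D:1):1,F:1):1);")
  expect_equal(rf_distance(t1, t2), 2)

  expect_error(rf_distance(a, parse_newick("((A:1,B:1):1,(C:1,X:1):1);")),
               "different leaf sets")
})

test_that("RF and wRF agree with the independent phangorn implementations", {
  set.seed(31)
  for (i in 1:30) {
    t1 <- random_tree(8, branch_pars = 0.2)
    t2 <- random_tree(8, branch_pars = 0.2)
    expect_equal(rf_distance(t1, t2), c(phangorn::RF.dist(t1, t2)))
    expect_equal(wrf_distance(t1, t2), c(phangorn::wRF.dist(t1, t2)),
                 tolerance = 1e-12)
  }
})

test_that("wRF sums absolute weight differences over the split union", {
  a <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(wrf_distance(a, a), 0)
  b <- parse_newick("((A:1,B:1):1.3,(C:1,D:1):1);")
  expect_equal(wrf_distance(a, b), 0.3)
  # disjoint internal splits contribute their full lengths
  c2 <- parse_newick("((A:1,C:1):0.5,(B:1,D:1):0.7);")
  expect_equal(wrf_distance(a, c2), 2 + 1.2)
  # pendant differences count too
  d2 <- parse_newick("((A:2,B:1):1,(C:1,D:1):1);")
  expect_equal(wrf_distance(a, d2), 1)
})

test_that("incompatibility graph marks exactly the conflicting pairs", {
  ab_cd <- "0011"  # side {C,D} of AB|CD (taxa A,B,C,D)
  ac_bd <- "0101"  # side {B,D} of AC|BD
  g <- incompatibility_graph(ab_cd, ac_bd)
  expect_equal(nrow(g$edges), 1)

  # AB|CDE vs ABC|DE on 5 leaves are compatible (nested)
  g2 <- incompatibility_graph("00111", "00011")
  expect_equal(nrow(g2$edges), 0)

  # pendants are compatible with everything
  g3 <- incompatibility_graph("00010", c("00111", "00011", "01010"))
  expect_equal(nrow(g3$edges), 0)
})

test_that("geodesic handles identity, shared-topology and cone cases", {
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  g0 <- geodesic(t1, t1)
  expect_equal(g0$k, 0)
  expect_equal(g0$length, 0)

  # same topology: single orthant, Euclidean over all splits
  t2 <- parse_newick("((A:1,B:2):1.5,(C:1,D:1):1);")
  g1 <- geodesic(t1, t2)
  expect_equal(g1$k, 0)
  expect_equal(g1$length, sqrt(1^2 + 0.5^2))

  # one incompatible pair: the cone path is the geodesic, length a + b
  t3 <- parse_newick("((A:1,C:1):0.5,(B:1,D:1):0.7);")
  g2 <- geodesic(t1, t3)
  expect_equal(g2$k, 1)
  expect_equal(g2$length, 2 + 1.2)
  expect_equal(bhv_distance(t1, t3), 3.2)
})

test_that("GTP geodesic length matches the brute-force support oracle", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    t1 <- random_tree(n, branch_pars = 0.3)
    t2 <- random_tree(n, branch_pars = 0.3)
    expect_equal(bhv_distance(t1, t2), oracle_bhv(t1, t2),
                 tolerance = 1e-9)
  }
})

test_that("geodesic supports satisfy ratio ordering and orthant validity", {
  set.seed(13)
  for (i in 1:20) {
    t1 <- random_tree(8, branch_pars = 0.2)
    t2 <- random_tree(8, branch_pars = 0.2)
    g <- geodesic(t1, t2)
    if (g$k < 1) next
    ratios <- vapply(g$legs, `[[`, numeric(1), "ratio")
    expect_true(all(diff(ratios) >= -1e-12))
    # every intermediate orthant's split set is pairwise compatible
    for (i_orth in 0:g$k) {
      keys <- g$common$split
      for (j in seq_len(g$k)) {
        keys <- c(keys, names(if (j <= i_orth) g$legs[[j]]$B
                              else g$legs[[j]]$A))
      }
      nk <- length(keys)
      for (p in seq_len(nk - 1)) {
        for (q in seq(p + 1, nk)) {
          expect_true(pathscape:::splits_compatible(keys[p], keys[q]))
        }
      }
    }
  }
})

test_that("BHV and wRF are symmetric metrics bounded by the cone path", {
  set.seed(19)
  for (i in 1:12) {
    trees <- lapply(1:3, function(j) random_tree(8, branch_pars = 0.2))
    d_b <- outer(1:3, 1:3, Vectorize(function(a, b) {
      if (a == b) 0 else bhv_distance(trees[[a]], trees[[b]])
    }))
    d_w <- outer(1:3, 1:3, Vectorize(function(a, b) {
      if (a == b) 0 else wrf_distance(trees[[a]], trees[[b]])
    }))
    expect_equal(d_b, t(d_b))
    expect_equal(d_w, t(d_w))
    # triangle inequality
    for (p in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))) {
      expect_lte(d_b[p[1], p[2]],
                 d_b[p[1], p[3]] + d_b[p[3], p[2]] + 1e-9)
      expect_lte(d_w[p[1], p[2]],
                 d_w[p[1], p[3]] + d_w[p[3], p[2]] + 1e-9)
    }
    # BHV <= wRF, and BHV <= cone path with equality when k = 1
    g <- geodesic(trees[[1]], trees[[2]])
    normA <- sqrt(sum(vapply(g$legs, function(l) l$normA^2, numeric(1))))
    normB <- sqrt(sum(vapply(g$legs, function(l) l$normB^2, numeric(1))))
    cone <- sqrt((normA + normB)^2 + sum((g$common$len1 - g$common$len2)^2))
    expect_lte(d_b[1, 2], d_w[1, 2] + 1e-12)
    expect_lte(g$length, cone + 1e-12)
    if (g$k == 1) expect_equal(g$length, cone, tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric with zero diagonal and round-trip as TSV", {
  set.seed(23)
  trees <- lapply(1:5, function(i) random_tree(6, branch_pars = 0.2))
  d <- tree_dist_matrix(trees, "wrf")
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 5), ignore_attr = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  write_dist_tsv(d, tmp)
  back <- as.matrix(utils::read.table(tmp, header = TRUE, sep = "\t"))
  expect_equal(unname(back), unname(d), tolerance = 1e-10)
})
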