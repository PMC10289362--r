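# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

rand_pair <- function(n_leaves, seed, mean_len = 0.1) {
  set.seed(seed)
  list(random_tree(n_leaves, branch_pars = mean_len),
       random_tree(n_leaves, branch_pars = mean_len))
}

# a small alignment/tree-sample fixture reused by pipeline tests
pipeline_fixture <- function(seed = 42, n_leaves = 6, n_sites = 300,
                             n_trees = 15, moves = 2, jitter_sd = 0.2) {
  set.seed(seed)
  tree <- random_tree(n_leaves, branch_pars = 0.15)
  cloud <- perturb_cloud(tree, n_trees, moves = moves, jitter_sd = jitter_sd)
  aln <- simulate_alignment(tree, n_sites)
  list(tree = tree, cloud = cloud, aln = aln)
}

# fixed 6-leaf tree for branch-length recovery checks. Lengths 0.1-0.5
# substitutions/site: every edge carries enough information at 10^5 sites
# that sampling noise sits well inside the 5% recovery band (edges near
# saturation inflate the variance of adjacent internal-edge estimates).
recovery_tree <- function() {
  parse_newick(
    "((A:0.1,B:0.25):0.2,((C:0.15,D:0.35):0.3,(E:0.2,F:0.5):0.4):0.25);")
}

expect_same_splits <- function(a, b, tol = 1e-12) {
  sa <- tree_splits(a); sb <- tree_splits(b)
  testthat::expect_identical(sa$split, sb$split)
  testthat::expect_lt(max(abs(sa$length - sb$length)), tol)
}
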