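#' Random rooted tree by sequential attachment
#'
#' Grows a rooted binary topology by attaching each new leaf to a uniformly
#' chosen position (any existing edge, or above the current root), which
#' yields the uniform distribution over rooted binary labeled topologies.
#' Branch lengths are drawn i.i.d. from an exponential or uniform
#' distribution.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param branch_dist `"exponential"` or `"uniform"`.
#' @param branch_pars distribution parameters: the mean for exponential
#'   (default 0.1), or `c(lo, hi)` for uniform.
#' @param labels taxon names; default `t01, t02, ...` (zero-padded so that
#'   lexicographic and numeric order agree).
#' @param seed optional integer seed for reproducibility.
#' @return a `phylo` object.
#' @export
random_tree <- function(n_leaves, branch_dist = c("exponential", "uniform"),
                        branch_pars = 0.1, labels = NULL, seed = NULL) {
  branch_dist <- match.arg(branch_dist)
  stopifnot(n_leaves >= 3)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) {
    labels <- paste0("t", formatC(seq_len(n_leaves),
                                  width = nchar(n_leaves), flag = "0"))
  }
  stopifnot(length(labels) == n_leaves, !anyDuplicated(labels))
  nid <- n_leaves + 1L
  root <- nid
  edges <- matrix(c(root, 1L, root, 2L), ncol = 2, byrow = TRUE)
  for (k in seq(3L, n_leaves)) {
    choice <- sample.int(nrow(edges) + 1L, 1L)
    if (choice > nrow(edges)) {
      nid <- nid + 1L
      edges <- rbind(edges, c(nid, root), c(nid, k))
      root <- nid
    } else {
      p <- edges[choice, 1]; ch <- edges[choice, 2]
      nid <- nid + 1L
      edges[choice, ] <- c(p, nid)
      edges <- rbind(edges, c(nid, ch), c(nid, k))
    }
  }
  ne <- nrow(edges)
  len <- switch(branch_dist,
    exponential = stats::rexp(ne, rate = 1 / branch_pars[1]),
    uniform = stats::runif(ne, branch_pars[1], branch_pars[2]))
  elen <- numeric(max(edges))
  elen[edges[, 2]] <- len
  children <- split(edges[, 2], edges[, 1])
  emit <- function(v) {
    if (v <= n_leaves) return(sprintf("%s:%.15g", labels[v], elen[v]))
    body <- paste(vapply(children[[as.character(v)]], emit, character(1)),
                  collapse = ",")
    if (v == root) sprintf("(%s);", body) else sprintf("(%s):%.15g", body,
                                                       elen[v])
  }
  parse_newick(emit(root))
}

#' Cloud of NNI-perturbed trees around a base tree
#'
#' Emulates a local sample of treespace (such as the cloud of trees from an
#' MCMC run): `n_trees` trees are returned, the first being the base tree
#' itself and each subsequent one an independently perturbed copy receiving
#' `moves` random nearest-neighbor-interchange moves and multiplicative
#' log-normal branch-length jitter.
#'
#' @param base a `phylo` object.
#' @param n_trees total number of trees returned (base included).
#' @param moves NNI moves applied to each perturbed copy.
#' @param jitter_sd standard deviation of the log-normal length jitter
#'   (0 disables jitter).
#' @param seed optional integer seed.
#' @return a `multiPhylo` list of `n_trees` trees.
#' @export
perturb_cloud <- function(base, n_trees, moves = 1, jitter_sd = 0.1,
                          seed = NULL) {
  stopifnot(inherits(base, "phylo"), n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_trees)
  out[[1]] <- base
  for (i in seq_len(n_trees - 1L)) {
    tr <- base
    if (moves > 0) tr <- phangorn::rNNI(tr, moves = moves)
    if (jitter_sd > 0) {
      tr$edge.length <- tr$edge.length *
        exp(stats::rnorm(length(tr$edge.length), 0, jitter_sd))
    }
    out[[i + 1L]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

#' Simulate a DNA alignment under JC69
#'
#' Forward simulation on a tree: root states are i.i.d. uniform over
#' `{A, C, G, T}` and child states are drawn from the JC69 transition
#' matrix of each edge ([jc69_transition()]).
#'
#' @param tree a `phylo` object with branch lengths.
#' @param n_sites number of sites.
#' @param seed optional integer seed.
#' @return a [dna_alignment()].
#' @export
simulate_alignment <- function(tree, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  po <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    pm <- jc69_transition(po$edge.length[e])
    s <- states[p, ]
    child <- integer(n_sites)
    for (st in 1:4) {
      idx <- which(s == st)
      if (length(idx)) {
        child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = pm[st, ])
      }
    }
    states[ch, ] <- child
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                function(r) paste(bases[r], collapse = ""))
  dna_alignment(tree$tip.label, seqs)
}

#' Write a self-contained simulated fixture
#'
#' Generates a random generating tree, a perturbation cloud emulating an
#' MCMC tree sample, and a JC69 alignment simulated on the generating tree;
#' writes `aln.phy`, `sample.nwk` and `truth.json` (generating tree and all
#' simulation parameters) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param n_leaves,n_sites,n_trees fixture dimensions.
#' @param moves,jitter_sd perturbation parameters, see [perturb_cloud()].
#' @param branch_dist,branch_pars branch-length model, see [random_tree()].
#' @param seed integer seed controlling every random draw.
#' @return invisibly, a list with the generating `tree`, the `sample` of
#'   trees and the alignment `aln`.
#' @export
simulate_fixture <- function(dir, n_leaves = 8, n_sites = 1000, n_trees = 50,
                             moves = 1, jitter_sd = 0.1,
                             branch_dist = "exponential", branch_pars = 0.1,
                             seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tree <- random_tree(n_leaves, branch_dist, branch_pars)
  cloud <- perturb_cloud(tree, n_trees, moves, jitter_sd)
  aln <- simulate_alignment(tree, n_sites)
  write_phylip(aln, file.path(dir, "aln.phy"))
  write_newick_file(cloud, file.path(dir, "sample.nwk"))
  jsonlite::write_json(
    list(generating_tree = write_newick(tree), n_leaves = n_leaves,
         n_sites = n_sites, n_trees = n_trees, moves = moves,
         jitter_sd = jitter_sd, branch_dist = branch_dist,
         branch_pars = branch_pars, seed = seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, sample = cloud, aln = aln))
}
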