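#' JC69 transition probability matrix
#'
#' Closed form for the Jukes-Cantor model: diagonal entries
#' \eqn{1/4 + 3/4\, e^{-4t/3}}, off-diagonal \eqn{1/4 - 1/4\, e^{-4t/3}},
#' where `t` is the branch length in expected substitutions per site.
#'
#' @param t branch length, `>= 0`.
#' @return a 4x4 row-stochastic matrix (states in order A, C, G, T).
#' @export
jc69_transition <- function(t) {
  if (!is.finite(t) && !identical(t, Inf)) stop("branch length must be >= 0")
  if (t < 0) stop("branch length must be >= 0, got ", t)
  e <- exp(-4 * t / 3)
  p_same <- 0.25 + 0.75 * e
  p_diff <- 0.25 - 0.25 * e
  m <- matrix(p_diff, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- p_same
  m
}

# Precomputed pruning context: postorder edge list and tip partials. The
# tree's topology and tip/alignment pairing are fixed; only edge lengths
# vary between evaluations (used heavily by the branch-length optimizer).
make_prune_ctx <- function(tree, patterns) {
  ntip <- length(tree$tip.label)
  npat <- ncol(patterns)
  miss <- is.na(match(tree$tip.label, rownames(patterns)))
  if (any(miss)) {
    stop("taxa missing from alignment: ",
         paste(tree$tip.label[miss], collapse = ", "))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  codes <- patterns[match(tree$tip.label, rownames(patterns)), , drop = FALSE]
  tip_part <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    m <- matrix(0, 4, npat)
    k <- codes[i, ]
    obs <- !is.na(k)
    m[cbind(k[obs], which(obs))] <- 1
    m[, !obs] <- 1     # gaps/ambiguity: fully missing
    tip_part[[i]] <- m
  }
  list(po = po, ntip = ntip, npat = npat,
       nnode = ntip + tree$Nnode, tip_part = tip_part)
}

# Felsenstein pruning under JC69 with uniform base frequencies, over the
# compressed patterns of a prune context. `lengths` are edge lengths in the
# context's postorder edge order. Partial likelihoods are rescaled per
# pattern whenever they threaten to underflow. Returns per-pattern
# log-likelihoods.
prune_ctx_ll <- function(ctx, lengths) {
  part <- vector("list", ctx$nnode)
  part[seq_len(ctx$ntip)] <- ctx$tip_part
  scl <- numeric(ctx$npat)       # shared log-scale accumulator (root-bound)
  edge <- ctx$po$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    pm <- jc69_transition(lengths[e])
    contrib <- pm %*% part[[ch]]
    part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
    mx <- pmax(part[[p]][1, ], part[[p]][2, ], part[[p]][3, ],
               part[[p]][4, ])
    if (min(mx) < 1e-120) {
      mx[mx <= 0] <- 1
      part[[p]] <- part[[p]] / rep(mx, each = 4L)
      scl <- scl + log(mx)
    }
  }
  root <- ctx$ntip + 1L
  log(colSums(0.25 * part[[root]])) + scl
}

prune_patterns <- function(tree, patterns, weights) {
  ctx <- make_prune_ctx(tree, patterns)
  prune_ctx_ll(ctx, ctx$po$edge.length)
}

#' JC69 log-likelihood of a tree
#'
#' Felsenstein's pruning algorithm over compressed site patterns, with
#' equilibrium base frequencies of 1/4, independent sites, and gaps or
#' ambiguity codes treated as missing data. The model is reversible, so the
#' result does not depend on root placement. Natural logarithms throughout;
#' no multinomial pattern constant is added, matching the convention of
#' standard ML phylogenetics programs.
#'
#' @param tree a `phylo` object whose leaf labels are contained in the
#'   alignment's taxa.
#' @param aln a [dna_alignment()].
#' @return an object of class `phylo_loglik`: list with `loglik` (total),
#'   `per_pattern` (log-likelihood per distinct site pattern) and `tree`.
#' @export
log_likelihood <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "dna_alignment"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  pp <- prune_patterns(tree, aln$patterns, aln$weights)
  structure(list(loglik = sum(aln$weights * pp), per_pattern = pp,
                 tree = tree),
            class = "phylo_loglik")
}

#' @export
print.phylo_loglik <- function(x, ...) {
  cat("JC69 log likelihood:", format(x$loglik, digits = 10), "\n")
  invisible(x)
}

#' Optimize branch lengths for a fixed topology
#'
#' Coordinate-wise maximization of the JC69 log-likelihood: each edge in
#' turn is optimized by Brent's method on `[min_len, max_len]` holding the
#' others fixed, sweeping all edges until the improvement over a full sweep
#' drops below `tol` or `max_sweeps` is reached. The topology is never
#' changed; multifurcating topologies are optimized as-is. The trace of
#' sweep log-likelihoods is non-decreasing by construction (a proposed edge
#' length is only accepted if it improves the likelihood).
#'
#' @param tree a `phylo` object (the starting tree; its branch lengths are
#'   the initial values).
#' @param aln a [dna_alignment()].
#' @param max_sweeps maximum number of passes over all edges.
#' @param tol convergence tolerance in log-likelihood units per sweep.
#' @param min_len,max_len search bounds for each branch length
#'   (substitutions/site).
#' @return a `phylo_loglik` with additional elements `n_sweeps` and `trace`
#'   (log-likelihood after each sweep).
#' @export
optimize_branch_lengths <- function(tree, aln, max_sweeps = 50, tol = 1e-6,
                                    min_len = 1e-8, max_len = 10) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "dna_alignment"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree <- ape::reorder.phylo(tree, "postorder")
  tree$edge.length[tree$edge.length < min_len] <- min_len
  ctx <- make_prune_ctx(tree, aln$patterns)
  lens <- tree$edge.length
  ll <- function(v) sum(aln$weights * prune_ctx_ll(ctx, v))
  cur <- ll(lens)
  if (!is.finite(cur)) stop("non-finite log-likelihood for starting tree")
  trace <- numeric(0)
  for (sweep in seq_along(integer(max_sweeps))) {
    before <- cur
    for (e in seq_along(lens)) {
      f <- function(x) { v <- lens; v[e] <- x; ll(v) }
      opt <- stats::optimize(f, c(min_len, max_len), maximum = TRUE,
                             tol = 1e-6)
      cand_x <- opt$maximum; cand_y <- opt$objective
      lo <- f(min_len)   # Brent never probes the boundary itself
      if (lo > cand_y) { cand_x <- min_len; cand_y <- lo }
      if (cand_y > cur) {
        lens[e] <- cand_x
        cur <- cand_y
      }
    }
    trace <- c(trace, cur)
    if (cur - before < tol) break
  }
  tree$edge.length <- lens
  res <- log_likelihood(tree, aln)
  res$n_sweeps <- length(trace)
  res$trace <- trace
  res
}
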