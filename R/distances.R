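#' Tree distances and BHV geodesics
#'
#' @name distances
#' @keywords internal
NULL

check_same_leaves <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    only1 <- setdiff(a, b); only2 <- setdiff(b, a)
    stop("trees have different leaf sets;",
         if (length(only1)) paste0(" only in tree 1: ",
                                   paste(only1, collapse = ", ")) else "",
         if (length(only2)) paste0(" only in tree 2: ",
                                   paste(only2, collapse = ", ")) else "")
  }
  invisible(a)
}

#' Unweighted Robinson-Foulds distance
#'
#' The number of nontrivial splits present in one tree but not the other
#' (size of the symmetric difference of the split sets).
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  a <- s1$split[!s1$trivial]; b <- s2$split[!s2$trivial]
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Weighted Robinson-Foulds distance
#'
#' The L1 distance over the union of all weighted splits of the two trees,
#' pendant splits included; a split absent from one tree contributes its
#' full length in the other.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return a non-negative real.
#' @export
wrf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  keys <- union(s1$split, s2$split)
  l1 <- stats::setNames(s1$length, s1$split)[keys]
  l2 <- stats::setNames(s2$length, s2$split)[keys]
  l1[is.na(l1)] <- 0; l2[is.na(l2)] <- 0
  sum(abs(l1 - l2))
}

# logical incompatibility matrix between two sets of canonical split
# encodings (rows = A, cols = B); TRUE where the splits cannot coexist
incompat_matrix <- function(A, B, n) {
  ma <- matrix(vapply(A, split_members, logical(n)), nrow = n)
  mb <- matrix(vapply(B, split_members, logical(n)), nrow = n)
  out <- matrix(FALSE, length(A), length(B),
                dimnames = list(A, B))
  for (i in seq_along(A)) {
    a <- ma[, i]
    for (j in seq_along(B)) {
      b <- mb[, j]
      out[i, j] <- any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b)
    }
  }
  out
}

#' Bipartite incompatibility graph between two split sets
#'
#' Edge (a, b) is present iff splits a and b are incompatible, i.e. all four
#' intersection cells of the two bipartitions are non-empty. Pendant splits
#' are compatible with everything.
#'
#' @param A,B character vectors of canonical split encodings (as produced by
#'   [tree_splits()]) over the same taxon set.
#' @return a list with elements `a`, `b` (the node labels) and `edges`
#'   (two-column integer matrix of indices into `a` and `b`).
#' @export
incompatibility_graph <- function(A, B) {
  n <- if (length(A)) nchar(A[1]) else if (length(B)) nchar(B[1]) else 0L
  inc <- incompat_matrix(A, B, n)
  idx <- which(inc, arr.ind = TRUE)
  list(a = A, b = B,
       edges = matrix(as.integer(idx), ncol = 2,
                      dimnames = list(NULL, c("a", "b"))))
}

# Minimum-weight vertex cover of a bipartite incompatibility graph via the
# standard max-flow construction (source -> A with capacity wa, B -> sink
# with capacity wb, incompatibility edges with infinite capacity). Returns
# list(weight, coverA, coverB) with indices into A/B.
min_vertex_cover <- function(wa, wb, edges) {
  na <- length(wa); nb <- length(wb)
  src <- 1L; a_ids <- 1L + seq_len(na); b_ids <- 1L + na + seq_len(nb)
  snk <- 2L + na + nb
  inf <- sum(wa) + sum(wb) + 1
  el <- rbind(cbind(src, a_ids),
              cbind(a_ids[edges[, 1]], b_ids[edges[, 2]]),
              cbind(b_ids, snk))
  caps <- c(wa, rep(inf, nrow(edges)), wb)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  mf <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  p1 <- as.integer(mf$partition1)  # source side of the min cut
  list(weight = mf$value,
       coverA = which(!(a_ids %in% p1)),
       coverB = which(b_ids %in% p1))
}

# One refinement test of the GTP algorithm: given a leg (A, B) with T1/T2
# lengths la, lb and the incompatibility matrix over the component, look for
# a vertex cover of normalized squared weight < 1. Returns NULL if the leg
# satisfies the geodesic condition, otherwise the two replacement legs in
# path order.
try_split_leg <- function(A, B, la, lb, inc) {
  wa <- la[A]^2 / sum(la[A]^2)
  wb <- lb[B]^2 / sum(lb[B]^2)
  sub <- inc[A, B, drop = FALSE]
  edges <- which(sub, arr.ind = TRUE)
  vc <- min_vertex_cover(unname(wa), unname(wb), edges)
  if (vc$weight >= 1 - 1e-12) return(NULL)
  C1 <- A[vc$coverA]; C2 <- B[vc$coverB]
  list(list(A = C1, B = setdiff(B, C2)),
       list(A = setdiff(A, C1), B = C2))
}

#' BHV geodesic between two trees (GTP algorithm)
#'
#' Computes the unique Billera-Holmes-Vogtmann geodesic by successive path
#' refinement. Splits shared by both trees (always including pendants, and
#' any split of one tree compatible with every split of the other, which is
#' carried as a shared coordinate shrinking to length 0) interpolate
#' linearly; the remaining tree-exclusive splits are partitioned into
#' ordered support legs \eqn{(A_i, B_i)} by repeatedly solving a
#' minimum-weight vertex cover on the bipartite incompatibility graph of
#' each leg, splitting the leg whenever a cover of normalized weight < 1
#' exists. Tree-exclusive splits of length `<= tol` are contracted first.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @param tol contraction tolerance for zero-length tree-exclusive splits.
#' @return an object of class `tree_geodesic`: list with `taxa`, `common`
#'   (data.frame: split, len1, len2), `legs` (each with named length vectors
#'   `A` (T1 lengths), `B` (T2 lengths), norms `normA`, `normB`, `ratio`),
#'   `k` (number of legs) and `length` (the BHV distance).
#' @export
geodesic <- function(t1, t2, tol = 1e-9) {
  taxa <- check_same_leaves(t1, t2)
  n <- length(taxa)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  l1 <- stats::setNames(s1$length, s1$split)
  l2 <- stats::setNames(s2$length, s2$split)
  common <- intersect(s1$split, s2$split)
  A0 <- setdiff(s1$split, s2$split)
  B0 <- setdiff(s2$split, s1$split)
  A0 <- A0[l1[A0] > tol]           # contract zero-length exclusive splits
  B0 <- B0[l2[B0] > tol]
  A0 <- sort(A0); B0 <- sort(B0)   # lexicographic order: deterministic
  inc <- incompat_matrix(A0, B0, n)
  # splits compatible with everything in the other tree act as shared
  # coordinates with length 0 on the other side
  a_free <- if (length(A0)) rowSums(inc) == 0 else logical(0)
  b_free <- if (length(B0)) colSums(inc) == 0 else logical(0)
  com <- data.frame(split = c(common, A0[a_free], B0[b_free]),
                    stringsAsFactors = FALSE)
  com$len1 <- ifelse(is.na(l1[com$split]), 0, l1[com$split])
  com$len2 <- ifelse(is.na(l2[com$split]), 0, l2[com$split])
  com <- com[order(com$split), , drop = FALSE]
  rownames(com) <- NULL
  A0 <- A0[!a_free]; B0 <- B0[!b_free]
  inc <- inc[!a_free, !b_free, drop = FALSE]

  legs <- list()
  if (length(A0)) {
    # independent subproblems = connected components of the incompatibility
    # graph (incompatible pairs never straddle a common split)
    memb <- local({
      nA <- length(A0); nB <- length(B0)
      g <- igraph::graph_from_edgelist(
        cbind(which(inc, arr.ind = TRUE)[, 1],
              nA + which(inc, arr.ind = TRUE)[, 2]), directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, nA + nB - igraph::vcount(g)))
      igraph::components(g)$membership
    })
    nA <- length(A0)
    for (comp in sort(unique(memb))) {
      Ac <- A0[memb[seq_len(nA)] == comp]
      Bc <- B0[memb[nA + seq_along(B0)] == comp]
      queue <- list(list(A = Ac, B = Bc))
      while (length(queue)) {
        leg <- queue[[1]]; queue <- queue[-1]
        res <- try_split_leg(leg$A, leg$B, l1, l2, inc)
        if (is.null(res)) legs <- c(legs, list(leg)) else queue <- c(res, queue)
      }
    }
  }
  legs <- lapply(legs, function(lg) {
    A <- sort(lg$A); B <- sort(lg$B)
    normA <- sqrt(sum(l1[A]^2)); normB <- sqrt(sum(l2[B]^2))
    list(A = l1[A], B = l2[B], normA = normA, normB = normB,
         ratio = normA / normB)
  })
  if (length(legs) > 1) {
    ord <- order(vapply(legs, `[[`, numeric(1), "ratio"),
                 vapply(legs, function(lg) names(lg$A)[1], character(1)))
    legs <- legs[ord]
  }
  leg_term <- sum(vapply(legs, function(lg) (lg$normA + lg$normB)^2,
                         numeric(1)))
  len <- sqrt(leg_term + sum((com$len1 - com$len2)^2))
  structure(list(taxa = taxa, t1 = t1, t2 = t2, common = com, legs = legs,
                 k = length(legs), length = len),
            class = "tree_geodesic")
}

#' @export
print.tree_geodesic <- function(x, ...) {
  cat("BHV geodesic: length", format(x$length, digits = 8), "with",
      x$k, "support legs and", nrow(x$common), "shared splits\n")
  invisible(x)
}

#' BHV distance between two trees
#'
#' The length of the BHV geodesic, see [geodesic()].
#'
#' @inheritParams geodesic
#' @return a non-negative real.
#' @export
bhv_distance <- function(t1, t2, tol = 1e-9) geodesic(t1, t2, tol)$length

#' Pairwise distance matrix for a set of trees
#'
#' @param trees a list of `phylo` objects on a common leaf set.
#' @param metric `"bhv"`, `"wrf"` or `"rf"`.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
tree_dist_matrix <- function(trees, metric = c("bhv", "wrf", "rf")) {
  metric <- match.arg(metric)
  fn <- switch(metric, bhv = bhv_distance, wrf = wrf_distance,
               rf = function(a, b) as.numeric(rf_distance(a, b)))
  s <- length(trees)
  d <- matrix(0, s, s)
  if (s > 1) {
    for (i in seq_len(s - 1)) {
      for (j in seq(i + 1, s)) {
        d[i, j] <- d[j, i] <- fn(trees[[i]], trees[[j]])
      }
    }
  }
  dimnames(d) <- list(seq_len(s), seq_len(s))
  d
}

#' Write a distance matrix as TSV
#'
#' Header row of tree indices; symmetric with zero diagonal.
#'
#' @param d a square matrix.
#' @param path output path.
#' @export
write_dist_tsv <- function(d, path) {
  utils::write.table(format(d, digits = 12, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
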