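# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the BHV oracle enumerates every valid ordered support
# partition and minimizes the path-length formula directly; the likelihood
# oracle marginalizes ancestral states exhaustively with transition matrices
# obtained from the rate matrix exponential.

# all ordered partitions of `items` into exactly k non-empty blocks
ordered_partitions <- function(items, k) {
  n <- length(items)
  if (k > n) return(list())
  if (k == 1) return(list(list(items)))
  asn <- expand.grid(rep(list(seq_len(k)), n))
  out <- list()
  for (r in seq_len(nrow(asn))) {
    a <- as.integer(asn[r, ])
    if (length(unique(a)) == k) {
      out[[length(out) + 1L]] <- lapply(seq_len(k), function(b) items[a == b])
    }
  }
  out
}

# brute-force BHV distance: min over all valid ordered supports
oracle_bhv <- function(t1, t2, tol = 1e-9) {
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  l1 <- stats::setNames(s1$length, s1$split)
  l2 <- stats::setNames(s2$length, s2$split)
  common <- intersect(s1$split, s2$split)
  A0 <- setdiff(s1$split, s2$split); A0 <- A0[l1[A0] > tol]
  B0 <- setdiff(s2$split, s1$split); B0 <- B0[l2[B0] > tol]
  compat <- function(a, b) pathscape:::splits_compatible(a, b)
  # splits compatible with every split of the other tree behave as shared
  # coordinates that shrink linearly to zero
  a_free <- vapply(A0, function(a) all(vapply(B0, compat, logical(1), a)),
                   logical(1))
  b_free <- vapply(B0, function(b) all(vapply(A0, compat, logical(1), b)),
                   logical(1))
  com_term <- sum((l1[common] - l2[common])^2) +
    sum(l1[A0[a_free]]^2) + sum(l2[B0[b_free]]^2)
  A0 <- A0[!a_free]; B0 <- B0[!b_free]
  if (!length(A0) && !length(B0)) return(sqrt(com_term))
  if (!length(A0) || !length(B0)) stop("unbalanced pools")  # cannot happen
  best <- Inf
  for (k in seq_len(min(length(A0), length(B0)))) {
    pas <- ordered_partitions(A0, k)
    pbs <- ordered_partitions(B0, k)
    for (pa in pas) {
      for (pb in pbs) {
        valid <- TRUE
        for (l in seq_len(k - 1)) {
          for (j in seq(l + 1, k)) {
            for (b in pb[[l]]) {
              for (a in pa[[j]]) {
                if (!compat(a, b)) { valid <- FALSE; break }
              }
              if (!valid) break
            }
            if (!valid) break
          }
          if (!valid) break
        }
        if (!valid) next
        na <- vapply(pa, function(s) sqrt(sum(l1[s]^2)), numeric(1))
        nb <- vapply(pb, function(s) sqrt(sum(l2[s]^2)), numeric(1))
        # only supports with non-decreasing ||A_i||/||B_i|| correspond to
        # realizable paths
        r <- na / nb
        if (k > 1 && any(diff(r) < -1e-12)) next
        val <- sum((na + nb)^2)
        if (val < best) best <- val
      }
    }
  }
  sqrt(best + com_term)
}

# exhaustive JC69 likelihood: sum over all ancestral state assignments,
# transition matrices from expm of the JC69 rate matrix
oracle_loglik <- function(tree, aln) {
  Q <- matrix(1 / 3, 4, 4); diag(Q) <- -1
  pmat <- function(t) as.matrix(Matrix::expm(Q * t))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- seq.int(ntip + 1L, nnode)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) pmat(tree$edge.length[e]))
  codes <- aln$patterns[match(tree$tip.label, rownames(aln$patterns)), ,
                        drop = FALSE]
  npat <- ncol(codes)
  per_pattern <- numeric(npat)
  grids <- expand.grid(rep(list(1:4), length(internal)))
  for (s in seq_len(npat)) {
    tot <- 0
    for (r in seq_len(nrow(grids))) {
      st <- integer(nnode)
      st[internal] <- as.integer(grids[r, ])
      st[seq_len(ntip)] <- codes[, s]
      pr <- 0.25  # root prior
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        if (ch <= ntip && is.na(st[ch])) next  # missing data: marginalized
        pr <- pr * P[[e]][st[p], st[ch]]
      }
      # missing tips: sum over their states = 1, so skipping the factor is
      # exact (rows of P sum to 1)
      tot <- tot + pr
    }
    per_pattern[s] <- log(tot)
  }
  sum(aln$weights * per_pattern)
}

# JC69 expected fraction of differing sites between two sequences at total
# path length t
jc69_mismatch <- function(t) 0.75 * (1 - exp(-4 * t / 3))
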