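#' Build a rooted tree from a compatible set of weighted splits
#'
#' Splits are given in canonical encoding (side not containing the first
#' taxon of the sorted master list). The tree is rooted at the node where
#' the first taxon attaches; this is a rooting convention only and does not
#' affect the split decomposition. Missing pendant splits are added with
#' length 0. Zero-length splits are retained as zero-length edges, so trees
#' sitting on orthant boundaries keep their (multifurcation-equivalent)
#' degenerate edges.
#'
#' @param split_keys character vector of canonical split encodings.
#' @param split_len numeric vector of non-negative lengths.
#' @param taxa sorted master taxon list.
#' @return a `phylo` object.
#' @export
tree_from_splits <- function(split_keys, split_len, taxa) {
  n <- length(taxa)
  stopifnot(length(split_keys) == length(split_len), n >= 2)
  if (n == 2L) {
    # both pendant edges induce the same bipartition; carry the summed
    # weight on one edge
    return(parse_newick(sprintf("(%s:%.15g,%s:0);", taxa[1],
                                sum(split_len), taxa[2])))
  }
  mem <- matrix(vapply(split_keys, split_members, logical(n)), nrow = n)
  sizes <- colSums(mem)
  len <- as.numeric(split_len)
  # taxon-1 pendant is stored as the size n-1 side
  i_root <- which(sizes == n - 1L)
  root_len <- if (length(i_root)) len[i_root[1]] else 0
  # ensure all other pendants (singleton clusters) exist
  have_single <- rep(FALSE, n)
  for (j in which(sizes == 1L)) have_single[which(mem[, j])] <- TRUE
  for (tx in setdiff(which(!have_single), 1L)) {
    v <- rep(FALSE, n); v[tx] <- TRUE
    mem <- cbind(mem, v); sizes <- c(sizes, 1L); len <- c(len, 0)
  }
  cl <- setdiff(which(sizes <= n - 2L), i_root)
  ord <- cl[order(sizes[cl], decreasing = TRUE)]
  parent <- integer(length(ord)); names(parent) <- as.character(ord)
  for (i in seq_along(ord)) {
    ci <- ord[i]; best <- 0L; bestsize <- Inf
    for (j in seq_len(i - 1L)) {
      cj <- ord[j]
      if (sizes[cj] > sizes[ci] && all(mem[, ci] <= mem[, cj]) &&
          sizes[cj] < bestsize) {
        best <- cj; bestsize <- sizes[cj]
      }
    }
    parent[i] <- best
  }
  children <- split(ord, parent)
  emit <- function(ci) {
    if (sizes[ci] == 1L) {
      return(sprintf("%s:%.15g", taxa[which(mem[, ci])], len[ci]))
    }
    kids <- children[[as.character(ci)]]
    sprintf("(%s):%.15g", paste(vapply(kids, emit, character(1)),
                                collapse = ","), len[ci])
  }
  top <- children[["0"]]
  nwk <- sprintf("(%s:%.15g,%s);", taxa[1], root_len,
                 paste(vapply(top, emit, character(1)), collapse = ","))
  parse_newick(nwk)
}

#' Tree at position lambda on a BHV geodesic
#'
#' Evaluates the closed-form parameterization of the geodesic: at position
#' \eqn{\lambda \in [0,1]} in the i-th orthant, the tree contains exactly
#' the splits \eqn{C \cup B_1 \cup \dots \cup B_i \cup A_{i+1} \cup \dots
#' \cup A_k}, with lengths
#' \deqn{|e| = \frac{(1-\lambda)\|A_j\| - \lambda\|B_j\|}{\|A_j\|}|e|_{T_1}
#'   \quad (e \in A_j), \qquad
#'   |e| = \frac{\lambda\|B_j\| - (1-\lambda)\|A_j\|}{\|B_j\|}|e|_{T_2}
#'   \quad (e \in B_j),}
#' and \eqn{(1-\lambda)|e|_{T_1} + \lambda|e|_{T_2}} for shared splits.
#' The orthant index is the largest i with
#' \eqn{\|A_i\|/(\|A_i\|+\|B_i\|) \le \lambda} (0 if none); a boundary
#' lambda is assigned to the orthant it enters, with the vanishing splits
#' dropped at length 0. Positions are proportional to distance traveled
#' along the geodesic.
#'
#' @param g a [geodesic()] object.
#' @param lam position in `[0, 1]`; 0 reproduces the first endpoint, 1 the
#'   second.
#' @return an object of class `path_point`: list with `lambda`, `orthant`
#'   (0..k) and `tree` (a `phylo`).
#' @export
tree_at <- function(g, lam) {
  stopifnot(inherits(g, "tree_geodesic"))
  if (!is.finite(lam) || lam < 0 || lam > 1) {
    stop("lambda must be in [0, 1], got ", lam)
  }
  bounds <- vapply(g$legs, function(lg) lg$normA / (lg$normA + lg$normB),
                   numeric(1))
  i <- sum(bounds <= lam)
  keys <- g$common$split
  lens <- (1 - lam) * g$common$len1 + lam * g$common$len2
  for (j in seq_len(g$k)) {
    lg <- g$legs[[j]]
    if (j <= i) {
      f <- (lam * lg$normB - (1 - lam) * lg$normA) / lg$normB
      keys <- c(keys, names(lg$B)); lens <- c(lens, f * unname(lg$B))
    } else {
      f <- ((1 - lam) * lg$normA - lam * lg$normB) / lg$normA
      keys <- c(keys, names(lg$A)); lens <- c(lens, f * unname(lg$A))
    }
  }
  if (any(lens < -1e-12)) {
    stop("internal error: negative path length ", min(lens))
  }
  lens[lens < 0] <- 0
  structure(list(lambda = lam, orthant = i,
                 tree = tree_from_splits(keys, lens, g$taxa)),
            class = "path_point")
}

#' @export
print.path_point <- function(x, ...) {
  cat("path_point at lambda =", x$lambda, "(orthant", paste0(x$orthant, ")"),
      "\n")
  invisible(x)
}

#' Equally spaced pathtrees between two trees
#'
#' Samples `m` trees at positions \eqn{\lambda_j = j/(m+1)}, `j = 1..m`, on
#' the BHV geodesic between `t1` and `t2` (endpoints excluded). Spacing is
#' uniform in lambda and therefore in arc length.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @param m number of pathtrees (>= 1).
#' @param tol contraction tolerance passed to [geodesic()].
#' @return a `multiPhylo` list of `m` trees with an attribute `info`, a
#'   data.frame with columns `lambda` and `orthant`.
#' @export
sample_path <- function(t1, t2, m, tol = 1e-9) {
  stopifnot(m >= 1)
  g <- geodesic(t1, t2, tol)
  lams <- seq_len(m) / (m + 1)
  pts <- lapply(lams, function(l) tree_at(g, l))
  trees <- lapply(pts, `[[`, "tree")
  class(trees) <- "multiPhylo"
  attr(trees, "info") <- data.frame(
    lambda = lams, orthant = vapply(pts, `[[`, numeric(1), "orthant"))
  trees
}

#' Pathtrees between every pair of starting trees
#'
#' Concatenates [sample_path()] output over all unordered pairs of the
#' starting trees, giving `m * s * (s - 1) / 2` pathtrees for `s` starting
#' trees.
#'
#' @param starting a list of >= 2 `phylo` objects on a shared leaf set.
#' @param m pathtrees per pair.
#' @param tol contraction tolerance passed to [geodesic()].
#' @return a list with `trees` (`multiPhylo`) and `info` (data.frame with
#'   columns `pair_i`, `pair_j`, `lambda`, `topology`).
#' @export
all_pairs_pathtrees <- function(starting, m, tol = 1e-9) {
  s <- length(starting)
  stopifnot(s >= 2, m >= 1)
  trees <- list()
  info <- NULL
  for (i in seq_len(s - 1)) {
    for (j in seq(i + 1, s)) {
      p <- sample_path(starting[[i]], starting[[j]], m, tol)
      pi <- attr(p, "info")
      trees <- c(trees, unclass(p))
      info <- rbind(info, data.frame(pair_i = i, pair_j = j,
                                     lambda = pi$lambda))
    }
  }
  class(trees) <- "multiPhylo"
  info$topology <- vapply(trees, topology_key, character(1))
  rownames(info) <- NULL
  list(trees = trees, info = info)
}

#' Write pathtrees and their sidecar table
#'
#' Trees go to `<stem>.nwk` (one Newick per line); metadata (pair id,
#' lambda, topology key) to `<stem>.tsv`.
#'
#' @param pt result of [all_pairs_pathtrees()].
#' @param stem output path stem.
#' @export
write_pathtrees <- function(pt, stem) {
  write_newick_file(pt$trees, paste0(stem, ".nwk"))
  info <- pt$info
  info$pair_id <- paste0(info$pair_i, "-", info$pair_j)
  utils::write.table(info[, c("pair_id", "lambda", "topology")],
                     paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stem)
}
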