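#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees are kept rooted
#' as written (the outer Newick node is the root); internal nodes of degree
#' three or more (multifurcations) are allowed. Edges without an explicit
#' branch length are assigned length 0.
#'
#' @param text a single Newick string (terminating `;` optional).
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string: ", substr(text, 1, 60))
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[!is.finite(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) {
    bad <- min(tree$edge.length)
    stop("negative branch length in Newick string: ", format(bad))
  }
  tree
}

#' Serialize a tree to Newick
#'
#' Branch lengths are always written, with 15 significant digits so that a
#' write/parse round trip reproduces the split decomposition to within 1e-12.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string (with trailing `;`).
#' @export
write_newick <- function(tree, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  ape::write.tree(tree, digits = digits)
}

#' Read/write multi-tree Newick files (one tree per line)
#'
#' @param path file path.
#' @return `read_newick_file`: a list of `phylo` objects (class `multiPhylo`).
#' @export
read_newick_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees found in ", path)
  trees <- lapply(lines, parse_newick)
  class(trees) <- "multiPhylo"
  trees
}

#' @rdname read_newick_file
#' @param trees a list of `phylo` objects.
#' @export
write_newick_file <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

#' Decompose a tree into weighted splits
#'
#' Every edge induces a bipartition (split) of the leaf set. Splits are
#' stored canonically as a 0/1 string over the sorted master taxon list,
#' keeping the side that does not contain the first taxon. The two edges
#' incident to a degree-2 root induce the same bipartition; their lengths
#' are summed into a single split weight, so distances computed from the
#' decomposition are rooting-invariant.
#'
#' @param tree a `phylo` object.
#' @return an object of class `tree_splits`: a list with elements `taxa`
#'   (sorted leaf labels), `split` (canonical 0/1 encodings, sorted),
#'   `length` (non-negative weights, one per split) and `trivial` (logical;
#'   `TRUE` for pendant splits separating a single leaf).
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- sort(tree$tip.label)
  n <- length(taxa)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(po$edge)
  below <- matrix(FALSE, nnode, n)
  below[cbind(seq_len(n), match(tree$tip.label, taxa))] <- TRUE
  keys <- character(nrow(po$edge))
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    below[p, ] <- below[p, ] | below[ch, ]
    side <- below[ch, ]
    if (side[1]) side <- !side
    keys[i] <- paste(as.integer(side), collapse = "")
  }
  len <- vapply(split(po$edge.length, keys), sum, numeric(1))
  keys_u <- sort(names(len))
  len <- unname(len[keys_u])
  sz <- vapply(keys_u, function(k) {
    sum(utf8ToInt(k) == utf8ToInt("1"))
  }, integer(1))
  structure(
    list(taxa = taxa, split = keys_u, length = len,
         trivial = sz == 1L | sz == n - 1L),
    class = "tree_splits"
  )
}

#' @export
print.tree_splits <- function(x, ...) {
  cat("tree_splits:", length(x$split), "splits over", length(x$taxa),
      "taxa (", sum(!x$trivial), "internal )\n")
  invisible(x)
}

# logical membership vector of a canonical split encoding
split_members <- function(key) {
  utf8ToInt(key) == utf8ToInt("1")
}

# two splits (canonical encodings over the same taxa) are compatible iff at
# least one of the four intersection cells of the bipartitions is empty
splits_compatible <- function(a, b) {
  A <- split_members(a); B <- split_members(b)
  !(any(A & B) && any(A & !B) && any(!A & B) && any(!A & !B))
}

#' Canonical topology key of a tree
#'
#' Two trees receive the same key iff their sets of nontrivial splits agree
#' after contracting internal edges of length `tol` or less, i.e. iff their
#' unweighted Robinson-Foulds distance is zero after contraction. Keys are
#' only comparable between trees on the same leaf set.
#'
#' @param tree a `phylo` object.
#' @param tol internal edges with length `<= tol` are contracted.
#' @return a character scalar.
#' @export
topology_key <- function(tree, tol = 1e-9) {
  sp <- tree_splits(tree)
  keep <- !sp$trivial & sp$length > tol
  paste(sp$split[keep], collapse = ";")
}

# DNA base coding used throughout: A=1, C=2, G=3, T=4; anything else
# (gaps, N, ambiguity codes) is treated as fully missing.
.dna_code <- function(chars) {
  code <- match(toupper(chars), c("A", "C", "G", "T"))
  code
}

#' Construct a DNA alignment with compressed site patterns
#'
#' @param taxa character vector of taxon names.
#' @param sequences character vector of equal-length DNA strings (same order
#'   as `taxa`). Characters outside `A,C,G,T` (case-insensitive) are treated
#'   as missing data.
#' @return an object of class `dna_alignment`: list with `taxa`, `sequences`,
#'   `n_sites`, `patterns` (integer matrix, taxa x patterns, `NA` = missing)
#'   and `weights` (pattern multiplicities, summing to `n_sites`).
#' @export
dna_alignment <- function(taxa, sequences) {
  stopifnot(length(taxa) == length(sequences), !anyDuplicated(taxa))
  nch <- unique(nchar(sequences))
  if (length(nch) != 1L) stop("sequences have unequal lengths")
  chm <- do.call(rbind, strsplit(toupper(sequences), ""))
  cols <- do.call(paste0, lapply(seq_len(nrow(chm)), function(i) chm[i, ]))
  u <- unique(cols)
  weights <- as.numeric(table(factor(cols, levels = u)))
  pat_ch <- do.call(cbind, strsplit(u, ""))
  patterns <- matrix(.dna_code(pat_ch), nrow = length(taxa))
  rownames(patterns) <- taxa
  structure(
    list(taxa = taxa, sequences = stats::setNames(sequences, taxa),
         n_sites = nch, patterns = patterns, weights = weights),
    class = "dna_alignment"
  )
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", length(x$taxa), "taxa,", x$n_sites, "sites,",
      ncol(x$patterns), "distinct site patterns\n")
  invisible(x)
}

#' Parse a relaxed PHYLIP DNA alignment
#'
#' Accepts relaxed PHYLIP: a header line `ntax nchar`, whitespace-delimited
#' taxon names of any length, and either sequential or interleaved sequence
#' blocks (auto-detected). Sequence characters may contain internal spaces.
#'
#' @param text the file contents as a single string or vector of lines.
#' @return a [dna_alignment()] object.
#' @export
parse_phylip <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP input")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2])) {
    stop("PHYLIP header must be 'ntax nchar', got: ", lines[1])
  }
  ntax <- hdr[1]; nchar_exp <- hdr[2]
  body <- lines[-1]
  if (length(body) < ntax) {
    stop("PHYLIP body has fewer lines (", length(body),
         ") than taxa in header (", ntax, ")")
  }
  strip <- function(s) gsub("\\s+", "", s)
  name_chunk <- function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    list(name = parts[1], seq = strip(paste(parts[-1], collapse = "")))
  }
  valid <- function(s) all(nchar(s) == nchar_exp)
  res <- NULL
  # one line per taxon, or interleaved blocks (continuation lines cycle
  # through the taxa in input order)
  first <- lapply(body[seq_len(ntax)], name_chunk)
  names_ <- vapply(first, `[[`, character(1), "name")
  seqs <- vapply(first, `[[`, character(1), "seq")
  rest <- if (length(body) > ntax) strip(body[-seq_len(ntax)]) else character(0)
  si <- seqs
  if (length(rest)) {
    idx <- rep_len(seq_len(ntax), length(rest))
    for (j in seq_along(rest)) si[idx[j]] <- paste0(si[idx[j]], rest[j])
  }
  if (valid(si) && !anyDuplicated(names_)) {
    res <- list(names = names_, seqs = si)
  } else {
    # sequential with wrapped sequences: a name line starts each taxon,
    # subsequent lines accumulate characters until nchar is reached
    nm <- character(ntax); sq <- character(ntax)
    li <- 1L
    ok <- TRUE
    for (tx in seq_len(ntax)) {
      if (li > length(body)) { ok <- FALSE; break }
      nc <- name_chunk(body[li]); li <- li + 1L
      nm[tx] <- nc$name
      acc <- nc$seq
      while (nchar(acc) < nchar_exp && li <= length(body)) {
        acc <- paste0(acc, strip(body[li])); li <- li + 1L
      }
      if (nchar(acc) != nchar_exp) { ok <- FALSE; break }
      sq[tx] <- acc
    }
    if (ok && li > length(body) && !anyDuplicated(nm)) {
      res <- list(names = nm, seqs = sq)
    }
  }
  if (is.null(res)) {
    stop("PHYLIP body does not match header: expected ", ntax, " x ",
         nchar_exp, " (sequential and interleaved readings both fail)")
  }
  dna_alignment(res$names, res$seqs)
}

#' @rdname parse_phylip
#' @param path path to a PHYLIP file.
#' @export
read_phylip <- function(path) parse_phylip(readLines(path, warn = FALSE))

#' Write a relaxed (sequential) PHYLIP file
#'
#' @param aln a [dna_alignment()] object.
#' @param path output path.
#' @export
write_phylip <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(aln$taxa), aln$n_sites), con)
  writeLines(paste(format(aln$taxa, width = max(nchar(aln$taxa)) + 2),
                   aln$sequences), con)
  invisible(path)
}
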