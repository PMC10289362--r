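#' Pipeline run configuration
#'
#' Bundles and validates all parameters of the landscape pipeline.
#'
#' @param alignment a [dna_alignment()] or path to a PHYLIP file.
#' @param trees a list of `phylo` objects or path to a Newick file (one tree
#'   per line), e.g. an MCMC tree sample.
#' @param outdir output directory for run artifacts.
#' @param m pathtrees per starting-tree pair.
#' @param n number of highest-likelihood trees selected for topology
#'   classification and branch-length optimization.
#' @param metric tree metric for the first-iteration MDS: `"bhv"` or
#'   `"wrf"`.
#' @param zoom_metric metric for subsequent (zoom) iterations; defaults to
#'   the faster `"wrf"`.
#' @param interpolation `"tps"` or `"cubic"` likelihood interpolation.
#' @param iterations number of zoom iterations (>= 1).
#' @param burnin_fraction fraction of the input tree sample dropped from the
#'   front before thinning.
#' @param stride keep every `stride`-th tree after burn-in.
#' @param grid interpolation grid resolution.
#' @param plots write contour/surface figures per iteration.
#' @param seed integer seed recorded in the run log and set at run start.
#' @param tol zero-length contraction tolerance.
#' @return an object of class `run_config`.
#' @export
run_config <- function(alignment, trees, outdir, m = 1, n = 10,
                       metric = c("bhv", "wrf"), zoom_metric = "wrf",
                       interpolation = c("tps", "cubic"), iterations = 1,
                       burnin_fraction = 0, stride = 1, grid = 80,
                       plots = TRUE, seed = 1, tol = 1e-9) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  zoom_metric <- match.arg(zoom_metric, c("wrf", "bhv"))
  stopifnot(m >= 1, n >= 1, iterations >= 1, stride >= 1,
            burnin_fraction >= 0, burnin_fraction < 1)
  structure(list(alignment = alignment, trees = trees, outdir = outdir,
                 m = m, n = n, metric = metric, zoom_metric = zoom_metric,
                 interpolation = interpolation, iterations = iterations,
                 burnin_fraction = burnin_fraction, stride = stride,
                 grid = grid, plots = plots, seed = as.integer(seed),
                 tol = tol),
            class = "run_config")
}

#' Thin an MCMC tree sample
#'
#' Drops the first `burnin_fraction` of the trees, then keeps every
#' `stride`-th of the remainder (starting with the first kept tree).
#'
#' @param trees list of `phylo` objects.
#' @param burnin_fraction fraction in `[0, 1)` dropped from the front.
#' @param stride keep every `stride`-th tree (>= 1).
#' @return the thinned list of trees.
#' @export
subsample_trees <- function(trees, burnin_fraction = 0, stride = 1) {
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1, stride >= 1)
  N <- length(trees)
  if (!N) stop("subsampling left no trees (empty input)")
  keep <- seq.int(floor(burnin_fraction * N) + 1L, N)
  keep <- keep[seq.int(1L, length(keep), by = stride)]
  if (!length(keep)) stop("subsampling left no trees")
  trees[keep]
}

#' Starting trees from the convex hull of an MDS embedding
#'
#' Computes pairwise distances between the sample trees, embeds them in 2-D
#' by classical MDS, and returns the trees on the vertices of the convex
#' hull of the embedding as starting trees for pathtree generation.
#'
#' @param trees list of >= 3 `phylo` objects.
#' @param metric `"bhv"` or `"wrf"`.
#' @param dist optional precomputed distance matrix.
#' @return a list with `trees` (the hull-vertex trees, CCW order), `index`
#'   (their indices in the input), `coords` (all MDS coordinates) and
#'   `dist`.
#' @export
select_starting_trees <- function(trees, metric = c("bhv", "wrf"),
                                  dist = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(trees) >= 3)
  if (is.null(dist)) dist <- tree_dist_matrix(trees, metric)
  coords <- mds_embed(dist, 2)
  # coincident embedded trees (duplicates) collapse to one hull vertex
  key <- paste(signif(coords[, 1], 10), signif(coords[, 2], 10))
  hull <- hull_vertices(coords)
  hull <- hull[!duplicated(key[hull])]
  list(trees = trees[hull], index = hull, coords = coords, dist = dist)
}

#' Select the n highest-likelihood trees
#'
#' Ties are broken by position (insertion order) so selection is
#' deterministic.
#'
#' @param loglik per-tree log-likelihoods.
#' @param n number of trees to select (`<=` sample size).
#' @return integer indices of the selected trees, best first.
#' @export
select_top_n <- function(loglik, n) {
  stopifnot(n >= 1, n <= length(loglik))
  order(-loglik)[seq_len(n)]
}

#' Cluster trees by topology and optimize one tree per cluster
#'
#' Groups the selected trees by [topology_key()]; within each cluster the
#' highest-likelihood member is used as the start for branch-length
#' optimization, yielding one optimized tree per distinct topology.
#'
#' @param trees selected trees (list of `phylo`).
#' @param loglik their log-likelihoods (used to pick the cluster start).
#' @param aln a [dna_alignment()].
#' @param tol topology-contraction tolerance.
#' @param ... passed to [optimize_branch_lengths()].
#' @return a list with `trees` (optimized, one per topology, in order of
#'   first appearance) and `info` (data.frame: topology, cluster_size,
#'   start_loglik, loglik, n_sweeps).
#' @export
cluster_and_optimize <- function(trees, loglik, aln, tol = 1e-9, ...) {
  stopifnot(length(trees) >= 1, length(trees) == length(loglik))
  keys <- vapply(trees, topology_key, character(1), tol = tol)
  ukeys <- unique(keys)
  opt_trees <- vector("list", length(ukeys))
  info <- data.frame(topology = ukeys, cluster_size = NA_integer_,
                     start_loglik = NA_real_, loglik = NA_real_,
                     n_sweeps = NA_integer_)
  for (i in seq_along(ukeys)) {
    members <- which(keys == ukeys[i])
    start <- members[which.max(loglik[members])]
    fit <- optimize_branch_lengths(trees[[start]], aln, ...)
    opt_trees[[i]] <- fit$tree
    info$cluster_size[i] <- length(members)
    info$start_loglik[i] <- loglik[start]
    info$loglik[i] <- fit$loglik
    info$n_sweeps[i] <- fit$n_sweeps
  }
  class(opt_trees) <- "multiPhylo"
  list(trees = opt_trees, info = info)
}

#' Compare the topology sets of two tree collections
#'
#' @param set_a,set_b lists of `phylo` objects on a shared leaf set.
#' @param tol topology-contraction tolerance.
#' @return a list with counts `shared` and `novel` (topologies of `set_a`
#'   present in / absent from `set_b`) and the corresponding key vectors.
#' @export
compare_topologies <- function(set_a, set_b, tol = 1e-9) {
  ka <- unique(vapply(set_a, topology_key, character(1), tol = tol))
  kb <- unique(vapply(set_b, topology_key, character(1), tol = tol))
  in_b <- ka %in% kb
  list(shared = sum(in_b), novel = sum(!in_b),
       shared_keys = ka[in_b], novel_keys = ka[!in_b])
}

write_loglik_tsv <- function(ids, topology, loglik, path, extra = NULL) {
  df <- data.frame(tree_id = ids, topology_key = topology, loglik = loglik)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full landscape pipeline
#'
#' Executes the iterative algorithm: (1) pairwise distances and MDS of the
#' input tree sample; (2) convex-hull vertices become starting trees; (3)
#' `m` equally spaced pathtrees on the geodesic between every starting-tree
#' pair; (4) JC69 log-likelihoods of all current trees; (5) the top `n`
#' trees are classified by topology; (6) one branch-length-optimized tree
#' per topology is added; (7) the landscape (MDS + interpolated likelihood
#' surface) is written with figures and tables; (8) further iterations zoom
#' in by taking the convex hull of the previous iteration's optimized trees
#' (in a fresh MDS embedding) as the new starting trees. Likelihood-based
#' selection uses the unoptimized pathtree likelihoods; optimized
#' likelihoods are reported and drive the coloring.
#'
#' @param config a [run_config()].
#' @return an object of class `pathscape_run`: list with per-iteration
#'   states (`iterations`), the global best tree (`best`), and the path of
#'   the JSON `run_log`. Artifacts are written under `config$outdir`
#'   (per-iteration subdirectories `iter1`, `iter2`, ...).
#' @export
run_pathscape <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  aln <- config$alignment
  if (is.character(aln)) aln <- read_phylip(aln)
  trees <- config$trees
  if (is.character(trees)) trees <- read_newick_file(trees)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "subsample"
  result <- list(iterations = list(), config = config)
  log_entries <- list()
  tryCatch({
    sample_trees <- subsample_trees(trees, config$burnin_fraction,
                                    config$stride)
    stage <- "select_starting_trees"
    sel <- select_starting_trees(sample_trees, config$metric)
    starting <- sel$trees
    best_global <- list(loglik = -Inf, tree = NULL, iteration = NA_integer_)

    for (it in seq_len(config$iterations)) {
      iter_dir <- file.path(config$outdir, paste0("iter", it))
      dir.create(iter_dir, showWarnings = FALSE, recursive = TRUE)
      metric_it <- if (it == 1) config$metric else config$zoom_metric

      stage <- sprintf("iteration %d: pathtrees", it)
      pt <- all_pairs_pathtrees(starting, config$m, config$tol)
      write_newick_file(starting, file.path(iter_dir, "starting.nwk"))
      write_pathtrees(pt, file.path(iter_dir, "pathtrees"))

      stage <- sprintf("iteration %d: likelihoods", it)
      current <- c(unclass(starting), unclass(pt$trees))
      class(current) <- "multiPhylo"
      ll <- vapply(current, function(tr) log_likelihood(tr, aln)$loglik,
                   numeric(1))
      keys <- vapply(current, topology_key, character(1), tol = config$tol)
      write_loglik_tsv(seq_along(current), keys, ll,
                       file.path(iter_dir, "logliks.tsv"))

      stage <- sprintf("iteration %d: optimize", it)
      top_idx <- select_top_n(ll, min(config$n, length(current)))
      opt <- cluster_and_optimize(current[top_idx], ll[top_idx], aln,
                                  tol = config$tol)
      write_newick_file(opt$trees, file.path(iter_dir, "optimized.nwk"))
      utils::write.table(opt$info, file.path(iter_dir, "optimized.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      stage <- sprintf("iteration %d: landscape", it)
      all_trees <- c(unclass(current), unclass(opt$trees))
      class(all_trees) <- "multiPhylo"
      all_ll <- c(ll, opt$info$loglik)
      land <- tree_landscape(all_trees, all_ll, metric = metric_it,
                             interpolation = config$interpolation,
                             grid = config$grid, tol = config$tol)
      write_landscape_tsv(land, file.path(iter_dir, "landscape.tsv"))
      write_shepard_tsv(land, file.path(iter_dir, "shepard.tsv"))
      ann <- list(starting = seq_along(starting),
                  selected = top_idx,
                  optimized = length(current) + seq_along(opt$trees),
                  best = length(current) + which.max(opt$info$loglik))
      if (isTRUE(config$plots)) {
        plot_landscape(land, "contour", file.path(iter_dir, "contour.png"),
                       annotations = ann)
        plot_landscape(land, "surface3d", file.path(iter_dir, "surface.png"),
                       annotations = ann)
      }

      it_best <- which.max(opt$info$loglik)
      if (opt$info$loglik[it_best] > best_global$loglik) {
        best_global <- list(loglik = opt$info$loglik[it_best],
                            tree = opt$trees[[it_best]], iteration = it)
      }
      state <- list(starting = starting, starting_index = sel$index,
                    pathtrees = pt, loglik = ll, top_idx = top_idx,
                    optimized = opt, landscape = land)
      result$iterations[[it]] <- state
      log_entries[[it]] <- list(
        iteration = it, metric = metric_it,
        n_starting = length(starting), m = config$m,
        n_pathtrees = length(pt$trees),
        n_current = length(current), n_selected = length(top_idx),
        n_topologies = nrow(opt$info),
        best_loglik = max(opt$info$loglik),
        shepard_pearson = land$shepard$pearson,
        starting_index = sel$index)

      if (it < config$iterations) {
        stage <- sprintf("iteration %d: zoom hull", it)
        # zoom on the optimized trees; if too few distinct trees for a 2-D
        # hull, widen to the selected trees, then fall back to keeping the
        # current starting trees
        sel_new <- NULL
        if (length(opt$trees) >= 3) {
          sel_new <- tryCatch(select_starting_trees(opt$trees,
                                                    config$zoom_metric),
                              error = function(e) NULL)
        }
        if (is.null(sel_new)) {
          zoom_set <- c(unclass(opt$trees), lapply(top_idx,
                                                   function(i) current[[i]]))
          class(zoom_set) <- "multiPhylo"
          sel_new <- tryCatch(select_starting_trees(zoom_set,
                                                    config$zoom_metric),
                              error = function(e) NULL)
        }
        if (!is.null(sel_new)) {
          sel <- sel_new
          starting <- sel$trees
        }  # else: degenerate zoom area, reuse current starting trees
      }
    }

    stage <- "finalize"
    write_newick_file(list(best_global$tree),
                      file.path(config$outdir, "best.nwk"))
    log_path <- file.path(config$outdir, "run_log.json")
    jsonlite::write_json(
      list(seed = config$seed, m = config$m, n = config$n,
           metric = config$metric, zoom_metric = config$zoom_metric,
           interpolation = config$interpolation,
           iterations = log_entries,
           best = list(loglik = best_global$loglik,
                       iteration = best_global$iteration,
                       newick = write_newick(best_global$tree))),
      log_path, auto_unbox = TRUE, digits = NA)
    result$best <- best_global
    result$run_log <- log_path
    class(result) <- "pathscape_run"
    result
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.pathscape_run <- function(x, ...) {
  cat("pathscape run:", length(x$iterations), "iteration(s); best loglik",
      format(x$best$loglik, digits = 10), "(iteration",
      paste0(x$best$iteration, ")"), "\n")
  invisible(x)
}
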