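#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: double-centers the squared distances and takes the top
#' eigenpairs, scaling eigenvectors by the square roots of the eigenvalues.
#' Negative eigenvalues (which arise for non-Euclidean tree distances such
#' as BHV) are truncated; the residual distortion is what [shepard_stats()]
#' quantifies. Each axis is flipped, if needed, so that its
#' largest-magnitude coordinate is positive, making the embedding
#' deterministic.
#'
#' @param d symmetric non-negative matrix with zero diagonal.
#' @param dim embedding dimension (default 2).
#' @return a numeric matrix (points x `dim`).
#' @export
mds_embed <- function(d, dim = 2) {
  d <- unname(as.matrix(d))
  if (nrow(d) != ncol(d) || !isSymmetric(d, tol = 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  co <- suppressWarnings(stats::cmdscale(d, k = dim))
  if (ncol(co) < dim) co <- cbind(co, matrix(0, nrow(co), dim - ncol(co)))
  for (j in seq_len(dim)) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  unname(co)
}

#' Convex hull vertices of a 2-D point cloud
#'
#' @param coords numeric matrix (points x 2).
#' @return vertex indices in counter-clockwise order; points interior to the
#'   hull or interior to a hull edge are excluded.
#' @export
hull_vertices <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 3)
  h <- grDevices::chull(coords)
  if (length(h) >= 3) {
    # orient counter-clockwise (positive signed area)
    x <- coords[h, 1]; y <- coords[h, 2]
    area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
    if (area2 < 0) h <- rev(h)
  }
  # drop vertices interior to a hull edge (collinear triples)
  scale2 <- max(apply(coords, 2, function(v) diff(range(v))))^2
  repeat {
    m <- length(h)
    if (m < 3) break
    drop <- rep(FALSE, m)
    for (i in seq_len(m)) {
      a <- coords[h[if (i == 1) m else i - 1], ]
      b <- coords[h[i], ]
      c2 <- coords[h[if (i == m) 1 else i + 1], ]
      cross <- (b[1] - a[1]) * (c2[2] - a[2]) - (b[2] - a[2]) * (c2[1] - a[1])
      if (abs(cross) <= 1e-12 * max(scale2, 1)) { drop[i] <- TRUE; break }
    }
    if (!any(drop)) break
    h <- h[!drop]
  }
  if (length(h) < 3) {
    stop("degenerate hull: points are collinear")
  }
  h
}

#' Shepard-diagram statistics of an embedding
#'
#' Correlations between the original distances and the embedded Euclidean
#' distances, computed over the strict upper triangle of the two matrices.
#'
#' @param d original distance matrix.
#' @param coords embedded coordinates (points x k).
#' @return a list with `pearson`, `spearman`, `kendall`, and the paired
#'   vectors `original` and `embedded` for Shepard-diagram plotting.
#' @export
shepard_stats <- function(d, coords) {
  d <- as.matrix(d)
  coords <- as.matrix(coords)
  stopifnot(nrow(d) == nrow(coords))
  iu <- upper.tri(d)
  orig <- d[iu]
  emb <- as.matrix(stats::dist(coords))[iu]
  if (length(orig) < 2) stop("need at least 2 distance pairs")
  list(pearson = stats::cor(orig, emb),
       spearman = stats::cor(orig, emb, method = "spearman"),
       kendall = stats::cor(orig, emb, method = "kendall"),
       original = orig, embedded = emb)
}

# radial basis kernels for scattered-data interpolation
.rbf_kernel <- function(r, method) {
  if (method == "tps") {
    out <- r * r * log(r)
    out[r == 0] <- 0
    out
  } else {
    r^3
  }
}

#' Interpolate a scalar field over a 2-D point cloud
#'
#' Exact (zero-smoothing) radial-basis interpolation with an affine drift
#' term: `tps` uses the thin-plate spline kernel \eqn{r^2 \log r}, `cubic`
#' the cubic radial kernel \eqn{r^3} (the scattered-data analogue of cubic
#' spline interpolation). Both reproduce the data values at the data sites
#' and reproduce affine fields exactly; grid cells outside the convex hull
#' of the points are masked with `NA`. Duplicate coordinates are collapsed
#' to their mean value before solving.
#'
#' @param coords numeric matrix (points x 2), not all collinear.
#' @param values scalar field at the points (e.g. log-likelihoods).
#' @param method `"tps"` or `"cubic"`.
#' @param grid resolution of the interpolation lattice (grid x grid over the
#'   bounding box).
#' @return an object of class `landscape_surface`: list with grid vectors
#'   `x`, `y`, matrix `z` (`NA` outside the hull), `method`, and a
#'   `predict` function for arbitrary points.
#' @export
interpolate_surface <- function(coords, values, method = c("tps", "cubic"),
                                grid = 300) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) == length(values), grid >= 2)
  if (nrow(coords) < 3) stop("need at least 3 points to interpolate")
  # collapse duplicate sites
  key <- paste(signif(coords[, 1], 12), signif(coords[, 2], 12))
  if (anyDuplicated(key)) {
    agg <- tapply(values, key, mean)
    first <- !duplicated(key)
    ord <- key[first]
    coords_u <- coords[first, , drop = FALSE]
    values_u <- as.numeric(agg[ord])
  } else {
    coords_u <- coords; values_u <- values
  }
  n <- nrow(coords_u)
  sv <- svd(scale(coords_u, scale = FALSE))$d
  if (n < 3 || sv[2] <= 1e-10 * max(sv[1], 1e-300)) {
    stop("points are collinear; a 2-D ", method,
         " interpolation surface is undefined",
         if (method == "cubic") " (thin-plate splines need >= 3 non-collinear points too)")
  }
  K <- .rbf_kernel(as.matrix(stats::dist(coords_u)), method)
  P <- cbind(1, coords_u)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(values_u, 0, 0, 0))
  w <- sol[seq_len(n)]; a <- sol[n + 1:3]
  predict_fn <- function(pts) {
    pts <- matrix(pts, ncol = 2)
    dd <- sqrt(outer(pts[, 1], coords_u[, 1], "-")^2 +
               outer(pts[, 2], coords_u[, 2], "-")^2)
    drop(.rbf_kernel(dd, method) %*% w + cbind(1, pts) %*% a)
  }
  gx <- seq(min(coords[, 1]), max(coords[, 1]), length.out = grid)
  gy <- seq(min(coords[, 2]), max(coords[, 2]), length.out = grid)
  gpts <- cbind(rep(gx, times = grid), rep(gy, each = grid))
  z <- predict_fn(gpts)
  hull <- grDevices::chull(coords)
  bnd <- coords[c(hull, hull[1]), , drop = FALSE]
  inside <- mgcv::in.out(bnd, gpts)
  z[!inside] <- NA_real_
  structure(list(x = gx, y = gy,
                 z = matrix(z, nrow = grid),  # z[i, j] at (gx[i], gy[j])
                 method = method, predict = predict_fn),
            class = "landscape_surface")
}

#' Assemble a treespace likelihood landscape
#'
#' Computes (or accepts) a pairwise tree distance matrix, embeds it in 2-D
#' by classical MDS, extracts the convex hull, interpolates the
#' log-likelihood surface inside the hull and records Shepard validation
#' statistics.
#'
#' @param trees list of `phylo` objects on a common leaf set.
#' @param loglik per-tree log-likelihoods.
#' @param metric `"bhv"` or `"wrf"` (ignored when `dist` is supplied).
#' @param interpolation `"tps"` or `"cubic"`.
#' @param grid interpolation grid resolution.
#' @param dist optional precomputed distance matrix.
#' @param tol topology-contraction tolerance for labeling.
#' @return an object of class `tree_landscape` with elements `trees`,
#'   `dist`, `coords`, `loglik`, `topology`, `hull`, `surface`, `shepard`,
#'   `metric`.
#' @export
tree_landscape <- function(trees, loglik, metric = c("bhv", "wrf"),
                           interpolation = c("tps", "cubic"), grid = 120,
                           dist = NULL, tol = 1e-9) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  stopifnot(length(trees) == length(loglik))
  if (length(trees) < 3) stop("a landscape needs at least 3 trees")
  if (is.null(dist)) dist <- tree_dist_matrix(trees, metric)
  coords <- mds_embed(dist, 2)
  hull <- hull_vertices(coords)
  surface <- interpolate_surface(coords, loglik, interpolation, grid)
  shepard <- shepard_stats(dist, coords)
  structure(list(trees = trees, dist = dist, coords = coords,
                 loglik = loglik,
                 topology = vapply(trees, topology_key, character(1),
                                   tol = tol),
                 hull = hull, surface = surface, shepard = shepard,
                 metric = metric, interpolation = interpolation),
            class = "tree_landscape")
}

#' @export
print.tree_landscape <- function(x, ...) {
  cat("tree_landscape:", length(x$trees), "trees,",
      length(unique(x$topology)), "topologies,", x$metric, "metric;",
      "MDS Pearson r =", format(x$shepard$pearson, digits = 4), "\n")
  invisible(x)
}

# rank-scaled purple spectrum: the lighter the shade, the lower the value
purple_spectrum <- function(values) {
  pal <- grDevices::colorRampPalette(c("#E8DAF5", "#B288D6", "#5B2A86",
                                       "#2A0845"))(max(length(values), 2))
  pal[rank(values, ties.method = "first")]
}

#' Plot a likelihood landscape
#'
#' `contour` mode draws the interpolated log-likelihood surface as a filled
#' raster with contour lines inside the convex hull, all trees as dots,
#' starting trees as triangles, selected/optimized trees on a purple
#' spectrum rank-scaled by log-likelihood (lighter = lower), and the best
#' tree as a red square. `surface3d` draws the interpolated surface in
#' perspective.
#'
#' @param l a [tree_landscape()].
#' @param mode `"contour"` or `"surface3d"`.
#' @param file output image path (`.png`/`.svg`/`.pdf`); `NULL` for no file.
#' @param annotations optional list with integer index vectors `starting`,
#'   `selected`, `optimized`, and scalar `best`, all indexing `l$trees`.
#' @return invisibly, a list with `mode`, `file`, and (contour mode) the
#'   ggplot object `plot`.
#' @export
plot_landscape <- function(l, mode = c("contour", "surface3d"), file = NULL,
                           annotations = list()) {
  mode <- match.arg(mode)
  if (!inherits(l, "tree_landscape") || !length(l$trees)) {
    stop("empty or invalid landscape")
  }
  s <- l$surface
  if (mode == "surface3d") {
    if (!is.null(file)) {
      grDevices::png(file, width = 900, height = 700)
      on.exit(grDevices::dev.off())
    }
    z <- s$z
    graphics::persp(s$x, s$y, z, theta = 35, phi = 28, expand = 0.6,
                    col = "#B288D6", border = NA, shade = 0.6,
                    xlab = "MDS 1", ylab = "MDS 2", zlab = "log L",
                    ticktype = "detailed")
    return(invisible(list(mode = mode, file = file, plot = NULL)))
  }
  gdf <- data.frame(x = rep(s$x, times = length(s$y)),
                    y = rep(s$y, each = length(s$x)),
                    z = as.vector(s$z))
  gdf <- gdf[is.finite(gdf$z), ]
  pts <- data.frame(x = l$coords[, 1], y = l$coords[, 2], loglik = l$loglik)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = gdf,
                         ggplot2::aes(x = x, y = y,
                                      fill = z)) +
    ggplot2::geom_contour(data = gdf,
                          ggplot2::aes(x = x, y = y,
                                       z = z),
                          colour = "grey25", linewidth = 0.2, bins = 12) +
    ggplot2::scale_fill_viridis_c(name = "log L") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = x, y = y),
                        size = 0.8, colour = "grey10") +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
  if (length(annotations$starting)) {
    p <- p + ggplot2::geom_point(data = pts[annotations$starting, ],
                                 ggplot2::aes(x = x, y = y),
                                 shape = 17, size = 3, colour = "black")
  }
  for (grp in c("selected", "optimized")) {
    idx <- annotations[[grp]]
    if (length(idx)) {
      dd <- pts[idx, ]
      dd$shade <- purple_spectrum(l$loglik[idx])
      p <- p + ggplot2::geom_point(data = dd,
                                   ggplot2::aes(x = x, y = y),
                                   colour = dd$shade,
                                   size = if (grp == "optimized") 3 else 1.8)
    }
  }
  if (length(annotations$best)) {
    p <- p + ggplot2::geom_point(data = pts[annotations$best[1], ,
                                            drop = FALSE],
                                 ggplot2::aes(x = x, y = y),
                                 shape = 15, size = 4, colour = "red")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5.2, dpi = 110)
  }
  invisible(list(mode = mode, file = file, plot = p))
}

#' Write landscape coordinate and Shepard tables
#'
#' @param l a [tree_landscape()].
#' @param path output TSV path.
#' @export
write_landscape_tsv <- function(l, path) {
  df <- data.frame(tree_id = seq_along(l$trees),
                   x = l$coords[, 1], y = l$coords[, 2],
                   loglik = l$loglik, topology = l$topology,
                   is_hull_vertex = seq_along(l$trees) %in% l$hull)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_tsv
#' @export
write_shepard_tsv <- function(l, path) {
  df <- data.frame(original = l$shepard$original,
                   embedded = l$shepard$embedded)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
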