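#' Non-metric multidimensional scaling with seeded restarts
#'
#' Kruskal stress-1 NMDS (monotone regression of fitted on observed
#' dissimilarities, as in [vegan::monoMDS()]) run from a classical-scaling
#' start plus `n_restarts - 1` random starts; the lowest-stress configuration
#' wins. Deterministic given `seed`.
#'
#' @param dissimilarity Symmetric matrix (or `dist`) with zero diagonal.
#' @param dims Embedding dimension (default 2).
#' @param n_restarts Number of starts, the first from classical scaling.
#' @param max_iter Iteration cap per start.
#' @param seed Integer seed for the random starts.
#' @return Object of class `nmds_fit`: `coordinates` (items x dims, centered),
#'   `stress` (Kruskal stress-1), `n_restarts_used`, `seed`.
#' @export
nmds <- function(dissimilarity, dims = 2L, n_restarts = 20L, max_iter = 300L,
                 seed = 1L) {
  D <- as.matrix(dissimilarity)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("dissimilarity matrix not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 items")
  if (n < 4L) warning("fewer than 4 items: a 2-D fit is trivially embeddable")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("item", seq_len(n))
  if (all(D == 0)) {
    warning("all dissimilarities are zero: degenerate configuration")
    coords <- matrix(0, n, dims, dimnames = list(rownames(D), NULL))
    return(structure(list(coordinates = coords, stress = 0,
                          n_restarts_used = 0L, seed = seed),
                     class = "nmds_fit"))
  }
  dd <- stats::as.dist(D)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) {
      y <- stats::cmdscale(dd, k = dims)
      if (ncol(y) < dims) cbind(y, matrix(0, n, dims - ncol(y))) else y
    } else {
      matrix(stats::runif(n * dims, -1, 1), n, dims)
    }
    fit <- vegan::monoMDS(dd, y = init, k = dims, model = "global",
                          maxit = max_iter, smin = 1e-10, sfgrmin = 1e-10)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- sweep(best$points, 2L, colMeans(best$points))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("NMDS", seq_len(dims))
  structure(list(coordinates = coords, stress = best$stress,
                 n_restarts_used = n_restarts, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat("NMDS fit:", nrow(x$coordinates), "items in", ncol(x$coordinates),
      "dimensions; Kruskal stress-1 =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, ...) {
  graphics::plot(x$coordinates[, 1L], x$coordinates[, 2L],
                 xlab = "NMDS1", ylab = "NMDS2", type = "n", ...)
  graphics::text(x$coordinates[, 1L], x$coordinates[, 2L],
                 labels = rownames(x$coordinates))
  invisible(x)
}

#' UPGMA dendrogram from a dissimilarity matrix
#'
#' Average-linkage agglomeration ([stats::hclust()], ties broken by smallest
#' index pair), returned as an ultrametric `phylo` tree whose node heights are
#' the merge distances divided by two, so cophenetic distances on the tree
#' reproduce ultrametric inputs exactly.
#'
#' @param dissimilarity Symmetric matrix (or `dist`).
#' @return Ultrametric `phylo` with attributes `merge_heights` (merge
#'   distance / 2 per agglomeration) and `hclust` (the raw clustering).
#' @export
upgma_dendrogram <- function(dissimilarity) {
  D <- as.matrix(dissimilarity)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("dissimilarity matrix not symmetric")
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("item", seq_len(nrow(D)))
  h <- stats::hclust(stats::as.dist(D), method = "average")
  tr <- ape::as.phylo(h)
  attr(tr, "merge_heights") <- h$height / 2
  attr(tr, "hclust") <- h
  tr
}
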