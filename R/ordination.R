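#' Compositional PCA via singular value decomposition of the clr matrix
#'
#' Column-centers the clr matrix (per-OTU mean over samples) and takes the
#' SVD. In the default form-biplot convention, scores are `U %*% S` so that
#' Euclidean distances among full-dimensional scores equal the Aitchison
#' distances among samples, and loadings are the right singular vectors `V`.
#' Component signs are fixed so the loading of largest magnitude on each
#' component is positive.
#'
#' @param clr a `clr_matrix` (samples x OTUs), at least 3 samples.
#' @return Object of class `coda_pca` with elements `scores`, `loadings`,
#'   `variance_fraction`, `sdev` (singular values / sqrt(n-1)), `singular`,
#'   `center`, `log_base`, `n`.
#' @export
compositional_pca <- function(clr) {
  m <- unclass(clr)
  if (nrow(m) < 3L) stop("compositional PCA needs at least 3 samples", call. = FALSE)
  center <- colMeans(m)
  mc <- sweep(m, 2L, center)
  sv <- svd(mc)
  tol <- max(dim(mc)) * max(sv$d) * .Machine$double.eps
  keep <- which(sv$d > tol)
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # reproducible sign convention
  for (j in seq_along(keep)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- u %*% diag(d, nrow = length(d))
  comp_names <- paste0("PC", seq_along(d))
  dimnames(scores) <- list(rownames(m), comp_names)
  dimnames(v) <- list(colnames(m), comp_names)
  structure(list(scores = scores, loadings = v,
                 variance_fraction = d^2 / sum(d^2),
                 sdev = d / sqrt(nrow(m) - 1), singular = d, center = center,
                 log_base = attr(clr, "log_base"), n = nrow(m)),
            class = "coda_pca")
}

#' @export
print.coda_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("compositional PCA: %d samples, %d components\n", x$n, length(vf)))
  cat(sprintf("  variance explained: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * vf[1L], if (length(vf) > 1L) 100 * vf[2L] else NA_real_))
  invisible(x)
}

#' Biplot coordinates in form or covariance scaling
#'
#' Form biplot: scores `U S`, loadings `V` — inter-sample distances
#' approximate Aitchison distances. Covariance biplot: scores `U`, loadings
#' `V S / sqrt(n - 1)` — the length of a loading vector over all components
#' equals the clr standard deviation of that OTU.
#'
#' @param res a `coda_pca`.
#' @param kind `"form"` or `"covariance"`.
#' @param ncomp number of components to return, default 2.
#' @return List with `samples` and `otus` coordinate data frames and
#'   `axis_labels` carrying variance percentages.
#' @export
biplot_coordinates <- function(res, kind = c("form", "covariance"), ncomp = 2L) {
  stopifnot(inherits(res, "coda_pca"))
  kind <- match.arg(kind)
  ncomp <- min(ncomp, length(res$singular))
  if (ncomp < 2L) stop("need at least 2 components", call. = FALSE)
  idx <- seq_len(ncomp)
  d <- res$singular[idx]
  u <- sweep(res$scores[, idx, drop = FALSE], 2L, d, "/")
  v <- res$loadings[, idx, drop = FALSE]
  if (kind == "form") {
    samples <- sweep(u, 2L, d, "*")
    otus <- v
  } else {
    samples <- u
    otus <- sweep(v, 2L, d / sqrt(res$n - 1), "*")
  }
  labels <- sprintf("PC%d (%.1f%%)", idx, 100 * res$variance_fraction[idx])
  list(samples = as.data.frame(samples), otus = as.data.frame(otus),
       axis_labels = labels, kind = kind)
}

#' Ward clustering of samples on a distance matrix
#'
#' Agglomerative hierarchical clustering with the Ward.D2 criterion (squared
#' distance update) on a metric distance matrix, typically the Aitchison
#' distance.
#'
#' @param d a `dist` object or symmetric distance matrix with zero diagonal.
#' @param k optional number of groups to cut the dendrogram into.
#' @return List with `hclust` (the dendrogram) and, if `k` given, `labels`
#'   (integer cluster per sample).
#' @export
ward_cluster <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
      stop("distance matrix must be square and symmetric", call. = FALSE)
    d <- stats::as.dist(m)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  out <- list(hclust = hc)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}

#' Re-close a count table to an OTU subset before clr
#'
#' The subset-reclosure convention: ordination of a selected OTU subset is
#' computed on the composition renormalized to that subset, not on a slice of
#' the full clr matrix.
#'
#' @param x a `count_table`.
#' @param otus OTU ids (or index) to keep.
#' @inheritParams clr_from_counts
#' @return A `clr_matrix` on the subset.
#' @export
subset_reclosure_clr <- function(x, otus, prior_mass = 0.5, log_base = 2) {
  clr_from_counts(subset_table(x, otus = otus), prior_mass = prior_mass,
                  log_base = log_base)
}

#' Normal-theory data ellipse for a 2-column score matrix
#'
#' Returns the boundary of the ellipse covering `level` of a bivariate normal
#' fitted to the points (chi-square radius, i.e. sqrt(qchisq(level, 2)) ~ 1.665
#' standard deviations at 75%).
#'
#' @param xy 2-column matrix of coordinates.
#' @param level coverage level, default 0.75.
#' @param n_points points on the boundary.
#' @return Two-column matrix of boundary coordinates.
#' @export
data_ellipse <- function(xy, level = 0.75, n_points = 100L) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  if (nrow(xy) < 3L) return(NULL)
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  r <- sqrt(stats::qchisq(level, df = 2))
  eg <- eigen(cv, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta))
  pts <- circ %*% diag(r * sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  sweep(pts, 2L, ctr, "+")
}
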