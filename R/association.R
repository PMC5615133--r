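#' Symmetric rho proportionality from a single clr matrix
#'
#' `rho(i, j) = 1 - var(x_i - x_j) / (var(x_i) + var(x_j))` computed on clr
#' columns across samples, which simplifies to
#' `2 cov(x_i, x_j) / (var(x_i) + var(x_j))`. Pairs involving a zero-variance
#' column are flagged `NA`.
#'
#' @param clr a `clr_matrix`.
#' @return Symmetric OTU x OTU matrix with unit diagonal (NA diagonal for
#'   zero-variance OTUs).
#' @export
rho_from_clr <- function(clr) {
  m <- unclass(clr)
  if (nrow(m) < 3L) stop("rho needs at least 3 samples", call. = FALSE)
  V <- stats::cov(m)
  v <- diag(V)
  denom <- outer(v, v, "+")
  rho <- 2 * V / denom
  zero_var <- v <= 0
  rho[zero_var, ] <- NA
  rho[, zero_var] <- NA
  diag(rho) <- ifelse(zero_var, NA, 1)
  rho
}

#' Expected rho over Dirichlet Monte-Carlo instances
#'
#' The rho proportionality metric measures the variance of the log-ratio
#' between two OTUs relative to their individual variances: 1 for perfectly
#' proportional pairs, about 0 for unrelated pairs. Its expected value over
#' clr-transformed Dirichlet instances is robust to count sparsity. rho is
#' invariant to the clr log base.
#'
#' @param mc an `mc_instances` (or a plain list of clr matrices).
#' @return Object of class `rho_graph`: list with `rho` (mean matrix across
#'   instances), `K`, `otu_ids`.
#' @export
expected_rho <- function(mc) {
  if (is.list(mc) && !inherits(mc, "mc_instances")) mc <- as_mc_instances(mc)
  stopifnot(inherits(mc, "mc_instances"))
  acc <- NULL
  for (k in seq_len(mc$K)) {
    r <- rho_from_clr(mc$instances[[k]])
    acc <- if (is.null(acc)) r else acc + r
  }
  rho <- acc / mc$K
  dimnames(rho) <- list(mc$otu_ids, mc$otu_ids)
  structure(list(rho = rho, K = mc$K, otu_ids = mc$otu_ids),
            class = "rho_graph")
}

#' @export
print.rho_graph <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("rho_graph: %d OTUs, E(rho) over %d instances; max off-diagonal %.3f\n",
              nrow(x$rho), x$K, max(off, na.rm = TRUE)))
  invisible(x)
}

#' Slope and correlation diagnostics for an OTU pair
#'
#' A single rho value encapsulates both the slope and the correlation of the
#' pairwise association; this returns them separately. `corr` is the Pearson
#' correlation of the clr columns; `slope` is the standardized major-axis
#' slope `sign(cov) * sqrt(var_j / var_i)` of column `j` on column `i`. A
#' perfectly proportional pair has slope 1 and correlation 1.
#'
#' @param clr a `clr_matrix`.
#' @param i,j column ids or indices.
#' @return List with `slope` and `corr`.
#' @export
pair_diagnostics <- function(clr, i, j) {
  m <- unclass(clr)
  xi <- m[, i]; xj <- m[, j]
  vi <- stats::var(xi); vj <- stats::var(xj)
  if (vi <= 0 || vj <= 0) stop("constant clr column", call. = FALSE)
  cv <- stats::cov(xi, xj)
  list(slope = if (cv == 0) sqrt(vj / vi) else sign(cv) * sqrt(vj / vi),
       corr = cv / sqrt(vi * vj))
}

#' Threshold-graph clusters of compositionally associated OTUs
#'
#' Keeps edges with `E(rho) > cutoff` (strict), takes connected components,
#' and discards components smaller than `min_size`. Pairs flagged `NA`
#' (zero-variance OTUs) carry no edges. When a taxonomy is supplied, each
#' member is annotated with its genus (unclassified pooled).
#'
#' @param graph a `rho_graph`.
#' @param cutoff rho threshold, default 0.65.
#' @param min_size minimum cluster size to report, default 3.
#' @param taxonomy optional taxonomy `data.frame`.
#' @return Object of class `cluster_set`: list with `clusters` (list of OTU id
#'   vectors, largest first) and `members` (`data.frame` cluster, otu_id,
#'   genus).
#' @export
rho_clusters <- function(graph, cutoff = 0.65, min_size = 3L, taxonomy = NULL) {
  stopifnot(inherits(graph, "rho_graph"))
  adj <- graph$rho > cutoff
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  comp <- connected_components(adj)
  sizes <- table(comp)
  keep_ids <- names(sizes)[sizes >= min_size]
  clusters <- lapply(keep_ids, function(cid) graph$otu_ids[comp == as.integer(cid)])
  clusters <- clusters[order(-vapply(clusters, length, 1L))]
  members <- if (length(clusters) > 0L) {
    do.call(rbind, lapply(seq_along(clusters), function(i)
      data.frame(cluster = i, otu_id = clusters[[i]], stringsAsFactors = FALSE)))
  } else {
    data.frame(cluster = integer(), otu_id = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(taxonomy) && nrow(members) > 0L) {
    bins <- taxon_bins(taxonomy, "genus")
    members$genus <- unname(bins[members$otu_id])
  }
  structure(list(clusters = clusters, members = members,
                 cutoff = cutoff, min_size = min_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) at E(rho) > %.2f, min size %d\n",
              length(x$clusters), x$cutoff, x$min_size))
  for (i in seq_along(x$clusters))
    cat(sprintf("  %s: %d OTUs\n", LETTERS[min(i, 26L)], length(x$clusters[[i]])))
  invisible(x)
}

# connected components of a logical adjacency matrix; BFS, order-independent
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Edge list of a rho graph above a cutoff, with pair diagnostics
#'
#' Mirrors the shape of a per-pair association table: one row per OTU pair
#' above the cutoff with its expected rho, slope and Pearson correlation
#' (computed on the supplied clr matrix, typically the CZM + clr path).
#'
#' @param graph a `rho_graph`.
#' @param clr a `clr_matrix` on the same OTUs used for the diagnostics.
#' @param cutoff rho threshold, default 0.65.
#' @return `data.frame` with columns `otu_i`, `otu_j`, `rho`, `slope`, `corr`.
#' @export
rho_edges <- function(graph, clr, cutoff = 0.65) {
  stopifnot(inherits(graph, "rho_graph"))
  r <- graph$rho
  idx <- which(upper.tri(r) & !is.na(r) & r > cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(otu_i = character(), otu_j = character(), rho = numeric(),
                      slope = numeric(), corr = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(idx)), function(q) {
    i <- idx[q, 1L]; j <- idx[q, 2L]
    dg <- pair_diagnostics(clr, graph$otu_ids[i], graph$otu_ids[j])
    data.frame(otu_i = graph$otu_ids[i], otu_j = graph$otu_ids[j],
               rho = r[i, j], slope = dg$slope, corr = dg$corr,
               stringsAsFactors = FALSE)
  }))
  out[order(-out$rho), , drop = FALSE]
}
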