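#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix (typically the Aitchison
#' distance). Total and within-group sums of squares are computed directly
#' from squared distances (Gower identity: the trace of the centered
#' `-d^2/2` matrix equals `sum(d^2)/n`); the pseudo-F statistic uses
#' `(g - 1, n - g)` degrees of freedom and the p-value is estimated by label
#' permutation with the add-one correction.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param labels group label per sample; at least 2 groups with >= 2 samples.
#' @param n_permutations number of label permutations, default 999.
#' @param seed integer seed for the permutations.
#' @return Object of class `permanova_result` with `pseudo_F`, `R2`,
#'   `p_value`, `df`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match distance matrix", call. = FALSE)
  tab <- table(labels)
  g <- length(tab)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("each group needs at least 2 samples", call. = FALSE)
  sst <- sum(d2[upper.tri(d2)]) / n
  if (sst <= 0) stop("degenerate distances: all samples identical", call. = FALSE)

  ssw_of <- function(lab) {
    s <- 0
    for (gl in unique(lab)) {
      idx <- which(lab == gl)
      s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  f_of <- function(lab) {
    ssw <- ssw_of(lab)
    ssb <- sst - ssw
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_of(labels)
  ssw_obs <- ssw_of(labels)
  r2 <- (sst - ssw_obs) / sst
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations),
               function(i) f_of(sample(labels)) >= f_obs, logical(1L)))
  })
  structure(list(pseudo_F = f_obs, R2 = r2,
                 p_value = (exceed + 1) / (n_permutations + 1),
                 df = c(between = g - 1L, within = n - g),
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.4f, P = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1L], x$df[2L], x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over group pairs
#'
#' Subsets the distance matrix to each pair of groups and runs [permanova()].
#' No multiplicity correction is applied; raw p-values are reported.
#'
#' @inheritParams permanova
#' @param pairs `"all"` or a list of 2-vectors of group labels.
#' @param cohort_order optional ordering used with `pairs = "successive"`.
#' @return `data.frame`: `groupA`, `groupB`, `pseudo_F`, `R2`, `p_value`.
#' @export
pairwise_permanova <- function(d, labels, pairs = "all", cohort_order = NULL,
                               n_permutations = 999, seed = 1) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (identical(pairs, "all")) {
    pl <- utils::combn(sort(groups), 2L, simplify = FALSE)
  } else if (identical(pairs, "successive")) {
    ord <- if (is.null(cohort_order)) sort(groups) else cohort_order
    pl <- lapply(seq_len(length(ord) - 1L), function(i) ord[c(i, i + 1L)])
  } else pl <- pairs
  out <- do.call(rbind, lapply(pl, function(p) {
    idx <- which(labels %in% p)
    res <- permanova(dm[idx, idx], labels[idx],
                     n_permutations = n_permutations, seed = seed)
    data.frame(groupA = p[1L], groupB = p[2L], pseudo_F = res$pseudo_F,
               R2 = res$R2, p_value = res$p_value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Within-group dispersion in clr space
#'
#' For each group: the centroid is the mean clr vector of its members, and
#' the dispersion summaries are the median (MCD) and interquartile range
#' (IQR) of member Aitchison distances to that centroid.
#'
#' @param clr a `clr_matrix`.
#' @param labels group label per sample; each group >= 2 samples.
#' @return `data.frame`: `group`, `n`, `MCD`, `IQR`.
#' @export
group_dispersion <- function(clr, labels) {
  m <- unclass(clr)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stop("labels must match clr rows", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2L)) stop("each group needs at least 2 samples", call. = FALSE)
  out <- do.call(rbind, lapply(names(tab), function(gl) {
    sub <- m[labels == gl, , drop = FALSE]
    ctr <- colMeans(sub)
    dd <- sqrt(rowSums(sweep(sub, 2L, ctr)^2))
    data.frame(group = gl, n = nrow(sub), MCD = stats::median(dd),
               IQR = stats::IQR(dd), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Shannon diversity per sample
#'
#' `H(s) = -sum_j p_j log(p_j)` in natural-log units, computed over the
#' positive counts of each sample with `p_j = count / depth`.
#'
#' @param x a `count_table` with positive depths.
#' @return `data.frame` of class `diversity_profile`: `sample_id`, `depth`,
#'   `shannon`, plus `age` and `cohort` when metadata is attached.
#' @export
shannon_diversity <- function(x) {
  stopifnot(inherits(x, "count_table"))
  d <- depths(x)
  if (any(d <= 0)) stop("zero-depth sample", call. = FALSE)
  H <- apply(x$counts, 1L, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log(p))
  })
  out <- data.frame(sample_id = rownames(x$counts), depth = unname(d),
                    shannon = unname(H), stringsAsFactors = FALSE)
  if (!is.null(x$metadata)) {
    out$age <- x$metadata$age
    out$cohort <- x$metadata$cohort
  }
  class(out) <- c("diversity_profile", class(out))
  out
}

#' Check whether diversity is confounded with read depth
#'
#' Spearman correlation of read depth against Shannon diversity with a
#' permutation p-value. The profile is flagged depth-confounded when
#' `|r| > 0.3` and `p < 0.01`.
#'
#' @param profile a `diversity_profile` (or any data.frame with `depth` and
#'   `shannon` columns), >= 10 samples.
#' @param n_permutations permutations for the p-value, default 999.
#' @param seed integer seed.
#' @return List with `rho` (Spearman), `p_value`, `flag`.
#' @export
depth_diversity_check <- function(profile, n_permutations = 999, seed = 1) {
  if (nrow(profile) < 10L) stop("need at least 10 samples", call. = FALSE)
  depth <- profile$depth; H <- profile$shannon
  if (length(unique(depth)) < 2L) stop("constant depth", call. = FALSE)
  r_obs <- stats::cor(depth, H, method = "spearman")
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i)
      abs(stats::cor(depth, sample(H), method = "spearman")) >= abs(r_obs),
      logical(1L)))
  })
  p <- (exceed + 1) / (n_permutations + 1)
  list(rho = r_obs, p_value = p, flag = abs(r_obs) > 0.3 && p < 0.01)
}

#' Locally weighted linear trend over age
#'
#' A loess-style smoother: at each grid point, a linear regression weighted by
#' the tricube kernel over the `span` fraction of nearest observations. With
#' values exactly linear in age the smoother reproduces the line.
#'
#' @param values per-sample numeric response (e.g. Shannon diversity or a clr
#'   abundance).
#' @param ages per-sample ages in years; >= 10 samples over >= 3 distinct ages.
#' @param span fraction of points in each local window, default 0.75.
#' @param grid evaluation points; default the integer age range.
#' @return `data.frame` with `age` and `fit`.
#' @export
smooth_age_trend <- function(values, ages, span = 0.75, grid = NULL) {
  stopifnot(length(values) == length(ages))
  ok <- !is.na(values) & !is.na(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 10L) stop("need at least 10 samples", call. = FALSE)
  if (length(unique(ages)) < 3L) stop("need at least 3 distinct ages", call. = FALSE)
  if (is.null(grid)) grid <- seq(floor(min(ages)), ceiling(max(ages)))
  q <- max(2L, ceiling(span * length(ages)))
  fit <- vapply(grid, function(x0) {
    dist <- abs(ages - x0)
    h <- sort(dist)[min(q, length(dist))]
    if (h <= 0) return(mean(values[dist == 0]))
    w <- (1 - pmin(dist / h, 1)^3)^3
    use <- w > 0
    xw <- ages[use] - x0; yw <- values[use]; ww <- w[use]
    sw <- sum(ww); sx <- sum(ww * xw); sxx <- sum(ww * xw^2)
    sy <- sum(ww * yw); sxy <- sum(ww * xw * yw)
    det <- sw * sxx - sx^2
    if (det < 1e-12 * max(sw * sxx, 1)) return(sy / sw)  # degenerate window
    (sxx * sy - sx * sxy) / det  # intercept at x0
  }, numeric(1L))
  data.frame(age = grid, fit = fit)
}
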