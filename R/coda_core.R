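#' Count-zero-multiplicative (CZM) zero replacement
#'
#' Replaces each zero count in sample *s* by the pseudo-proportion
#' `delta = prior_mass / depth[s]` and multiplicatively shrinks the non-zero
#' proportions by `1 - n_zeros * delta` so every row still sums to 1. Rows
#' without zeros are returned as the plain closure `count / depth`.
#'
#' @param x a `count_table` with positive depths.
#' @param prior_mass pseudo-count mass assigned to a zero cell, default 0.5.
#' @return A strictly positive samples x OTUs matrix of proportions (class
#'   `composition`), each row summing to 1.
#' @export
czm_replace <- function(x, prior_mass = 0.5) {
  stopifnot(inherits(x, "count_table"))
  if (prior_mass <= 0) stop("prior_mass must be positive", call. = FALSE)
  d <- depths(x)
  zero_rows <- which(d == 0)
  if (length(zero_rows) > 0L)
    stop("sample(s) with zero depth: ",
         paste(rownames(x$counts)[zero_rows], collapse = ", "), call. = FALSE)
  p <- x$counts / d
  nz <- rowSums(x$counts == 0)
  delta <- prior_mass / d
  shrink <- 1 - nz * delta
  if (any(shrink <= 0))
    stop("zero replacement exceeds total mass; depth too small for prior",
         call. = FALSE)
  out <- p * shrink
  dm <- matrix(delta, nrow = nrow(p), ncol = ncol(p))
  out[x$counts == 0] <- dm[x$counts == 0]
  structure(out, class = c("composition", class(out)))
}

#' Closure: scale positive values to proportions
#'
#' @param m matrix or vector of strictly positive values.
#' @return Rows rescaled to sum to 1 (class `composition`).
#' @export
closure <- function(m) {
  if (is.vector(m)) m <- matrix(m, nrow = 1L)
  if (any(m <= 0)) stop("closure requires strictly positive values", call. = FALSE)
  structure(m / rowSums(m), class = c("composition", class(m)))
}

#' Centered log-ratio (clr) transform
#'
#' `clr(x)[s, j] = log(x[s, j]) - mean_j log(x[s, j])`, computed per sample.
#' Rows of the result sum to zero; Euclidean distances between rows are
#' Aitchison distances.
#'
#' @param comp strictly positive samples x OTUs matrix (need not be closed:
#'   clr is scale-invariant per row).
#' @param log_base 2 (default; effect sizes are then in log2 units) or `exp(1)`.
#' @return A `clr_matrix`: numeric matrix with a `log_base` attribute.
#' @export
clr_transform <- function(comp, log_base = 2) {
  m <- unclass(comp)
  if (is.vector(m)) m <- matrix(m, nrow = 1L)
  if (any(m <= 0)) stop("clr requires strictly positive entries", call. = FALSE)
  lm <- log(m, base = log_base)
  out <- lm - rowMeans(lm)
  attr(out, "log_base") <- log_base
  class(out) <- c("clr_matrix", "matrix", "array")
  out
}

#' clr matrix from counts via CZM zero replacement
#'
#' Convenience wrapper: [czm_replace()] then [clr_transform()]. This is the
#' deterministic (non-Monte-Carlo) path used for exploratory ordination and
#' PERMANOVA.
#'
#' @inheritParams czm_replace
#' @inheritParams clr_transform
#' @return A `clr_matrix`.
#' @export
clr_from_counts <- function(x, prior_mass = 0.5, log_base = 2) {
  clr_transform(czm_replace(x, prior_mass = prior_mass), log_base = log_base)
}

#' Dirichlet Monte-Carlo posterior instances of a count table
#'
#' For each of `K` instances and each sample, draws a composition from
#' `Dirichlet(counts[s, ] + prior_mass)` and clr-transforms it. These
#' instances propagate the count-based uncertainty of low-abundance OTUs into
#' every downstream statistic; expected values of a statistic are means over
#' instances.
#'
#' @param x a `count_table`.
#' @param K number of instances, default 128; must be >= 2.
#' @param prior_mass per-cell Dirichlet prior, default 0.5.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param log_base clr log base, default 2.
#' @return An object of class `mc_instances`: list with elements `instances`
#'   (list of `K` clr matrices), `K`, `prior_mass`, `seed`, `log_base`,
#'   `sample_ids`, `otu_ids`.
#' @export
dirichlet_instances <- function(x, K = 128, prior_mass = 0.5, seed = 1,
                                log_base = 2) {
  stopifnot(inherits(x, "count_table"))
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (prior_mass <= 0) stop("prior_mass must be positive", call. = FALSE)
  n <- nrow(x$counts); D <- ncol(x$counts)
  alpha <- x$counts + prior_mass
  instances <- with_seed(seed, {
    lapply(seq_len(K), function(k) {
      g <- matrix(stats::rgamma(n * D, shape = alpha), nrow = n, ncol = D)
      lg <- log(g / rowSums(g), base = log_base)
      out <- lg - rowMeans(lg)
      dimnames(out) <- dimnames(x$counts)
      attr(out, "log_base") <- log_base
      class(out) <- c("clr_matrix", "matrix", "array")
      out
    })
  })
  structure(list(instances = instances, K = as.integer(K),
                 prior_mass = prior_mass, seed = seed, log_base = log_base,
                 sample_ids = rownames(x$counts), otu_ids = colnames(x$counts)),
            class = "mc_instances")
}

#' @export
print.mc_instances <- function(x, ...) {
  cat(sprintf("mc_instances: K=%d, %d samples x %d OTUs, prior=%.3g, seed=%s, log base %s\n",
              x$K, length(x$sample_ids), length(x$otu_ids), x$prior_mass,
              format(x$seed), format(x$log_base)))
  invisible(x)
}

# coerce a plain list of clr matrices into the mc_instances contract
as_mc_instances <- function(mats, log_base = 2, seed = NA) {
  stopifnot(is.list(mats), length(mats) >= 2L)
  structure(list(instances = mats, K = length(mats), prior_mass = NA_real_,
                 seed = seed, log_base = log_base,
                 sample_ids = rownames(mats[[1L]]),
                 otu_ids = colnames(mats[[1L]])),
            class = "mc_instances")
}

#' Aitchison distance between samples
#'
#' Euclidean distance between clr-transformed rows. Given a `count_table`,
#' the CZM + clr path ([clr_from_counts()]) is used.
#'
#' @param x a `clr_matrix` or a `count_table`.
#' @param ... passed to [clr_from_counts()] when `x` is a `count_table`.
#' @return A `dist` object over samples.
#' @export
aitchison_distance <- function(x, ...) {
  if (inherits(x, "count_table")) x <- clr_from_counts(x, ...)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::dist(unclass(x), method = "euclidean")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Stable per-stage seed derivation from one pipeline seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
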