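# Shared in-code fixtures. Everything is generated at test time; seeds are
# frozen so expected values computed once by an independent oracle stay valid.

# small deterministic count table with names
toy_table <- function(n = 4L, D = 5L, seed = 42L, zeros = TRUE) {
  set.seed(seed)
  m <- matrix(rpois(n * D, lambda = 50), n, D)
  if (zeros) m[cbind(seq_len(min(n, D)), seq_len(min(n, D)))] <- 0
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("otu", seq_len(D)))
  count_table(m)
}

# clr matrix of iid Gaussian noise (already row-centered), for geometry tests
gauss_clr <- function(n, D, sd = 1, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n * D, sd = sd), n, D)
  m <- m - rowMeans(m)
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("otu", seq_len(D)))
  attr(m, "log_base") <- 2
  class(m) <- c("clr_matrix", "matrix", "array")
  m
}

# independent PERMANOVA oracle: direct between/within sums of squares
# from group means in coordinate space is NOT used; instead compute F from
# squared distances with the textbook formula, written separately from the
# package implementation.
oracle_permanova_F <- function(dmat, labels) {
  d2 <- as.matrix(dmat)^2
  n <- nrow(d2)
  g <- length(unique(labels))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (gl in unique(labels)) {
    idx <- which(labels == gl)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

# exhaustive-enumeration PERMANOVA p-value over all distinct label permutations
oracle_permanova_exact_p <- function(dmat, labels) {
  f_obs <- oracle_permanova_F(dmat, labels)
  n <- length(labels)
  perms <- combinat_permutations(labels)
  fs <- vapply(perms, function(l) oracle_permanova_F(dmat, l), numeric(1L))
  mean(fs >= f_obs - 1e-12)
}

# all distinct arrangements of a label multiset (small n only)
combinat_permutations <- function(labels) {
  n <- length(labels)
  idx_perms <- all_perms(n)
  arr <- lapply(idx_perms, function(p) labels[p])
  unique(arr)
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  q <- 0L
  for (p in sub) for (i in seq_len(n)) {
    q <- q + 1L
    out[[q]] <- append(p, n, after = i - 1L)
  }
  out
}
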