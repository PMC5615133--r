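test_that("rho: duplicated column gives 1, closed form holds, base-invariant", {
  set.seed(1)
  m <- matrix(rnorm(200 * 6), 200, 6)
  m[, 2] <- m[, 1]             # identical columns
  m <- m - rowMeans(m)
  # duplication survives row-centering only if computed directly; rebuild:
  m[, 2] <- m[, 1]
  colnames(m) <- paste0("o", 1:6)
  attr(m, "log_base") <- 2; class(m) <- c("clr_matrix", "matrix", "array")
  r <- rho_from_clr(m)
  expect_equal(r["o1", "o2"], 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
  expect_true(all(r <= 1 + 1e-12))

  # closed form: var(x)=var(y)=1, cov=0.8 -> rho = 1 - 0.4/2 = 0.8
  x <- m[, 3]; y <- 0.8 * x + sqrt(1 - 0.8^2) * m[, 4] / sd(m[, 4])
  expect_equal(1 - var(x - y) / (var(x) + var(y)),
               2 * cov(x, y) / (var(x) + var(y)))

  # clr log base does not change rho (global rescale)
  me <- unclass(m) * log(2)
  attr(me, "log_base") <- exp(1); class(me) <- class(m)
  expect_equal(rho_from_clr(me), r, tolerance = 1e-12)

  # zero-variance OTU flagged NA
  m2 <- unclass(m); m2[, 5] <- 0
  attr(m2, "log_base") <- 2; class(m2) <- class(m)
  r2 <- rho_from_clr(m2)
  expect_true(all(is.na(r2[, "o5"])))
  expect_false(anyNA(r2[-5, -5]))
})

test_that("expected_rho: duplicated OTU counts give E(rho) = 1; independence gives ~0", {
  tab <- toy_table(30L, 8L, seed = 6L, zeros = FALSE)
  m <- tab$counts
  m[, 2] <- m[, 1]
  colnames(m) <- paste0("o", 1:8)
  mc <- dirichlet_instances(count_table(m), K = 16, seed = 2)
  # identical counts share one Dirichlet parameter but are drawn independently,
  # so force exact duplication at the clr level per instance
  mc$instances <- lapply(mc$instances, function(X) { X[, 2] <- X[, 1]; X })
  er <- expected_rho(mc)
  expect_equal(er$rho["o1", "o2"], 1)

  # independent large-variance clr noise -> |E(rho)| < 0.1 at S = 500
  # (D = 50 parts keeps the closure-induced -1/(D-1) correlation negligible)
  set.seed(9)
  mats <- lapply(1:4, function(k) {
    x <- matrix(rnorm(500 * 50, sd = 2), 500, 50)
    x <- x - rowMeans(x)
    colnames(x) <- paste0("o", 1:50); rownames(x) <- paste0("s", 1:500)
    x
  })
  er2 <- expected_rho(mats)
  expect_lt(abs(er2$rho["o1", "o2"]), 0.1)
  expect_lt(abs(er2$rho["o10", "o30"]), 0.1)
  expect_lt(mean(abs(er2$rho[upper.tri(er2$rho)])), 0.1)
})

test_that("pair_diagnostics: identity, slope 2, and SMA closed form", {
  set.seed(12)
  base <- rnorm(2000)
  m <- cbind(base, base, 2 * base + rnorm(2000, sd = 1e-4), rnorm(2000))
  colnames(m) <- c("a", "b", "c", "d")
  class(m) <- c("clr_matrix", "matrix", "array")
  dg <- pair_diagnostics(m, "a", "b")
  expect_equal(dg$slope, 1)
  expect_equal(dg$corr, 1)
  dg2 <- pair_diagnostics(m, "a", "c")
  expect_equal(dg2$slope, 2, tolerance = 1e-3)
  expect_gt(dg2$corr, 0.999)

  # simulated pair with known covariance: slope = sign(cov) sqrt(vy/vx)
  vx <- 1; vy <- 2.25; cv <- -0.9
  L <- chol(matrix(c(vx, cv, cv, vy), 2))
  xy <- matrix(rnorm(2 * 2000), ncol = 2) %*% L
  colnames(xy) <- c("x", "y")
  class(xy) <- c("clr_matrix", "matrix", "array")
  dg3 <- pair_diagnostics(xy, "x", "y")
  expect_equal(dg3$slope, sign(cov(xy[, 1], xy[, 2])) * sqrt(var(xy[, 2]) / var(xy[, 1])))
  expect_equal(abs(dg3$slope), sqrt(vy / vx), tolerance = 0.02 * sqrt(vy / vx) * 3)

  m2 <- m; m2[, 4] <- 5
  expect_error(pair_diagnostics(m2, "a", "d"), "constant")
})

test_that("noise-free proportional columns give slope 1, corr 1 to 1e-9", {
  # proportional abundances: y = c * x  =>  equal clr columns
  set.seed(31)
  x <- rgamma(50, 5); other <- matrix(rgamma(50 * 3, 5), 50, 3)
  comp <- closure(cbind(x, 2.5 * x, other))
  colnames(comp) <- paste0("o", 1:5)
  clr <- clr_transform(comp)
  dg <- pair_diagnostics(clr, "o1", "o2")
  expect_equal(dg$slope, 1, tolerance = 1e-9)
  expect_equal(dg$corr, 1, tolerance = 1e-9)
  expect_equal(rho_from_clr(clr)["o1", "o2"], 1, tolerance = 1e-9)
})

test_that("rho_clusters: chain, size filter, insertion-order invariance", {
  ids <- c("a", "b", "c", "d", "e", "f", "g")
  r <- diag(1, 7); dimnames(r) <- list(ids, ids)
  link <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  r <- link(r, "a", "b", 0.7); r <- link(r, "b", "c", 0.7)  # chain a-b-c
  r <- link(r, "d", "e", 0.7)                               # pair, too small
  r <- link(r, "f", "g", 0.64)                              # below cutoff
  g <- structure(list(rho = r, K = 16, otu_ids = ids), class = "rho_graph")
  cs <- rho_clusters(g, cutoff = 0.65, min_size = 3)
  expect_length(cs$clusters, 1L)
  expect_setequal(cs$clusters[[1]], c("a", "b", "c"))

  # two size-2 components discarded at min_size 3; kept at min_size 2
  cs2 <- rho_clusters(g, cutoff = 0.65, min_size = 2)
  expect_length(cs2$clusters, 2L)

  # relabeling/permutation invariance of membership
  perm <- c(4, 2, 6, 1, 7, 3, 5)
  g_p <- structure(list(rho = r[perm, perm], K = 16, otu_ids = ids[perm]),
                   class = "rho_graph")
  cs_p <- rho_clusters(g_p, cutoff = 0.65, min_size = 3)
  expect_setequal(cs_p$clusters[[1]], c("a", "b", "c"))

  # cutoff is strict: an edge exactly at the cutoff does not count
  r3 <- link(diag(1, 7), 1, 2, 0.65); dimnames(r3) <- list(ids, ids)
  g3 <- structure(list(rho = r3, K = 16, otu_ids = ids), class = "rho_graph")
  expect_length(rho_clusters(g3, cutoff = 0.65, min_size = 2)$clusters, 0L)
})

test_that("planted blocks in generated counts are recovered end to end", {
  b <- generate_table(microcoda:::fixture_spec("blocks"))
  mc <- dirichlet_instances(b$table, K = 16, seed = 4)
  er <- expected_rho(mc)
  cs <- rho_clusters(er, cutoff = 0.65, min_size = 3)
  truth <- b$truth$blocks
  expect_length(cs$clusters, length(truth))
  got <- lapply(cs$clusters, sort)
  for (blk in truth)
    expect_true(any(vapply(got, function(g) setequal(g, blk), logical(1))))
})

test_that("rho_edges mirrors the pair table with diagnostics", {
  b <- generate_table(microcoda:::fixture_spec("blocks"))
  mc <- dirichlet_instances(b$table, K = 8, seed = 4)
  er <- expected_rho(mc)
  clr <- clr_from_counts(b$table)
  edges <- rho_edges(er, clr, cutoff = 0.65)
  expect_true(all(c("otu_i", "otu_j", "rho", "slope", "corr") %in% names(edges)))
  expect_true(all(edges$rho > 0.65))
  expect_true(all(abs(edges$corr) <= 1))
  # edges connect OTUs within the same truth block
  block_of <- rep(seq_along(b$truth$blocks),
                  vapply(b$truth$blocks, length, 1L))
  names(block_of) <- unlist(b$truth$blocks)
  same <- block_of[edges$otu_i] == block_of[edges$otu_j]
  expect_true(all(same[!is.na(same)]))
})
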