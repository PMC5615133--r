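test_that("permanova agrees with vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(rnorm(30 * 6), 30, 6)
  m[1:15, 1] <- m[1:15, 1] + 1.5
  labels <- rep(c("A", "B"), each = 15)
  d <- dist(m)
  ours <- permanova(d, labels, n_permutations = 199, seed = 1)
  va <- vegan::adonis2(d ~ g, data = data.frame(g = labels), permutations = 199)
  expect_equal(ours$pseudo_F, va$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, va$R2[1], tolerance = 1e-10)
})

test_that("permanova: saturated significance and errors", {
  set.seed(5)
  m <- rbind(matrix(rnorm(60), 10), matrix(rnorm(60, mean = 20), 10))
  labels <- rep(c("A", "B"), each = 10)
  res <- permanova(dist(m), labels, n_permutations = 99, seed = 7)
  expect_equal(res$p_value, 1 / 100)
  expect_true(res$R2 > 0.9 && res$R2 <= 1)

  expect_error(permanova(dist(m), rep("A", 20)), "2 groups")
  expect_error(permanova(dist(matrix(0, 4, 3)), rep(c("A", "B"), 2)),
               "degenerate")
  # determinism given seed
  res2 <- permanova(dist(m), labels, n_permutations = 99, seed = 7)
  expect_identical(res$p_value, res2$p_value)
})

test_that("R2 increases along an injected shift ladder", {
  set.seed(11)
  base <- matrix(rnorm(40 * 8), 40, 8)
  labels <- rep(c("A", "B"), each = 20)
  r2s <- sapply(c(0.5, 1.5, 3), function(delta) {
    m <- base; m[labels == "B", 1] <- m[labels == "B", 1] + delta
    permanova(dist(m), labels, n_permutations = 49, seed = 1)$R2
  })
  expect_true(all(diff(r2s) > 0))
})

test_that("pairwise_permanova subsets independently of other groups", {
  set.seed(21)
  m <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 3), 10),
             matrix(rnorm(40, 10), 10))
  labels <- rep(c("A", "B", "C"), each = 10)
  res <- pairwise_permanova(dist(m), labels, n_permutations = 99, seed = 2)
  expect_equal(nrow(res), 3L)
  idx <- labels %in% c("A", "B")
  solo <- permanova(dist(m[idx, ]), labels[idx], n_permutations = 99, seed = 2)
  expect_equal(res$pseudo_F[res$groupA == "A" & res$groupB == "B"],
               solo$pseudo_F, tolerance = 1e-12)
  expect_equal(res$p_value[res$groupA == "A" & res$groupB == "B"], solo$p_value)
})

test_that("group_dispersion: degenerate group, sigma scaling, order invariance", {
  m <- rbind(matrix(1, 5, 4), matrix(rnorm(20), 5, 4))
  rownames(m) <- paste0("s", 1:10)
  class(m) <- c("clr_matrix", "matrix", "array")
  labels <- rep(c("same", "noise"), each = 5)
  disp <- group_dispersion(m, labels)
  expect_equal(disp$MCD[disp$group == "same"], 0)
  expect_equal(disp$IQR[disp$group == "same"], 0)

  set.seed(33)
  n <- 200
  m2 <- rbind(matrix(rnorm(n * 10, sd = 1), n, 10),
              matrix(rnorm(n * 10, sd = 2), n, 10))
  class(m2) <- c("clr_matrix", "matrix", "array")
  lab2 <- rep(c("narrow", "wide"), each = n)
  d2 <- group_dispersion(m2, lab2)
  ratio <- d2$MCD[d2$group == "wide"] / d2$MCD[d2$group == "narrow"]
  expect_equal(ratio, 2, tolerance = 0.1)

  perm <- sample(2 * n)
  m3 <- m2[perm, , drop = FALSE]; class(m3) <- class(m2)
  d3 <- group_dispersion(m3, lab2[perm])
  expect_equal(d3[order(d3$group), ], d2[order(d2$group), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group_dispersion agrees with vegan::betadisper medians", {
  skip_if_not_installed("vegan")
  set.seed(44)
  m <- matrix(rnorm(60 * 5), 60, 5)
  class(m) <- c("clr_matrix", "matrix", "array")
  labels <- rep(c("A", "B", "C"), each = 20)
  ours <- group_dispersion(m, labels)
  bd <- vegan::betadisper(dist(unclass(m)), labels, type = "centroid")
  med <- tapply(bd$distances, labels, median)
  expect_equal(ours$MCD, as.numeric(med[ours$group]), tolerance = 1e-8)
})

test_that("shannon_diversity: closed forms and independent oracle", {
  m <- rbind(rep(7, 10), c(100, rep(0, 9)), c(50, 50, rep(0, 8)))
  dimnames(m) <- list(paste0("s", 1:3), paste0("o", 1:10))
  dp <- shannon_diversity(count_table(m))
  expect_equal(dp$shannon, c(log(10), 0, log(2)))

  tab <- toy_table(8L, 12L, seed = 19L)
  dp2 <- shannon_diversity(tab)
  oracle <- apply(tab$counts, 1, function(r) {
    p <- r[r > 0] / sum(r); -sum(p * log(p))
  })
  expect_equal(dp2$shannon, unname(oracle))
  expect_true(all(dp2$shannon <= log(rowSums(tab$counts > 0)) + 1e-12))
  # invariant to OTU order and depth rescaling of a fixed composition
  m4 <- m[c(1, 3, 2), c(sample(10))]
  rownames(m4) <- paste0("x", 1:3)
  expect_setequal(round(shannon_diversity(count_table(m4))$shannon, 12),
                  round(dp$shannon, 12))
  expect_equal(shannon_diversity(count_table(m * 13))$shannon, dp$shannon)
})

test_that("depth_diversity_check flags forced dependence and respects ranks", {
  set.seed(3)
  depth <- round(exp(rnorm(60, log(2e4), 0.5)))
  prof <- data.frame(depth = depth, shannon = depth / 1e4 + rnorm(60, sd = 0.01))
  chk <- depth_diversity_check(prof, n_permutations = 199, seed = 1)
  expect_true(chk$flag)
  expect_gt(chk$rho, 0.9)
  # rank statistic: invariant under monotone depth rescaling
  prof2 <- prof; prof2$depth <- prof$depth^2 / 1000
  chk2 <- depth_diversity_check(prof2, n_permutations = 199, seed = 1)
  expect_equal(chk$rho, chk2$rho)
  expect_error(depth_diversity_check(prof[1:5, ]), "at least 10")
  expect_error(depth_diversity_check(data.frame(depth = rep(1, 12),
                                                shannon = rnorm(12))),
               "constant")
})

test_that("smooth_age_trend: linear exactness, constants, loess oracle", {
  set.seed(6)
  ages <- sample(3:80, 60, replace = TRUE)
  vals <- 2 + 0.05 * ages
  tr <- smooth_age_trend(vals, ages, span = 0.75)
  expect_lt(max(abs(tr$fit - (2 + 0.05 * tr$age))), 1e-6)

  trc <- smooth_age_trend(rep(3.3, 60), ages)
  expect_equal(trc$fit, rep(3.3, nrow(trc)))

  # cross-implementation oracle: stats::loess degree-1 on a noisy sine
  ages2 <- seq(1, 100, length.out = 300)
  vals2 <- sin(ages2 / 15) + rnorm(300, sd = 0.1)
  tr2 <- smooth_age_trend(vals2, ages2, span = 0.4, grid = seq(10, 90))
  lo <- loess(vals2 ~ ages2, span = 0.4, degree = 1,
              control = loess.control(surface = "direct"))
  pred <- predict(lo, data.frame(ages2 = seq(10, 90)))
  expect_lt(max(abs(tr2$fit - pred)), 0.05)

  expect_error(smooth_age_trend(1:20, rep(5, 20)), "distinct ages")
})
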