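make_mc <- function(tab, K = 16, seed = 1) dirichlet_instances(tab, K = K, seed = seed)

test_that("effect_size: antisymmetry, errors, and spike detection", {
  b <- generate_table(synthetic_spec(n_groups = 2, samples_per_group = 20,
                                     n_otus = 40, seed = 55,
                                     group_shifts = data.frame(group = 2, otu = 5,
                                                               shift = 3)))
  mc <- make_mc(b$table)
  labels <- b$table$metadata$cohort
  ab <- effect_size(mc, labels, c("G1", "G2"), seed = 3)
  ba <- effect_size(mc, labels, c("G2", "G1"), seed = 3)
  expect_equal(ab$effect, -ba$effect)
  expect_equal(ab$diff_btw, -ba$diff_btw)
  expect_equal(ab$diff_win, ba$diff_win)
  expect_true(all(ab$diff_win >= 0))
  expect_true(all(is.finite(ab$effect)))

  # the spiked OTU (shift +3 log2 in G2) has a large positive effect
  spiked <- b$truth$spiked$otu_id[1]
  expect_gte(ab$effect[ab$otu_id == spiked], 1)
  # and dominates the table
  expect_equal(ab$otu_id[which.max(abs(ab$effect))], spiked)

  expect_error(effect_size(mc, labels, c("G1", "nope")), "unknown group")
  labels_bad <- labels; labels_bad[labels_bad == "G2"] <- "G1"
  labels_bad[1] <- "G2"
  expect_error(effect_size(mc, labels_bad, c("G1", "G2")), "at least 2")
})

test_that("effect precision improves with K (across-seed sd shrinks)", {
  b <- generate_table(synthetic_spec(n_groups = 2, samples_per_group = 15,
                                     n_otus = 20, seed = 66))
  sd_at <- function(K) {
    effs <- sapply(1:6, function(s) {
      mc <- dirichlet_instances(b$table, K = K, seed = s)
      effect_size(mc, b$table$metadata$cohort, c("G1", "G2"), seed = 1)$effect
    })
    mean(apply(effs, 1, sd))
  }
  expect_lt(sd_at(64), sd_at(4))
})

test_that("pairwise_effects: combinatorics and declared cohort order", {
  b <- generate_table(synthetic_spec(n_groups = 3, samples_per_group = 8,
                                     n_otus = 15, seed = 77))
  mc <- make_mc(b$table, K = 4)
  labels <- b$table$metadata$cohort
  all_p <- pairwise_effects(mc, labels, "all", seed = 2)
  expect_equal(length(unique(all_p$pair)), 3L)
  succ <- pairwise_effects(mc, labels, "successive",
                           cohort_order = c("G2", "G1", "G3"), seed = 2)
  expect_equal(unique(succ$pair), c("G2 vs G1", "G1 vs G3"))
  # seven ordered cohorts give six successive comparisons
  expect_length(seq_len(7 - 1), 6)
  expect_error(pairwise_effects(mc, labels, "successive",
                                cohort_order = c("G1", "G2", "XX")),
               "permutation")
  # pair list independent of sample order
  perm <- sample(length(labels))
  mc_perm <- mc
  mc_perm$instances <- lapply(mc$instances, function(m) m[perm, , drop = FALSE])
  mc_perm$sample_ids <- mc$sample_ids[perm]
  succ2 <- pairwise_effects(mc_perm, labels[perm], "successive",
                            cohort_order = c("G2", "G1", "G3"), seed = 2)
  expect_equal(unique(succ2$pair), unique(succ$pair))
})

test_that("select_explanatory applies both cuts with reasons", {
  eff <- data.frame(otu_id = rep(c("a", "b", "c", "d"), 2),
                    pair = rep(c("p1", "p2"), each = 4),
                    effect = c(1.2, 0.2, -1.5, 0.3, 0.5, 0.1, 0.2, 0.4),
                    stringsAsFactors = FALSE)
  rho <- structure(list(rho = matrix(c(1, 0.7, 0, 0,
                                       0.7, 1, 0, 0,
                                       0, 0, 1, 0.2,
                                       0, 0, 0.2, 1), 4, 4,
                                     dimnames = list(c("a", "b", "c", "d"),
                                                     c("a", "b", "c", "d"))),
                        K = 16, otu_ids = c("a", "b", "c", "d")),
                   class = "rho_graph")
  sel <- select_explanatory(eff, rho, effect_cut = 1, rho_cut = 0.65)
  expect_setequal(sel$otu_id, c("a", "b", "c"))
  expect_equal(sel$reason[sel$otu_id == "a"], "both")   # effect 1.2 and rho 0.7
  expect_equal(sel$reason[sel$otu_id == "b"], "rho")
  expect_equal(sel$reason[sel$otu_id == "c"], "effect") # |-1.5| >= 1
  expect_false("d" %in% sel$otu_id)

  rho_bad <- rho; rho_bad$rho <- rho$rho[1:3, 1:3]
  expect_error(select_explanatory(eff, rho_bad), "same OTU set")
})

test_that("bin_by_taxon pools unclassified and matches group-by oracle", {
  tax <- parse_lineage(c(o1 = "Bacteria;F;C;O;Fam;Blautia",
                         o2 = "Bacteria;F;C;O;Fam;Blautia",
                         o3 = "Bacteria;B;C;O;Fam;Prevotella",
                         o4 = ""))
  eff <- data.frame(otu_id = rep(c("o1", "o2", "o3", "o4"), 2),
                    pair = rep(c("A vs B", "B vs C"), each = 4),
                    effect = c(0.5, 1.5, -2, 0.1, 0, 0.2, 1.2, -1.1),
                    stringsAsFactors = FALSE)
  out <- bin_by_taxon(eff, tax, rank = "genus")
  expect_setequal(unique(out$effects$bin), c("Blautia", "Prevotella", "unclassified"))
  s <- out$summary
  bl <- s[s$bin == "Blautia" & s$pair == "A vs B", ]
  expect_equal(bl$n_otus, 2L)
  expect_equal(bl$median_effect, median(c(0.5, 1.5)))
  expect_equal(bl$n_above_cut, 1L)
  # all OTUs one genus -> one bin
  tax1 <- parse_lineage(rep("Bacteria;F;C;O;Fam;Blautia", 4),
                        otu_ids = c("o1", "o2", "o3", "o4"))
  out1 <- bin_by_taxon(eff, tax1)
  expect_equal(unique(out1$effects$bin), "Blautia")
  expect_error(bin_by_taxon(eff, tax, rank = "kingdom"))
})
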