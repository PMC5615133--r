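#' Specify a Dirichlet-multinomial synthetic OTU table
#'
#' The generator emulates the structure of a cross-sectional 16S cohort study:
#' a shared base log2 composition with heavy right skew, per-group clr shifts
#' on chosen OTUs (the "spiked" differential signal), blocks of OTUs riding a
#' shared latent log-abundance (true proportional pairs, the rho signal),
#' per-sample biological noise, lognormal read depths, and multinomial
#' counting at finite depth (optionally Dirichlet-overdispersed). Sparsity
#' arises naturally from rare OTUs at finite depth.
#'
#' @param n_groups number of cohorts, default 2.
#' @param samples_per_group samples per cohort (scalar or vector), default 50.
#' @param n_otus number of OTUs, default 200.
#' @param base_log_sd sd of the base log2 composition across OTUs, default 2
#'   (gives a realistic many-rare / few-dominant profile).
#' @param base_log_composition optional explicit base log2 composition vector
#'   (length `n_otus`); overrides `base_log_sd`.
#' @param group_shifts `data.frame(group, otu, shift)` of clr shifts in log2
#'   units (`group` and `otu` are indices), or NULL.
#' @param proportional_blocks list of disjoint OTU index vectors sharing one
#'   latent log2 abundance, or NULL.
#' @param sigma_block sd of the within-block jitter around the shared latent,
#'   default 0.1 log2 units.
#' @param sigma_latent sd of the shared block latent across samples, default
#'   1.5 log2 units (dominates the jitter, so true within-block rho ~ 1).
#' @param sigma_otu sd of the independent per-OTU, per-sample biological
#'   noise, default 0.5 log2 units.
#' @param theta Dirichlet overdispersion precision; `Inf` (default) gives
#'   plain multinomial counting.
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters, defaults
#'   `log(3e4)` and 0.3 (depths ~ 10^4-10^5).
#' @param group_names cohort labels; defaults to the eight age-cohort labels
#'   when `n_groups == 8`, else `G1..Gk`.
#' @param age_ranges list of `c(lo, hi)` ages per group; defaults mirror the
#'   eight-cohort design (3-6, 8-12, 13-14, 19-24, 19-24, 30-50, 60-79,
#'   94-105) when `n_groups == 8`.
#' @param n_genera number of synthetic genera for the taxonomy dressing.
#' @param seed integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_groups = 2L, samples_per_group = 50L, n_otus = 200L,
                           base_log_sd = 2, base_log_composition = NULL,
                           group_shifts = NULL, proportional_blocks = NULL,
                           sigma_block = 0.1, sigma_latent = 1.5,
                           sigma_otu = 0.5, theta = Inf,
                           depth_meanlog = log(3e4), depth_sdlog = 0.3,
                           group_names = NULL, age_ranges = NULL,
                           n_genera = 20L, seed = 1L) {
  if (n_groups < 1L || n_otus < 2L) stop("invalid dimensions", call. = FALSE)
  samples_per_group <- rep_len(samples_per_group, n_groups)
  if (any(samples_per_group < 2L)) stop("need >= 2 samples per group", call. = FALSE)
  if (!is.null(base_log_composition) && length(base_log_composition) != n_otus)
    stop("base_log_composition must have length n_otus", call. = FALSE)
  if (!is.null(group_shifts)) {
    stopifnot(all(c("group", "otu", "shift") %in% names(group_shifts)))
    if (any(!is.finite(group_shifts$shift))) stop("shifts must be finite", call. = FALSE)
    if (any(group_shifts$group > n_groups) || any(group_shifts$otu > n_otus))
      stop("group_shifts index out of range", call. = FALSE)
  }
  if (!is.null(proportional_blocks)) {
    all_idx <- unlist(proportional_blocks)
    if (anyDuplicated(all_idx)) stop("proportional blocks must be disjoint", call. = FALSE)
    if (any(all_idx > n_otus)) stop("block index out of range", call. = FALSE)
  }
  if (is.null(group_names)) {
    group_names <- if (n_groups == 8L) {
      c("kid3-6", "prim8-12", "mid13-14", "you19-24", "ys19-24",
        "mid30-50", "eld60-79", "cent94+")
    } else paste0("G", seq_len(n_groups))
  }
  stopifnot(length(group_names) == n_groups)
  if (is.null(age_ranges)) {
    age_ranges <- if (n_groups == 8L) {
      list(c(3, 6), c(8, 12), c(13, 14), c(19, 24), c(19, 24),
           c(30, 50), c(60, 79), c(94, 105))
    } else {
      lapply(seq_len(n_groups), function(g) {
        lo <- 3 + (g - 1) * floor(92 / n_groups)
        c(lo, lo + max(1, floor(92 / n_groups) - 1))
      })
    }
  }
  structure(list(n_groups = as.integer(n_groups),
                 samples_per_group = as.integer(samples_per_group),
                 n_otus = as.integer(n_otus), base_log_sd = base_log_sd,
                 base_log_composition = base_log_composition,
                 group_shifts = group_shifts,
                 proportional_blocks = proportional_blocks,
                 sigma_block = sigma_block, sigma_latent = sigma_latent,
                 sigma_otu = sigma_otu, theta = theta,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 group_names = group_names, age_ranges = age_ranges,
                 n_genera = as.integer(n_genera), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic count table with known truth
#'
#' Per sample: base log2 composition + its group's clr shifts + block latents
#' + independent noise, closed to a probability vector, optionally
#' Dirichlet-perturbed with precision `theta`, then a multinomial draw at a
#' lognormal depth. Fully deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (a `count_table` with metadata and synthetic
#'   taxonomy), `truth` (spiked OTU table, block memberships, per-group
#'   expected log2 compositions) and `spec`.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    D <- spec$n_otus
    base <- if (is.null(spec$base_log_composition))
      stats::rnorm(D, 0, spec$base_log_sd) else spec$base_log_composition
    shift_mat <- matrix(0, spec$n_groups, D)
    if (!is.null(spec$group_shifts))
      shift_mat[cbind(spec$group_shifts$group, spec$group_shifts$otu)] <-
        spec$group_shifts$shift
    in_block <- rep(0L, D)
    for (b in seq_along(spec$proportional_blocks))
      in_block[spec$proportional_blocks[[b]]] <- b

    n <- sum(spec$samples_per_group)
    group_of <- rep(seq_len(spec$n_groups), spec$samples_per_group)
    counts <- matrix(0, n, D)
    expected <- matrix(0, spec$n_groups, D)
    for (g in seq_len(spec$n_groups))
      expected[g, ] <- base + shift_mat[g, ]

    depth <- pmax(100, round(stats::rlnorm(n, spec$depth_meanlog, spec$depth_sdlog)))
    for (s in seq_len(n)) {
      g <- group_of[s]
      lam <- base + shift_mat[g, ]
      eps <- stats::rnorm(D, 0, spec$sigma_otu)
      for (b in seq_along(spec$proportional_blocks)) {
        members <- spec$proportional_blocks[[b]]
        u <- stats::rnorm(1L, 0, spec$sigma_latent)
        eps[members] <- u + stats::rnorm(length(members), 0, spec$sigma_block)
      }
      lam <- lam + eps
      p <- 2^(lam - max(lam))
      p <- p / sum(p)
      if (is.finite(spec$theta)) {
        gdraw <- stats::rgamma(D, shape = spec$theta * p)
        p <- gdraw / sum(gdraw)
      }
      counts[s, ] <- stats::rmultinom(1L, size = depth[s], prob = p)
    }
    otu_ids <- sprintf("otu_%03d", seq_len(D))
    sample_ids <- sprintf("s%04d", seq_len(n))
    dimnames(counts) <- list(sample_ids, otu_ids)

    ages <- vapply(seq_len(n), function(s) {
      r <- spec$age_ranges[[group_of[s]]]
      sample(seq(r[1L], r[2L]), 1L)
    }, numeric(1L))
    meta <- data.frame(sample_id = sample_ids, age = ages,
                       cohort = spec$group_names[group_of],
                       sex = sample(c("F", "M"), n, replace = TRUE),
                       site = "synthetic", stringsAsFactors = FALSE)
    tax <- synthetic_taxonomy(otu_ids, spec$n_genera)

    keep <- colSums(counts) > 0  # an all-zero OTU cannot enter the container
    truth <- list(
      spiked = if (is.null(spec$group_shifts))
        data.frame(group = character(), otu_id = character(), shift = numeric(),
                   stringsAsFactors = FALSE)
      else data.frame(group = spec$group_names[spec$group_shifts$group],
                      otu_id = otu_ids[spec$group_shifts$otu],
                      shift = spec$group_shifts$shift, stringsAsFactors = FALSE),
      blocks = lapply(spec$proportional_blocks, function(b) otu_ids[b]),
      expected_log2 = `dimnames<-`(expected, list(spec$group_names, otu_ids)),
      dropped_empty_otus = otu_ids[!keep])
    tab <- count_table(counts[, keep, drop = FALSE],
                       taxonomy = tax[keep, , drop = FALSE], metadata = meta)
    list(table = tab, truth = truth, spec = spec)
  })
}

synthetic_taxonomy <- function(otu_ids, n_genera) {
  D <- length(otu_ids)
  genus_of <- sample.int(n_genera, D, replace = TRUE)
  # a fraction of OTUs stays unclassified at genus, as in real 16S data
  unclass_mask <- stats::runif(D) < 0.15
  phyla <- paste0("Phylum", ((genus_of - 1L) %% 4L) + 1L)
  lin <- sprintf("Bacteria;%s;Class%d;Order%d;Family%d;Genus%d",
                 phyla, genus_of, genus_of, genus_of, genus_of)
  lin[unclass_mask] <- sprintf("Bacteria;%s", phyla[unclass_mask])
  parse_lineage(lin, otu_ids = otu_ids)
}

#' Write a named fixture bundle to disk
#'
#' Each fixture is a frozen-seed call to [generate_table()] written as the
#' same TSV formats the I/O layer reads: `counts.tsv` (canonical orientation
#' with a taxonomy column), `metadata.tsv`, `truth_spiked.tsv`,
#' `truth_blocks.tsv`.
#'
#' Fixtures: `tiny` (12 x 20 smoke table), `null` (2 exchangeable groups of
#' 50, depth ~1e4, 100 OTUs), `spiked` (one OTU shifted +3 log2 units),
#' `blocks` (three proportional blocks), `cohort_like` (8 cohorts, 1,000
#' samples, 600 OTUs at reduced depth).
#'
#' @param name fixture name.
#' @param dir output directory (created if needed).
#' @return The [generate_table()] bundle, invisibly, with `$dir` added.
#' @export
make_fixture <- function(name = c("tiny", "null", "spiked", "blocks", "cohort_like"),
                         dir = tempfile(paste0("fixture_", name[1L]))) {
  name <- match.arg(name)
  spec <- fixture_spec(name)
  bundle <- generate_table(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(bundle$table, file.path(dir, "counts.tsv"))
  utils::write.table(bundle$table$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$spiked, file.path(dir, "truth_spiked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  blocks_df <- if (length(bundle$truth$blocks) > 0L)
    do.call(rbind, lapply(seq_along(bundle$truth$blocks), function(i)
      data.frame(block = i, otu_id = bundle$truth$blocks[[i]],
                 stringsAsFactors = FALSE)))
  else data.frame(block = integer(), otu_id = character(), stringsAsFactors = FALSE)
  utils::write.table(blocks_df, file.path(dir, "truth_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$dir <- dir
  invisible(bundle)
}

fixture_spec <- function(name) {
  switch(name,
    tiny = synthetic_spec(n_groups = 2L, samples_per_group = 6L, n_otus = 20L,
                          depth_meanlog = log(2000), seed = 101L),
    null = synthetic_spec(n_groups = 2L, samples_per_group = 50L, n_otus = 100L,
                          depth_meanlog = log(1e4), depth_sdlog = 0,
                          seed = 202L),
    spiked = synthetic_spec(n_groups = 2L, samples_per_group = 50L,
                            n_otus = 100L, depth_meanlog = log(1e4),
                            depth_sdlog = 0,
                            group_shifts = data.frame(group = 2L, otu = 10L,
                                                      shift = 3),
                            seed = 303L),
    blocks = synthetic_spec(n_groups = 2L, samples_per_group = 200L,
                            n_otus = 60L,
                            base_log_composition = rep(seq(-2, 2, length.out = 12), 5),
                            proportional_blocks = list(1:4, 11:14, 21:24),
                            seed = 404L),
    cohort_like = synthetic_spec(n_groups = 8L,
                                 samples_per_group = 125L, n_otus = 600L,
                                 depth_meanlog = log(2000), seed = 505L))
}
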