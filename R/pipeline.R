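#' Validate a flat key:value pipeline configuration
#'
#' Reads a plain-text config of `key: value` lines (lines starting with `#`
#' ignored), injects defaults for anything missing, checks every invariant,
#' and aggregates all errors into one message. The same checks run when a
#' config is supplied as a named list.
#'
#' Recognized keys and defaults: `counts` (path, required), `metadata` (path,
#' optional), `out_dir` (required for [run_pipeline()]), `K` 128, `prior` 0.5,
#' `seed` 1, `log_base` 2, `min_prop_any` 0.001, `min_prev` 0.2, `pairs`
#' successive, `effect_cut` 1, `rho_cut` 0.65, `cluster_min_size` 3,
#' `permutations` 999, `cohort_order` (comma-separated, optional), `span`
#' 0.75.
#'
#' @param config path to a config file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    lines <- readLines(config)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", lines))
    bad <- vapply(kv, length, 1L) != 3L
    if (any(bad)) stop("unparseable config line(s): ",
                       paste(lines[bad], collapse = " | "), call. = FALSE)
    config <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  }
  defaults <- list(K = 128, prior = 0.5, seed = 1, log_base = 2,
                   min_prop_any = 0.001, min_prev = 0.2, pairs = "successive",
                   effect_cut = 1, rho_cut = 0.65, cluster_min_size = 3,
                   permutations = 999, span = 0.75,
                   metadata = NULL, cohort_order = NULL, out_dir = NULL)
  unknown <- setdiff(names(config), c("counts", names(defaults)))
  errs <- character()
  if (length(unknown) > 0L)
    errs <- c(errs, paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[names(config) %in% c("counts", names(defaults))])
  num_keys <- c("K", "prior", "seed", "log_base", "min_prop_any", "min_prev",
                "effect_cut", "rho_cut", "cluster_min_size", "permutations", "span")
  for (k in num_keys) cfg[[k]] <- suppressWarnings(as.numeric(cfg[[k]]))
  if (is.null(cfg$counts)) errs <- c(errs, "missing required key: counts")
  if (any(is.na(unlist(cfg[num_keys])))) errs <- c(errs, "non-numeric numeric key")
  else {
    if (cfg$K < 2) errs <- c(errs, "K must be >= 2")
    if (cfg$prior <= 0) errs <- c(errs, "prior must be positive")
    if (cfg$effect_cut <= 0) errs <- c(errs, "effect_cut must be positive")
    if (cfg$rho_cut <= 0 || cfg$rho_cut >= 1)
      errs <- c(errs, "rho_cut must lie in (0, 1)")
    if (cfg$cluster_min_size < 2) errs <- c(errs, "cluster_min_size must be >= 2")
    if (cfg$permutations < 1) errs <- c(errs, "permutations must be >= 1")
    if (!cfg$pairs %in% c("successive", "all"))
      errs <- c(errs, "pairs must be 'successive' or 'all'")
  }
  if (is.character(cfg$cohort_order) && length(cfg$cohort_order) == 1L)
    cfg$cohort_order <- trimws(strsplit(cfg$cohort_order, ",")[[1L]])
  if (length(errs) > 0L)
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full compositional analysis pipeline
#'
#' Stages: read + join -> abundance/prevalence filter -> CZM + clr -> Dirichlet
#' Monte-Carlo instances -> compositional PCA (full set and subset-reclosure
#' PCA on the selected OTUs) -> pairwise effect sizes -> expected rho +
#' threshold clusters -> explanatory-OTU selection -> PERMANOVA + dispersion
#' -> Shannon diversity + depth check. All numeric artifacts are written as
#' TSV under `out_dir`, figures as PNG, and a `provenance.json` records the
#' seed, stage seeds, package version and config.
#'
#' @param config a `pipeline_config`, config file path, or named list.
#' @return List of in-memory results (invisibly); side effect: `out_dir`
#'   populated.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(..., collapse = " ")))
  }

  log_stage("read", cfg$counts)
  tab <- read_count_table(cfg$counts)
  if (!is.null(cfg$metadata)) {
    meta <- read_sample_metadata(cfg$metadata)
    tab <- join_metadata(tab, meta, policy = "intersect")
  }
  if (is.null(tab$metadata)) stop("pipeline requires sample metadata (cohort labels)",
                                  call. = FALSE)
  labels <- tab$metadata$cohort
  cohort_order <- if (!is.null(cfg$cohort_order)) cfg$cohort_order else
    sort(unique(labels))
  if (!setequal(cohort_order, unique(labels)))
    stop("cohort_order does not match metadata cohorts: ",
         paste(setdiff(cohort_order, unique(labels)), collapse = ", "), call. = FALSE)

  log_stage("filter", sprintf("%d OTUs in", ncol(tab$counts)))
  tab <- filter_otus(tab, filter_spec(min_prop_any = cfg$min_prop_any,
                                      min_prevalence = cfg$min_prev))
  report <- attr(tab, "filter_report")
  utils::write.table(report, file.path(cfg$out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("clr", sprintf("%d OTUs retained", ncol(tab$counts)))
  clr <- clr_from_counts(tab, prior_mass = cfg$prior, log_base = cfg$log_base)
  mc <- dirichlet_instances(tab, K = cfg$K, prior_mass = cfg$prior,
                            seed = derive_seed(cfg$seed, "dirichlet"),
                            log_base = cfg$log_base)

  log_stage("pca")
  pca <- compositional_pca(clr)
  write_pca <- function(p, prefix) {
    utils::write.table(data.frame(sample_id = rownames(p$scores), p$scores[, 1:2]),
                       file.path(cfg$out_dir, paste0(prefix, "_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(otu_id = rownames(p$loadings), p$loadings[, 1:2]),
                       file.path(cfg$out_dir, paste0(prefix, "_loadings.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(component = seq_along(p$variance_fraction),
                                  variance_fraction = p$variance_fraction),
                       file.path(cfg$out_dir, paste0(prefix, "_variance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_pca(pca, "pca_full")

  log_stage("effects", cfg$pairs)
  eff <- pairwise_effects(mc, labels, pairs = cfg$pairs,
                          cohort_order = cohort_order,
                          seed = derive_seed(cfg$seed, "effects"))
  utils::write.table(eff, file.path(cfg$out_dir, "effect_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("rho")
  rho <- expected_rho(mc)
  edges <- rho_edges(rho, clr, cutoff = cfg$rho_cut)
  utils::write.table(edges, file.path(cfg$out_dir, "rho_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- rho_clusters(rho, cutoff = cfg$rho_cut,
                           min_size = cfg$cluster_min_size,
                           taxonomy = tab$taxonomy)
  utils::write.table(clusters$members, file.path(cfg$out_dir, "rho_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("select")
  sel <- select_explanatory(eff, rho, effect_cut = cfg$effect_cut,
                            rho_cut = cfg$rho_cut)
  utils::write.table(sel, file.path(cfg$out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pca_sub <- NULL
  if (nrow(sel) >= 3L) {
    clr_sub <- subset_reclosure_clr(tab, sel$otu_id, prior_mass = cfg$prior,
                                    log_base = cfg$log_base)
    pca_sub <- compositional_pca(clr_sub)
    write_pca(pca_sub, "pca_selected")
  }

  log_stage("permanova")
  d <- stats::dist(unclass(clr))
  pm <- permanova(d, labels, n_permutations = cfg$permutations,
                  seed = derive_seed(cfg$seed, "permanova"))
  ppm <- pairwise_permanova(d, labels, pairs = "all",
                            n_permutations = cfg$permutations,
                            seed = derive_seed(cfg$seed, "pairwise_permanova"))
  disp <- group_dispersion(clr, labels)
  s1 <- merge(ppm, disp, by.x = "groupA", by.y = "group", all.x = TRUE)
  s1 <- s1[order(match(s1$groupA, cohort_order), match(s1$groupB, cohort_order)), ]
  last <- disp[disp$group == cohort_order[length(cohort_order)], , drop = FALSE]
  if (nrow(last) == 1L)  # placeholder row so every group's dispersion appears
    s1 <- rbind(s1, data.frame(groupA = last$group, groupB = NA, pseudo_F = NA,
                               R2 = NA, p_value = NA, n = last$n,
                               MCD = last$MCD, IQR = last$IQR))
  utils::write.table(s1, file.path(cfg$out_dir, "permanova_dispersion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("diversity")
  div <- shannon_diversity(tab)
  utils::write.table(div, file.path(cfg$out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  depth_check <- depth_diversity_check(div, n_permutations = cfg$permutations,
                                       seed = derive_seed(cfg$seed, "depthcheck"))
  trend <- if (length(unique(div$age)) >= 3L)
    smooth_age_trend(div$shannon, div$age, span = cfg$span) else NULL
  if (!is.null(trend))
    utils::write.table(trend, file.path(cfg$out_dir, "diversity_trend.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("figures")
  pipeline_figures(cfg$out_dir, labels_by_sample = stats::setNames(labels, tab$metadata$sample_id))

  prov <- list(package = "microcoda",
               version = as.character(utils::packageVersion("microcoda")),
               seed = cfg$seed,
               stage_seeds = list(dirichlet = derive_seed(cfg$seed, "dirichlet"),
                                  effects = derive_seed(cfg$seed, "effects"),
                                  permanova = derive_seed(cfg$seed, "permanova")),
               config = cfg[!vapply(cfg, is.null, TRUE)],
               n_samples = nrow(tab$counts), n_otus = ncol(tab$counts))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = tab, clr = clr, pca = pca, pca_selected = pca_sub,
                 effects = eff, rho = rho, clusters = clusters, selection = sel,
                 permanova = pm, pairwise_permanova = ppm, dispersion = disp,
                 diversity = div, depth_check = depth_check, trend = trend))
}

# figures are rebuilt from the written TSVs, never from in-memory state
pipeline_figures <- function(out_dir, labels_by_sample) {
  scores_path <- file.path(out_dir, "pca_full_scores.tsv")
  var_path <- file.path(out_dir, "pca_full_variance.tsv")
  if (file.exists(scores_path)) {
    sc <- utils::read.delim(scores_path)
    vf <- utils::read.delim(var_path)$variance_fraction
    grp <- factor(labels_by_sample[sc$sample_id])
    grDevices::png(file.path(out_dir, "biplot_samples.png"), 900, 900, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
    graphics::plot(sc$PC1, sc$PC2, col = cols[grp], pch = 19, cex = 0.6,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * vf[2]),
                   main = "Compositional PCA (75% normal-theory ellipses)")
    for (g in seq_len(nlevels(grp))) {
      pts <- cbind(sc$PC1, sc$PC2)[as.integer(grp) == g, , drop = FALSE]
      ell <- data_ellipse(pts, 0.75)
      if (!is.null(ell)) graphics::lines(ell, col = cols[g])
    }
    graphics::legend("topright", legend = levels(grp), col = cols, pch = 19,
                     cex = 0.7)
  }
  eff_path <- file.path(out_dir, "effect_table.tsv")
  if (file.exists(eff_path)) {
    eff <- utils::read.delim(eff_path)
    grDevices::png(file.path(out_dir, "effect_strips.png"), 900, 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    pr <- factor(eff$pair, levels = unique(eff$pair))
    graphics::stripchart(effect ~ pr, data = eff, vertical = TRUE, pch = 19,
                         cex = 0.5, method = "jitter", las = 2,
                         col = ifelse(abs(eff$effect) >= 1, "firebrick", "grey50"),
                         ylab = "expected effect size (log2)")
    graphics::abline(h = c(-1, 1), lty = 2)
  }
  trend_path <- file.path(out_dir, "diversity_trend.tsv")
  div_path <- file.path(out_dir, "diversity.tsv")
  if (file.exists(trend_path) && file.exists(div_path)) {
    div <- utils::read.delim(div_path)
    tr <- utils::read.delim(trend_path)
    grDevices::png(file.path(out_dir, "diversity_age.png"), 900, 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(div$age, div$shannon, pch = 19, cex = 0.5, col = "grey60",
                   xlab = "age (years)", ylab = "Shannon diversity (nats)")
    graphics::lines(tr$age, tr$fit, lwd = 2)
  }
}
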