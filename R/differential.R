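#' Expected standardized effect size between two groups
#'
#' For each Dirichlet Monte-Carlo instance, samples from the two groups are
#' paired by independent uniform resampling with replacement (equalizing
#' unequal group sizes); per OTU the instance statistic is the median of the
#' paired between-group clr differences divided by the elementwise maximum of
#' the two within-group absolute differences:
#' `effect_k(j) = median( (x_B - x_A) / max(|x_A - x_A'|, |x_B - x_B'|) )`.
#' The reported `effect`, `diff_btw` (median between-group difference) and
#' `diff_win` (median within-group dispersion) are arithmetic means over the
#' instances — expected values of the test statistic. An `|effect| >= 1` means
#' the between-group difference reliably exceeds the within-group dispersion.
#'
#' Antisymmetry contract: the computation runs on the alphabetically sorted
#' pair and the sign is flipped if the requested order differs, so swapping
#' `(A, B)` negates `effect` and `diff_btw` exactly.
#'
#' @param mc an `mc_instances`.
#' @param labels group label per sample (aligned with `mc$sample_ids`).
#' @param pair character vector of two group labels `c(A, B)`; positive
#'   effects mean higher clr abundance in `B`.
#' @param n_resample number of resampled pairs per instance; default
#'   `max(nA, nB)`.
#' @param seed integer seed for the resampling.
#' @return `data.frame` with columns `otu_id`, `groupA`, `groupB`, `pair`,
#'   `diff_btw`, `diff_win`, `effect`.
#' @export
effect_size <- function(mc, labels, pair, n_resample = NULL, seed = 1) {
  stopifnot(inherits(mc, "mc_instances"), length(pair) == 2L)
  labels <- as.character(labels)
  if (length(labels) != length(mc$sample_ids))
    stop("labels must align with mc$sample_ids", call. = FALSE)
  if (!all(pair %in% labels))
    stop("unknown group label: ", paste(setdiff(pair, labels), collapse = ", "),
         call. = FALSE)
  flip <- pair[1L] > pair[2L]
  sp <- sort(pair)
  ia <- which(labels == sp[1L]); ib <- which(labels == sp[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  R <- if (is.null(n_resample)) max(length(ia), length(ib)) else as.integer(n_resample)

  D <- length(mc$otu_ids)
  acc_z <- acc_w <- acc_e <- numeric(D)
  with_seed(seed, {
    for (k in seq_len(mc$K)) {
      X <- unclass(mc$instances[[k]])
      iA <- resample_pairs(ia, R); iB <- resample_pairs(ib, R)
      z <- X[iB$first, , drop = FALSE] - X[iA$first, , drop = FALSE]
      w <- pmax(abs(X[iA$first, , drop = FALSE] - X[iA$second, , drop = FALSE]),
                abs(X[iB$first, , drop = FALSE] - X[iB$second, , drop = FALSE]))
      acc_z <- acc_z + col_medians(z)
      acc_w <- acc_w + col_medians(w)
      acc_e <- acc_e + col_medians(z / w)
    }
  })
  sgn <- if (flip) -1 else 1
  data.frame(otu_id = mc$otu_ids,
             groupA = pair[1L], groupB = pair[2L],
             pair = paste(pair[1L], "vs", pair[2L]),
             diff_btw = sgn * acc_z / mc$K,
             diff_win = acc_w / mc$K,
             effect = sgn * acc_e / mc$K,
             stringsAsFactors = FALSE, row.names = NULL)
}

# draw R indices (first) and R distinct partners (second) from idx, uniformly
# with replacement; partners are forced to differ so within-group differences
# are never identically zero
resample_pairs <- function(idx, R) {
  first <- idx[sample.int(length(idx), R, replace = TRUE)]
  second <- idx[sample.int(length(idx), R, replace = TRUE)]
  clash <- which(second == first)
  while (length(clash) > 0L) {
    second[clash] <- idx[sample.int(length(idx), length(clash), replace = TRUE)]
    clash <- clash[second[clash] == first[clash]]
  }
  list(first = first, second = second)
}

col_medians <- function(m) apply(m, 2L, stats::median)

#' Effect sizes for successive or all group pairs
#'
#' @param mc an `mc_instances`.
#' @param labels group label per sample.
#' @param pairs `"successive"` (adjacent pairs in `cohort_order`, as in an
#'   ordered age-cohort design) or `"all"` (every unordered pair).
#' @param cohort_order declared ordering of the cohort labels; defaults to
#'   `sort(unique(labels))`. Must be a permutation of the observed labels.
#' @param seed integer seed.
#' @param n_resample see [effect_size()].
#' @return Long `data.frame`, one block of rows per pair (class
#'   `effect_table`).
#' @export
pairwise_effects <- function(mc, labels, pairs = c("successive", "all"),
                             cohort_order = NULL, seed = 1, n_resample = NULL) {
  pairs <- match.arg(pairs)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(cohort_order)) cohort_order <- sort(groups)
  if (!setequal(cohort_order, groups))
    stop("cohort_order must be a permutation of the observed labels", call. = FALSE)
  pl <- if (pairs == "successive") {
    lapply(seq_len(length(cohort_order) - 1L),
           function(i) cohort_order[c(i, i + 1L)])
  } else {
    utils::combn(cohort_order, 2L, simplify = FALSE)
  }
  out <- do.call(rbind, lapply(pl, function(p)
    effect_size(mc, labels, p, n_resample = n_resample, seed = seed)))
  class(out) <- c("effect_table", class(out))
  out
}

#' Select explanatory OTUs by effect size or compositional association
#'
#' An OTU is retained if its absolute expected effect size reaches
#' `effect_cut` in any group-pair comparison, or if it belongs to at least one
#' OTU pair with expected rho above `rho_cut`.
#'
#' @param eff an effect table from [pairwise_effects()].
#' @param rho a `rho_graph` from [expected_rho()] on the same OTU set.
#' @param effect_cut effect threshold (inclusive), default 1.
#' @param rho_cut rho threshold (strict), default 0.65.
#' @return `data.frame` with columns `otu_id`, `reason` (`effect`, `rho` or
#'   `both`), `max_abs_effect`, `max_rho`.
#' @export
select_explanatory <- function(eff, rho, effect_cut = 1, rho_cut = 0.65) {
  stopifnot(inherits(rho, "rho_graph"))
  otus <- unique(eff$otu_id)
  if (!setequal(otus, rownames(rho$rho)))
    stop("effect table and rho graph must cover the same OTU set", call. = FALSE)
  max_eff <- tapply(abs(eff$effect), eff$otu_id, max)[otus]
  rm_ <- rho$rho[otus, otus]
  diag(rm_) <- NA
  max_rho <- apply(rm_, 1L, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  by_eff <- !is.na(max_eff) & max_eff >= effect_cut
  by_rho <- max_rho > rho_cut
  keep <- by_eff | by_rho
  reason <- ifelse(by_eff & by_rho, "both", ifelse(by_eff, "effect", "rho"))
  data.frame(otu_id = otus[keep], reason = reason[keep],
             max_abs_effect = as.numeric(max_eff[keep]),
             max_rho = as.numeric(max_rho[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bin effect-size rows by taxonomic rank
#'
#' Annotates each effect row with the taxon bin of its OTU (unclassified OTUs
#' pooled into one bin) and summarizes per bin and pair.
#'
#' @param eff an effect table.
#' @param tax taxonomy `data.frame` from [parse_lineage()].
#' @param rank one of phylum, class, family, genus (order accepted too).
#' @param effect_cut threshold used for the per-bin exceedance count.
#' @return List with `effects` (annotated long table) and `summary`
#'   (`bin`, `pair`, `n_otus`, `median_effect`, `n_above_cut`).
#' @export
bin_by_taxon <- function(eff, tax, rank = "genus", effect_cut = 1) {
  bins <- taxon_bins(tax, rank = rank)
  missing <- setdiff(unique(eff$otu_id), names(bins))
  if (length(missing) > 0L)
    stop("OTUs missing from taxonomy: ", paste(utils::head(missing, 5L),
                                               collapse = ", "), call. = FALSE)
  ann <- eff
  ann$bin <- unname(bins[ann$otu_id])
  agg <- do.call(rbind, lapply(split(ann, list(ann$bin, ann$pair), drop = TRUE),
    function(d) data.frame(bin = d$bin[1L], pair = d$pair[1L],
                           n_otus = nrow(d),
                           median_effect = stats::median(d$effect),
                           n_above_cut = sum(abs(d$effect) >= effect_cut),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(effects = ann, summary = agg)
}
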