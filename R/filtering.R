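#' Specify abundance/prevalence OTU filters
#'
#' The default thresholds retain OTUs whose relative abundance exceeds 0.1% in
#' at least one sample (strict `>`) and that are present (count > 0) in at
#' least 20% of samples (inclusive `>=`). The optional band bounds implement
#' robustness filters: `min_prop_any_strict` drops OTUs that never exceed a
#' higher floor (e.g. 1%), `max_prop_any` drops OTUs that ever exceed a
#' ceiling (e.g. 2%).
#'
#' @param min_prop_any minimum relative abundance required in at least one
#'   sample (strict), default 0.001.
#' @param min_prevalence minimum fraction of samples with a positive count
#'   (inclusive), default 0.2.
#' @param max_prop_any optional ceiling on per-sample relative abundance.
#' @param min_prop_any_strict optional higher abundance floor (band filter).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_prop_any = 0.001, min_prevalence = 0.2,
                        max_prop_any = NULL, min_prop_any_strict = NULL) {
  for (v in list(min_prop_any, min_prevalence, max_prop_any, min_prop_any_strict))
    if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1))
      stop("filter fractions must lie in [0, 1]", call. = FALSE)
  if (!is.null(max_prop_any) && !is.null(min_prop_any_strict) &&
      min_prop_any_strict >= max_prop_any)
    stop("min_prop_any_strict must be < max_prop_any", call. = FALSE)
  structure(list(min_prop_any = min_prop_any, min_prevalence = min_prevalence,
                 max_prop_any = max_prop_any,
                 min_prop_any_strict = min_prop_any_strict),
            class = "filter_spec")
}

#' Apply abundance/prevalence filters to the OTUs of a count table
#'
#' Proportions are computed against each sample's original (pre-filter) read
#' depth, so the retained set does not depend on the order in which filters
#' are applied. Samples are never removed.
#'
#' @param x a `count_table` with positive depths.
#' @param spec a [filter_spec()].
#' @return The filtered `count_table`, with a `filter_report` attribute: a
#'   `data.frame` of removed OTUs and the reason (`abundance`, `prevalence`,
#'   `band_low`, `band_high`).
#' @export
filter_otus <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "count_table"), inherits(spec, "filter_spec"))
  d <- depths(x)
  if (any(d <= 0)) stop("all samples must have positive depth", call. = FALSE)
  prop <- x$counts / d
  max_prop <- apply(prop, 2L, max)
  prevalence <- colMeans(x$counts > 0)

  reason <- rep(NA_character_, ncol(x$counts))
  reason[max_prop <= spec$min_prop_any] <- "abundance"
  reason[is.na(reason) & prevalence < spec$min_prevalence] <- "prevalence"
  if (!is.null(spec$min_prop_any_strict))
    reason[is.na(reason) & max_prop <= spec$min_prop_any_strict] <- "band_low"
  if (!is.null(spec$max_prop_any))
    reason[is.na(reason) & max_prop > spec$max_prop_any] <- "band_high"

  report <- data.frame(otu_id = colnames(x$counts)[!is.na(reason)],
                       reason = reason[!is.na(reason)],
                       stringsAsFactors = FALSE)
  keep <- is.na(reason)
  if (sum(keep) == 0L) {
    cond <- simpleError("filter spec removes all OTUs")
    cond$report <- report
    stop(cond)
  }
  if (sum(keep) < 2L)
    stop("filter spec leaves fewer than 2 OTUs", call. = FALSE)
  out <- subset_table(x, otus = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is 0 or 1.
#'
#' @param x a `count_table`.
#' @return A `count_table` without singleton OTUs.
#' @export
drop_singletons <- function(x) {
  stopifnot(inherits(x, "count_table"))
  keep <- colSums(x$counts) > 1
  if (sum(keep) < 2L) stop("fewer than 2 OTUs left after dropping singletons",
                           call. = FALSE)
  if (all(keep)) return(x)
  subset_table(x, otus = which(keep))
}
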