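#' Construct a validated OTU count table
#'
#' The central container of the package: an integer matrix of read counts with
#' samples in rows and OTUs in columns, optionally carrying a taxonomy table
#' and per-sample metadata. Per-sample read depth is always derived as the row
#' sum, never stored.
#'
#' @param counts integer matrix, samples x OTUs, with unique row and column
#'   names. Non-negative; at least 2 samples and 2 OTUs.
#' @param taxonomy optional taxonomy `data.frame` as returned by
#'   [parse_lineage()], with one row per OTU.
#' @param metadata optional per-sample metadata `data.frame` with columns
#'   `sample_id`, `age`, `cohort`, and optionally `sex` and `site`.
#' @return An object of class `count_table`.
#' @seealso [read_count_table()], [join_metadata()]
#' @export
count_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names", call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 samples and 2 OTUs", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values", call. = FALSE)
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
         call. = FALSE)
  bad <- which(counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
         call. = FALSE)
  storage.mode(counts) <- "double"  # keeps exactness, avoids integer overflow on sums
  if (!is.null(taxonomy)) taxonomy <- validate_taxonomy(taxonomy, colnames(counts))
  if (!is.null(metadata)) metadata <- validate_metadata(metadata, rownames(counts))
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs\n", nrow(x$counts), ncol(x$counts)))
  d <- depths(x)
  cat(sprintf("  read depth: median %.0f [%.0f, %.0f]\n",
              stats::median(d), min(d), max(d)))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$counts == 0)))
  if (!is.null(x$taxonomy)) cat("  taxonomy: attached\n")
  if (!is.null(x$metadata))
    cat(sprintf("  metadata: %s\n", paste(setdiff(names(x$metadata), "sample_id"),
                                          collapse = ", ")))
  invisible(x)
}

#' Per-sample read depth
#'
#' @param x a `count_table`.
#' @return Named numeric vector of row sums.
#' @export
depths <- function(x) {
  stopifnot(inherits(x, "count_table"))
  rowSums(x$counts)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by samples and/or OTUs
#'
#' Taxonomy and metadata are subset consistently; depth is re-derived.
#'
#' @param x a `count_table`.
#' @param samples,otus character, integer or logical index into samples / OTUs.
#' @return A `count_table`.
#' @export
subset_table <- function(x, samples = NULL, otus = NULL) {
  stopifnot(inherits(x, "count_table"))
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[match(colnames(counts), tax$otu_id), , drop = FALSE]
  meta <- x$metadata
  if (!is.null(meta)) meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  count_table(counts, taxonomy = tax, metadata = meta)
}

validate_metadata <- function(meta, sample_ids) {
  meta <- as.data.frame(meta)
  req <- c("sample_id", "age", "cohort")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  unmatched <- setdiff(sample_ids, meta$sample_id)
  if (length(unmatched) > 0L)
    stop("samples without metadata: ", paste(utils::head(unmatched, 5L), collapse = ", "),
         call. = FALSE)
  if (any(!is.na(meta$age) & meta$age < 0))
    stop("age must be >= 0", call. = FALSE)
  if (!"sex" %in% names(meta)) meta$sex <- "unknown"
  meta$sex[!meta$sex %in% c("F", "M")] <- "unknown"
  if (!"site" %in% names(meta)) meta$site <- NA_character_
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

validate_taxonomy <- function(tax, otu_ids) {
  tax <- as.data.frame(tax)
  if (!"otu_id" %in% names(tax)) stop("taxonomy missing 'otu_id' column", call. = FALSE)
  tax$otu_id <- as.character(tax$otu_id)
  missing_otus <- setdiff(otu_ids, tax$otu_id)
  if (length(missing_otus) > 0L) {
    # OTUs absent from the taxonomy are unclassified at all ranks
    fill <- as.data.frame(matrix("unclassified", nrow = length(missing_otus),
                                 ncol = length(tax_ranks()),
                                 dimnames = list(NULL, tax_ranks())))
    fill <- cbind(data.frame(otu_id = missing_otus, stringsAsFactors = FALSE), fill)
    tax <- rbind(tax[, c("otu_id", tax_ranks())], fill)
  }
  tax <- tax[match(otu_ids, tax$otu_id), c("otu_id", tax_ranks()), drop = FALSE]
  rownames(tax) <- NULL
  tax
}

tax_ranks <- function() c("domain", "phylum", "class", "order", "family", "genus")
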