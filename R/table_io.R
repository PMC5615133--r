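#' Read an OTU count table from a TSV file
#'
#' The canonical on-disk layout has sample ids in the header row and OTU ids in
#' the first column (classic QIIME orientation); the transposed layout is
#' accepted via `orientation = "samples_in_rows"`. A trailing character column
#' named `taxonomy` (any case) is interpreted as a per-OTU lineage string and
#' parsed with [parse_lineage()]. Lines starting with `#` are treated as
#' comments, so files written by [write_count_table()] round-trip.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"otus_in_rows"` (canonical) or `"samples_in_rows"`.
#' @param lineage_delim delimiter passed to [parse_lineage()] when a taxonomy
#'   column is present.
#' @return A `count_table`, normalized to samples x OTUs.
#' @export
read_count_table <- function(path,
                             orientation = c("otus_in_rows", "samples_in_rows"),
                             lineage_delim = ";") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, row.names = NULL,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("not a parseable count-table TSV: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]

  tax_col <- which(tolower(names(df)) == "taxonomy")
  lineages <- NULL
  if (length(tax_col) == 1L && orientation == "otus_in_rows") {
    lineages <- as.character(df[[tax_col]])
    names(lineages) <- ids
    df <- df[, -tax_col, drop = FALSE]
  }

  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                     ids[bad[1L]], names(df)[j], v[bad[1L]]), call. = FALSE)
      df[[j]] <- num
    }
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  if (orientation == "otus_in_rows") m <- t(m)
  tax <- if (!is.null(lineages)) parse_lineage(lineages, delim = lineage_delim) else NULL
  count_table(m, taxonomy = tax)
}

#' Write a count table to TSV in the canonical orientation
#'
#' OTU ids go in the first column and sample ids in the header; a leading `#`
#' comment line records the package version. If taxonomy is attached, the
#' lineage is written as a final `taxonomy` column so the file is
#' self-contained.
#'
#' @param x a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  m <- t(x$counts)  # canonical: OTUs in rows
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) {
    ranks <- tax_ranks()
    lin <- apply(x$taxonomy[match(df$otu_id, x$taxonomy$otu_id), ranks], 1L,
                 paste, collapse = ";")
    df$taxonomy <- lin
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# microcoda v%s count table",
                     as.character(utils::packageVersion("microcoda"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with at least `sample_id`, `age`, `cohort` columns.
#' @return A validated metadata `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
  req <- c("sample_id", "age", "cohort")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Read a separate two-column taxonomy TSV
#'
#' Alternative to embedding lineages in the count table: a TSV whose first
#' column is the OTU id and second column the lineage string.
#'
#' @param path TSV path.
#' @param delim lineage delimiter passed to [parse_lineage()].
#' @return Taxonomy `data.frame` (see [parse_lineage()]).
#' @export
read_taxonomy <- function(path, delim = ";") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy TSV needs otu id and lineage columns",
                          call. = FALSE)
  parse_lineage(as.character(df[[2L]]), otu_ids = as.character(df[[1L]]),
                delim = delim)
}

#' Attach sample metadata to a count table
#'
#' @param x a `count_table`.
#' @param meta metadata `data.frame` (see [read_sample_metadata()]).
#' @param policy `"strict"` errors on any count-table sample without a metadata
#'   row; `"intersect"` keeps only samples present in both and records the
#'   dropped ids in the `"dropped_samples"` attribute of the result.
#' @return An annotated `count_table`.
#' @export
join_metadata <- function(x, meta, policy = c("strict", "intersect")) {
  stopifnot(inherits(x, "count_table"))
  policy <- match.arg(policy)
  meta <- as.data.frame(meta)
  meta$sample_id <- as.character(meta$sample_id)
  ids <- rownames(x$counts)
  unmatched <- setdiff(ids, meta$sample_id)
  if (policy == "strict") {
    if (length(unmatched) > 0L)
      stop("strict join: samples without metadata: ",
           paste(utils::head(unmatched, 10L), collapse = ", "), call. = FALSE)
    keep <- ids
  } else {
    keep <- intersect(ids, meta$sample_id)
    if (length(keep) == 0L) stop("empty intersection of samples", call. = FALSE)
  }
  out <- count_table(x$counts[keep, , drop = FALSE], taxonomy = x$taxonomy,
                     metadata = meta[meta$sample_id %in% keep, , drop = FALSE])
  attr(out, "dropped_samples") <- unmatched
  out
}

#' Parse taxonomy lineage strings into a ranked table
#'
#' Lineages are split on `delim`, optional rank prefixes of the form `g__`
#' (RDP/SILVA style) are stripped, and absent or empty ranks are marked
#' `"unclassified"`. Parsing is lenient: malformed entries become fully
#' unclassified rather than erroring. Ranks are assumed to be ordered
#' domain, phylum, class, order, family, genus.
#'
#' @param lineages character vector of lineage strings, named by OTU id (or
#'   supply `otu_ids`).
#' @param otu_ids optional OTU ids, same length as `lineages`.
#' @param delim field delimiter, default `";"`.
#' @return `data.frame` with columns `otu_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
parse_lineage <- function(lineages, otu_ids = names(lineages), delim = ";") {
  if (is.null(otu_ids)) otu_ids <- paste0("otu_", seq_along(lineages))
  ranks <- tax_ranks()
  out <- matrix("unclassified", nrow = length(lineages), ncol = length(ranks),
                dimnames = list(NULL, ranks))
  for (i in seq_along(lineages)) {
    s <- lineages[[i]]
    if (is.na(s) || !nzchar(trimws(s))) next
    parts <- trimws(strsplit(s, delim, fixed = TRUE)[[1L]])
    parts <- sub("^[a-zA-Z]__", "", parts)
    parts <- parts[seq_len(min(length(parts), length(ranks)))]
    ok <- nzchar(parts) & !tolower(parts) %in% c("na", "unclassified", "unknown")
    out[i, seq_along(parts)][ok] <- parts[ok]
  }
  data.frame(otu_id = as.character(otu_ids), out, stringsAsFactors = FALSE)
}

#' Bin OTUs at a taxonomic rank, pooling unclassified OTUs
#'
#' @param tax taxonomy `data.frame` from [parse_lineage()].
#' @param rank one of phylum, class, order, family, genus.
#' @param unclassified_label label for the pooled unclassified bin.
#' @return Named character vector: OTU id -> bin label.
#' @export
taxon_bins <- function(tax, rank = "genus", unclassified_label = "unclassified") {
  rank <- match.arg(rank, c("phylum", "class", "order", "family", "genus"))
  lab <- tax[[rank]]
  lab[is.na(lab) | lab == "unclassified"] <- unclassified_label
  stats::setNames(lab, tax$otu_id)
}
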