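#' Align a count table with metadata and taxonomy
#'
#' Restricts a study to the intersection of the table's and the metadata's
#' sample identifiers (case-sensitive), reporting identifiers present on only
#' one side. OTUs lacking a taxonomy entry are reported but retained (they
#' are grouped as unclassified downstream).
#'
#' @param table a [count_table].
#' @param meta metadata data frame (see [validate_metadata]).
#' @param tax optional taxonomy data frame.
#' @return A list of class `study_bundle` with elements `table`, `metadata`,
#'   `taxonomy`, and `dropped` (lists of table-only and metadata-only sample
#'   ids, and OTUs without taxonomy).
#' @export
align_study <- function(table, meta, tax = NULL) {
  stopifnot(inherits(table, "count_table"))
  validate_metadata(meta)
  if (!is.null(tax)) validate_taxonomy(tax)

  common <- intersect(table$sample_ids, meta$sample_id)
  if (!length(common)) {
    stop("no samples shared between count table and metadata", call. = FALSE)
  }
  table_only <- setdiff(table$sample_ids, meta$sample_id)
  meta_only <- setdiff(meta$sample_id, table$sample_ids)
  # keep the table's column order for the intersection
  keep <- table$sample_ids[table$sample_ids %in% common]
  out_table <- subset_count_table(table, sample_ids = keep)
  out_meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  rownames(out_meta) <- NULL

  no_tax <- character()
  if (!is.null(tax)) no_tax <- setdiff(table$otu_ids, tax$otu_id)

  if (length(table_only) || length(meta_only)) {
    message("align_study: dropped ", length(table_only),
            " table-only and ", length(meta_only),
            " metadata-only sample id(s)")
  }
  structure(list(
    table = out_table,
    metadata = out_meta,
    taxonomy = tax,
    dropped = list(table_only = table_only, metadata_only = meta_only,
                   otus_without_taxonomy = no_tax)
  ), class = "study_bundle")
}
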