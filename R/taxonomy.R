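TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Validate a taxonomy table
#'
#' A taxonomy table is a data frame with column `otu_id` plus the seven
#' canonical ranks (`kingdom` ... `species`) as character columns; unresolved
#' ranks are `NA` and may only trail resolved ones (a resolved genus implies a
#' resolved family, and so on).
#'
#' @param tax data frame as described above.
#' @return `tax`, invisibly, after validation.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("otu_id", TAX_RANKS)
  missing <- setdiff(need, colnames(tax))
  if (length(missing)) {
    stop("taxonomy table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tax$otu_id)) {
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(tax$otu_id[duplicated(tax$otu_id)]), collapse = ", "),
         call. = FALSE)
  }
  res <- !is.na(as.matrix(tax[TAX_RANKS]))
  if (nrow(tax)) {
    for (j in 2:length(TAX_RANKS)) {
      bad <- res[, j] & !res[, j - 1L]
      if (any(bad)) {
        stop("taxonomy for '", tax$otu_id[which(bad)[1]], "' resolves ",
             TAX_RANKS[j], " but not ", TAX_RANKS[j - 1L], call. = FALSE)
      }
    }
  }
  invisible(tax)
}

#' Read a taxonomy table
#'
#' Two-column TSV: `otu_id` and a semicolon-delimited lineage with rank
#' prefixes (`k__Bacteria;p__Proteobacteria;...`). Empty values after a
#' prefix, or missing trailing ranks, become `NA`.
#'
#' @param path file path.
#' @return A validated taxonomy data frame (see [validate_taxonomy]).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("taxonomy file needs 2 columns (otu_id, lineage)",
                          call. = FALSE)
  out <- data.frame(otu_id = df[[1]], stringsAsFactors = FALSE)
  ranks <- matrix(NA_character_, nrow(df), length(TAX_RANKS),
                  dimnames = list(NULL, TAX_RANKS))
  for (i in seq_len(nrow(df))) {
    parts <- trimws(strsplit(df[[2]][i], ";", fixed = TRUE)[[1]])
    for (k in seq_along(parts)) {
      if (k > length(TAX_RANKS)) break
      v <- sub(paste0("^", TAX_PREFIXES[k]), "", parts[k])
      if (nzchar(v)) ranks[i, k] <- v
    }
  }
  out <- cbind(out, as.data.frame(ranks, stringsAsFactors = FALSE))
  validate_taxonomy(out)
  out
}

#' Write a taxonomy table as prefixed-lineage TSV
#'
#' @param tax taxonomy data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  validate_taxonomy(tax)
  lineage <- apply(as.matrix(tax[TAX_RANKS]), 1L, function(r) {
    r[is.na(r)] <- ""
    paste0(TAX_PREFIXES, r, collapse = ";")
  })
  utils::write.table(data.frame(otu_id = tax$otu_id, lineage = lineage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genus-level labels for OTUs
#'
#' Returns the genus name when resolved; otherwise the deepest resolved rank
#' value prefixed by its rank marker (e.g. `f__Lachnospiraceae`), so that
#' OTUs classified "at the genus level or above" all remain countable.
#' OTUs with no resolved rank at all are labelled `Unclassified`.
#'
#' @param tax taxonomy data frame (see [validate_taxonomy]).
#' @return Character vector of labels, one per row of `tax`, named by otu_id.
#' @export
genus_labels <- function(tax) {
  validate_taxonomy(tax)
  m <- as.matrix(tax[TAX_RANKS])
  labels <- vapply(seq_len(nrow(m)), function(i) {
    if (!is.na(m[i, "genus"])) return(m[i, "genus"])
    deepest <- which(!is.na(m[i, ]))
    if (!length(deepest)) return("Unclassified")
    k <- max(deepest)
    paste0(TAX_PREFIXES[k], m[i, k])
  }, character(1))
  stats::setNames(labels, tax$otu_id)
}
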