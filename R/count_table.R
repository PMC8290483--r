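#' OTU count table
#'
#' The universal currency of the pipeline: an OTU-by-sample matrix of
#' nonnegative integer read counts with duplicate-free row and column
#' identifiers. Rows are OTUs, columns are samples.
#'
#' @param counts matrix (or object coercible to one) of nonnegative whole
#'   numbers; rows are OTUs, columns are samples.
#' @param otu_ids,sample_ids character identifier vectors; default to the
#'   dimnames of `counts`, or are auto-generated when absent.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix carrying the identifiers as dimnames), `otu_ids`, and
#'   `sample_ids`.
#' @examples
#' ct <- count_table(matrix(c(1, 2, 0, 5, 3, 0), nrow = 3, byrow = TRUE))
#' colSums(ct$counts)
#' @export
count_table <- function(counts, otu_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) {
    otu_ids <- if (nrow(counts)) sprintf("Otu%04d", seq_len(nrow(counts))) else character()
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (ncol(counts)) sprintf("S%03d", seq_len(ncol(counts))) else character()
  }
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(counts)) {
    stop("length of `otu_ids` (", length(otu_ids), ") does not match rows (",
         nrow(counts), ")", call. = FALSE)
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length of `sample_ids` (", length(sample_ids),
         ") does not match columns (", ncol(counts), ")", call. = FALSE)
  }
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(counts)) {
    if (anyNA(counts) || !is.numeric(counts)) {
      stop("counts must be numeric with no missing values", call. = FALSE)
    }
    if (any(counts < 0)) {
      bad <- which(counts < 0, arr.ind = TRUE)[1, ]
      stop("negative count at OTU '", otu_ids[bad[1]], "', sample '",
           sample_ids[bad[2]], "'", call. = FALSE)
    }
    if (!all(is_wholenumber(counts))) {
      bad <- which(!is_wholenumber(counts), arr.ind = TRUE)[1, ]
      stop("non-integer count at OTU '", otu_ids[bad[1]], "', sample '",
           sample_ids[bad[2]], "'", call. = FALSE)
    }
    if (any(counts > .Machine$integer.max)) {
      stop("counts exceed integer range", call. = FALSE)
    }
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  structure(list(counts = counts, otu_ids = otu_ids, sample_ids = sample_ids),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", length(x$otu_ids), " OTUs x ", length(x$sample_ids),
      " samples; total reads ", sum(as.numeric(x$counts)), "\n", sep = "")
  invisible(x)
}

#' Restrict a count table to given samples and/or OTUs
#'
#' @param table a [count_table].
#' @param sample_ids,otu_ids identifiers to keep, in the requested order;
#'   `NULL` keeps everything.
#' @return A [count_table].
#' @export
subset_count_table <- function(table, sample_ids = NULL, otu_ids = NULL) {
  m <- table$counts
  if (!is.null(sample_ids)) m <- m[, sample_ids, drop = FALSE]
  if (!is.null(otu_ids)) m <- m[otu_ids, , drop = FALSE]
  count_table(m)
}

#' Read an OTU count table
#'
#' TSV dialect: first column holds OTU identifiers, header row holds sample
#' identifiers, remaining cells are nonnegative integers. BIOM files are read
#' through the `biomformat` package.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return A [count_table].
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1L) stop("malformed header in ", path, call. = FALSE)
  otu_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in header of ", path, call. = FALSE)
  }
  m <- matrix(0L, nrow = nrow(df), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | !is_wholenumber(v))
    if (length(bad)) {
      stop("invalid count '", df[[j + 1L]][bad[1]], "' at row '",
           otu_ids[bad[1]], "', column '", sample_ids[j], "' in ", path,
           call. = FALSE)
    }
    m[, j] <- as.integer(v)
  }
  count_table(m, otu_ids = otu_ids, sample_ids = sample_ids)
}

#' Write an OTU count table as TSV
#'
#' @param table a [count_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(otu_id = table$otu_ids, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("otu_id", table$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
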