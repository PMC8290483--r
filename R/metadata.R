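SAMPLE_TYPES <- c("child_stool", "mother_stool", "breast_milk", "blank",
                  "positive_control")
DOMAINS <- c("bacteria_16S", "fungi_ITS2")

#' Default age-bin boundary table
#'
#' The recruitment strata of the cohort design this pipeline targets: three
#' newborn day-of-life (DOL) windows, 3- and 6-month windows, and
#' month-of-life (MOL) windows at 1, 2, 3, and 5 years. Month bins are
#' converted to days with a 30.44-day month. The table is data, not logic:
#' supply your own bins for a different design.
#'
#' @return Data frame with columns `age_bin`, `min_days`, `max_days`, in
#'   chronological order.
#' @export
default_age_bins <- function() {
  data.frame(
    age_bin  = c("DOL 0-5", "DOL 13-17", "DOL 26-35", "DOL 83-115",
                 "DOL 165-200", "MOL 11-13", "MOL 22-26", "MOL 33-39",
                 "MOL 57-63"),
    min_days = c(0, 13, 26, 83, 165, 334, 669, 1004, 1735),
    max_days = c(5, 17, 35, 115, 200, 396, 792, 1188, 1918),
    stringsAsFactors = FALSE
  )
}

# maternal/milk bins carry no child age; listed for ordering and lookups
MATERNAL_BINS <- c("Mother-wk1", "Mother-wk4", "Milk-wk1", "Milk-wk4")

#' Assign age bins from age in days
#'
#' @param age_days integer vector (NA allowed).
#' @param bins bin boundary table, as from [default_age_bins()].
#' @return Character vector of bin labels; `NA` where no bin matches.
#' @export
assign_age_bin <- function(age_days, bins = default_age_bins()) {
  vapply(age_days, function(a) {
    if (is.na(a)) return(NA_character_)
    hit <- which(bins$min_days <= a & a <= bins$max_days)
    if (length(hit)) bins$age_bin[hit[1]] else NA_character_
  }, character(1))
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `subject_id`, `mother_subject_id`,
#' `age_days`, `age_bin`, `sample_type`, `domain`, `batch`. Sample ids must
#' be unique (case-sensitively); blanks and positive controls must carry no
#' age; where both `age_days` and a child `age_bin` are present they must
#' agree with the bin boundaries.
#'
#' @param meta data frame.
#' @param bins bin boundary table used for the consistency check.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, bins = default_age_bins()) {
  need <- c("sample_id", "subject_id", "mother_subject_id", "age_days",
            "age_bin", "sample_type", "domain", "batch")
  missing <- setdiff(need, colnames(meta))
  if (length(missing)) {
    stop("metadata missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(meta$sample_type), SAMPLE_TYPES)
  if (length(bad_type)) {
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  bad_dom <- setdiff(unique(meta$domain), DOMAINS)
  if (length(bad_dom)) {
    stop("unknown domain: ", paste(bad_dom, collapse = ", "), call. = FALSE)
  }
  ctrl <- meta$sample_type %in% c("blank", "positive_control")
  if (any(ctrl & !is.na(meta$age_days))) {
    stop("blank/positive_control samples must have no age_days: ",
         paste(meta$sample_id[ctrl & !is.na(meta$age_days)], collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(meta$age_days) & meta$age_days < 0)) {
    stop("negative age_days", call. = FALSE)
  }
  both <- !is.na(meta$age_days) & !is.na(meta$age_bin) &
    meta$age_bin %in% bins$age_bin
  if (any(both)) {
    expected <- assign_age_bin(meta$age_days[both], bins)
    bad <- which(expected != meta$age_bin[both])
    if (length(bad)) {
      i <- which(both)[bad[1]]
      stop("age_bin '", meta$age_bin[i], "' inconsistent with age_days ",
           meta$age_days[i], " for sample '", meta$sample_id[i], "'",
           call. = FALSE)
    }
  }
  invisible(meta)
}

#' Read sample metadata from TSV
#'
#' @param path file path.
#' @param bins bin boundary table for validation.
#' @return Validated metadata data frame.
#' @export
read_metadata <- function(path, bins = default_age_bins()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  meta$age_days <- suppressWarnings(as.integer(meta$age_days))
  validate_metadata(meta, bins)
  meta
}

#' Write sample metadata as TSV
#'
#' @param meta metadata data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
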