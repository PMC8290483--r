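#' Per-OTU prevalence across blank samples
#'
#' Fraction of blank (template-free control) samples in which each OTU has a
#' count strictly greater than zero.
#'
#' @param table a [count_table].
#' @param blank_ids character vector of blank sample ids (nonempty subset of
#'   the table's samples).
#' @return Named numeric vector of fractions in `[0, 1]`, one per OTU.
#' @export
blank_prevalence <- function(table, blank_ids) {
  stopifnot(inherits(table, "count_table"))
  if (!length(blank_ids)) {
    stop("no blank samples supplied; skip decontamination for this stratum",
         call. = FALSE)
  }
  missing <- setdiff(blank_ids, table$sample_ids)
  if (length(missing)) {
    stop("blank ids not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rowMeans(table$counts[, blank_ids, drop = FALSE] > 0)
}

#' Geometric-mean-plus-SD dispersion score
#'
#' The blank-vs-specimen comparison statistic: the geometric mean of counts
#' (pseudocount convention `exp(mean(log(c + 1))) - 1`, so all-zero vectors
#' score 0) plus one sample standard deviation (n-1 denominator; defined as 0
#' for a single observation).
#'
#' @param counts nonnegative numeric vector (nonempty).
#' @return Nonnegative scalar.
#' @examples
#' dispersion_score(c(0, 0, 0)) # 0
#' dispersion_score(7)          # 7
#' @export
dispersion_score <- function(counts) {
  if (!length(counts)) stop("empty count vector", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  gm <- expm1(mean(log1p(counts)))
  s <- if (length(counts) > 1L) stats::sd(counts) else 0
  gm + s
}

#' Arithmetic mean-plus-SD blank background
#'
#' The per-OTU background level subtracted from specimen counts for
#' blank-associated OTUs that are too abundant in specimens to be removed
#' outright: arithmetic mean of blank counts plus one sample SD.
#'
#' @param counts nonnegative numeric vector of blank counts (nonempty).
#' @return Nonnegative scalar.
#' @export
blank_background <- function(counts) {
  if (!length(counts)) stop("empty count vector", call. = FALSE)
  mean(counts) + (if (length(counts) > 1L) stats::sd(counts) else 0)
}

#' Classify OTUs against blank samples
#'
#' Implements the blank-based contaminant rule: an OTU present in strictly
#' more than `blank_prevalence_threshold` of blanks is *removed* when its
#' geometric-mean-plus-SD count in blanks exceeds that in specimens, and
#' *background-subtracted* otherwise (abundant in specimens yet recurrent in
#' blanks). All other OTUs are kept.
#'
#' @param table a [count_table] containing both blanks and specimens.
#' @param blank_ids,specimen_ids disjoint, nonempty sample id sets.
#' @param cfg an [analysis_config].
#' @return Data frame with one row per OTU: `otu_id`, `action` (keep /
#'   remove / subtract), `blank_prevalence`, `blank_dispersion`,
#'   `sample_dispersion`, `blank_background`.
#' @export
classify_contaminants <- function(table, blank_ids, specimen_ids,
                                  cfg = analysis_config()) {
  stopifnot(inherits(table, "count_table"))
  if (!length(blank_ids) || !length(specimen_ids)) {
    stop("blank and specimen sets must both be nonempty", call. = FALSE)
  }
  if (length(intersect(blank_ids, specimen_ids))) {
    stop("blank and specimen sets overlap", call. = FALSE)
  }
  missing <- setdiff(c(blank_ids, specimen_ids), table$sample_ids)
  if (length(missing)) {
    stop("sample ids not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bl <- table$counts[, blank_ids, drop = FALSE]
  sp <- table$counts[, specimen_ids, drop = FALSE]
  prev <- rowMeans(bl > 0)
  blank_disp <- row_gm(bl) + row_sd(bl)
  samp_disp <- row_gm(sp) + row_sd(sp)
  bg <- rowMeans(bl) + row_sd(bl)
  action <- rep("keep", nrow(bl))
  flagged <- prev > cfg$blank_prevalence_threshold
  action[flagged & blank_disp > samp_disp] <- "remove"
  action[flagged & !(blank_disp > samp_disp)] <- "subtract"
  data.frame(
    otu_id = table$otu_ids,
    action = action,
    blank_prevalence = prev,
    blank_dispersion = blank_disp,
    sample_dispersion = samp_disp,
    blank_background = bg,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Apply contaminant decisions to a count table
#'
#' Removed OTUs are dropped; for subtract OTUs each specimen count becomes
#' `max(0, floor(count - blank_background))`; kept OTUs are unchanged. The
#' output is restricted to `specimen_ids` (blank and control columns drop
#' out).
#'
#' @param table a [count_table].
#' @param decisions data frame from [classify_contaminants] covering every
#'   OTU in `table`.
#' @param specimen_ids sample ids to retain in the output.
#' @return A [count_table] over the specimen columns.
#' @export
apply_decontam <- function(table, decisions,
                           specimen_ids = table$sample_ids) {
  stopifnot(inherits(table, "count_table"))
  if (!setequal(decisions$otu_id, table$otu_ids)) {
    stop("decisions must cover exactly the OTUs of the table", call. = FALSE)
  }
  decisions <- decisions[match(table$otu_ids, decisions$otu_id), ,
                         drop = FALSE]
  m <- table$counts[, specimen_ids, drop = FALSE]
  sub <- which(decisions$action == "subtract")
  for (i in sub) {
    m[i, ] <- pmax(0, floor(m[i, ] - decisions$blank_background[i]))
  }
  keep_rows <- decisions$action != "remove"
  count_table(m[keep_rows, , drop = FALSE])
}

#' Drop samples below a total-count floor
#'
#' Samples whose column sums are strictly below `min_total` are removed;
#' survivor order is preserved.
#'
#' @param table a [count_table].
#' @param min_total nonnegative integer (reads).
#' @return List with `table` (the filtered [count_table]) and `dropped`
#'   (data frame of `sample_id`, `total` for removed samples).
#' @export
filter_low_depth <- function(table, min_total) {
  stopifnot(inherits(table, "count_table"))
  stop_if_not_scalar_number(min_total, "min_total")
  if (min_total < 0) stop("min_total must be >= 0", call. = FALSE)
  totals <- colSums(table$counts)
  drop <- totals < min_total
  if (all(drop) && length(drop)) {
    stop("all samples fall below ", min_total,
         " total reads; inspect sequencing depth before filtering",
         call. = FALSE)
  }
  list(
    table = subset_count_table(table, sample_ids = table$sample_ids[!drop]),
    dropped = data.frame(sample_id = table$sample_ids[drop],
                         total = unname(totals[drop]),
                         stringsAsFactors = FALSE)
  )
}

#' Run blank-based QC per stratum and recombine
#'
#' Executes classification, background subtraction, and low-depth filtering
#' independently within each stratum (e.g. stool vs. breast milk, which are
#' extracted and amplified separately and have distinct blank contamination
#' profiles), then recombines the cleaned strata into one table. A stratum
#' without blanks passes through with a warning (classification needs
#' blanks); its depth filter still applies.
#'
#' @param table a [count_table] containing blanks and specimens.
#' @param strata named list; each element is a list with `blank_ids` and
#'   `specimen_ids` (disjoint sample id vectors).
#' @param cfg an [analysis_config].
#' @return List with `table` (merged cleaned [count_table]; OTUs surviving
#'   in any stratum, zero-filled elsewhere) and `reports` (per stratum: the
#'   decision table, dropped samples with totals, and the stratum label).
#' @export
run_decontam <- function(table, strata, cfg = analysis_config()) {
  stopifnot(inherits(table, "count_table"))
  if (!length(strata) || is.null(names(strata))) {
    stop("strata must be a nonempty named list", call. = FALSE)
  }
  cleaned <- list()
  reports <- list()
  for (label in names(strata)) {
    st <- strata[[label]]
    if (!length(st$specimen_ids)) {
      stop("stratum '", label, "' has no specimens", call. = FALSE)
    }
    if (!length(st$blank_ids)) {
      warning("stratum '", label,
              "' has no blanks; passing through without contaminant filtering")
      decisions <- data.frame(
        otu_id = table$otu_ids, action = "keep",
        blank_prevalence = NA_real_, blank_dispersion = NA_real_,
        sample_dispersion = NA_real_, blank_background = NA_real_,
        stringsAsFactors = FALSE
      )
      tab <- subset_count_table(table, sample_ids = st$specimen_ids)
    } else {
      decisions <- classify_contaminants(table, st$blank_ids,
                                         st$specimen_ids, cfg)
      tab <- apply_decontam(table, decisions, st$specimen_ids)
    }
    flt <- filter_low_depth(tab, cfg$min_sample_depth)
    cleaned[[label]] <- flt$table
    reports[[label]] <- list(stratum = label, decisions = decisions,
                             dropped_samples = flt$dropped)
  }
  list(table = merge_count_tables(cleaned), reports = reports)
}

# union of OTUs (zero-filled), columns concatenated in stratum order
merge_count_tables <- function(tables) {
  if (length(tables) == 1L) return(tables[[1]])
  otus <- Reduce(union, lapply(tables, function(t) t$otu_ids))
  samples <- unlist(lapply(tables, function(t) t$sample_ids), use.names = FALSE)
  if (anyDuplicated(samples)) {
    stop("strata share specimen samples; strata must partition specimens",
         call. = FALSE)
  }
  m <- matrix(0L, nrow = length(otus), ncol = length(samples),
              dimnames = list(otus, samples))
  for (t in tables) {
    m[t$otu_ids, t$sample_ids] <- t$counts
  }
  count_table(m)
}
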