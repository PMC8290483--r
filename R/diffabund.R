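#' Aggregate OTU counts to genus-level labels
#'
#' Counts are summed over OTUs sharing a [genus_labels] label (genus when
#' resolved, otherwise the deepest resolved rank, otherwise `Unclassified`).
#' Aggregation conserves column totals exactly. OTUs with no taxonomy entry
#' are grouped under `Unclassified`.
#'
#' @param table a [count_table].
#' @param tax taxonomy data frame (see [validate_taxonomy]).
#' @return A [count_table] whose "OTU" ids are genus-level labels, sorted
#'   alphabetically.
#' @export
aggregate_by_genus <- function(table, tax) {
  stopifnot(inherits(table, "count_table"))
  labels_all <- genus_labels(tax)
  labels <- labels_all[table$otu_ids]
  labels[is.na(labels)] <- "Unclassified"
  agg <- rowsum(table$counts, group = labels, reorder = TRUE)
  count_table(agg)
}

#' Relative abundance matrix
#'
#' Divides each sample's counts by its total; columns sum to 1.
#'
#' @param x a [count_table] or numeric matrix with positive column sums.
#' @return Numeric matrix of fractions with the input dimnames.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0] %||% which(totals <= 0)
    stop("zero-total column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(m, 2L, totals, "/")
}

#' Genus-level two-group differential abundance
#'
#' Two-sided Wilcoxon rank-sum test of each genus's relative abundance
#' between two sample groups, Benjamini-Hochberg adjusted across genera.
#' Genera absent from every sample of both groups are excluded (recorded in
#' the `excluded` attribute).
#'
#' @param relabund relative-abundance matrix (genus x sample), as from
#'   [relative_abundance] on an aggregated table.
#' @param group1_ids,group2_ids sample id vectors (>= 2 samples each).
#' @param alpha_level significance level on adjusted p-values.
#' @return Data frame sorted by adjusted then raw p-value: `label`,
#'   `median_group1`, `median_group2`, `direction` (sign of median
#'   difference, group1 minus group2), `raw_p`, `adjusted_p`, `significant`.
#' @export
group_difference_test <- function(relabund, group1_ids, group2_ids,
                                  alpha_level = 0.05) {
  missing <- setdiff(c(group1_ids, group2_ids), colnames(relabund))
  if (length(missing)) {
    stop("sample ids not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(group1_ids) < 2L || length(group2_ids) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (length(intersect(group1_ids, group2_ids))) {
    stop("groups overlap", call. = FALSE)
  }
  g1 <- relabund[, group1_ids, drop = FALSE]
  g2 <- relabund[, group2_ids, drop = FALSE]
  present <- rowSums(g1) + rowSums(g2) > 0
  excluded <- rownames(relabund)[!present]
  g1 <- g1[present, , drop = FALSE]
  g2 <- g2[present, , drop = FALSE]
  raw_p <- vapply(seq_len(nrow(g1)), function(i) {
    suppressWarnings(stats::wilcox.test(g1[i, ], g2[i, ],
                                        alternative = "two.sided"))$p.value
  }, numeric(1))
  med1 <- apply(g1, 1L, stats::median)
  med2 <- apply(g2, 1L, stats::median)
  out <- data.frame(
    label = rownames(g1),
    median_group1 = unname(med1),
    median_group2 = unname(med2),
    direction = sign(unname(med1) - unname(med2)),
    raw_p = raw_p,
    adjusted_p = stats::p.adjust(raw_p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out$significant <- out$adjusted_p < alpha_level
  out <- out[order(out$adjusted_p, out$raw_p, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Top genera by mean relative abundance
#'
#' Ranks genera by their mean relative abundance across samples (ties broken
#' lexicographically). With `pool = TRUE`, returns the relative-abundance
#' matrix restricted to the top `k` genera with the remainder pooled into an
#' `Other` row.
#'
#' @param relabund relative-abundance matrix (genus x sample).
#' @param k number of genera to keep (>= 1; capped at the number of genera).
#' @param pool return a pooled matrix instead of labels.
#' @return Character vector of ranked labels, or the pooled matrix.
#' @export
top_genera <- function(relabund, k, pool = FALSE) {
  stop_if_not_scalar_number(k, "k")
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  means <- rowMeans(relabund)
  ord <- order(-means, rownames(relabund))
  top <- rownames(relabund)[ord][seq_len(min(k, nrow(relabund)))]
  if (!pool) return(top)
  rest <- setdiff(rownames(relabund), top)
  out <- relabund[top, , drop = FALSE]
  if (length(rest)) {
    out <- rbind(out, Other = colSums(relabund[rest, , drop = FALSE]))
  }
  out
}
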