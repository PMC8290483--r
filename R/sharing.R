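#' Presence matrix at a relative-abundance threshold
#'
#' An OTU is present in a sample iff its relative abundance is strictly
#' greater than `threshold` (default 0.01%).
#'
#' @param table a [count_table]; every sample must have a positive total.
#' @param threshold presence threshold as a fraction (strict inequality).
#' @return Logical OTU-by-sample matrix with dimnames.
#' @export
presence_matrix <- function(table, threshold = 1e-4) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(table$sample_ids[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(table$counts, 2L, totals, "/") > threshold
}

#' Number of OTUs shared by two samples
#'
#' @param presence logical matrix from [presence_matrix].
#' @param a,b sample ids (columns of `presence`).
#' @return Integer count of OTUs present in both samples.
#' @export
shared_count <- function(presence, a, b) {
  missing <- setdiff(c(a, b), colnames(presence))
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(presence[, a] & presence[, b])
}

#' Build related and candidate-unrelated mother-infant pairs
#'
#' Pairs child stool samples of a postpartum window with maternal samples of
#' the matching window and source: week-1 pairs match newborns (DOL 0-5) to
#' `Mother-wk1` stool or `Milk-wk1` breast milk; week-4 pairs match DOL
#' 26-35 infants to the `-wk4` equivalents. Related pairs link a child to
#' its own mother via `mother_subject_id`; candidate unrelated pairs are all
#' other child-by-mother combinations within the same window and source.
#'
#' @param meta metadata data frame (one domain).
#' @param source `"mother_stool"` or `"breast_milk"`.
#' @param window `"wk1"` or `"wk4"`.
#' @return List of class `pair_set`: `related` and `unrelated` data frames
#'   (`child_sample`, `mother_sample`), plus `source` and `window`.
#' @export
build_pair_set <- function(meta, source = c("mother_stool", "breast_milk"),
                           window = c("wk1", "wk4")) {
  source <- match.arg(source)
  window <- match.arg(window)
  child_bin <- c(wk1 = "DOL 0-5", wk4 = "DOL 26-35")[[window]]
  mother_bin <- if (source == "mother_stool") {
    paste0("Mother-", window)
  } else {
    paste0("Milk-", window)
  }
  children <- meta[meta$sample_type == "child_stool" &
                     !is.na(meta$age_bin) & meta$age_bin == child_bin, ,
                   drop = FALSE]
  mothers <- meta[meta$sample_type == source &
                    !is.na(meta$age_bin) & meta$age_bin == mother_bin, ,
                  drop = FALSE]
  if (!nrow(children) || !nrow(mothers)) {
    stop("no ", if (!nrow(children)) "child" else "maternal",
         " samples for window '", window, "', source '", source, "'",
         call. = FALSE)
  }
  grid <- expand.grid(child = seq_len(nrow(children)),
                      mother = seq_len(nrow(mothers)))
  child_sample <- children$sample_id[grid$child]
  mother_sample <- mothers$sample_id[grid$mother]
  related <- !is.na(children$mother_subject_id[grid$child]) &
    children$mother_subject_id[grid$child] == mothers$subject_id[grid$mother]
  structure(list(
    related = data.frame(child_sample = child_sample[related],
                         mother_sample = mother_sample[related],
                         stringsAsFactors = FALSE),
    unrelated = data.frame(child_sample = child_sample[!related],
                           mother_sample = mother_sample[!related],
                           stringsAsFactors = FALSE),
    source = source, window = window
  ), class = "pair_set")
}

#' Shared-OTU comparison of related vs. resampled unrelated pairs
#'
#' Computes shared-OTU counts for every related mother-infant pair, then
#' draws equal-size subsamples of the unrelated pairs (without replacement,
#' matching the related-pair count) and compares the two count sets with a
#' two-sided Wilcoxon rank-sum test. With `n_draws > 1` the per-draw
#' p-values are all reported and summarized by their median.
#'
#' @param presence logical matrix from [presence_matrix].
#' @param pairs a `pair_set` from [build_pair_set]. Pairs whose samples are
#'   absent from `presence` (e.g. removed by QC) are dropped with a warning.
#' @param n_draws number of unrelated subsample draws (default 1).
#' @param seed integer seed for the draws.
#' @return List of class `shared_otu_result`: `related_counts`,
#'   `unrelated_counts` (matrix, one column per draw), `raw_p` (per draw),
#'   `p` (median over draws), `median_related`, `median_unrelated`,
#'   `n_related`, `n_draws`, `seed`, `source`, `window`.
#' @export
related_vs_unrelated <- function(presence, pairs, n_draws = 1L, seed = NULL) {
  stopifnot(inherits(pairs, "pair_set"))
  known <- colnames(presence)
  ok_rel <- pairs$related$child_sample %in% known &
    pairs$related$mother_sample %in% known
  ok_unr <- pairs$unrelated$child_sample %in% known &
    pairs$unrelated$mother_sample %in% known
  if (any(!ok_rel)) {
    warning(sum(!ok_rel), " related pair(s) dropped (samples not in matrix)")
  }
  rel <- pairs$related[ok_rel, , drop = FALSE]
  unr <- pairs$unrelated[ok_unr, , drop = FALSE]
  n_rel <- nrow(rel)
  if (n_rel < 3L) stop("fewer than 3 related pairs", call. = FALSE)
  if (nrow(unr) < n_rel) {
    stop("fewer unrelated candidate pairs (", nrow(unr),
         ") than related pairs (", n_rel, ")", call. = FALSE)
  }
  pair_counts <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      sum(presence[, df$child_sample[i]] & presence[, df$mother_sample[i]])
    }, numeric(1))
  }
  rel_counts <- pair_counts(rel)
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      idx <- sample.int(nrow(unr), n_rel)
      pair_counts(unr[idx, , drop = FALSE])
    })
  })
  unr_mat <- do.call(cbind, draws)
  raw_p <- vapply(draws, function(u) {
    suppressWarnings(stats::wilcox.test(rel_counts, u,
                                        alternative = "two.sided"))$p.value
  }, numeric(1))
  structure(list(
    related_counts = rel_counts,
    unrelated_counts = unr_mat,
    raw_p = raw_p,
    p = stats::median(raw_p),
    median_related = stats::median(rel_counts),
    median_unrelated = stats::median(as.vector(unr_mat)),
    n_related = n_rel,
    n_draws = as.integer(n_draws),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    source = pairs$source,
    window = pairs$window
  ), class = "shared_otu_result")
}

#' Rank OTUs by how many related pairs share them
#'
#' Annotates each OTU with the number (and fraction) of related pairs in
#' which both members carry it, plus its mean relative abundance in the
#' paired child vs. maternal samples, to support the
#' higher-in-newborn/higher-in-mother comparison.
#'
#' @param presence logical matrix from [presence_matrix].
#' @param pairs a `pair_set`; only pairs with both samples present are used.
#' @param table the [count_table] the presence matrix came from (for
#'   relative abundances).
#' @return Data frame sorted by decreasing sharing (ties broken by otu_id):
#'   `otu_id`, `n_pairs`, `frac_pairs`, `mean_relabund_child`,
#'   `mean_relabund_mother`, `higher_in`.
#' @export
top_shared_otus <- function(presence, pairs, table) {
  stopifnot(inherits(pairs, "pair_set"), inherits(table, "count_table"))
  known <- colnames(presence)
  rel <- pairs$related[pairs$related$child_sample %in% known &
                         pairs$related$mother_sample %in% known, ,
                       drop = FALSE]
  if (!nrow(rel)) stop("no related pairs with data", call. = FALSE)
  shared <- presence[, rel$child_sample, drop = FALSE] &
    presence[, rel$mother_sample, drop = FALSE]
  n_pairs <- rowSums(shared)
  relab <- sweep(table$counts, 2L, colSums(table$counts), "/")
  mean_child <- rowMeans(relab[, rel$child_sample, drop = FALSE])
  mean_mother <- rowMeans(relab[, rel$mother_sample, drop = FALSE])
  out <- data.frame(
    otu_id = rownames(presence),
    n_pairs = unname(n_pairs),
    frac_pairs = unname(n_pairs) / nrow(rel),
    mean_relabund_child = unname(mean_child),
    mean_relabund_mother = unname(mean_mother),
    higher_in = ifelse(mean_child > mean_mother, "child", "mother"),
    stringsAsFactors = FALSE
  )
  out[order(-out$n_pairs, out$otu_id), , drop = FALSE]
}
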