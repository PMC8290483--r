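#' Rarefy a count table to a common depth
#'
#' Each sample's reads are subsampled uniformly without replacement to
#' exactly `depth` (via [vegan::rrarefy]); samples whose total falls below
#' `depth` are excluded and reported. Deterministic given `seed`.
#'
#' @param table a [count_table].
#' @param depth positive integer target depth.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A [count_table] whose columns each sum to `depth`, with attribute
#'   `excluded` (data frame of excluded `sample_id`, `total`).
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  stop_if_not_scalar_number(depth, "depth")
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  depth <- as.integer(depth)
  totals <- colSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth, call. = FALSE)
  x <- t(table$counts[, keep, drop = FALSE])
  # vegan warns heuristically when the smallest positive count exceeds 1;
  # inputs here are validated integer counts, so muffle that one warning
  r <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(x, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- count_table(t(r))
  attr(out, "excluded") <- data.frame(
    sample_id = table$sample_ids[!keep],
    total = unname(totals[!keep]),
    stringsAsFactors = FALSE
  )
  out
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts, in natural-log
#' units.
#'
#' @param counts nonnegative numeric vector with at least one positive entry.
#' @return Nonnegative scalar; 0 for a single-taxon community.
#' @examples
#' shannon(c(10, 10, 10, 10)) # log(4)
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all-zero count vector", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Observed richness
#'
#' Number of taxa with a count strictly greater than zero.
#'
#' @param counts nonnegative numeric vector.
#' @return Integer count.
#' @export
observed_richness <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  sum(counts > 0)
}

#' Per-sample alpha diversity after rarefaction
#'
#' Computes observed richness and Shannon diversity on a rarefied table.
#' The default depth is the minimum retained sample total ("account for
#' unequal sampling depth" with no sample lost); with `replicates > 1` the
#' metrics are averaged over independent rarefaction draws.
#'
#' @param table a [count_table] (after QC).
#' @param depth integer depth, or `NULL` for the minimum sample total.
#' @param seed integer seed for the rarefaction draw(s).
#' @param replicates number of rarefaction draws to average (default 1).
#' @return Data frame with columns `sample_id`, `richness`, `shannon`,
#'   `rarefaction_depth`, `seed`.
#' @export
alpha_diversity <- function(table, depth = NULL, seed = 1L, replicates = 1L) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(table$sample_ids[totals <= 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(depth)) depth <- min(totals)
  acc_rich <- acc_shan <- NULL
  ids <- NULL
  for (r in seq_len(replicates)) {
    rt <- rarefy(table, depth, seed = if (is.null(seed)) NULL else seed + r - 1L)
    rich <- apply(rt$counts, 2L, observed_richness)
    shan <- apply(rt$counts, 2L, shannon)
    if (is.null(ids)) {
      ids <- rt$sample_ids
      acc_rich <- rich
      acc_shan <- shan
    } else {
      acc_rich <- acc_rich + rich
      acc_shan <- acc_shan + shan
    }
  }
  data.frame(
    sample_id = ids,
    richness = unname(acc_rich / replicates),
    shannon = unname(acc_shan / replicates),
    rarefaction_depth = as.integer(depth),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stringsAsFactors = FALSE
  )
}

#' Compare each age bin's alpha diversity to an adult reference bin
#'
#' Two-sided two-sample Wilcoxon rank-sum test of every non-reference bin
#' against the reference bin (exact when sample sizes permit and there are
#' no ties, otherwise normal approximation with continuity correction, as in
#' [stats::wilcox.test]), with Bonferroni adjustment over the bins tested.
#'
#' @param alpha data frame from [alpha_diversity].
#' @param meta metadata with `sample_id` and `age_bin`; only samples present
#'   in `alpha` are used.
#' @param reference_bin label of the adult reference bin (>= 2 samples).
#' @param metric `"richness"` or `"shannon"`.
#' @param alpha_level significance level on adjusted p-values.
#' @return Data frame with one row per tested bin: `age_bin`, `n_bin`,
#'   `n_reference`, `statistic`, `median_bin`, `median_reference`, `raw_p`,
#'   `adjusted_p`, `significant`, `direction` (sign of median difference
#'   bin minus reference).
#' @export
compare_bins_to_reference <- function(alpha, meta, reference_bin,
                                      metric = c("shannon", "richness"),
                                      alpha_level = 0.05) {
  metric <- match.arg(metric)
  merged <- merge(alpha[, c("sample_id", metric)],
                  meta[, c("sample_id", "age_bin")], by = "sample_id")
  merged <- merged[!is.na(merged$age_bin), , drop = FALSE]
  ref_vals <- merged[[metric]][merged$age_bin == reference_bin]
  if (length(ref_vals) < 2L) {
    stop("reference bin '", reference_bin, "' has fewer than 2 samples",
         call. = FALSE)
  }
  bins <- setdiff(unique(merged$age_bin), reference_bin)
  # chronological order where bins are known, then any extras
  known <- c(default_age_bins()$age_bin, MATERNAL_BINS)
  bins <- c(intersect(known, bins), setdiff(bins, known))
  rows <- lapply(bins, function(b) {
    vals <- merged[[metric]][merged$age_bin == b]
    if (length(vals) < 2L) {
      warning("bin '", b, "' has fewer than 2 samples; skipped")
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(vals, ref_vals,
                                              alternative = "two.sided"))
    data.frame(age_bin = b, n_bin = length(vals),
               n_reference = length(ref_vals),
               statistic = unname(wt$statistic),
               median_bin = stats::median(vals),
               median_reference = stats::median(ref_vals),
               raw_p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no bin with >= 2 samples to test", call. = FALSE)
  }
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = "bonferroni")
  out$significant <- out$adjusted_p < alpha_level
  out$direction <- sign(out$median_bin - out$median_reference)
  rownames(out) <- NULL
  out
}
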