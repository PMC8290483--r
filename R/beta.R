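#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over the raw counts of the
#' two samples (computed via [vegan::vegdist]).
#'
#' @param table a [count_table]; every sample must have a positive total.
#' @return Symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sample ids.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(table$sample_ids[totals <= 0], collapse = ", "), call. = FALSE)
  }
  d <- vegan::vegdist(t(table$counts), method = "bray")
  m <- as.matrix(d)
  diag(m) <- 0
  m
}

# all n! permutations of 1..n as an (n! x n) matrix; guarded to small n
all_permutations <- function(n) {
  if (n > 9L) stop("refusing to enumerate permutations for n > 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Permutation test of a continuous covariate on a distance matrix
#'
#' Partitions distance-matrix variation by a single continuous covariate
#' (e.g. age in days): with `A = d^2` and centering matrix `J`, the
#' Gower-centered matrix is `G = -J A J / 2`; the model sum of squares is
#' `tr(H G H)` for the hat matrix `H` of the design `[1, z]`, the total is
#' `tr(G)`, and the pseudo-F is `(SS_model / 1) / (SS_res / (n - 2))`.
#' Significance comes from random permutations of the covariate
#' (`p = (1 + #{F* >= F}) / (1 + n_perm)`); when `n! <= n_perm` all
#' permutations are enumerated instead and `p = #{F* >= F} / n!`.
#'
#' @param dm distance matrix (square symmetric matrix or `dist`).
#' @param covariate numeric vector, one value per sample of `dm`. If named,
#'   it is matched to the matrix dimnames.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draws.
#' @return List of class `permanova_result`: `pseudo_f`, `r_squared`,
#'   `p_value`, `n_permutations`, `df_model`, `df_residual`, `seed`,
#'   `method` (`"sampled"` or `"exhaustive"`).
#' @export
permanova_continuous <- function(dm, covariate, n_perm = 999, seed = NULL) {
  m <- as.matrix(dm)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!is.null(names(covariate)) && !is.null(rownames(m))) {
    missing <- setdiff(rownames(m), names(covariate))
    if (length(missing)) {
      stop("covariate missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    covariate <- covariate[rownames(m)]
  }
  if (length(covariate) != n) {
    stop("covariate length does not match distance matrix", call. = FALSE)
  }
  if (anyNA(covariate)) stop("covariate contains NA", call. = FALSE)
  z <- as.numeric(covariate)
  if (stats::sd(z) == 0) stop("covariate is constant", call. = FALSE)

  A <- m^2
  rm_ <- rowMeans(A); gm_ <- mean(A)
  G <- -0.5 * (A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm_)
  ss_total <- sum(diag(G))
  df_model <- 1L
  df_res <- n - 2L
  # tr(HGH) = tr(HG); the intercept part vanishes because G is centered,
  # leaving the quadratic form in the centered covariate
  f_of <- function(zv) {
    zc <- zv - mean(zv)
    ssm <- sum(zc * (G %*% zc)) / sum(zc^2)
    (ssm / df_model) / ((ss_total - ssm) / df_res)
  }
  f_obs <- f_of(z)
  zc_obs <- z - mean(z)
  ssm_obs <- sum(zc_obs * (G %*% zc_obs)) / sum(zc_obs^2)

  if (factorial(n) <= n_perm) {
    perms <- all_permutations(n)
    fs <- apply(perms, 1L, function(idx) f_of(z[idx]))
    p <- mean(fs >= f_obs - 1e-12)
    method <- "exhaustive"
    n_used <- nrow(perms)
  } else {
    fs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) f_of(sample(z)), numeric(1))
    })
    p <- (1 + sum(fs >= f_obs - 1e-12)) / (1 + n_perm)
    method <- "sampled"
    n_used <- as.integer(n_perm)
  }
  structure(list(
    pseudo_f = f_obs,
    r_squared = ssm_obs / ss_total,
    p_value = p,
    n_permutations = n_used,
    df_model = df_model,
    df_residual = df_res,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    method = method
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test on distances: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%s, %d permutations)\n",
    x$pseudo_f, x$df_model, x$df_residual, x$r_squared, x$p_value, x$method,
    x$n_permutations))
  invisible(x)
}

#' Distances from each age bin to a reference bin
#'
#' For every non-reference bin, collects the Bray-Curtis distance of each
#' bin member to every reference-bin member (all cross pairs), plus the
#' within-reference pairwise distances (each unordered pair once) as the
#' comparison distribution.
#'
#' @param dm distance matrix with sample ids as dimnames.
#' @param meta metadata with `sample_id` and `age_bin`.
#' @param reference_bin reference bin label (>= 2 samples in `dm`).
#' @return List of class `bin_distances`: `reference_bin`,
#'   `reference_within` (numeric vector), and `bins` (named list of
#'   cross-distance vectors in chronological bin order).
#' @export
distances_to_reference <- function(dm, meta, reference_bin) {
  m <- as.matrix(dm)
  meta <- meta[meta$sample_id %in% rownames(m) & !is.na(meta$age_bin), ,
               drop = FALSE]
  ref_ids <- meta$sample_id[meta$age_bin == reference_bin]
  if (length(ref_ids) < 2L) {
    stop("reference bin '", reference_bin, "' has fewer than 2 samples",
         call. = FALSE)
  }
  bins <- setdiff(unique(meta$age_bin), reference_bin)
  known <- c(default_age_bins()$age_bin, MATERNAL_BINS)
  bins <- c(intersect(known, bins), setdiff(bins, known))
  out <- list()
  for (b in bins) {
    ids <- meta$sample_id[meta$age_bin == b]
    if (!length(ids)) {
      warning("bin '", b, "' has no samples in the distance matrix; skipped")
      next
    }
    out[[b]] <- as.vector(m[ids, ref_ids, drop = FALSE])
  }
  within <- m[ref_ids, ref_ids][upper.tri(diag(length(ref_ids)))]
  structure(list(reference_bin = reference_bin,
                 reference_within = within,
                 bins = out),
            class = "bin_distances")
}

#' Test each bin's distance-to-reference distribution
#'
#' Two-sided Wilcoxon rank-sum test of each bin's cross distances against
#' the within-reference distance distribution, Bonferroni-adjusted over the
#' bins tested. Repeated distances to the same reference individuals are
#' treated as independent observations, mirroring the source procedure (a
#' documented caveat).
#'
#' @param bd a `bin_distances` object from [distances_to_reference].
#' @param alpha_level significance level on adjusted p-values.
#' @return Data frame with `age_bin`, `n_distances`, `median_distance`,
#'   `reference_median`, `raw_p`, `adjusted_p`, `significant`.
#' @export
bin_distance_test <- function(bd, alpha_level = 0.05) {
  stopifnot(inherits(bd, "bin_distances"))
  if (!length(bd$reference_within)) {
    stop("no within-reference distances", call. = FALSE)
  }
  rows <- lapply(names(bd$bins), function(b) {
    x <- bd$bins[[b]]
    wt <- suppressWarnings(stats::wilcox.test(x, bd$reference_within,
                                              alternative = "two.sided"))
    data.frame(age_bin = b, n_distances = length(x),
               median_distance = stats::median(x),
               reference_median = stats::median(bd$reference_within),
               raw_p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = "bonferroni")
  out$significant <- out$adjusted_p < alpha_level
  rownames(out) <- NULL
  out
}
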