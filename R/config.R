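#' Analysis configuration
#'
#' Bundles the constants used across the pipeline: the 1,000-read sample
#' depth floor, the strict 50% blank-prevalence threshold for contaminant
#' classification, the strict 0.01% relative-abundance presence threshold
#' for shared-OTU analysis, permutation and resampling counts, the
#' significance level, and the RNG seed threaded into every randomized step.
#'
#' @param min_sample_depth samples with totals strictly under this are
#'   dropped (reads; default 1000).
#' @param blank_prevalence_threshold fraction of blanks an OTU must exceed
#'   (strictly) to be treated as blank-associated (default 0.5).
#' @param presence_threshold relative-abundance fraction above which
#'   (strictly) an OTU counts as present (default 1e-4, i.e. 0.01%).
#' @param n_permutations permutations for the community variance test
#'   (default 999).
#' @param n_resample_draws unrelated-pair subsample draws (default 1).
#' @param alpha_level significance level on adjusted p-values (default 0.05).
#' @param rng_seed integer seed recorded in every report.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_sample_depth = 1000,
                            blank_prevalence_threshold = 0.5,
                            presence_threshold = 1e-4,
                            n_permutations = 999,
                            n_resample_draws = 1,
                            alpha_level = 0.05,
                            rng_seed = 1L) {
  stop_if_not_scalar_number(min_sample_depth, "min_sample_depth")
  stop_if_not_scalar_number(blank_prevalence_threshold,
                            "blank_prevalence_threshold")
  stop_if_not_scalar_number(presence_threshold, "presence_threshold")
  stop_if_not_scalar_number(n_permutations, "n_permutations")
  stop_if_not_scalar_number(n_resample_draws, "n_resample_draws")
  stop_if_not_scalar_number(alpha_level, "alpha_level")
  if (min_sample_depth < 0) stop("min_sample_depth must be >= 0")
  if (blank_prevalence_threshold < 0 || blank_prevalence_threshold > 1) {
    stop("blank_prevalence_threshold must be in [0, 1]")
  }
  if (presence_threshold < 0 || presence_threshold >= 1) {
    stop("presence_threshold must be in [0, 1)")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (n_resample_draws < 1) stop("n_resample_draws must be >= 1")
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("alpha_level must be in (0, 1)")
  }
  structure(list(
    min_sample_depth = as.integer(min_sample_depth),
    blank_prevalence_threshold = blank_prevalence_threshold,
    presence_threshold = presence_threshold,
    n_permutations = as.integer(n_permutations),
    n_resample_draws = as.integer(n_resample_draws),
    alpha_level = alpha_level,
    rng_seed = as.integer(rng_seed)
  ), class = "analysis_config")
}
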