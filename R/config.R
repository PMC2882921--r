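# Analysis thresholds. Defaults follow the study design: arrays scaled to an
# average intensity of 100 with values under 1 set to 1; probe sets absent in
# >= 95% of all samples treated as non-informative; contrasts significant at
# BH-adjusted p <= 0.05 with fold change >= 2; genes called "not expressed"
# below 5% presence; aberrant expression in tumor cells above 10% presence.

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default.
#'
#' @param scale_target per-array target for the average signal intensity
#'   (arbitrary scanner units; default 100).
#' @param signal_floor lower bound applied to scaled signals (default 1);
#'   also makes the log2 transform used for testing well-defined.
#' @param scale_trim trim fraction of the per-array mean used for scaling
#'   (default 0, a plain arithmetic mean; set e.g. 0.02 for data conditioned
#'   on MAS5-style trimmed means).
#' @param noninformative_absent_frac a probe set with a not-present call in
#'   at least this fraction of all samples is non-informative (default 0.95).
#' @param alpha significance level on the BH-adjusted p value (default 0.05).
#' @param min_fold_change minimal linear fold change retained (default 2).
#' @param rescue_min_present_frac a gene absent in every environment
#'   population is rescued into the tumor compartment when its presence
#'   fraction in MMC strictly exceeds this (default 0: at least one present
#'   call).
#' @param not_expressed_max_present_frac presence fraction below which a gene
#'   counts as not expressed in MMC and in CD3/CD14/PMN (default 0.05).
#' @param not_expressed_niche_max_present_frac maximal presence fraction
#'   tolerated in BMSC and OC for the not-expressed category (default 0:
#'   zero present calls).
#' @param aberrant_min_mmc_present_frac MMC presence fraction that must be
#'   strictly exceeded for aberrant expression relative to all-absent BMPC
#'   (default 0.10).
#' @param log2_test if `TRUE` (default) t-tests run on log2-transformed
#'   floored signals; fold changes are always ratios of linear-scale means.
#' @param welch use the Welch unequal-variance t instead of the pooled
#'   Student t (default `FALSE`).
#' @param niche_requires_other_niche if `TRUE`, a niche gene must also beat
#'   the other niche population (BMSC over OC and vice versa);
#'   default `FALSE`.
#' @param random_seed optional integer seed recorded with the configuration.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(scale_target = 100,
                            signal_floor = 1,
                            scale_trim = 0,
                            noninformative_absent_frac = 0.95,
                            alpha = 0.05,
                            min_fold_change = 2,
                            rescue_min_present_frac = 0,
                            not_expressed_max_present_frac = 0.05,
                            not_expressed_niche_max_present_frac = 0,
                            aberrant_min_mmc_present_frac = 0.10,
                            log2_test = TRUE,
                            welch = FALSE,
                            niche_requires_other_niche = FALSE,
                            random_seed = NULL) {
  cfg <- list(scale_target = scale_target,
              signal_floor = signal_floor,
              scale_trim = scale_trim,
              noninformative_absent_frac = noninformative_absent_frac,
              alpha = alpha,
              min_fold_change = min_fold_change,
              rescue_min_present_frac = rescue_min_present_frac,
              not_expressed_max_present_frac = not_expressed_max_present_frac,
              not_expressed_niche_max_present_frac =
                not_expressed_niche_max_present_frac,
              aberrant_min_mmc_present_frac = aberrant_min_mmc_present_frac,
              log2_test = isTRUE(log2_test),
              welch = isTRUE(welch),
              niche_requires_other_niche = isTRUE(niche_requires_other_niche),
              random_seed = random_seed)
  frac_fields <- c("noninformative_absent_frac", "rescue_min_present_frac",
                   "not_expressed_max_present_frac",
                   "not_expressed_niche_max_present_frac",
                   "aberrant_min_mmc_present_frac", "scale_trim")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop(f, " must be a fraction in [0, 1]")
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(cfg$min_fold_change) || cfg$min_fold_change < 1) {
    stop("min_fold_change must be >= 1")
  }
  if (!is.numeric(cfg$scale_target) || cfg$scale_target <= 0) {
    stop("scale_target must be > 0")
  }
  if (!is.numeric(cfg$signal_floor) || cfg$signal_floor < 0) {
    stop("signal_floor must be >= 0")
  }
  structure(cfg, class = "analysis_config")
}
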