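#' Pipeline configuration
#'
#' Collects every tunable constant of the demographic trade-off pipeline in a
#' single validated object. Defaults mirror the analysis protocol: modulus
#' exponent 0.4, 31.5 m canopy subplots packed to twice their area, seedling
#' height classes split at 200 and 500 mm, at least 10 observations per
#' species and size class, sampling caps of 200 growth and 1000 survival
#' observations, 1000 eigenvalue permutations, the 0.3 loading rule, a
#' Bonferroni-adjusted trait threshold of p < 0.0125, and 10%/90% life-history
#' hulls.
#'
#' @param lambda_modulus exponent of the modulus growth transform.
#' @param subplot_side_m side length (m) of the canopy-packing subplots.
#' @param packing_multiplier overstory crown-area threshold as a multiple of
#'   subplot area.
#' @param include_crossing logical; whether the stem whose crown first pushes
#'   the cumulative area over the threshold is itself overstory (default) or
#'   the first understory stem. The verbal packing rule admits both readings.
#' @param seedling_breaks_mm seedling height class breaks (mm); heights below
#'   the first break form the small class, heights in `[break1, break2)` the
#'   large class, and taller seedlings are dropped.
#' @param min_obs minimum observations per species and size class for a rate
#'   to be estimated.
#' @param growth_cap,survival_cap per species-by-class subsampling caps
#'   (without replacement) on growth and survival observations.
#' @param n_permutations permutations for the eigenvalue significance test.
#' @param loading_threshold absolute loading above which a rate is considered
#'   significantly related to a significant component.
#' @param bonferroni_alpha significance threshold for post-hoc trait fits.
#' @param hull_fractions fractions of species covered by the life-history
#'   convex hulls.
#' @param recruit_height_cutoff_mm first-measured height (mm) below which a
#'   newly tagged seedling counts as a recruit for transition rates.
#' @param n_chains,n_iter,n_burnin MCMC settings shared by the growth and
#'   survival models; `n_iter` counts post-burn-in draws per chain.
#' @param exclude_species character vector of species (palms, hemi-epiphytes,
#'   unidentified morphospecies) that take part in canopy layering but are
#'   excluded from rate estimation.
#' @param rng_seed integer seed from which all pipeline randomness flows.
#' @return an object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(lambda_modulus = 0.4,
                            subplot_side_m = 31.5,
                            packing_multiplier = 2.0,
                            include_crossing = TRUE,
                            seedling_breaks_mm = c(200, 500),
                            min_obs = 10L,
                            growth_cap = 200L,
                            survival_cap = 1000L,
                            n_permutations = 1000L,
                            loading_threshold = 0.3,
                            bonferroni_alpha = 0.0125,
                            hull_fractions = c(0.10, 0.90),
                            recruit_height_cutoff_mm = 500,
                            n_chains = 3L,
                            n_iter = 1500L,
                            n_burnin = 750L,
                            exclude_species = character(0),
                            rng_seed = 1L) {
  cfg <- list(
    lambda_modulus = lambda_modulus,
    subplot_side_m = subplot_side_m,
    packing_multiplier = packing_multiplier,
    include_crossing = isTRUE(include_crossing),
    seedling_breaks_mm = as.numeric(seedling_breaks_mm),
    min_obs = as.integer(min_obs),
    growth_cap = as.integer(growth_cap),
    survival_cap = as.integer(survival_cap),
    n_permutations = as.integer(n_permutations),
    loading_threshold = loading_threshold,
    bonferroni_alpha = bonferroni_alpha,
    hull_fractions = as.numeric(hull_fractions),
    recruit_height_cutoff_mm = recruit_height_cutoff_mm,
    n_chains = as.integer(n_chains),
    n_iter = as.integer(n_iter),
    n_burnin = as.integer(n_burnin),
    exclude_species = as.character(exclude_species),
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$lambda_modulus > 0,
    cfg$subplot_side_m > 0,
    cfg$packing_multiplier > 0,
    length(cfg$seedling_breaks_mm) == 2L,
    all(cfg$seedling_breaks_mm > 0),
    diff(cfg$seedling_breaks_mm) > 0,
    cfg$min_obs >= 1L,
    cfg$growth_cap >= 1L,
    cfg$survival_cap >= 1L,
    cfg$loading_threshold > 0, cfg$loading_threshold < 1,
    cfg$bonferroni_alpha > 0, cfg$bonferroni_alpha < 1,
    all(cfg$hull_fractions > 0), all(cfg$hull_fractions <= 1),
    cfg$recruit_height_cutoff_mm > 0,
    cfg$n_chains >= 2L,
    cfg$n_iter >= 10L,
    cfg$n_burnin >= 0L,
    !is.na(cfg$rng_seed)
  )
  if (cfg$n_permutations < 1L) {
    stop("n_permutations must be a positive integer")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("demographic trade-off pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Deterministic derived seeds: one master seed fans out to named stages so
# that changing e.g. the number of permutations never perturbs the simulator.
derive_seed <- function(rng_seed, stage) {
  offsets <- c(truth = 11L, trees = 23L, seedlings = 37L, subsample = 53L,
               growth_fit = 67L, survival_fit = 79L, permutation = 97L,
               imputation = 101L, posthoc = 113L, replicate = 127L)
  if (!stage %in% names(offsets)) stop("unknown seeding stage: ", stage)
  (as.integer(rng_seed) * 269L + offsets[[stage]]) %% 2147483629L
}
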