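#' Estimate all demographic rates from census tables
#'
#' Orchestrates the rate-estimation stages for one site: canopy layering of
#' every tree census, extraction of growth and survival observations with
#' first-census classing, per-class subsampling caps, the hierarchical
#' growth and survival fits for each of the four size classes, seed-to-
#' seedling transition rates, and assembly of the normalized species x 9
#' rate matrix.
#'
#' @param tables list with `trees`, `seedlings`, `seed_traps`, `allometry`
#'   data frames (the [census_tables] schemas); any of the first three may
#'   be `NULL`, in which case the corresponding rates stay missing.
#' @param config a [pipeline_config()]. Species in
#'   `config$exclude_species` (palms, hemi-epiphytes, unidentified) take
#'   part in canopy layering but are dropped from all rate estimates.
#' @param plot_dims tree plot dimensions `c(xmax, ymax)` in meters.
#' @return list with `rates` (a [assemble_rates_matrix()] result),
#'   `growth_fits`, `survival_fits` (per class), `transitions`,
#'   `assignments`, and `converged` (all model fits met the diagnostics
#'   contract).
#' @export
fit_demographic_rates <- function(tables, config = pipeline_config(),
                                  plot_dims) {
  trees <- tables$trees
  assignments <- NULL
  if (!is.null(trees)) {
    assignments <- do.call(rbind, lapply(split(trees, trees$census_index),
      function(census) {
        assign_layers(census, tables$allometry, plot_dims,
                      side = config$subplot_side_m,
                      multiplier = config$packing_multiplier,
                      include_crossing = config$include_crossing)
      }))
    rownames(assignments) <- NULL
  }
  growth_obs <- extract_growth_observations(trees, tables$seedlings,
                                            assignments,
                                            breaks = config$seedling_breaks_mm)
  survival_obs <- extract_survival_observations(trees, tables$seedlings,
                                                assignments,
                                                breaks = config$seedling_breaks_mm)
  if (length(config$exclude_species)) {
    growth_obs <- growth_obs[!growth_obs$species %in% config$exclude_species, ]
    survival_obs <- survival_obs[!survival_obs$species %in% config$exclude_species, ]
  }
  growth_obs <- subsample_observations(growth_obs, config$growth_cap,
                                       derive_seed(config$rng_seed, "subsample"))
  survival_obs <- subsample_observations(survival_obs, config$survival_cap,
                                         derive_seed(config$rng_seed, "subsample") + 1L)
  growth_obs$y <- modulus_transform(growth_obs$increment, config$lambda_modulus)

  growth_fits <- list(); survival_fits <- list()
  for (cls in size_classes()) {
    g <- growth_obs[growth_obs$size_class == cls, , drop = FALSE]
    if (nrow(g) && any(table(g$species) >= config$min_obs)) {
      growth_fits[[cls]] <- fit_growth_model(
        g, config, seed = derive_seed(config$rng_seed, "growth_fit") +
          match(cls, size_classes()))
    }
    s <- survival_obs[survival_obs$size_class == cls, , drop = FALSE]
    if (nrow(s) && any(table(s$species) >= config$min_obs)) {
      survival_fits[[cls]] <- fit_survival_model(
        s, config, seed = derive_seed(config$rng_seed, "survival_fit") +
          match(cls, size_classes()))
    }
  }
  transitions <- NULL
  if (!is.null(tables$seedlings) && !is.null(tables$seed_traps)) {
    transitions <- transition_rates(tables$seedlings, tables$seed_traps,
                                    config$recruit_height_cutoff_mm)
    if (length(config$exclude_species)) {
      transitions <- transitions[!transitions$species %in% config$exclude_species, ]
    }
  }
  rates <- assemble_rates_matrix(growth_fits, survival_fits, transitions, config)
  list(rates = rates, growth_fits = growth_fits,
       survival_fits = survival_fits, transitions = transitions,
       assignments = assignments,
       converged = all(vapply(c(growth_fits, survival_fits),
                              function(f) f$converged, logical(1L))))
}

#' Run the full trade-off pipeline and write its outputs
#'
#' End-to-end driver: simulates a synthetic community (or takes validated
#' tables), estimates all demographic rates, extracts and tests the
#' trade-off axes, and writes the results plus a machine-readable manifest
#' to `output_dir`. All randomness flows from `config$rng_seed`; manifests
#' contain no timestamps, so identical seeds give byte-identical outputs.
#'
#' Written files: `rates_matrix.csv` (normalized rates, NA cells empty),
#' `eigenvalues.csv`, `loadings.csv`, `scores.csv`, `labels.csv`,
#' `transitions.csv`, `assignments.csv`, and `manifest.json` (seed, config,
#' a hash of the config, package version, per-stage row counts,
#' convergence flag).
#'
#' @param config a [pipeline_config()]; validated before any work starts.
#' @param tables optional validated input tables (as for
#'   [fit_demographic_rates()], plus `plot_dims` attribute or argument).
#' @param design a [simulation_design()] used when `tables` is `NULL`.
#' @param plot_dims plot dimensions; defaults to the design's.
#' @param output_dir directory for outputs (created if needed).
#' @return invisibly, a list with `rates`, `pca`, `transitions`, and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), tables = NULL,
                         design = simulation_design(), plot_dims = NULL,
                         output_dir = tempfile("demaxes_run_")) {
  validate_pipeline_config(config)
  if (is.null(tables)) {
    community <- simulate_community(design, seed = config$rng_seed)
    tables <- community[c("trees", "seedlings", "seed_traps", "allometry")]
    if (is.null(plot_dims)) plot_dims <- design$plot_dims
  }
  if (is.null(plot_dims)) stop("plot_dims required with user tables")
  stage <- "rates"
  result <- tryCatch({
    fits <- fit_demographic_rates(tables, config, plot_dims)
    stage <- "pca"
    pca <- tradeoff_pca(fits$rates, config)
    list(fits = fits, pca = pca)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  fits <- result$fits; pca <- result$pca

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(output_dir, name)
  rm_df <- data.frame(species = rownames(fits$rates$values),
                      fits$rates$values, check.names = FALSE)
  write_census_table(rm_df, out("rates_matrix.csv"))
  write_census_table(data.frame(component = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues,
                                var_prop = pca$var_prop,
                                p_value = pca$p_values,
                                label = pca$labels),
                     out("eigenvalues.csv"))
  write_census_table(data.frame(column = rownames(pca$loadings),
                                pca$loadings, check.names = FALSE),
                     out("loadings.csv"))
  write_census_table(data.frame(species = rownames(pca$scores),
                                pca$scores, check.names = FALSE),
                     out("scores.csv"))
  if (!is.null(fits$transitions)) {
    write_census_table(fits$transitions, out("transitions.csv"))
  }
  if (!is.null(fits$assignments)) {
    write_census_table(fits$assignments, out("assignments.csv"))
  }
  manifest <- list(
    seed = config$rng_seed,
    config = unclass(config),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("demaxes")),
    n_species_rates = nrow(fits$rates$values),
    n_rate_columns = ncol(fits$rates$values),
    labels = pca$labels[1:2],
    converged = fits$converged
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(rates = fits$rates, pca = pca,
                 transitions = fits$transitions, manifest = manifest,
                 output_dir = output_dir))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
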