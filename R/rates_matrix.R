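#' Seed-to-seedling transition rates
#'
#' For every species and census interval the rate of newly emerging
#' seedlings per hectare per year (recruits scaled from the summed seedling
#' plot area) is divided by the rate of seeds captured per hectare per year
#' (counts scaled from the summed trap area). Per-interval ratios are
#' averaged across all intervals in which the species had seeds in the traps
#' (a zero-seed interval yields no ratio), means above one are replaced by
#' one, and the result is natural-log transformed. Species with seeds in no
#' interval get a missing (not infinite) transition rate.
#'
#' A recruit is a seedling first tagged at a census after the first, whose
#' first recorded height is below `recruit_height_cutoff_mm`.
#'
#' @param seedlings seedling table ([census_tables] schema).
#' @param seed_traps seed-trap table.
#' @param recruit_height_cutoff_mm first-height cutoff for recruits (mm).
#' @return data frame with `species`, `mean_transition` (capped at 1),
#'   `log_transition`, `n_intervals` (intervals with seeds).
#' @export
transition_rates <- function(seedlings, seed_traps,
                             recruit_height_cutoff_mm = 500) {
  census_dates <- sort(unique(seedlings$census_date))
  if (length(census_dates) < 2L) stop("need at least two seedling censuses")
  intervals <- data.frame(start = census_dates[-length(census_dates)],
                          end = census_dates[-1L])
  # plot area actually monitored (summed over distinct plots)
  plots <- seedlings[!duplicated(seedlings$plot_id), c("plot_id", "plot_area")]
  plot_area_ha <- sum(plots$plot_area) / 1e4
  # first record per seedling determines recruit status
  ord <- order(seedlings$seedling_id, seedlings$census_date, method = "radix")
  first <- seedlings[ord, ][!duplicated(seedlings$seedling_id[ord]), , drop = FALSE]
  recruits <- first[first$census_date > census_dates[1L] &
                      !is.na(first$height) &
                      first$height < recruit_height_cutoff_mm, , drop = FALSE]
  species <- sort(unique(c(seedlings$species, seed_traps$species)))
  ratios <- matrix(NA_real_, length(species), nrow(intervals),
                   dimnames = list(species, NULL))
  for (i in seq_len(nrow(intervals))) {
    t_years <- intervals$end[i] - intervals$start[i]
    # recruits first seen at the census closing this interval
    rec_i <- recruits[abs(recruits$census_date - intervals$end[i]) < 1e-9, , drop = FALSE]
    rec_per_ha_yr <- table(factor(rec_i$species, levels = species)) /
      plot_area_ha / t_years
    # traps whose collection window overlaps the interval
    tr <- seed_traps[seed_traps$window_start < intervals$end[i] - 1e-9 &
                       seed_traps$window_end > intervals$start[i] + 1e-9, , drop = FALSE]
    if (nrow(tr) == 0L) next
    traps_u <- tr[!duplicated(tr$trap_id), c("trap_id", "trap_area")]
    trap_area_ha <- sum(traps_u$trap_area) / 1e4
    trap_years <- mean(tr$window_end - tr$window_start)
    seeds_per_ha_yr <- tapply(tr$count, factor(tr$species, levels = species),
                              sum, default = 0) / trap_area_ha / trap_years
    has_seeds <- seeds_per_ha_yr > 0
    ratios[has_seeds, i] <- as.numeric(rec_per_ha_yr[has_seeds]) /
      as.numeric(seeds_per_ha_yr[has_seeds])
  }
  n_int <- rowSums(!is.na(ratios))
  mean_tr <- ifelse(n_int > 0, rowMeans(ratios, na.rm = TRUE), NA_real_)
  capped <- pmin(mean_tr, 1)
  data.frame(species = species,
             mean_transition = capped,
             log_transition = ifelse(!is.na(capped) & capped > 0,
                                     log(capped), NA_real_),
             n_intervals = n_int,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the species-by-rate matrix
#'
#' Combines the class-specific growth fits (posterior mean transformed
#' growth), survival fits (log expected lifespan) and log transition rates
#' into the 9-column species matrix, applies the retention rule — a species
#' is kept only with growth/survival estimates in at least two of the eight
#' class cells (the transition column does not count towards retention) —
#' and z-scores every column over its observed cells.
#'
#' @param growth_fits named list of [fit_growth_model()] results, one per
#'   size class (names from [size_classes()]); classes may be absent.
#' @param survival_fits named list of [fit_survival_model()] results.
#' @param transitions result of [transition_rates()], or `NULL`.
#' @param config a [pipeline_config()].
#' @return object of class `rates_matrix`: `values` (z-scored matrix with
#'   NA for missing cells), `center`/`scale` (per-column normalization),
#'   `n_cells` (observed growth+survival cells per species), `columns`
#'   (the [rate_columns()] descriptor).
#' @export
assemble_rates_matrix <- function(growth_fits, survival_fits,
                                  transitions = NULL,
                                  config = pipeline_config()) {
  info <- rate_columns()
  species <- sort(unique(c(
    unlist(lapply(growth_fits, function(f) f$species_estimates$species)),
    unlist(lapply(survival_fits, function(f) f$species_estimates$species))
  )))
  m <- matrix(NA_real_, length(species), nrow(info),
              dimnames = list(species, info$column))
  for (cls in size_classes()) {
    gf <- growth_fits[[cls]]
    if (!is.null(gf)) {
      est <- gf$species_estimates
      m[est$species, paste0("growth_", cls)] <- est$g_mean
    }
    sf <- survival_fits[[cls]]
    if (!is.null(sf)) {
      est <- sf$species_estimates
      m[est$species, paste0("surv_", cls)] <- est$lifespan
    }
  }
  if (!is.null(transitions)) {
    tr <- transitions[transitions$species %in% species &
                        !is.na(transitions$log_transition), , drop = FALSE]
    m[tr$species, "log_transition"] <- tr$log_transition
  }
  gs_cols <- info$column[info$rate_type != "transition"]
  n_cells <- rowSums(!is.na(m[, gs_cols, drop = FALSE]))
  m <- m[n_cells >= 2L, , drop = FALSE]
  n_cells <- n_cells[n_cells >= 2L]
  if (nrow(m) == 0L) stop("no species with growth and survival estimates in at least two size classes")
  center <- colMeans(m, na.rm = TRUE)
  scale <- apply(m, 2L, stats::sd, na.rm = TRUE)
  empty <- colSums(!is.na(m)) < 2L   # unobserved columns stay NA untouched
  center[empty] <- 0; scale[empty] <- 1
  degenerate <- !empty & !is.na(scale) & scale < 1e-12
  if (any(degenerate)) {
    stop("rate column(s) with zero variance: ",
         paste(colnames(m)[degenerate], collapse = ", "))
  }
  values <- sweep(sweep(m, 2L, center, "-"), 2L, scale, "/")
  structure(list(values = values, center = center, scale = scale,
                 n_cells = n_cells, columns = info),
            class = "rates_matrix")
}

#' @export
print.rates_matrix <- function(x, ...) {
  cat(sprintf("rates matrix: %d species x %d rates, %.1f%% cells observed\n",
              nrow(x$values), ncol(x$values),
              100 * mean(!is.na(x$values))))
  invisible(x)
}
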