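#' Size-class and rate-column layout
#'
#' The pipeline estimates growth and survival in four ontogenetic classes —
#' seedlings below 20 cm height, seedlings of 20-50 cm, understory trees and
#' overstory trees (>= 1 cm dbh, split by canopy layer) — plus one
#' seed-to-seedling transition rate, giving the 9-column species rate matrix.
#'
#' @return `size_classes()`: the four class labels in ontogenetic order.
#'   `rate_columns()`: data frame describing the 9 matrix columns (`column`,
#'   `rate_type` growth/survival/transition, `stage` seedling/tree/NA).
#' @export
size_classes <- function() {
  c("seedling_lt20", "seedling_20_50", "understory", "overstory")
}

#' @rdname size_classes
#' @export
rate_columns <- function() {
  cls <- size_classes()
  data.frame(
    column = c(paste0("growth_", cls), paste0("surv_", cls), "log_transition"),
    rate_type = c(rep("growth", 4L), rep("survival", 4L), "transition"),
    stage = c(rep(c("seedling", "seedling", "tree", "tree"), 2L), NA),
    stringsAsFactors = FALSE
  )
}

default_axis_loadings <- function() {
  cols <- rate_columns()$column
  L <- rbind(
    # axis 1: fast-slow continuum -- growth against survival in every class,
    # transition aligned with survival
    axis1 = c(rep(0.5, 4L), rep(-0.9, 4L), -0.5),
    # axis 2: ontogenetic axis -- seedling classes against tree classes
    # within each rate type, transition aligned with seedling performance
    axis2 = c(0.4, 0.4, -0.4, -0.4, 0.7, 0.7, -0.7, -0.7, 0.5)
  )
  colnames(L) <- cols
  L
}

default_trait_loadings <- function() {
  # stature loads against the seedling end of axis 2; dense wood with the
  # survival end of axis 1; large seeds with recruitment; high SLA with fast
  # seedling growth
  rbind(axis1 = c(max_dbh = 0.15, wood_density = -0.30, seed_mass = -0.10, sla = 0.50),
        axis2 = c(max_dbh = -0.80, wood_density = -0.10, seed_mass = 0.80, sla = 0.30))
}

#' Synthetic community design
#'
#' Describes the simulated forest: community size, census layout, sampling
#' effort, and how the two latent life-history axes map onto the nine
#' demographic rate columns and the four traits. Defaults emulate a single
#' densely censused 1-ha tropical forest subsample: 150 species, three
#' censuses 5 years apart, ~10,500 mapped stems >= 1 cm dbh, 400 seedling
#' plots of 1 m2 and 150 seed traps of 0.5 m2.
#'
#' @param n_species number of species.
#' @param n_censuses number of censuses (>= 2).
#' @param interval_years census interval in years.
#' @param plot_dims tree plot dimensions (m).
#' @param stems_per_species initial mapped stems per species.
#' @param seedlings_per_species initial tagged seedlings per species.
#' @param n_seedling_plots,seedling_plot_area seedling plot count and area (m2).
#' @param n_traps,trap_area seed trap count and area (m2).
#' @param seed_rain_per_ha median annual seed rain per species (seeds/ha/yr).
#' @param axis_loadings 2 x 9 matrix mapping (axis1, axis2) to the link-scale
#'   rate columns (log for growth, logit for survival and transition).
#' @param trait_loadings 2 x 4 matrix mapping the axes to log-scale traits.
#' @param rate_noise_sd link-scale sd of species deviations around the axis
#'   structure.
#' @param trait_noise_sd log-scale sd of trait deviations.
#' @param growth_sd_tree,growth_sd_seedling within-individual sd of dbh and
#'   height increments (mm per sqrt(yr)).
#' @param base_growth log-scale intercepts of mean annual growth per class
#'   (mm/yr dbh for tree classes, mm/yr height for seedling classes).
#' @param base_survival logit-scale intercepts of annual survival per class.
#' @param base_transition logit-scale intercept of the seed-to-seedling
#'   transition probability.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_species = 150L,
                              n_censuses = 3L,
                              interval_years = 5,
                              plot_dims = c(100, 100),
                              stems_per_species = 70L,
                              seedlings_per_species = 50L,
                              n_seedling_plots = 400L,
                              seedling_plot_area = 1,
                              n_traps = 150L,
                              trap_area = 0.5,
                              seed_rain_per_ha = 2000,
                              axis_loadings = default_axis_loadings(),
                              trait_loadings = default_trait_loadings(),
                              rate_noise_sd = 0.2,
                              trait_noise_sd = 0.4,
                              growth_sd_tree = 3,
                              growth_sd_seedling = 25,
                              base_growth = c(seedling_lt20 = log(30),
                                              seedling_20_50 = log(40),
                                              understory = log(1.2),
                                              overstory = log(3)),
                              base_survival = c(seedling_lt20 = stats::qlogis(0.80),
                                                seedling_20_50 = stats::qlogis(0.88),
                                                understory = stats::qlogis(0.95),
                                                overstory = stats::qlogis(0.97)),
                              base_transition = stats::qlogis(0.08)) {
  if (n_species < 1L) stop("design must contain at least one species")
  stopifnot(n_censuses >= 2L, interval_years > 0, length(plot_dims) == 2L,
            all(plot_dims > 0), stems_per_species >= 1L,
            seedlings_per_species >= 0L, n_seedling_plots >= 1L,
            n_traps >= 1L, trap_area > 0, seedling_plot_area > 0,
            rate_noise_sd >= 0, trait_noise_sd >= 0)
  axis_loadings <- as.matrix(axis_loadings)
  stopifnot(nrow(axis_loadings) == 2L, ncol(axis_loadings) == 9L)
  colnames(axis_loadings) <- rate_columns()$column
  info <- rate_columns()
  g <- info$rate_type == "growth"; s <- info$rate_type == "survival"
  if (!(all(axis_loadings[1, g] * axis_loadings[1, s][1] < 0) &&
        length(unique(sign(axis_loadings[1, g]))) == 1L &&
        length(unique(sign(axis_loadings[1, s]))) == 1L)) {
    stop("axis 1 loadings must oppose growth and survival in all classes")
  }
  seedling <- !is.na(info$stage) & info$stage == "seedling"
  tree <- !is.na(info$stage) & info$stage == "tree"
  if (!all(axis_loadings[2, seedling] * rep(axis_loadings[2, tree], length.out = sum(seedling)) < 0)) {
    stop("axis 2 loadings must oppose seedling and tree classes")
  }
  design <- list(
    n_species = as.integer(n_species), n_censuses = as.integer(n_censuses),
    interval_years = interval_years, plot_dims = plot_dims,
    stems_per_species = as.integer(stems_per_species),
    seedlings_per_species = as.integer(seedlings_per_species),
    n_seedling_plots = as.integer(n_seedling_plots),
    seedling_plot_area = seedling_plot_area,
    n_traps = as.integer(n_traps), trap_area = trap_area,
    seed_rain_per_ha = seed_rain_per_ha,
    axis_loadings = axis_loadings, trait_loadings = as.matrix(trait_loadings),
    rate_noise_sd = rate_noise_sd, trait_noise_sd = trait_noise_sd,
    growth_sd_tree = growth_sd_tree, growth_sd_seedling = growth_sd_seedling,
    base_growth = base_growth, base_survival = base_survival,
    base_transition = base_transition
  )
  class(design) <- "simulation_design"
  design
}

#' Draw species-level parameters along the latent trade-off axes
#'
#' Species positions on the two axes are i.i.d. standard normal; each of the
#' nine rate columns is `loading x axes + noise` on its link scale
#' (exponential link for growth means, logistic for survival and transition
#' probabilities), and the four traits are generated analogously on the log
#' scale. The result is the ground truth every downstream stage is judged
#' against.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: list with `species` (data frame
#'   of ids, axis positions, transition, seed rain and traits), `growth` and
#'   `survival` (n_species x 4 matrices of true mean annual increments and
#'   annual survival probabilities), and the design.
#' @export
draw_species_parameters <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(as.integer(seed))
  n <- design$n_species
  axes <- matrix(stats::rnorm(2L * n), ncol = 2L,
                 dimnames = list(NULL, c("axis1", "axis2")))
  eta <- axes %*% design$axis_loadings +
    matrix(stats::rnorm(n * 9L, sd = design$rate_noise_sd), ncol = 9L)
  cls <- size_classes()
  growth <- exp(sweep(eta[, paste0("growth_", cls), drop = FALSE], 2L,
                      design$base_growth[cls], "+"))
  survival <- stats::plogis(sweep(eta[, paste0("surv_", cls), drop = FALSE], 2L,
                                  design$base_survival[cls], "+"))
  transition <- stats::plogis(design$base_transition + eta[, "log_transition"])
  traits <- exp(axes %*% design$trait_loadings +
                  matrix(stats::rnorm(n * ncol(design$trait_loadings),
                                      sd = design$trait_noise_sd),
                         ncol = ncol(design$trait_loadings)))
  traits <- sweep(traits, 2L, c(max_dbh = 200, wood_density = 0.55,
                                seed_mass = 0.05, sla = 15)[colnames(design$trait_loadings)],
                  "*")
  seed_rain <- design$seed_rain_per_ha * stats::rlnorm(n, 0, 0.5)
  colnames(growth) <- cls
  colnames(survival) <- cls
  truth <- list(
    species = data.frame(species = sprintf("sp%03d", seq_len(n)),
                         axis1 = axes[, 1], axis2 = axes[, 2],
                         transition = transition, seed_rain = seed_rain,
                         traits, stringsAsFactors = FALSE),
    growth = growth, survival = survival, design = design
  )
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic community truth: %d species, %d censuses\n",
              nrow(x$species), x$design$n_censuses))
  invisible(x)
}

# Normal(mean, sd) truncated below at `lower`, via inverse-cdf sampling.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
}

#' Simulate the mapped tree censuses
#'
#' Stems are placed uniformly in the plot with initial diameters from a
#' shifted-exponential size distribution (minimum 10 mm). At every census the
#' simulator layers the living stems with the same perfect-plasticity rule as
#' the analysis (site-default allometry), then over each interval a stem in
#' class k survives with probability `s_k^t` and survivors add a dbh
#' increment drawn from Normal(g_k * t, sd * sqrt(t)) truncated below at
#' 0.1 mm. Dead stems are recorded once, at the first census after death.
#'
#' @param truth a [draw_species_parameters()] result.
#' @param seed integer seed.
#' @return stem table in the [census_tables] schema.
#' @export
simulate_tree_census <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  design <- truth$design
  set.seed(as.integer(seed))
  n <- design$n_species * design$stems_per_species
  state <- data.frame(
    tree_id = sprintf("t%06d", seq_len(n)),
    species = rep(truth$species$species, each = design$stems_per_species),
    x = stats::runif(n, 0, design$plot_dims[1]),
    y = stats::runif(n, 0, design$plot_dims[2]),
    dbh = 10 + stats::rexp(n, rate = 1 / 45),
    alive = TRUE, recorded_dead = FALSE,
    stringsAsFactors = FALSE
  )
  allometry <- synthetic_allometry()
  t_int <- design$interval_years
  rows <- vector("list", design$n_censuses)
  spi <- match(state$species, truth$species$species)
  for (ci in seq_len(design$n_censuses)) {
    date <- 2000 + (ci - 1L) * t_int
    rec <- state$alive | !state$recorded_dead
    rows[[ci]] <- data.frame(
      tree_id = state$tree_id[rec], species = state$species[rec],
      x = state$x[rec], y = state$y[rec],
      census_index = ci, census_date = date,
      dbh = ifelse(state$alive[rec], state$dbh[rec], NA_real_),
      status = ifelse(state$alive[rec], "alive", "dead"),
      stringsAsFactors = FALSE
    )
    state$recorded_dead[!state$alive] <- TRUE
    if (ci == design$n_censuses) break
    # class-specific demography for the coming interval
    census <- rows[[ci]][rows[[ci]]$status == "alive", , drop = FALSE]
    layers <- assign_layers(census, allometry, design$plot_dims)
    layer <- layers$layer[match(state$tree_id, layers$tree_id)]
    idx_alive <- which(state$alive)
    cls <- layer[idx_alive]
    s <- truth$survival[cbind(spi[idx_alive], match(cls, size_classes()))]
    g <- truth$growth[cbind(spi[idx_alive], match(cls, size_classes()))]
    surv <- stats::runif(length(idx_alive)) < s^t_int
    state$alive[idx_alive[!surv]] <- FALSE
    grow_idx <- idx_alive[surv]
    inc <- rtruncnorm_lower(length(grow_idx), g[surv] * t_int,
                            design$growth_sd_tree * sqrt(t_int), 0.1)
    state$dbh[grow_idx] <- state$dbh[grow_idx] + inc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate seedling plots and seed traps
#'
#' Seed rain is spatially uniform: per species and census interval each trap
#' collects a Poisson count with mean `rain * trap_area * t`. New recruits
#' appear in the seedling plots as a Poisson draw with mean
#' `rain * transition * plot_area * t`, enter at heights uniform in (10, 200)
#' mm (so they start in the below-20-cm class) and are first recorded at the
#' census closing the interval. Established seedlings survive and grow by the
#' height-class rates exactly as stems do by diameter.
#'
#' @param truth a [draw_species_parameters()] result.
#' @param seed integer seed.
#' @return list with `seedlings` and `seed_traps` tables in the
#'   [census_tables] schema.
#' @export
simulate_seedlings_and_seeds <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  design <- truth$design
  set.seed(as.integer(seed))
  n0 <- design$n_species * design$seedlings_per_species
  t_int <- design$interval_years
  state <- data.frame(
    seedling_id = sprintf("q%06d", seq_len(n0)),
    species = rep(truth$species$species, each = design$seedlings_per_species),
    plot_id = sprintf("p%04d", sample.int(design$n_seedling_plots, n0, replace = TRUE)),
    height = stats::runif(n0, 10, 450),
    alive = TRUE, recorded_dead = FALSE,
    stringsAsFactors = FALSE
  )
  plot_area_total <- design$n_seedling_plots * design$seedling_plot_area
  trap_area <- design$trap_area
  seed_rows <- list()
  rows <- vector("list", design$n_censuses)
  recruit_counter <- 0L
  for (ci in seq_len(design$n_censuses)) {
    date <- 2000 + (ci - 1L) * t_int
    rec <- state$alive | !state$recorded_dead
    rows[[ci]] <- data.frame(
      seedling_id = state$seedling_id[rec], species = state$species[rec],
      plot_id = state$plot_id[rec], plot_area = design$seedling_plot_area,
      census_date = date,
      height = ifelse(state$alive[rec], state$height[rec], NA_real_),
      status = ifelse(state$alive[rec], "alive", "dead"),
      stringsAsFactors = FALSE
    )
    state$recorded_dead[!state$alive] <- TRUE
    if (ci == design$n_censuses) break
    # seed rain caught in traps over the interval
    rain <- truth$species$seed_rain          # seeds / ha / yr
    counts <- stats::rpois(design$n_traps * design$n_species,
                           lambda = rep(rain, each = design$n_traps) / 1e4 *
                             trap_area * t_int)
    seed_rows[[ci]] <- data.frame(
      trap_id = rep(sprintf("tr%03d", seq_len(design$n_traps)), times = design$n_species),
      species = rep(truth$species$species, each = design$n_traps),
      window_start = date, window_end = date + t_int,
      count = counts, trap_area = trap_area,
      stringsAsFactors = FALSE
    )
    # established seedlings: class by height at the interval start
    idx_alive <- which(state$alive)
    cls <- ifelse(state$height[idx_alive] < 200, "seedling_lt20", "seedling_20_50")
    spi <- match(state$species[idx_alive], truth$species$species)
    ki <- match(cls, size_classes())
    s <- truth$survival[cbind(spi, ki)]
    g <- truth$growth[cbind(spi, ki)]
    surv <- stats::runif(length(idx_alive)) < s^t_int
    state$alive[idx_alive[!surv]] <- FALSE
    grow_idx <- idx_alive[surv]
    inc <- rtruncnorm_lower(length(grow_idx), g[surv] * t_int,
                            design$growth_sd_seedling * sqrt(t_int), 0.1)
    state$height[grow_idx] <- state$height[grow_idx] + inc
    # new recruits from the seed rain, thinned to the monitored plot area
    lam <- rain * truth$species$transition * plot_area_total / 1e4 * t_int
    n_rec <- stats::rpois(design$n_species, lam)
    if (sum(n_rec) > 0L) {
      nr <- sum(n_rec)
      recruits <- data.frame(
        seedling_id = sprintf("r%06d", recruit_counter + seq_len(nr)),
        species = rep(truth$species$species, n_rec),
        plot_id = sprintf("p%04d", sample.int(design$n_seedling_plots, nr, replace = TRUE)),
        height = stats::runif(nr, 10, 200),
        alive = TRUE, recorded_dead = FALSE,
        stringsAsFactors = FALSE
      )
      recruit_counter <- recruit_counter + nr
      state <- rbind(state, recruits)
    }
  }
  seedlings <- do.call(rbind, rows)
  seedlings <- seedlings[order(seedlings$seedling_id, seedlings$census_date), ]
  rownames(seedlings) <- NULL
  traps <- do.call(rbind, seed_rows)
  rownames(traps) <- NULL
  list(seedlings = seedlings, seed_traps = traps)
}

synthetic_allometry <- function() {
  data.frame(species = ".default", a = 0.03615016, b = 1.281928,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic community
#'
#' Convenience wrapper: draws the species parameters and simulates trees,
#' seedlings and seed traps with seeds derived deterministically from one
#' master seed.
#'
#' @param design a [simulation_design()].
#' @param seed master integer seed.
#' @return list with `trees`, `seedlings`, `seed_traps`, `allometry`,
#'   `traits` tables and the `truth` object.
#' @export
simulate_community <- function(design = simulation_design(), seed = 1L) {
  truth <- draw_species_parameters(design, derive_seed(seed, "truth"))
  trees <- simulate_tree_census(truth, derive_seed(seed, "trees"))
  sl <- simulate_seedlings_and_seeds(truth, derive_seed(seed, "seedlings"))
  traits <- data.frame(species = truth$species$species,
                       truth$species[, c("max_dbh", "wood_density",
                                         "seed_mass", "sla")],
                       stringsAsFactors = FALSE)
  list(trees = trees, seedlings = sl$seedlings, seed_traps = sl$seed_traps,
       allometry = synthetic_allometry(), traits = traits, truth = truth)
}

#' True rate matrix implied by a synthetic truth
#'
#' Maps the generator's species parameters onto the analysis scales of the
#' 9-column rate matrix (modulus-transformed growth, log expected lifespan,
#' log capped transition), for parameter-recovery and axis-congruence checks.
#'
#' @param truth a `synthetic_truth`.
#' @param lambda modulus exponent.
#' @return n_species x 9 numeric matrix with species rownames.
#' @export
true_rates_matrix <- function(truth, lambda = 0.4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- cbind(modulus_transform(truth$growth, lambda),
             lifespan_transform(truth$survival),
             log(pmin(truth$species$transition, 1)))
  dimnames(m) <- list(truth$species$species, rate_columns()$column)
  m
}
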