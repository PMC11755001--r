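#' Growth observations from consecutive censuses
#'
#' For every individual whose main stem survived a census interval, the
#' annual increment is `(size_t2 - size_t1) / t` — dbh (mm/yr) for trees,
#' height (mm/yr) for seedlings. The size class of an observation is fixed by
#' the state at the FIRST census of the interval: the canopy layer assignment
#' for trees, the height class for seedlings (below `breaks[1]` mm, between
#' `breaks[1]` and `breaks[2]` mm; taller seedlings are outside the study
#' focus and dropped). Negative increments (shrinkage, breakage) are
#' retained; the modulus transform handles them downstream.
#'
#' @param trees stem table (validated schema) or `NULL`.
#' @param seedlings seedling table or `NULL`.
#' @param assignments canopy assignment table from [assign_layers()] covering
#'   every census (required when `trees` is given).
#' @param breaks seedling height class breaks in mm.
#' @return data frame with `species`, `size_class`, `increment`, `t`.
#' @export
extract_growth_observations <- function(trees = NULL, seedlings = NULL,
                                        assignments = NULL,
                                        breaks = c(200, 500)) {
  out <- list()
  if (!is.null(trees)) {
    if (is.null(assignments)) stop("tree growth requires canopy assignments")
    p <- consecutive_pairs(trees, "tree_id", "dbh")
    surv <- p$status1 == "alive" & p$status2 == "alive"
    p <- p[surv, , drop = FALSE]
    key <- paste(p$id, p$census_index1)
    akey <- paste(assignments$tree_id, assignments$census_index)
    layer <- assignments$layer[match(key, akey)]
    if (anyNA(layer)) stop("missing canopy assignment for ",
                           sum(is.na(layer)), " tree interval(s)")
    out$trees <- data.frame(
      species = p$species, size_class = layer,
      increment = (p$size2 - p$size1) / p$t, t = p$t,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(seedlings)) {
    p <- consecutive_pairs(seedlings, "seedling_id", "height")
    surv <- p$status1 == "alive" & p$status2 == "alive"
    p <- p[surv, , drop = FALSE]
    cls <- seedling_class(p$size1, breaks)
    keep <- !is.na(cls)
    out$seedlings <- data.frame(
      species = p$species[keep], size_class = cls[keep],
      increment = (p$size2[keep] - p$size1[keep]) / p$t[keep], t = p$t[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(species = character(0),
                                      size_class = character(0),
                                      increment = numeric(0), t = numeric(0))
  rownames(res) <- NULL
  res
}

#' Survival observations from consecutive censuses
#'
#' One binary observation per individual alive at the first census of an
#' interval and recorded again at the next: `alive = 1` if still alive,
#' `alive = 0` if dead, together with the interval length `t` in years.
#' Individuals recorded as `missing` at the second census are censored and
#' contribute no observation. Classes follow the first-census state as for
#' growth.
#'
#' @inheritParams extract_growth_observations
#' @return data frame with `species`, `size_class`, `alive`, `t`.
#' @export
extract_survival_observations <- function(trees = NULL, seedlings = NULL,
                                          assignments = NULL,
                                          breaks = c(200, 500)) {
  out <- list()
  if (!is.null(trees)) {
    if (is.null(assignments)) stop("tree survival requires canopy assignments")
    p <- consecutive_pairs(trees, "tree_id", "dbh")
    p <- p[p$status1 == "alive" & p$status2 %in% c("alive", "dead"), , drop = FALSE]
    key <- paste(p$id, p$census_index1)
    akey <- paste(assignments$tree_id, assignments$census_index)
    layer <- assignments$layer[match(key, akey)]
    out$trees <- data.frame(
      species = p$species, size_class = layer,
      alive = as.integer(p$status2 == "alive"), t = p$t,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(seedlings)) {
    p <- consecutive_pairs(seedlings, "seedling_id", "height")
    p <- p[p$status1 == "alive" & p$status2 %in% c("alive", "dead"), , drop = FALSE]
    cls <- seedling_class(p$size1, breaks)
    keep <- !is.na(cls)
    out$seedlings <- data.frame(
      species = p$species[keep], size_class = cls[keep],
      alive = as.integer(p$status2[keep] == "alive"), t = p$t[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(species = character(0),
                                      size_class = character(0),
                                      alive = integer(0), t = numeric(0))
  rownames(res) <- NULL
  res
}

# All (record_i, record_{i+1}) pairs of consecutive censuses per individual.
consecutive_pairs <- function(df, id_col, size_col) {
  ord <- order(df[[id_col]], df$census_date, method = "radix")
  df <- df[ord, , drop = FALSE]
  same <- df[[id_col]][-nrow(df)] == df[[id_col]][-1L]
  i <- which(same)
  ci1 <- if ("census_index" %in% names(df)) df$census_index[i] else
    stats::ave(seq_along(df[[id_col]]), df[[id_col]], FUN = seq_along)[i]
  data.frame(
    id = df[[id_col]][i], species = df$species[i],
    census_index1 = ci1,
    size1 = df[[size_col]][i], size2 = df[[size_col]][i + 1L],
    status1 = df$status[i], status2 = df$status[i + 1L],
    t = df$census_date[i + 1L] - df$census_date[i],
    stringsAsFactors = FALSE
  )
}

seedling_class <- function(height, breaks) {
  ifelse(height < breaks[1], "seedling_lt20",
         ifelse(height < breaks[2], "seedling_20_50", NA_character_))
}

#' Cap observations per species and size class
#'
#' Keeps all observations when a species has at most `cap` in a class, and a
#' seeded uniform without-replacement subsample of exactly `cap` otherwise.
#' Mirrors the sampling caps used to bound model fitting cost (200 growth /
#' 1000 survival observations per species and class).
#'
#' @param obs observation data frame with `species` and `size_class`.
#' @param cap maximum observations per species-by-class cell, positive.
#' @param seed integer seed; identical seeds give identical subsets.
#' @return subset of `obs` rows.
#' @export
subsample_observations <- function(obs, cap, seed = 1L) {
  stopifnot(cap > 0)
  set.seed(as.integer(seed))
  cell <- paste(obs$species, obs$size_class, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(obs)), factor(cell, levels = sort(unique(cell)))),
                        function(idx) {
                          if (length(idx) <= cap) idx else sort(sample(idx, cap))
                        }), use.names = FALSE)
  obs[sort(keep), , drop = FALSE]
}
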