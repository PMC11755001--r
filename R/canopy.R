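#' Crown area from stem diameter
#'
#' Power-law crown allometry: crown area (m2) = `a * dbh^b` with dbh in
#' millimeters. Coefficients are species-specific where available, otherwise
#' a site-level default applies (e.g. a = 0.03615016, b = 1.281928 for a
#' Neotropical moist forest).
#'
#' @param dbh_mm stem diameter (mm), positive.
#' @param a,b allometric coefficients, positive.
#' @return crown area in square meters.
#' @export
crown_area <- function(dbh_mm, a, b) {
  stopifnot(is.numeric(dbh_mm), is.numeric(a), is.numeric(b))
  if (any(dbh_mm <= 0, na.rm = TRUE)) stop("dbh must be positive")
  if (any(a <= 0, na.rm = TRUE) || any(b <= 0, na.rm = TRUE)) {
    stop("allometric coefficients must be positive")
  }
  a * dbh_mm^b
}

#' Tile a plot into canopy subplots
#'
#' Divides an axis-aligned rectangular plot into half-open square tiles
#' `[i*s, (i+1)*s) x [j*s, (j+1)*s)` of side `s` (default 31.5 m), starting
#' at the south-west corner. Trailing partial tiles along the north and east
#' edges are kept as smaller subplots with their true area, so the threshold
#' of the packing rule always refers to actual ground area.
#'
#' @param plot_dims numeric `c(xmax, ymax)` in meters, positive.
#' @param side tile side length in meters.
#' @return data frame with one row per tile: `subplot_id`, `x0`, `y0`,
#'   `width`, `height`, `area`.
#' @export
grid_subplots <- function(plot_dims, side = 31.5) {
  stopifnot(length(plot_dims) == 2L, all(plot_dims > 0), side > 0)
  nx <- ceiling(plot_dims[1] / side)
  ny <- ceiling(plot_dims[2] / side)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  width <- pmin(side, plot_dims[1] - ix * side)
  height <- pmin(side, plot_dims[2] - iy * side)
  data.frame(
    subplot_id = sprintf("s%03d_%03d", ix, iy),
    x0 = ix * side, y0 = iy * side,
    width = width, height = height,
    area = width * height,
    stringsAsFactors = FALSE
  )
}

#' Locate points in the subplot grid
#'
#' @param x,y coordinates in meters from the south-west corner.
#' @param plot_dims plot dimensions `c(xmax, ymax)`.
#' @param side tile side length (m).
#' @return character vector of subplot ids matching [grid_subplots()].
#' @export
subplot_of <- function(x, y, plot_dims, side = 31.5) {
  stopifnot(length(plot_dims) == 2L)
  if (any(x < 0 | y < 0 | x > plot_dims[1] | y > plot_dims[2], na.rm = TRUE)) {
    stop("point outside plot bounds")
  }
  # points exactly on the far boundary fall in the last (partial) tile
  ix <- pmin(floor(x / side), ceiling(plot_dims[1] / side) - 1)
  iy <- pmin(floor(y / side), ceiling(plot_dims[2] / side) - 1)
  sprintf("s%03d_%03d", ix, iy)
}

lookup_allometry <- function(species, allometry) {
  idx <- match(species, allometry$species)
  default <- match(".default", allometry$species)
  idx[is.na(idx)] <- default
  if (anyNA(idx)) {
    stop("no allometric coefficients and no site default for species: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  allometry[idx, c("a", "b")]
}

#' Assign stems to canopy layers by crown packing
#'
#' Implements the perfect-plasticity canopy assignment for one census:
#' within each subplot the alive stems are ranked from largest to smallest
#' dbh (ties broken by tree id so the output is reproducible) and assigned
#' to the overstory in that order until their cumulative crown area exceeds
#' `multiplier` times the subplot ground area; all remaining stems are
#' understory. By default the stem whose crown first pushes the cumulative
#' sum over the threshold is still overstory (`include_crossing = TRUE`);
#' the stricter reading that stops before the crossing is available via the
#' switch.
#'
#' @param stems data frame of one census with columns `tree_id`, `species`,
#'   `x`, `y`, `dbh`, `status` (and optionally `census_index`). Only alive
#'   stems are assigned.
#' @param allometry allometry table (`species`, `a`, `b`; optional
#'   `".default"` row).
#' @param plot_dims plot dimensions `c(xmax, ymax)` in meters.
#' @param side subplot side (m).
#' @param multiplier crown-packing threshold as a multiple of subplot area.
#' @param include_crossing see Description.
#' @return data frame with `tree_id`, `species`, `census_index`,
#'   `subplot_id`, `crown_area`, `layer` (`"overstory"`/`"understory"`).
#' @export
assign_layers <- function(stems, allometry, plot_dims, side = 31.5,
                          multiplier = 2.0, include_crossing = TRUE) {
  stopifnot(multiplier > 0)
  alive <- stems[!is.na(stems$status) & stems$status == "alive", , drop = FALSE]
  if (nrow(alive) == 0L) {
    return(data.frame(tree_id = character(0), species = character(0),
                      census_index = integer(0), subplot_id = character(0),
                      crown_area = numeric(0), layer = character(0),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(alive$dbh)) stop("alive stems must have a dbh for crown allometry")
  ab <- lookup_allometry(alive$species, allometry)
  grid <- grid_subplots(plot_dims, side)
  sub <- subplot_of(alive$x, alive$y, plot_dims, side)
  out <- data.frame(
    tree_id = alive$tree_id,
    species = alive$species,
    census_index = if ("census_index" %in% names(alive)) alive$census_index else NA_integer_,
    subplot_id = sub,
    crown_area = crown_area(alive$dbh, ab$a, ab$b),
    layer = NA_character_,
    stringsAsFactors = FALSE
  )
  ord <- order(out$subplot_id, -alive$dbh, out$tree_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  area <- grid$area[match(out$subplot_id, grid$subplot_id)]
  threshold <- multiplier * area
  cum <- stats::ave(out$crown_area, out$subplot_id, FUN = cumsum)
  # a stem is assigned while the cumulative area of its predecessors has not
  # yet exceeded the threshold; under the stricter reading the crossing stem
  # itself is already understory
  out$layer <- if (include_crossing) {
    ifelse(cum - out$crown_area <= threshold, "overstory", "understory")
  } else {
    ifelse(cum <= threshold, "overstory", "understory")
  }
  rownames(out) <- NULL
  out
}
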