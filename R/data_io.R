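#' @name census_tables
#' @title Census table schemas and validation
#'
#' @description
#' The pipeline consumes five long-format, comma-separated tables with
#' mandatory header rows (UTF-8; dates as decimal years; coordinates in
#' meters from the plot's south-west corner):
#'
#' * **stems** — `tree_id, species, x, y, census_index, census_date, dbh,
#'   status`: one row per individual and census; `dbh` in mm (NA when dead),
#'   `status` one of `alive`/`dead`. Tree tables hold individuals >= 1 cm
#'   dbh, so `dbh >= 10` whenever alive.
#' * **seedlings** — `seedling_id, species, plot_id, plot_area, census_date,
#'   height, status`: `height` in mm (> 0 when alive), `plot_area` in m2,
#'   `status` one of `alive`/`dead`/`missing`. Missing seedlings contribute
#'   no survival observation for that interval.
#' * **seed traps** — `trap_id, species, window_start, window_end, count,
#'   trap_area`: seed counts per trap, species and collection window
#'   (decimal years), `trap_area` in m2.
#' * **allometry** — `species, a, b`: crown area (m2) = `a * dbh(mm)^b`; a
#'   row with species `".default"` supplies the site-level fallback.
#' * **traits** — `species, max_dbh, wood_density, seed_mass, sla`: any cell
#'   may be NA; present values must be positive.
#'
#' `validate_*` functions split a data frame into accepted typed records and
#' rejected rows with row-level reasons; `read_census_tables()` applies them
#' to files.
NULL

table_schemas <- list(
  stems = list(
    cols = c("tree_id", "species", "x", "y", "census_index", "census_date",
             "dbh", "status"),
    numeric = c("x", "y", "census_index", "census_date", "dbh"),
    character = c("tree_id", "species", "status")
  ),
  seedlings = list(
    cols = c("seedling_id", "species", "plot_id", "plot_area", "census_date",
             "height", "status"),
    numeric = c("plot_area", "census_date", "height"),
    character = c("seedling_id", "species", "plot_id", "status")
  ),
  seed_traps = list(
    cols = c("trap_id", "species", "window_start", "window_end", "count",
             "trap_area"),
    numeric = c("window_start", "window_end", "count", "trap_area"),
    character = c("trap_id", "species")
  ),
  allometry = list(
    cols = c("species", "a", "b"),
    numeric = c("a", "b"),
    character = "species"
  ),
  traits = list(
    cols = c("species", "max_dbh", "wood_density", "seed_mass", "sla"),
    numeric = c("max_dbh", "wood_density", "seed_mass", "sla"),
    character = "species"
  )
)

check_columns <- function(df, what) {
  schema <- table_schemas[[what]]
  missing <- setdiff(schema$cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in schema$numeric) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(df[[col]] <- as.numeric(as.character(df[[col]])))
    }
  }
  for (col in schema$character) df[[col]] <- as.character(df[[col]])
  df[schema$cols]
}

# Accumulate row-level reasons, then partition once.
reject_frame <- function(df, reasons) {
  bad <- !is.na(reasons)
  list(records = df[!bad, , drop = FALSE],
       rejected = cbind(df[bad, , drop = FALSE],
                        reason = reasons[bad])[seq_len(sum(bad)), , drop = FALSE])
}

first_reason <- function(n, ...) {
  reasons <- rep(NA_character_, n)
  checks <- list(...)
  for (i in seq(1, length(checks), by = 2)) {
    hit <- checks[[i]] & is.na(reasons)
    reasons[hit] <- checks[[i + 1]]
  }
  reasons
}

# strictly increasing dates in the order the censuses appear per individual;
# a stable sort on id alone keeps the file's row order within individuals
flag_nonincreasing_dates <- function(id, date) {
  ord <- order(id, method = "radix")
  dup <- unlist(tapply(date[ord], factor(id[ord], levels = unique(id[ord])),
                       function(d) c(FALSE, diff(d) <= 0)), use.names = FALSE)
  bad_ids <- unique(id[ord][dup])
  id %in% bad_ids
}

#' Validate a stem table
#'
#' @param df data frame with the stem schema (see [census_tables]).
#' @param plot_dims optional numeric `c(xmax, ymax)`; when given, stems
#'   outside `[0, xmax] x [0, ymax]` are rejected.
#' @return list with `records` (accepted rows), `rejected` (rows plus a
#'   `reason` column; all censuses of a tree with non-increasing dates are
#'   rejected together), and `summary` (n stems, n species, n censuses).
#' @export
validate_stem_table <- function(df, plot_dims = NULL) {
  df <- check_columns(df, "stems")
  alive <- !is.na(df$status) & df$status == "alive"
  out_of_bounds <- if (is.null(plot_dims)) rep(FALSE, nrow(df)) else {
    !is.na(df$x) & !is.na(df$y) &
      (df$x < 0 | df$y < 0 | df$x > plot_dims[1] | df$y > plot_dims[2])
  }
  reasons <- first_reason(
    nrow(df),
    is.na(df$tree_id) | df$tree_id == "", "missing tree_id",
    is.na(df$species) | df$species == "", "missing species",
    !df$status %in% c("alive", "dead"), "unknown status",
    is.na(df$census_date), "unparseable census date",
    alive & is.na(df$dbh), "alive stem without dbh",
    alive & !is.na(df$dbh) & df$dbh < 0, "negative dbh",
    alive & !is.na(df$dbh) & df$dbh < 10, "dbh below 10 mm in tree table",
    out_of_bounds, "coordinates outside plot"
  )
  keep <- is.na(reasons)
  bad_dates <- rep(FALSE, nrow(df))
  if (any(keep)) {
    bad_dates[keep] <- flag_nonincreasing_dates(df$tree_id[keep],
                                                df$census_date[keep])
  }
  reasons[keep & bad_dates] <- "census dates not strictly increasing for tree"
  res <- reject_frame(df, reasons)
  res$summary <- c(n_stems = length(unique(res$records$tree_id)),
                   n_species = length(unique(res$records$species)),
                   n_censuses = length(unique(res$records$census_index)))
  res
}

#' Validate a seedling table
#' @inheritParams validate_stem_table
#' @return list with `records`, `rejected`, `summary`.
#' @export
validate_seedling_table <- function(df) {
  df <- check_columns(df, "seedlings")
  alive <- !is.na(df$status) & df$status == "alive"
  reasons <- first_reason(
    nrow(df),
    is.na(df$seedling_id) | df$seedling_id == "", "missing seedling_id",
    is.na(df$species) | df$species == "", "missing species",
    !df$status %in% c("alive", "dead", "missing"), "unknown status",
    is.na(df$census_date), "unparseable census date",
    is.na(df$plot_area) | df$plot_area <= 0, "nonpositive plot area",
    alive & (is.na(df$height) | df$height <= 0), "alive seedling without positive height"
  )
  keep <- is.na(reasons)
  bad_dates <- rep(FALSE, nrow(df))
  if (any(keep)) {
    bad_dates[keep] <- flag_nonincreasing_dates(df$seedling_id[keep],
                                                df$census_date[keep])
  }
  reasons[keep & bad_dates] <- "census dates not strictly increasing for seedling"
  res <- reject_frame(df, reasons)
  res$summary <- c(n_seedlings = length(unique(res$records$seedling_id)),
                   n_species = length(unique(res$records$species)))
  res
}

#' Validate a seed-trap table
#' @inheritParams validate_stem_table
#' @return list with `records`, `rejected`, `summary`.
#' @export
validate_seed_trap_table <- function(df) {
  df <- check_columns(df, "seed_traps")
  reasons <- first_reason(
    nrow(df),
    is.na(df$species) | df$species == "", "missing species",
    is.na(df$count) | df$count < 0 | df$count != round(df$count),
    "count not a nonnegative integer",
    is.na(df$trap_area) | df$trap_area <= 0, "nonpositive trap area",
    is.na(df$window_start) | is.na(df$window_end) |
      df$window_end <= df$window_start, "empty or inverted collection window"
  )
  res <- reject_frame(df, reasons)
  res$summary <- c(n_traps = length(unique(res$records$trap_id)),
                   n_species = length(unique(res$records$species)))
  res
}

#' Validate an allometry table
#' @inheritParams validate_stem_table
#' @return list with `records`, `rejected`.
#' @export
validate_allometry_table <- function(df) {
  df <- check_columns(df, "allometry")
  reasons <- first_reason(
    nrow(df),
    is.na(df$species) | df$species == "", "missing species",
    is.na(df$a) | df$a <= 0, "nonpositive crown-area coefficient a",
    is.na(df$b) | df$b <= 0, "nonpositive crown-area exponent b"
  )
  reject_frame(df, reasons)
}

#' Validate a species trait table
#' @inheritParams validate_stem_table
#' @return list with `records`, `rejected`.
#' @export
validate_trait_table <- function(df) {
  df <- check_columns(df, "traits")
  nonpos <- function(v) !is.na(v) & v <= 0
  reasons <- first_reason(
    nrow(df),
    is.na(df$species) | df$species == "", "missing species",
    nonpos(df$max_dbh) | nonpos(df$wood_density) |
      nonpos(df$seed_mass) | nonpos(df$sla), "nonpositive trait value"
  )
  reject_frame(df, reasons)
}

#' Read and validate the pipeline input tables
#'
#' Reads comma-separated files with mandatory headers and runs the schema
#' validators. Any table may be omitted (`NULL` path). A short summary of
#' accepted and rejected rows is reported via `message()`.
#'
#' @param paths named list with any of `stems`, `seedlings`, `seed_traps`,
#'   `allometry`, `traits` giving file paths.
#' @param plot_dims optional plot dimensions passed to the stem validator.
#' @return named list of validator results (see [validate_stem_table()]).
#' @export
read_census_tables <- function(paths, plot_dims = NULL) {
  validators <- list(stems = function(df) validate_stem_table(df, plot_dims),
                     seedlings = validate_seedling_table,
                     seed_traps = validate_seed_trap_table,
                     allometry = validate_allometry_table,
                     traits = validate_trait_table)
  unknown <- setdiff(names(paths), names(validators))
  if (length(unknown)) stop("unknown table name(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (nm in names(paths)) {
    if (is.null(paths[[nm]])) next
    df <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    out[[nm]] <- validators[[nm]](df)
    message(sprintf("%s: %d rows accepted, %d rejected", nm,
                    nrow(out[[nm]]$records), nrow(out[[nm]]$rejected)))
  }
  out
}

#' Write a pipeline table as CSV
#'
#' UTF-8, comma-separated, header row, no row names, NA cells left empty —
#' the exact dialect [read_census_tables()] expects back, so write/read
#' round-trips are lossless.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
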