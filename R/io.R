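#' @importFrom utils read.csv write.csv
NULL

.community_base_cols <- c("haul_id", "lon", "lat", "year", "depth",
                          "bot_temp", "seabed", "swept_area")
.seabed_levels <- c("mud_to_muddy_sand", "sand")

#' Names of the species count columns of a community table
#'
#' Count columns are prefixed `sp_`; everything else is haul metadata.
#'
#' @param table a community table (`data.frame`).
#' @return character vector of count column names (possibly empty).
#' @export
species_columns <- function(table) {
  grep("^sp_", names(table), value = TRUE)
}

#' Validate a haul-by-species community table
#'
#' Checks the schema shared by all pipeline stages: one row per haul with
#' coordinates (WGS84 decimal degrees), survey year, depth (m, > 0), bottom
#' temperature (deg C), seabed class (`mud_to_muddy_sand` or `sand`), swept
#' area (km^2, > 0) and non-negative integer counts in `sp_`-prefixed columns.
#'
#' @param table a `data.frame`.
#' @return `table`, invisibly, if valid; otherwise an error.
#' @export
validate_community <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(.community_base_cols, names(table))
  if (length(missing))
    stop("community table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(table$haul_id))
    stop("duplicate haul_id values in community table")
  if (!length(species_columns(table)))
    stop("community table has no species count columns (prefix 'sp_')")
  num_cols <- c("lon", "lat", "year", "depth", "bot_temp", "swept_area")
  for (cl in num_cols)
    if (!is.numeric(table[[cl]]) || anyNA(table[[cl]]))
      stop("column '", cl, "' must be numeric with no missing values")
  if (any(table$depth <= 0)) stop("depth must be strictly positive")
  if (any(table$swept_area <= 0)) stop("swept_area must be strictly positive")
  bad <- setdiff(unique(as.character(table$seabed)), .seabed_levels)
  if (length(bad))
    stop("unknown seabed level(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.seabed_levels, collapse = " or "), ")")
  Y <- as.matrix(table[species_columns(table)])
  if (anyNA(Y) || any(Y < 0) || any(Y != round(Y)))
    stop("species counts must be non-negative integers with no missing values")
  invisible(table)
}

#' Read / write community tables
#'
#' CSV with the exact schema checked by [validate_community()].
#'
#' @param path file path.
#' @return `read_community()` returns a validated `data.frame`.
#' @export
read_community <- function(path) {
  if (!file.exists(path)) stop("community file not found: ", path)
  validate_community(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_community
#' @param table community table to write.
#' @export
write_community <- function(table, path) {
  validate_community(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' Expects columns `species`, `age_maturity` (years, > 0), `repro_mode`
#' (`viviparous`/`oviparous`, mapped to 1/0) and `trophic_level`. Flags (with
#' a warning) pairwise trait correlations of |r| >= 0.7, the collinearity
#' screen applied to candidate covariates and traits.
#'
#' @param path CSV path.
#' @return `data.frame` with numeric columns `age_maturity`, `repro_mode`
#'   (1 = viviparous), `trophic_level`, keyed by `species`.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "age_maturity", "repro_mode", "trophic_level")
  missing <- setdiff(need, names(tr))
  if (length(missing))
    stop("trait table is missing columns: ", paste(missing, collapse = ", "))
  if (is.character(tr$repro_mode)) {
    bad <- setdiff(unique(tr$repro_mode), c("viviparous", "oviparous"))
    if (length(bad))
      stop("unknown repro_mode level(s): ", paste(bad, collapse = ", "))
    tr$repro_mode <- as.integer(tr$repro_mode == "viviparous")
  }
  if (anyNA(tr[need])) stop("trait table contains missing values")
  if (any(tr$age_maturity <= 0)) stop("age_maturity must be positive")
  if (any(tr$trophic_level <= 2 | tr$trophic_level >= 5))
    stop("trophic_level outside the plausible (2, 5) range")
  cm <- stats::cor(tr[, c("age_maturity", "repro_mode", "trophic_level")])
  if (any(abs(cm[upper.tri(cm)]) >= 0.7))
    warning("some traits are highly correlated (|r| >= 0.7)")
  tr[c("species", "age_maturity", "repro_mode", "trophic_level")]
}

#' Read a ranked taxonomy table
#'
#' CSV with a `species` identifier plus the six ranks `phylum`, `class`,
#' `order`, `family`, `genus`, `species_name`, ordered coarse to fine.
#'
#' @param path CSV path.
#' @return `data.frame` of the seven columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tx <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", .taxonomy_ranks)
  missing <- setdiff(need, names(tx))
  if (length(missing))
    stop("taxonomy table is missing columns: ", paste(missing, collapse = ", "))
  if (anyNA(tx[need]) || any(tx[need] == ""))
    stop("taxonomy table contains missing ranks")
  tx[need]
}

#' Read a prediction grid
#'
#' CSV of cell centres with columns `cell_id`, `lon`, `lat`, `year`, `depth`,
#' `bot_temp`, `seabed`; `cell_area` (km^2) is computed from latitude via
#' [cell_areas()] when absent.
#'
#' @param path CSV path.
#' @param resolution cell size in degrees used when computing `cell_area`.
#' @return validated `data.frame` including `cell_area`.
#' @export
read_grid <- function(path, resolution = 0.05) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  g <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lon", "lat", "year", "depth", "bot_temp", "seabed")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop("grid table is missing columns: ", paste(missing, collapse = ", "))
  if (!"cell_area" %in% names(g))
    g$cell_area <- cell_areas(g$lat, resolution = resolution)
  if (any(g$cell_area <= 0)) stop("cell_area must be strictly positive")
  g
}

#' Write trait, taxonomy and grid tables
#'
#' Plain-CSV writers matching the corresponding readers, so a write/read
#' round trip is the identity (numeric `repro_mode` is accepted on reading).
#'
#' @param x the table to write.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(x, path) {
  stopifnot(all(c("species", "age_maturity", "repro_mode",
                  "trophic_level") %in% names(x)))
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(all(c("species", .taxonomy_ranks) %in% names(x)))
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
write_grid <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged Adriatic elasmobranch reference tables
#'
#' Trait values (age at first maturity in years, reproductive mode, trophic
#' level) and ranked taxonomy for the nine demersal elasmobranchs retained
#' from the 1996-2019 North-Central Adriatic MEDITS hauls, as compiled from
#' the published field-guide and diet-study sources.
#'
#' @return a `data.frame` (traits or taxonomy).
#' @export
adriatic_traits <- function() {
  read_traits(system.file("extdata", "adriatic_traits.csv",
                          package = "hjsdm", mustWork = TRUE))
}

#' @rdname adriatic_traits
#' @export
adriatic_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "adriatic_taxonomy.csv",
                            package = "hjsdm", mustWork = TRUE))
}
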