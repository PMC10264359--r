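#' Drop scarcely recorded species
#'
#' Retains species recorded in at least `min_occ_frac` of the hauls *and*
#' with at least `min_total` individuals over the whole data set; the survey
#' screen applied before model fitting (defaults: 2% of hauls, 150
#' individuals). Haul rows are unchanged. Idempotent.
#'
#' @param table community table (see [validate_community()]).
#' @param min_occ_frac minimum occurrence fraction in `[0, 1]`.
#' @param min_total minimum total individuals (>= 0).
#' @return the community table with failing `sp_` columns removed.
#' @export
filter_species <- function(table, min_occ_frac = 0.02, min_total = 150) {
  validate_community(table)
  stopifnot(min_occ_frac >= 0, min_occ_frac <= 1, min_total >= 0)
  sp <- species_columns(table)
  Y <- as.matrix(table[sp])
  keep <- colMeans(Y > 0) >= min_occ_frac & colSums(Y) >= min_total
  if (!any(keep))
    stop("no species pass the filters (min_occ_frac = ", min_occ_frac,
         ", min_total = ", min_total, ")")
  table[c(setdiff(names(table), sp), sp[keep])]
}

#' Build the fixed-effect design matrix
#'
#' Columns, in order: `intercept` (1), `log_depth` (natural log of depth in
#' m), `bot_temp` (deg C), `seabed_sand` (indicator; `mud_to_muddy_sand` is
#' the reference level), `log_swept_area` (natural log of km^2), and
#' `year_centered` (survey year minus its mean, the linear temporal trend).
#' Each column carries a group label used by [variance_partition()].
#'
#' @param table community table.
#' @return object of class `hjsdm_design`: list with `X` (haul x covariate
#'   matrix), `groups` (named group label per column) and `year_mean`.
#' @export
build_design <- function(table) {
  validate_community(table)
  X <- cbind(intercept      = 1,
             log_depth      = log(table$depth),
             bot_temp       = table$bot_temp,
             seabed_sand    = as.numeric(as.character(table$seabed) == "sand"),
             log_swept_area = log(table$swept_area),
             year_centered  = table$year - mean(table$year))
  rownames(X) <- as.character(table$haul_id)
  structure(list(X = X,
                 groups = c(intercept = "intercept", log_depth = "depth",
                            bot_temp = "temperature", seabed_sand = "seabed",
                            log_swept_area = "effort", year_centered = "year"),
                 year_mean = mean(table$year)),
            class = "hjsdm_design")
}

#' Split counts into the two hurdle responses
#'
#' Presence-absence `Y_pa = 1[y > 0]`, and scaled log abundance at presences
#' `Y_abu = (log y - m_j) / s_j` where `m_j`, `s_j` are the per-species mean
#' and sample standard deviation (n - 1 denominator) of the natural-log
#' counts over presence hauls, so each species' `Y_abu` has mean 0 and unit
#' variance. `Y_abu` is `NA` exactly where `Y_pa = 0`; `(m_j, s_j)` are kept
#' for back-transforming predictions.
#'
#' @param table community table (already species-filtered).
#' @return object of class `hjsdm_hurdle`: list with matrices `Y_pa`,
#'   `Y_abu` and `scale_params` (`data.frame` species, m, s, n_presence).
#' @export
make_hurdle <- function(table) {
  validate_community(table)
  Y <- as.matrix(table[species_columns(table)])
  colnames(Y) <- sub("^sp_", "", colnames(Y))
  Y_pa <- (Y > 0) * 1L
  npres <- colSums(Y_pa)
  if (any(npres < 2))
    stop("species with fewer than 2 presence hauls (",
         paste(colnames(Y)[npres < 2], collapse = ", "),
         "): scaled abundance is undefined; filter species more strictly")
  logY <- suppressWarnings(log(Y))
  logY[Y == 0] <- NA
  m <- colMeans(logY, na.rm = TRUE)
  s <- apply(logY, 2, stats::sd, na.rm = TRUE)
  if (any(s == 0))
    stop("species with constant positive counts (zero log-scale sd): ",
         paste(colnames(Y)[s == 0], collapse = ", "))
  Y_abu <- sweep(sweep(logY, 2, m, "-"), 2, s, "/")
  rownames(Y_pa) <- rownames(Y_abu) <- as.character(table$haul_id)
  structure(list(Y_pa = Y_pa, Y_abu = Y_abu,
                 scale_params = data.frame(species = colnames(Y), m = m, s = s,
                                           n_presence = npres,
                                           row.names = NULL)),
            class = "hjsdm_hurdle")
}

#' Invert the per-species abundance scaling
#'
#' Maps scaled log abundance `v` back to the count scale, `exp(m_j + s_j v)`.
#'
#' @param v matrix (haul x species) of scaled log abundances.
#' @param scale_params `scale_params` component of [make_hurdle()].
#' @return matrix of positive abundances on the original count scale.
#' @export
unscale_abundance <- function(v, scale_params) {
  v <- as.matrix(v)
  stopifnot(ncol(v) == nrow(scale_params))
  exp(sweep(sweep(v, 2, scale_params$s, "*"), 2, scale_params$m, "+"))
}
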