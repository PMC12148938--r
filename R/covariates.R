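#' Shannon crop diversity
#'
#' Shannon index `H' = -sum(p_i ln p_i)` over the proportions of cropland
#' covered by each crop, with `0 ln 0` taken as 0. Area fractions are
#' renormalized to proportions of the total cropland, so the index is
#' invariant to rescaling all areas by a constant, and is bounded by
#' `ln(n_crops)`.
#'
#' @param area_fractions non-negative per-crop areas (any common unit).
#' @return `H'` in nats.
#' @export
shannon_crop_diversity <- function(area_fractions) {
  if (any(area_fractions < 0, na.rm = TRUE)) {
    abort("area fractions must be non-negative")
  }
  tot <- sum(area_fractions)
  if (!is.finite(tot) || tot <= 0) {
    abort("Shannon crop diversity undefined: all crop areas are zero")
  }
  p <- area_fractions / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-site statistical weights from crop area fractions
#'
#' Each site is weighted by the relative area of the focal crop,
#' `RA = A_focal / sum(A_i)` over all crops in the site's pixel, then the
#' weights are rescaled so their mean over the included sites is exactly 1
#' (`weight_j = N * RA_j / sum(RA)`), avoiding an apparent reduction in
#' effective sample size.
#'
#' @param focal_area per-site harvested area of the focal crop (>= 0).
#' @param total_area per-site total harvested area over all crops (> 0
#'   wherever `focal_area > 0`).
#' @param site_id optional site identifiers.
#' @return tibble with `site_id`, `ra` (in \[0, 1\]) and `weight`
#'   (mean exactly 1).
#' @export
site_weights <- function(focal_area, total_area, site_id = NULL) {
  stopifnot(length(focal_area) == length(total_area))
  if (any(focal_area < 0) || any(total_area < 0)) {
    abort("areas must be non-negative")
  }
  if (any(focal_area > total_area + 1e-9)) {
    abort("focal crop area exceeds total crop area")
  }
  ra <- ifelse(total_area > 0, focal_area / total_area, 0)
  if (sum(ra) <= 0) abort("all relative areas are zero; no weights defined")
  n <- length(ra)
  tibble::tibble(
    site_id = site_id %||% seq_len(n),
    ra = ra,
    weight = n * ra / sum(ra)
  )
}

#' Landscape classification and the combined land-use-landscape variable
#'
#' Landscapes with less than 30% natural vegetation are "human-modified",
#' landscapes with more than 70% are "natural"; the band in between is
#' excluded from the land-conversion models. Combined with the site's land
#' use this yields four modelled categories with primary vegetation in
#' natural landscapes as the reference.
#'
#' @param natural_fraction natural-habitat fraction in \[0, 1\].
#' @param lower,upper classification thresholds (strict inequalities).
#' @return `classify_landscape()`: factor with levels `modified`,
#'   `intermediate`, `natural`.
#' @export
classify_landscape <- function(natural_fraction, lower = 0.30, upper = 0.70) {
  bad <- natural_fraction < 0 | natural_fraction > 1
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("natural fraction out of [0, 1]: %g",
                  natural_fraction[which(bad)[1]]))
  }
  out <- dplyr::case_when(
    natural_fraction < lower ~ "modified",
    natural_fraction > upper ~ "natural",
    TRUE ~ "intermediate"
  )
  factor(out, levels = c("modified", "intermediate", "natural"))
}

#' @rdname classify_landscape
#' @param land_use `"primary vegetation"` or `"cropland"`.
#' @param landscape factor from `classify_landscape()`.
#' @return `combine_lu_landscape()`: factor with levels `PV_natural`
#'   (reference), `PV_modified`, `crop_natural`, `crop_modified`,
#'   `excluded_intermediate`.
#' @export
combine_lu_landscape <- function(land_use, landscape) {
  lu_ok <- land_use %in% c("primary vegetation", "cropland")
  if (!all(lu_ok)) {
    abort(sprintf("unknown land use '%s'", land_use[which(!lu_ok)[1]]))
  }
  out <- dplyr::case_when(
    landscape == "intermediate" ~ "excluded_intermediate",
    land_use == "primary vegetation" & landscape == "natural" ~ "PV_natural",
    land_use == "primary vegetation" & landscape == "modified" ~ "PV_modified",
    land_use == "cropland" & landscape == "natural" ~ "crop_natural",
    TRUE ~ "crop_modified"
  )
  factor(out, levels = c("PV_natural", "PV_modified", "crop_natural",
                         "crop_modified", "excluded_intermediate"))
}

#' Tropical / non-tropical region from latitude
#'
#' Sites between 23.5 N and 23.5 S are tropical; the boundary itself is
#' included in the tropics (a measure-zero convention).
#'
#' @param latitude_deg latitude in degrees, within \[-90, 90\].
#' @param boundary tropic boundary in degrees.
#' @return factor with levels `non_tropical` (reference), `tropical`.
#' @export
geographic_region <- function(latitude_deg, boundary = 23.5) {
  if (any(abs(latitude_deg) > 90, na.rm = TRUE)) {
    abort("latitude outside [-90, 90]")
  }
  factor(ifelse(abs(latitude_deg) <= boundary, "tropical", "non_tropical"),
         levels = c("non_tropical", "tropical"))
}

#' Buffer-focal difference of a raster layer
#'
#' The mean of the layer over the available Moore neighbours (the ring of
#' up to eight cells around the focal cell, missing values excluded) minus
#' the focal value, approximating a one-cell (~10 km) buffer around each
#' ~10-km cell.
#'
#' @param layer numeric matrix.
#' @param row,col optional focal cell; if omitted the full difference
#'   matrix is returned.
#' @return matrix (or scalar for a single cell); cells with no valid
#'   neighbour are `NA`.
#' @export
buffer_focal_difference <- function(layer, row = NULL, col = NULL) {
  stopifnot(is.matrix(layer))
  diffm <- moore_neighbour_mean(layer) - layer
  if (is.null(row)) return(diffm)
  stopifnot(row >= 1, row <= nrow(layer), col >= 1, col <= ncol(layer))
  out <- diffm[row, col]
  if (is.na(out) && !is.na(layer[row, col])) {
    warn("no valid neighbour for the requested cell; difference undefined")
  }
  out
}

#' Duration of substantial human landscape modification
#'
#' Years elapsed, at the reference year, since the fraction of a cell under
#' human land use first reached the threshold (30% by default). Cells that
#' never crossed the threshold get 0 years ("never substantially
#' modified"), so the left-skew transform downstream places them at the
#' latest-modification end consistently.
#'
#' @param years numeric vector of time-series years.
#' @param fractions human-use fraction at each year.
#' @param threshold crossing threshold.
#' @param reference_year year from which duration is counted.
#' @return duration in years (>= 0).
#' @export
duration_of_modification <- function(years, fractions, threshold = 0.30,
                                     reference_year = 2000) {
  if (length(years) == 0L) abort("empty human-use time series")
  stopifnot(length(years) == length(fractions))
  o <- order(years)
  years <- years[o]; fractions <- fractions[o]
  hit <- which(fractions >= threshold)
  if (length(hit) == 0L) return(0)
  max(reference_year - years[hit[1]], 0)
}

#' Greedy correlation screening of continuous covariates
#'
#' Repeatedly finds the pair of retained covariates with the largest
#' absolute Pearson correlation above the threshold and removes one of the
#' two: a non-priority variable is always removed in favour of a priority
#' one, and among two priority variables the one later in the priority
#' order is removed. Ties fall back to column order for determinism.
#'
#' @param data data frame holding the covariate columns.
#' @param vars covariate column names to screen.
#' @param threshold absolute correlation above which a pair is "strong".
#' @param priority variable names to keep, in decreasing priority.
#' @return list with `retained` (names), `removed` (names) and `log`
#'   (tibble of removal steps with the offending correlation).
#' @export
correlation_screen <- function(data, vars, threshold = 0.6,
                               priority = c("yield", "natural", "subsist")) {
  stopifnot(all(vars %in% names(data)))
  retained <- vars
  log <- list()
  rank_of <- function(v) {
    i <- match(v, priority)
    ifelse(is.na(i), length(priority) + 1L, i)
  }
  repeat {
    if (length(retained) < 2L) break
    cm <- abs(stats::cor(as.data.frame(data[retained])))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) <= threshold) break
    ij <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    a <- retained[ij[1]]; b <- retained[ij[2]]
    ra <- rank_of(a); rb <- rank_of(b)
    drop_var <- if (ra < rb) b else if (rb < ra) a else
      retained[max(ij)]  # equal priority: drop the later column
    keep_var <- setdiff(c(a, b), drop_var)
    log[[length(log) + 1L]] <- tibble::tibble(
      removed = drop_var, kept = keep_var,
      r = stats::cor(data[[a]], data[[b]])
    )
    retained <- setdiff(retained, drop_var)
  }
  list(retained = retained, removed = setdiff(vars, retained),
       log = dplyr::bind_rows(log))
}

#' Choose the agricultural data year closest to a sampling midpoint
#'
#' Picks the available estimate year nearest to the sampling midpoint; on a
#' tie the earlier year wins, as the earlier management state is the more
#' likely driver of the sampled biodiversity.
#'
#' @param midpoint_year sampling midpoint (possibly fractional).
#' @param available_years candidate years.
#' @return one of `available_years` (vectorized over `midpoint_year`).
#' @export
select_agri_year <- function(midpoint_year,
                             available_years = c(2000, 2005, 2010)) {
  available_years <- sort(available_years)
  vapply(midpoint_year, function(y) {
    d <- abs(available_years - y)
    available_years[which(d == min(d))[1L]]  # sorted, so ties pick earlier
  }, numeric(1))
}

#' Assemble a model-ready dataset from sites and a landscape grid
#'
#' Joins survey sites to grid cells, keeps only sites in cells cultivating
#' the focal crop, engineers the covariate set of the yield-biodiversity
#' models (yield, natural habitat, subsistence yield, crop diversity,
#' buffer-focal differences, duration of modification, climate), applies
#' skew transforms, standardizes the continuous covariates (mean 0, sd 1)
#' and stores the frozen transform and standardization state for reuse in
#' projections. Site weights follow the focal-crop relative area, and the
#' combined land-use-landscape category is attached for conversion models.
#'
#' @param sites site table (`site_id`, `study_id`, `block_id`, `row`,
#'   `col`, `latitude_like`, `land_use`, plus response columns `richness`,
#'   `abundance`, `rcar` if present).
#' @param grid a [landscape_grid()].
#' @param crop focal crop name.
#' @param transforms named list of [transform_spec()]s per covariate;
#'   default applies a left-skew log to `duration` and a right-skew log to
#'   `precipitation`.
#' @param screen apply [correlation_screen()] and drop the removed columns.
#' @param threshold correlation-screening threshold.
#' @return tibble, one row per retained site, with standardized covariates,
#'   responses, `weight`, grouping ids, `region`, `lu_landscape`; the
#'   frozen specs in `attr(, "covariate_specs")`, the screening log in
#'   `attr(, "screen_log")` and excluded sites in `attr(, "excluded")`.
#' @export
assemble_model_dataset <- function(sites, grid, crop,
                                   transforms = NULL, screen = TRUE,
                                   threshold = 0.6) {
  stopifnot(all(c("site_id", "study_id", "block_id", "row", "col",
                  "latitude_like", "land_use") %in% names(sites)))
  d <- grid_dims(grid)
  inside <- sites$row >= 1 & sites$row <= d[1] &
    sites$col >= 1 & sites$col <= d[2]
  excluded <- sites$site_id[!inside]
  sites <- sites[inside, , drop = FALSE]
  covs <- cell_covariates(grid, sites$row, sites$col, crop)
  in_crop <- covs$area_focal > 0
  excluded <- c(excluded, sites$site_id[!in_crop])
  sites <- sites[in_crop, , drop = FALSE]
  covs <- covs[in_crop, , drop = FALSE]
  if (nrow(sites) == 0L) abort("no sites fall in cells cultivating the crop")

  cont <- c("yield", "natural", "subsist", "crop_div", "yield_bfd",
            "natural_bfd", "duration", "temperature", "precipitation")
  # the left-skew constant is fitted from the full raster (not just the
  # training sites) so counterfactual grids stay inside the transform's
  # domain; margin 20 years is the convention for the duration variable
  transforms <- transforms %||% list(
    duration = transform_spec(
      "left_skew_log", margin = 20,
      C = make_left_skew_constant(max(grid$duration, na.rm = TRUE), 20)),
    precipitation = transform_spec("right_skew_log", offset = 0.01)
  )
  specs <- list()
  out <- tibble::tibble(
    site_id = sites$site_id, study_id = sites$study_id,
    block_id = sites$block_id
  )
  for (resp in intersect(c("richness", "abundance", "rcar", "log_abundance",
                           "log10_rcar"), names(sites))) {
    out[[resp]] <- sites[[resp]]
  }
  for (v in cont) {
    tr <- transforms[[v]] %||% transform_spec("none")
    x <- apply_transform(covs[[v]], tr)
    tr <- attr(x, "spec")  # keep the fitted left-skew constant
    std <- standardizer(x)
    out[[v]] <- apply_standardizer(as.numeric(x), std)
    specs[[v]] <- list(transform = tr, standardizer = std,
                       train_range = range(out[[v]], na.rm = TRUE))
  }
  out$land_use <- factor(sites$land_use,
                         levels = c("primary vegetation", "cropland"))
  out$region <- geographic_region(sites$latitude_like)
  out$lu_landscape <- combine_lu_landscape(
    as.character(out$land_use), classify_landscape(covs$natural))
  w <- site_weights(covs$area_focal, covs$area_total, site_id = out$site_id)
  out$weight <- w$weight

  screen_log <- tibble::tibble()
  if (screen) {
    sc <- correlation_screen(out, cont, threshold = threshold)
    screen_log <- sc$log
    out <- out[, setdiff(names(out), sc$removed), drop = FALSE]
    specs <- specs[setdiff(names(specs), sc$removed)]
  }
  attr(out, "covariate_specs") <- specs
  attr(out, "continuous") <- intersect(cont, names(out))
  attr(out, "screen_log") <- screen_log
  attr(out, "excluded") <- excluded
  attr(out, "crop") <- crop
  out
}
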