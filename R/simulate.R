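#' Simulation configuration
#'
#' Bundles the dimensions, crop list, site hierarchy, spatial autocorrelation
#' scale, true fixed-effect coefficients and random-effect standard
#' deviations used by the synthetic-data generator. Defaults describe a
#' modest agricultural region: a 10-km equal-area lattice, four staple
#' crops, and a PREDICTS-like survey hierarchy of studies containing
#' spatial blocks containing sites.
#'
#' `true_beta` maps each response to a named coefficient vector over the
#' generated design columns. Recognised term names: `intercept`, the
#' continuous covariates (`yield`, `natural`, `subsist`, `crop_div`,
#' `yield_bfd`, `natural_bfd`, `duration`, `temperature`, `precipitation`,
#' all standardized before use), the indicators `land_use` (cropland vs
#' primary vegetation) and `region` (tropical vs non-tropical), and `a:b`
#' products of the above.
#'
#' @param grid_rows,grid_cols grid dimensions (cells).
#' @param cell_size_km cell edge length, km.
#' @param crops crop names.
#' @param n_studies,blocks_per_study,sites_per_block survey hierarchy sizes.
#' @param smoothing_scale_cells autocorrelation length of the simulated
#'   fields, in cells (Gaussian-kernel smoothing scale).
#' @param cropland_range range of the simulated cropland fraction.
#' @param true_beta named list with elements `richness`, `log_abundance`,
#'   `log10_rcar`, each a named coefficient vector.
#' @param re_sd named vector with elements `study`, `block`, `site`
#'   (non-negative standard deviations; `site` acts as the
#'   observation-level random effect of the richness model).
#' @param residual_sd residual standard deviation of the two Gaussian
#'   responses (log_e rescaled abundance, log10 RCAR).
#' @param focal_crop crop whose cultivated cells receive survey sites.
#' @param seed master seed; every sub-stream (grid, placement, responses)
#'   derives its own seed from it deterministically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid_rows = 40, grid_cols = 40, cell_size_km = 10,
                       crops = c("maize", "soybean", "wheat", "rice"),
                       n_studies = 20, blocks_per_study = 2,
                       sites_per_block = 10,
                       smoothing_scale_cells = 3,
                       cropland_range = c(0.05, 0.9),
                       true_beta = NULL,
                       re_sd = c(study = 0.3, block = 0.2, site = 0.2),
                       residual_sd = 0.5,
                       focal_crop = crops[[1]],
                       seed = 1L) {
  if (is.null(true_beta)) {
    true_beta <- list(
      richness      = c(intercept = 2.5, yield = -0.25, natural = 0.15,
                        land_use = -0.4),
      log_abundance = c(intercept = -1, yield = -0.3, natural = 0.2,
                        land_use = -0.5),
      log10_rcar    = c(intercept = 2, yield = 0.15, natural = -0.1,
                        land_use = 0.25)
    )
  }
  cfg <- list(
    grid_rows = grid_rows, grid_cols = grid_cols, cell_size_km = cell_size_km,
    crops = crops, n_studies = n_studies, blocks_per_study = blocks_per_study,
    sites_per_block = sites_per_block,
    smoothing_scale_cells = smoothing_scale_cells,
    cropland_range = cropland_range, true_beta = true_beta,
    re_sd = re_sd, residual_sd = residual_sd, focal_crop = focal_crop,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) abort(sprintf("invalid sim_config field '%s': %s", field, why))
  }
  for (f in c("grid_rows", "grid_cols", "n_studies", "blocks_per_study",
              "sites_per_block")) {
    chk(is_scalar_num(cfg[[f]]) && cfg[[f]] >= 1, f, "must be a count >= 1")
  }
  chk(is_scalar_num(cfg$cell_size_km) && cfg$cell_size_km > 0,
      "cell_size_km", "must be positive")
  chk(is_scalar_num(cfg$smoothing_scale_cells) && cfg$smoothing_scale_cells >= 0,
      "smoothing_scale_cells", "must be non-negative")
  chk(length(cfg$crops) >= 1 && !anyDuplicated(cfg$crops),
      "crops", "must be distinct names")
  chk(length(cfg$cropland_range) == 2 && all(cfg$cropland_range >= 0) &&
        all(cfg$cropland_range <= 1) &&
        cfg$cropland_range[1] <= cfg$cropland_range[2],
      "cropland_range", "must be an increasing range within [0, 1]")
  chk(all(c("study", "block", "site") %in% names(cfg$re_sd)) &&
        all(cfg$re_sd >= 0), "re_sd",
      "needs non-negative 'study', 'block', 'site' entries")
  chk(is_scalar_num(cfg$residual_sd) && cfg$residual_sd > 0,
      "residual_sd", "must be positive")
  chk(cfg$focal_crop %in% cfg$crops, "focal_crop", "must be one of crops")
  chk(all(c("richness", "log_abundance", "log10_rcar") %in%
            names(cfg$true_beta)), "true_beta",
      "needs richness, log_abundance and log10_rcar coefficient vectors")
  for (b in cfg$true_beta) {
    chk(!is.null(names(b)) && all(nzchar(names(b))), "true_beta",
        "coefficient vectors must be named")
  }
  invisible(cfg)
}

#' True simulation parameters
#'
#' Convenience accessor returning the ground-truth parameters implied by a
#' [sim_config()], in the shape used by parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with per-response coefficient vectors, random-effect SDs and
#'   the Gaussian residual SD.
#' @export
true_params <- function(config) {
  list(
    beta_richness = config$true_beta$richness,
    beta_log_abundance = config$true_beta$log_abundance,
    beta_log10_rcar = config$true_beta$log10_rcar,
    sigma_study = unname(config$re_sd[["study"]]),
    sigma_block = unname(config$re_sd[["block"]]),
    sigma_site = unname(config$re_sd[["site"]]),
    residual_sd_gaussian = config$residual_sd
  )
}

#' Generate a synthetic landscape grid
#'
#' Draws spatially autocorrelated layers (smoothed Gaussian noise rescaled
#' monotonically into each layer's range) for per-crop yield, harvested-area
#' fraction and subsistence yield, plus cropland, primary-vegetation and
#' natural-habitat fractions, duration of substantial human modification,
#' mean annual temperature and annual precipitation. Compositional
#' constraints hold cell by cell: fraction layers lie in \[0, 1\], per-crop
#' areas sum to at most the cropland fraction, cropland plus primary
#' vegetation is at most 1, and natural habitat is at least the
#' primary-vegetation fraction.
#'
#' @param config a [sim_config()].
#' @return a [landscape_grid()]. Deterministic given `config$seed`.
#' @export
generate_landscape_grid <- function(config) {
  validate_sim_config(config)
  nr <- config$grid_rows; nc <- config$grid_cols
  sc <- config$smoothing_scale_cells
  crops <- config$crops

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(config$seed, "grid"))

  natural <- rfield01(nr, nc, sc)
  primary <- natural * rfield01(nr, nc, sc)
  cr_lo <- config$cropland_range[1]; cr_hi <- config$cropland_range[2]
  cropland <- pmin(cr_lo + (cr_hi - cr_lo) * rfield01(nr, nc, sc), 1 - primary)

  # per-crop layers; presence mask keeps some cells crop-free
  yields <- list(); areas <- list(); subsist <- list()
  yield_max <- setNames(seq(6, 9, length.out = length(crops)), crops)
  share_w <- list()
  for (cp in crops) {
    presence <- rfield01(nr, nc, sc) > 0.3
    share_w[[cp]] <- presence * (rfield01(nr, nc, sc) + 0.05)
    yfield <- rfield01(nr, nc, sc)
    yields[[cp]] <- yield_max[[cp]] * yfield^0.7
    subsist[[cp]] <- 0.3 * yields[[cp]] +
      0.7 * yield_max[[cp]] * 0.5 * rfield01(nr, nc, sc)
  }
  utilization <- 0.6 + 0.4 * rfield01(nr, nc, sc)
  wsum <- Reduce(`+`, share_w)
  for (cp in crops) {
    share <- ifelse(wsum > 0, share_w[[cp]] / pmax(wsum, 1e-12), 0)
    areas[[cp]] <- cropland * utilization * share
  }

  duration <- round(pmax((rfield01(nr, nc, sc) - 0.2) / 0.8, 0) * 2000)
  temperature <- -2 + 30 * rfield01(nr, nc, sc)
  precipitation <- 100 + 2900 * rfield01(nr, nc, sc)^2

  cell_km <- config$cell_size_km
  cells <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  cells$x_km <- (cells$col - 0.5) * cell_km
  cells$y_km <- (nr - cells$row + 0.5) * cell_km
  # pseudo-coordinates: rows span 50 S to 50 N so both regions occur
  cells$latitude_like <- 50 - (cells$row - 0.5) / nr * 100
  cells$longitude_like <- (cells$col - 0.5) / nc * 20

  idx <- cbind(cells$row, cells$col)
  cells$cropland <- cropland[idx]
  cells$primary_veg <- primary[idx]
  cells$natural <- natural[idx]
  cells$duration <- duration[idx]
  cells$temperature <- temperature[idx]
  cells$precipitation <- precipitation[idx]
  for (cp in crops) {
    cells[[paste0("yield_", cp)]] <- yields[[cp]][idx]
    cells[[paste0("area_", cp)]] <- areas[[cp]][idx]
    cells[[paste0("subsist_", cp)]] <- subsist[[cp]][idx]
  }
  landscape_grid(cells, nr, nc, cell_km, crops)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# raw (untransformed) cell-level covariates for the focal crop, one row per
# requested cell; shared between the site generator and the covariate builder
cell_covariates <- function(grid, rows, cols, crop) {
  crops <- attr(grid, "crops")
  if (!crop %in% crops) abort(sprintf("unknown crop '%s'", crop))
  need <- c(paste0("yield_", crop), paste0("subsist_", crop),
            paste0("area_", crops), "natural", "duration", "temperature",
            "precipitation")
  missing <- setdiff(need, names(grid))
  if (length(missing) > 0) {
    abort(sprintf("grid lacks required layer(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ymat <- grid_layer(grid, paste0("yield_", crop))
  nmat <- grid_layer(grid, "natural")
  ybfd <- moore_neighbour_mean(ymat) - ymat
  nbfd <- moore_neighbour_mean(nmat) - nmat
  area_mats <- lapply(crops, function(cp) grid_layer(grid, paste0("area_", cp)))
  idx <- cbind(rows, cols)
  area <- vapply(area_mats, function(m) m[idx], numeric(length(rows)))
  if (length(rows) == 1L) area <- matrix(area, nrow = 1L)
  crop_div <- apply(area, 1L, function(a) {
    if (sum(a) <= 0) 0 else shannon_crop_diversity(a)
  })
  tibble::tibble(
    yield = ymat[idx],
    natural = nmat[idx],
    subsist = grid_layer(grid, paste0("subsist_", crop))[idx],
    crop_div = crop_div,
    yield_bfd = ybfd[idx],
    natural_bfd = nbfd[idx],
    duration = grid_layer(grid, "duration")[idx],
    temperature = grid_layer(grid, "temperature")[idx],
    precipitation = grid_layer(grid, "precipitation")[idx],
    area_focal = grid_layer(grid, paste0("area_", crop))[idx],
    area_total = rowSums(area)
  )
}

# build the generator design matrix for a named coefficient vector
design_for_beta <- function(beta, covs) {
  cols <- lapply(names(beta), function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- rep(1, nrow(covs))
    for (p in parts) {
      if (p == "intercept") next
      if (!p %in% names(covs)) {
        abort(sprintf("true_beta term '%s' has no generated covariate '%s'",
                      term, p))
      }
      col <- col * covs[[p]]
    }
    col
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(beta)
  X
}

#' Generate PREDICTS-like survey sites with known ground truth
#'
#' Places sites in grid cells where the focal crop is cultivated, following
#' the study / spatial-block / site hierarchy of the configuration, assigns
#' each site a land use (cropland or primary vegetation), and draws the
#' three biodiversity responses from the generative counterparts of the
#' fitted models: species richness from a Poisson distribution with
#' log-linear mean plus study, block and site (observation-level) random
#' intercepts; log_e rescaled abundance and log10 RCAR from Gaussian
#' distributions with study and block random intercepts. Continuous
#' covariates are standardized across the generated sites before the
#' coefficients are applied, so the stored coefficients live on the same
#' scale that the models are fitted on.
#'
#' @param grid a [landscape_grid()].
#' @param params a [true_params()] list (defaults to `true_params(config)`).
#' @param config a [sim_config()].
#' @return list with `sites` (site table: ids, location, land use, effort,
#'   richness, abundance, rcar) and `dataset` (the model-ready tibble with
#'   standardized covariates, transformed responses, weights, and the true
#'   linear predictors in columns `lp_*`). Deterministic given the seed.
#' @export
generate_sites <- function(grid, params = NULL, config) {
  validate_sim_config(config)
  params <- params %||% true_params(config)
  crop <- config$focal_crop
  area_layer <- paste0("area_", crop)
  if (!area_layer %in% names(grid)) {
    abort(sprintf("grid lacks required layer(s): %s", area_layer))
  }
  eligible <- which(grid[[area_layer]] > 0)
  if (length(eligible) == 0L) abort("no cells cultivate the focal crop")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # --- placement stream -----------------------------------------------
  set.seed(split_seed(config$seed, "placement"))
  n_sites <- config$n_studies * config$blocks_per_study * config$sites_per_block
  study_centre <- sample(eligible, config$n_studies, replace = TRUE)
  pick_near <- function(centre_idx, radius) {
    r0 <- grid$row[centre_idx]; c0 <- grid$col[centre_idx]
    near <- eligible[abs(grid$row[eligible] - r0) <= radius &
                       abs(grid$col[eligible] - c0) <= radius]
    if (length(near) == 0L) centre_idx else near
  }
  rows <- integer(0)
  site_tbl <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    sid <- sprintf("S%03d", s)
    blocks <- vector("list", config$blocks_per_study)
    for (b in seq_len(config$blocks_per_study)) {
      near_s <- pick_near(study_centre[s], 6L)
      bc <- near_s[sample.int(length(near_s), 1L)]
      near_b <- pick_near(bc, 2L)
      cell_idx <- near_b[sample.int(length(near_b), config$sites_per_block,
                                    replace = TRUE)]
      blocks[[b]] <- tibble::tibble(
        study_id = sid,
        block_id = sprintf("%s_B%02d", sid, b),
        cell = cell_idx
      )
    }
    site_tbl[[s]] <- dplyr::bind_rows(blocks)
  }
  sites <- dplyr::bind_rows(site_tbl)
  sites$site_id <- sprintf("%s_s%02d", sites$block_id,
                           stats::ave(seq_len(n_sites), sites$block_id,
                                      FUN = seq_along))
  sites$land_use <- sample(c("cropland", "primary vegetation"), n_sites,
                           replace = TRUE)
  sites$effort <- 1

  # --- covariates ------------------------------------------------------
  covs <- cell_covariates(grid, grid$row[sites$cell], grid$col[sites$cell],
                          crop)
  cont <- c("yield", "natural", "subsist", "crop_div", "yield_bfd",
            "natural_bfd", "duration", "temperature", "precipitation")
  covs_std <- covs
  for (v in cont) {
    s <- sd(covs[[v]])
    covs_std[[v]] <- if (s < .Machine$double.eps) covs[[v]] * 0 else
      (covs[[v]] - mean(covs[[v]])) / s
  }
  covs_std$land_use <- as.numeric(sites$land_use == "cropland")
  covs_std$region <- as.numeric(abs(grid$latitude_like[sites$cell]) <= 23.5)

  # --- responses -------------------------------------------------------
  set.seed(split_seed(config$seed, "responses"))
  draw_re <- function(ids, sdv) {
    u <- setNames(rnorm(length(unique(ids)), 0, sdv), unique(ids))
    unname(u[ids])
  }
  resp <- list()
  lp <- list()
  for (rname in c("richness", "log_abundance", "log10_rcar")) {
    beta <- config$true_beta[[rname]]
    X <- design_for_beta(beta, covs_std)
    eta <- drop(X %*% beta)
    u_s <- draw_re(sites$study_id, config$re_sd[["study"]])
    u_b <- draw_re(sites$block_id, config$re_sd[["block"]])
    if (rname == "richness") {
      u_o <- rnorm(n_sites, 0, config$re_sd[["site"]])
      lp[[rname]] <- eta + u_s + u_b + u_o
      resp[[rname]] <- rpois(n_sites, exp(lp[[rname]]))
    } else {
      lp[[rname]] <- eta + u_s + u_b
      resp[[rname]] <- rnorm(n_sites, lp[[rname]], config$residual_sd)
    }
  }

  # raw abundance backed out of the modelled scale for the site table;
  # one max-abundance scale per study
  study_max <- setNames(rlnorm(config$n_studies, 4, 1),
                        sprintf("S%03d", seq_len(config$n_studies)))
  abundance <- pmax(exp(resp$log_abundance) - 0.01, 0) *
    unname(study_max[sites$study_id])

  site_table <- tibble::tibble(
    site_id = sites$site_id, study_id = sites$study_id,
    block_id = sites$block_id,
    row = grid$row[sites$cell], col = grid$col[sites$cell],
    longitude_like = grid$longitude_like[sites$cell],
    latitude_like = grid$latitude_like[sites$cell],
    land_use = sites$land_use, effort = sites$effort,
    richness = resp$richness, abundance = abundance,
    rcar = 10^resp$log10_rcar
  )

  w <- site_weights(covs$area_focal, covs$area_total,
                    site_id = sites$site_id)
  dataset <- tibble::tibble(
    site_id = sites$site_id, study_id = sites$study_id,
    block_id = sites$block_id,
    richness = resp$richness,
    log_abundance = resp$log_abundance,
    log10_rcar = resp$log10_rcar,
    land_use = factor(sites$land_use,
                      levels = c("primary vegetation", "cropland")),
    region = factor(ifelse(covs_std$region == 1, "tropical", "non_tropical"),
                    levels = c("non_tropical", "tropical")),
    weight = w$weight,
    lp_richness = lp$richness,
    lp_log_abundance = lp$log_abundance,
    lp_log10_rcar = lp$log10_rcar
  )
  for (v in cont) dataset[[v]] <- covs_std[[v]]
  attr(dataset, "continuous") <- cont
  list(sites = site_table, dataset = dataset)
}

#' Generate synthetic community samples and a range-size table
#'
#' Draws species range sizes from a log-normal distribution and per-site
#' abundances whose response to the local yield depends on range size
#' (species with larger ranges benefit more when `coupling > 0`), so the
#' abundance-weighted mean range size (RCAR) carries a built-in yield
#' gradient of known sign.
#'
#' @param grid a [landscape_grid()].
#' @param n_species number of species (>= 2).
#' @param n_sites number of sampled sites.
#' @param range_meanlog,range_sdlog log-normal range-size parameters
#'   (`range_sdlog > 0`).
#' @param coupling strength of the range-size-dependent yield response;
#'   0 removes the RCAR-yield gradient.
#' @param crop crop whose yield drives the gradient.
#' @param seed random seed.
#' @return list with `communities` (long tibble: site_id, taxon, abundance,
#'   effort, yield at the site) and `ranges` (taxon, range_size).
#' @export
generate_communities <- function(grid, n_species, n_sites = 500,
                                 range_meanlog = 4, range_sdlog = 1,
                                 coupling = 1, crop = attr(grid, "crops")[1],
                                 seed = 1L) {
  if (!is_scalar_num(n_species) || n_species < 2) {
    abort("n_species must be >= 2")
  }
  if (!is_scalar_num(range_sdlog) || range_sdlog <= 0) {
    abort("range_sdlog must be positive")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(split_seed(seed, "communities"))

  taxa <- sprintf("sp%04d", seq_len(n_species))
  ranges <- rlnorm(n_species, range_meanlog, range_sdlog)
  affinity <- coupling * as.numeric(scale(log(ranges)))
  cells <- sample(nrow(grid), n_sites, replace = TRUE)
  y <- grid[[paste0("yield_", crop)]][cells]
  y_std <- if (sd(y) < .Machine$double.eps) y * 0 else as.numeric(scale(y))
  lambda <- exp(outer(y_std, affinity) +
                  matrix(rnorm(n_sites * n_species, 0, 0.3),
                         n_sites, n_species))
  ab <- matrix(rpois(n_sites * n_species, lambda), n_sites, n_species)
  communities <- tibble::tibble(
    site_id = rep(sprintf("c%05d", seq_len(n_sites)), times = n_species),
    taxon = rep(taxa, each = n_sites),
    abundance = as.vector(ab),
    effort = 1,
    yield = rep(y, times = n_species)
  )
  list(communities = communities,
       ranges = tibble::tibble(taxon = taxa, range_size = ranges))
}
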