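#' Attainable yields within climate zones
#'
#' Attainable yield is the area-weighted 95th percentile of observed yields
#' within zones of similar annual precipitation and growing-degree days
#' (proxied here by mean annual temperature). Zones form an
#' `n_bins` x `n_bins` grid of quantile bins over the two climate
#' variables, computed over the cultivated cells; each cultivated cell maps
#' to exactly one zone. Zones left without cultivated cells fall back to
#' the global area-weighted percentile (logged in the result). The
#' weighted quantile uses lower interpolation on the cumulative-weight
#' grid ([weighted_quantile()]).
#'
#' @param grid a [landscape_grid()].
#' @param crop crop name.
#' @param n_bins climate bins per axis.
#' @param prob percentile defining "attainable" (default 0.95).
#' @return tibble over cultivated cells: `row`, `col`, `zone`,
#'   `attainable`; attribute `"zones"` holds the per-zone table.
#' @export
attainable_yield <- function(grid, crop, n_bins = 3, prob = 0.95) {
  area <- grid[[paste0("area_", crop)]]
  if (is.null(area)) abort(sprintf("grid lacks layer area_%s", crop))
  cult <- which(area > 0)
  if (length(cult) == 0L) abort(sprintf("no cell cultivates %s", crop))
  y <- grid[[paste0("yield_", crop)]][cult]
  w <- area[cult]
  bin_of <- function(x, n) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n + 1)))
    if (length(br) < 2L) return(rep(1L, length(x)))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  pb <- bin_of(grid$precipitation[cult], n_bins)
  tb <- bin_of(grid$temperature[cult], n_bins)
  zone <- paste0("p", pb, "_t", tb)
  zones <- tibble::tibble(zone = zone, yield = y, w = w) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(attainable = weighted_quantile(.data$yield, .data$w, prob),
                     n_cells = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(row = grid$row[cult], col = grid$col[cult],
                        zone = zone) |>
    dplyr::left_join(zones, by = "zone") |>
    dplyr::select("row", "col", "zone", "attainable")
  fallback <- is.na(out$attainable)
  if (any(fallback)) {
    out$attainable[fallback] <- weighted_quantile(y, w, prob)
  }
  attr(out, "zones") <- zones
  attr(out, "n_fallback") <- sum(fallback)
  out
}

#' Close yield gaps on a landscape grid
#'
#' Raises every cultivated cell's yield to its zone's attainable yield
#' where the current yield is below it (`new = max(current, attainable)`);
#' no other layer changes and no yield ever decreases.
#'
#' @param grid a [landscape_grid()].
#' @param attainables named list mapping crop name to the output of
#'   [attainable_yield()] for that crop.
#' @return the modified grid.
#' @export
close_yield_gaps <- function(grid, attainables) {
  for (crop in names(attainables)) {
    at <- attainables[[crop]]
    ycol <- paste0("yield_", crop)
    if (!ycol %in% names(grid)) abort(sprintf("grid lacks layer %s", ycol))
    key_grid <- paste(grid$row, grid$col)
    key_at <- paste(at$row, at$col)
    m <- match(key_grid, key_at)
    target <- at$attainable[m]
    grid[[ycol]] <- ifelse(!is.na(target), pmax(grid[[ycol]], target),
                           grid[[ycol]])
  }
  grid
}

# raw-scale prediction contexts for one crop over given cells;
# overrides adjust the mechanically changing covariates
crop_context <- function(grid, crop, cells, land_use,
                         yield_mult = 1, natural_delta = 0) {
  covs <- cell_covariates(grid, grid$row[cells], grid$col[cells], crop)
  covs$yield <- covs$yield * yield_mult
  covs$natural <- covs$natural + natural_delta
  covs$natural_bfd <- covs$natural_bfd - natural_delta
  covs$land_use <- factor(land_use,
                          levels = c("primary vegetation", "cropland"))
  covs$region <- geographic_region(grid$latitude_like[cells])
  covs
}

metric_fits <- function(fits, crops) {
  # a single fit is shared across crops; otherwise one fit per crop
  if (inherits(fits, "bd_fit")) {
    setNames(rep(list(fits), length(crops)), crops)
  } else {
    missing <- setdiff(crops, names(fits))
    if (length(missing) > 0) {
      abort(sprintf("no model supplied for crop(s): %s",
                    paste(missing, collapse = ", ")))
    }
    fits[crops]
  }
}

#' Aggregate pixel biodiversity across crops and land uses
#'
#' For every pixel containing cropland of at least one modelled crop,
#' predicts the biodiversity metric in the cropland and primary-vegetation
#' contexts of each crop present and aggregates
#' `BD = sum_i p_i (BD_cropland p_cropland + BD_pv p_pv)`, where `p_i` is
#' crop i's share of the pixel's cropland and `p_cropland`, `p_pv` are the
#' land-use fractions of the pixel. Crops absent from a pixel contribute
#' nothing; pixel area outside the modelled crops' cropland and primary
#' vegetation is deliberately not renormalized over.
#'
#' @param grid a [landscape_grid()].
#' @param fits a single converged `bd_fit` shared by all crops, or a named
#'   list with one fit per crop.
#' @param crops crops to aggregate over (default: the grid's crops).
#' @return tibble `row`, `col`, `bd`, `extrapolated` over pixels with
#'   cropland of at least one modelled crop.
#' @export
project_grid_bd <- function(grid, fits, crops = attr(grid, "crops")) {
  fits <- metric_fits(fits, crops)
  area <- sapply(crops, function(cp) grid[[paste0("area_", cp)]])
  if (is.null(dim(area))) area <- matrix(area, nrow = nrow(grid))
  has_crop <- rowSums(area) > 0
  cells <- which(has_crop)
  if (length(cells) == 0L) abort("no pixel cultivates any modelled crop")
  p_cropland <- grid$cropland[cells]
  p_pv <- grid$primary_veg[cells]
  bd <- numeric(length(cells))
  extrap <- rep(FALSE, length(cells))
  for (cp in crops) {
    a <- grid[[paste0("area_", cp)]][cells]
    p_i <- ifelse(p_cropland > 0, a / p_cropland, 0)
    present <- p_i > 0
    if (!any(present)) next
    sub <- cells[present]
    bd_c <- predict_response(fits[[cp]],
                             crop_context(grid, cp, sub, "cropland"))
    bd_pv <- predict_response(fits[[cp]],
                              crop_context(grid, cp, sub,
                                           "primary vegetation"))
    extrap[present] <- extrap[present] |
      attr(bd_c, "extrapolated") | attr(bd_pv, "extrapolated")
    bd[present] <- bd[present] +
      p_i[present] * (as.numeric(bd_c) * p_cropland[present] +
                        as.numeric(bd_pv) * p_pv[present])
  }
  tibble::tibble(row = grid$row[cells], col = grid$col[cells], bd = bd,
                 extrapolated = extrap)
}

#' Per-pixel percentage change between two biodiversity surfaces
#'
#' `100 (new - base) / base` per pixel; pixels with a zero baseline are
#' undefined (`NA`), never infinite. For display, RCAR changes are
#' conventionally multiplied by -1 so that warm colours mean worse
#' outcomes; `rcar_flip = TRUE` adds that `display` column.
#'
#' @param bd_new,bd_base tibbles from [project_grid_bd()] on co-registered
#'   grids.
#' @param metric metric name carried in the result.
#' @param rcar_flip add the sign-flipped display column.
#' @return a `bd_change_map` tibble: `row`, `col`, `pct_change` (and
#'   `display` if flipped).
#' @export
pct_change_map <- function(bd_new, bd_base, metric = "richness",
                           rcar_flip = identical(metric, "rcar")) {
  joined <- dplyr::inner_join(bd_base, bd_new, by = c("row", "col"),
                              suffix = c("_base", "_new"))
  pct <- ifelse(joined$bd_base != 0,
                100 * (joined$bd_new - joined$bd_base) / joined$bd_base,
                NA_real_)
  out <- tibble::tibble(row = joined$row, col = joined$col,
                        pct_change = pct)
  if (rcar_flip) out$display <- -out$pct_change
  attr(out, "metric") <- metric
  class(out) <- c("bd_change_map", class(out))
  out
}

#' Summarize a change map
#'
#' @param map a [pct_change_map()] result.
#' @return tibble: fraction of valid pixels decreasing, mean, median,
#'   fraction exactly zero, and the number of valid pixels.
#' @export
summarize_changes <- function(map) {
  x <- map$pct_change
  x <- x[!is.na(x)]
  if (length(x) == 0L) abort("change map has no valid pixel")
  tibble::tibble(
    frac_decreasing = mean(x < 0),
    mean = mean(x),
    median = median(x),
    frac_zero = mean(x == 0),
    n_valid = length(x)
  )
}
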