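#' Pixel composition for one crop
#'
#' Extracts the per-pixel quantities the scenario engines manipulate: the
#' cropland and primary-vegetation fractions of the pixel, the focal
#' crop's area fraction and its share of the cropland, its yield, and the
#' natural-habitat fraction.
#'
#' @param grid a [landscape_grid()].
#' @param crop crop name.
#' @return tibble over pixels cultivating the crop.
#' @export
pixel_composition <- function(grid, crop) {
  acol <- paste0("area_", crop); ycol <- paste0("yield_", crop)
  if (!all(c(acol, ycol) %in% names(grid))) {
    abort(sprintf("grid lacks layer(s) for crop '%s'", crop))
  }
  cells <- which(grid[[acol]] > 0)
  if (length(cells) == 0L) abort(sprintf("no cell cultivates %s", crop))
  tibble::tibble(
    row = grid$row[cells], col = grid$col[cells], cell = cells,
    p_cropland = grid$cropland[cells],
    p_pv = grid$primary_veg[cells],
    natural = grid$natural[cells],
    crop_frac = grid[[acol]][cells],
    p_i = grid[[acol]][cells] / grid$cropland[cells],
    yield = grid[[ycol]][cells]
  )
}

#' Crop production of a pixel composition
#'
#' Production is harvested area times yield; areas are pixel-area
#' fractions, so production is in yield units per unit pixel area.
#'
#' @param composition a [pixel_composition()] tibble (or any tibble with
#'   `crop_frac` and `yield`).
#' @param pixel_area pixel area (default 1).
#' @return numeric production per pixel.
#' @export
production_of <- function(composition, pixel_area = 1) {
  composition$crop_frac * composition$yield * pixel_area
}

#' Expansion scenario: more area at year-2000 yield
#'
#' Increases the crop's cultivated area by a fraction `delta` at the cost
#' of primary vegetation, with the equivalent loss in the natural-habitat
#' fraction; yield is untouched (converted land is assumed as suitable as
#' existing local farmland), so production scales exactly by `1 + delta`.
#' Compositions that would exceed 100% cropland or drive primary
#' vegetation negative are handled by [validity_mask()], not clamped.
#'
#' @param composition a [pixel_composition()] tibble.
#' @param delta fractional production increase (>= 0).
#' @return the counterfactual composition (same columns).
#' @export
expansion_scenario <- function(composition, delta) {
  stopifnot(is_scalar_num(delta), delta >= 0)
  d <- composition$crop_frac * delta
  out <- composition
  out$crop_frac <- composition$crop_frac + d
  out$p_cropland <- composition$p_cropland + d
  out$p_pv <- composition$p_pv - d
  out$natural <- composition$natural - d
  out$p_i <- ifelse(out$p_cropland > 0, out$crop_frac / out$p_cropland, 0)
  out
}

#' Intensification patterns
#'
#' Resolves a named intensification pattern into the intensified sub-share
#' `s` of the crop's area, its yield multiplier `1 + g`, and (for the
#' restoration variant) the share of the crop's area returned to primary
#' vegetation. The sub-share and yield increase satisfy
#' `s (1 + g) + (1 - s) = 1 + delta`, so production matches the expansion
#' scenario analytically; the restoration pattern uses the conventional
#' 91.8% / 8.2% split, whose production factor 0.918 x 1.10 = 1.0098 is
#' accepted as approximately a 1% increase.
#'
#' @param pattern one of `"uniform"`, `"yield2pct_on_50pct"`,
#'   `"yield10pct_on_10pct"`, `"yield10pct_restore"`.
#' @param delta target fractional production increase.
#' @return list with `s`, `g`, `restore_frac`.
#' @export
intensification_pattern <- function(pattern = c("uniform",
                                                "yield2pct_on_50pct",
                                                "yield10pct_on_10pct",
                                                "yield10pct_restore"),
                                    delta = 0.01) {
  pattern <- match.arg(pattern)
  out <- switch(pattern,
                uniform = list(s = 1, g = delta, restore_frac = 0),
                yield2pct_on_50pct = list(s = 0.5, g = 0.02,
                                          restore_frac = 0),
                yield10pct_on_10pct = list(s = 0.1, g = 0.10,
                                           restore_frac = 0),
                yield10pct_restore = list(s = 0.918, g = 0.10,
                                          restore_frac = 0.082))
  if (pattern %in% c("yield2pct_on_50pct", "yield10pct_on_10pct") &&
      abs(out$s * out$g - delta) > 1e-12) {
    abort(sprintf(
      "pattern '%s' implies a production increase of %.4g, not delta = %g",
      pattern, out$s * out$g, delta))
  }
  out$pattern <- pattern
  out
}

#' Intensification scenario inputs
#'
#' Splits the crop's area into an intensified sub-share `s` at yield
#' `x (1 + g)` and the remainder at the year-2000 yield; land-use
#' fractions are unchanged except under the restoration pattern, where the
#' stated share of the crop's area is converted back to primary vegetation
#' (raising the natural-habitat fraction accordingly).
#'
#' @param composition a [pixel_composition()] tibble.
#' @param delta fractional production increase.
#' @param pattern pattern name, see [intensification_pattern()].
#' @return list with the counterfactual `composition`, the pattern
#'   parameters, and `yield_hi` (the intensified yield).
#' @export
intensification_scenario <- function(composition, delta,
                                     pattern = "uniform") {
  pat <- intensification_pattern(pattern, delta)
  out <- composition
  if (pat$restore_frac > 0) {
    r <- composition$crop_frac * pat$restore_frac
    out$crop_frac <- composition$crop_frac - r
    out$p_cropland <- composition$p_cropland - r
    out$p_pv <- composition$p_pv + r
    out$natural <- composition$natural + r
    out$p_i <- ifelse(out$p_cropland > 0, out$crop_frac / out$p_cropland, 0)
  }
  pat$s_within <- if (pat$restore_frac > 0) 1 else pat$s
  list(composition = out, pattern = pat,
       yield_hi = composition$yield * (1 + pat$g))
}

#' Validity of a counterfactual composition
#'
#' A counterfactual pixel is invalid if its cropland fraction exceeds 1 or
#' its primary-vegetation fraction is negative; invalid pixels are masked
#' out of all summaries and reported as a percentage.
#'
#' @param composition a composition tibble.
#' @param tol numerical tolerance.
#' @return logical vector, `TRUE` where valid.
#' @export
validity_mask <- function(composition, tol = 1e-9) {
  composition$p_cropland <= 1 + tol & composition$p_pv >= -tol
}

#' Per-pixel production-increase targets from the local yield gap
#'
#' `delta = fraction x (attainable - current) / current`, floored at zero
#' where there is no gap, so scenarios can target, for example, 1% of the
#' local yield gap instead of a fixed production increase.
#'
#' @param grid a [landscape_grid()].
#' @param crop crop name.
#' @param attainable output of [attainable_yield()] for the crop.
#' @param fraction fraction of the yield gap to target.
#' @return tibble `row`, `col`, `delta`.
#' @export
yield_gap_target <- function(grid, crop, attainable, fraction = 0.01) {
  comp <- pixel_composition(grid, crop)
  m <- match(paste(comp$row, comp$col),
             paste(attainable$row, attainable$col))
  att <- attainable$attainable[m]
  delta <- pmax(fraction * (att - comp$yield) / comp$yield, 0)
  delta[is.na(delta)] <- 0
  tibble::tibble(row = comp$row, col = comp$col, delta = delta)
}

#' Compare expansion against intensification per pixel
#'
#' For every valid pixel cultivating the crop, computes the percentage
#' biodiversity change (relative to the year-2000 baseline aggregate
#' `BD = BD_cropland p_cropland + BD_pv p_pv`) under a production-matched
#' expansion and intensification of `delta`, their difference (expansion
#' minus intensification), and the winner per metric. For species richness
#' and abundance a higher change is the better outcome; for RCAR the
#' polarity is inverted (an RCAR increase is homogenization, the worse
#' outcome). Exact ties are reported as their own class. The area-weighted
#' fraction of pixels where intensification is better uses the crop's
#' harvested area as weights.
#'
#' @param grid a [landscape_grid()].
#' @param crop crop name.
#' @param fits named list mapping metric name (e.g. `richness`,
#'   `abundance`, `rcar`) to a converged `bd_fit`.
#' @param delta fractional production increase, or a per-pixel target from
#'   [yield_gap_target()].
#' @param pattern intensification pattern name.
#' @return a `bd_scenario_result` tibble with per-pixel changes, winners
#'   and validity; per-metric area-weighted summaries in
#'   `attr(, "summary")`, masked percentage in `attr(, "masked_pct")`.
#' @export
compare_strategies <- function(grid, crop, fits, delta = 0.01,
                               pattern = "uniform") {
  if (is.null(names(fits)) || !all(nzchar(names(fits)))) {
    abort("fits must be a named list of metric -> bd_fit")
  }
  comp <- pixel_composition(grid, crop)
  if (is.data.frame(delta) && pattern != "uniform") {
    abort("per-pixel yield-gap targets require the uniform pattern")
  }
  if (is.data.frame(delta)) {
    m <- match(paste(comp$row, comp$col), paste(delta$row, delta$col))
    delta_vec <- delta$delta[m]
    delta_vec[is.na(delta_vec)] <- 0
  } else {
    delta_vec <- rep(delta, nrow(comp))
  }

  exp_comp <- expansion_scenario_vec(comp, delta_vec)
  pat <- intensification_pattern(pattern, delta = if (is.data.frame(delta))
    0.01 else delta)
  int_res <- intensification_scenario_vec(comp, delta_vec, pat)
  valid <- validity_mask(exp_comp) & validity_mask(int_res$composition) &
    int_res$feasible

  cells <- comp$cell
  out <- tibble::tibble(row = comp$row, col = comp$col, valid = valid,
                        area = comp$crop_frac, delta = delta_vec)
  summaries <- list()
  for (metric in names(fits)) {
    fit <- fits[[metric]]
    base_c <- predict_response(fit, crop_context(grid, crop, cells,
                                                 "cropland"))
    base_pv <- predict_response(fit, crop_context(grid, crop, cells,
                                                  "primary vegetation"))
    bd_base <- as.numeric(base_c) * comp$p_cropland +
      as.numeric(base_pv) * comp$p_pv

    # expansion: yields unchanged; natural habitat (and its buffer-focal
    # difference) mechanically recomputed for the lost fraction
    d_loss <- comp$crop_frac * delta_vec
    exp_c <- predict_response(fit, crop_context(grid, crop, cells,
                                                "cropland",
                                                natural_delta = -d_loss))
    exp_pv <- predict_response(fit, crop_context(grid, crop, cells,
                                                 "primary vegetation",
                                                 natural_delta = -d_loss))
    bd_exp <- as.numeric(exp_c) * exp_comp$p_cropland +
      as.numeric(exp_pv) * exp_comp$p_pv

    # intensification: the crop's sub-share s at raised yield, the rest at
    # the year-2000 yield; restoration variant also returns area to PV
    r_gain <- comp$crop_frac * pat$restore_frac
    int_c_hi <- predict_response(
      fit, crop_context(grid, crop, cells, "cropland",
                        yield_mult = 1 + int_res$g_vec,
                        natural_delta = r_gain))
    int_c_lo <- predict_response(
      fit, crop_context(grid, crop, cells, "cropland",
                        natural_delta = r_gain))
    int_pv <- predict_response(
      fit, crop_context(grid, crop, cells, "primary vegetation",
                        natural_delta = r_gain))
    # restoration: all remaining crop area is intensified; otherwise the
    # sub-share s of the crop's (unchanged) area
    s_within <- if (pat$restore_frac > 0) 1 else pat$s
    share_hi <- int_res$composition$p_i * s_within
    # written so a null increment (hi == lo) is exactly the baseline
    bd_c_mix <- as.numeric(int_c_lo) +
      share_hi * (as.numeric(int_c_hi) - as.numeric(int_c_lo))
    bd_int <- bd_c_mix * int_res$composition$p_cropland +
      as.numeric(int_pv) * int_res$composition$p_pv

    pct_exp <- ifelse(bd_base != 0, 100 * (bd_exp - bd_base) / bd_base,
                      NA_real_)
    pct_int <- ifelse(bd_base != 0, 100 * (bd_int - bd_base) / bd_base,
                      NA_real_)
    diff <- pct_exp - pct_int
    higher_better <- !identical(metric, "rcar")
    winner <- dplyr::case_when(
      is.na(diff) ~ NA_character_,
      diff == 0 ~ "tie",
      (diff > 0) == higher_better ~ "expansion",
      TRUE ~ "intensification"
    )
    out[[paste0("pct_exp_", metric)]] <- pct_exp
    out[[paste0("pct_int_", metric)]] <- pct_int
    out[[paste0("diff_", metric)]] <- diff
    out[[paste0("winner_", metric)]] <- winner

    ok <- valid & !is.na(winner)
    w <- out$area[ok]
    frac <- function(cls) {
      if (sum(w) == 0) return(NA_real_)
      100 * sum(w[winner[ok] == cls]) / sum(w)
    }
    summaries[[metric]] <- tibble::tibble(
      metric = metric,
      intensification_better_pct = frac("intensification"),
      expansion_better_pct = frac("expansion"),
      tie_pct = frac("tie")
    )
  }
  attr(out, "summary") <- dplyr::bind_rows(summaries)
  attr(out, "masked_pct") <- 100 * mean(!valid)
  attr(out, "crop") <- crop
  attr(out, "pattern") <- pat$pattern
  class(out) <- c("bd_scenario_result", class(out))
  out
}

# vectorized helpers over per-pixel deltas
expansion_scenario_vec <- function(comp, delta_vec) {
  d <- comp$crop_frac * delta_vec
  out <- comp
  out$crop_frac <- comp$crop_frac + d
  out$p_cropland <- comp$p_cropland + d
  out$p_pv <- comp$p_pv - d
  out$natural <- comp$natural - d
  out$p_i <- ifelse(out$p_cropland > 0, out$crop_frac / out$p_cropland, 0)
  out
}

intensification_scenario_vec <- function(comp, delta_vec, pat) {
  if (pat$pattern == "uniform") {
    g_vec <- delta_vec
    feasible <- rep(TRUE, nrow(comp))
  } else {
    g_vec <- rep(pat$g, nrow(comp))
    feasible <- rep(pat$s <= 1, nrow(comp))
  }
  out <- comp
  if (pat$restore_frac > 0) {
    r <- comp$crop_frac * pat$restore_frac
    out$crop_frac <- comp$crop_frac - r
    out$p_cropland <- comp$p_cropland - r
    out$p_pv <- comp$p_pv + r
    out$natural <- comp$natural + r
    out$p_i <- ifelse(out$p_cropland > 0, out$crop_frac / out$p_cropland, 0)
  }
  list(composition = out, g_vec = g_vec, feasible = feasible)
}
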