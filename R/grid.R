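#' Landscape grid container
#'
#' A landscape grid is a tibble with one row per cell of a projected
#' equal-area lattice, carrying `row`, `col`, `x_km`, `y_km`,
#' `latitude_like`, `longitude_like` and one column per named layer
#' (per-crop yields, harvested-area fractions and subsistence yields, plus
#' cropland / primary-vegetation / natural-habitat fractions, duration of
#' substantial human modification, mean annual temperature and annual
#' precipitation). Grid shape, cell size and the crop list are stored as
#' attributes so that layers can be reshaped to matrices for neighbourhood
#' operations.
#'
#' @param cells tibble of cell rows as described above.
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_km cell edge length in km.
#' @param crops character vector of crop names.
#' @return a `landscape_grid` tibble.
#' @export
landscape_grid <- function(cells, n_rows, n_cols, cell_size_km, crops) {
  stopifnot(nrow(cells) == n_rows * n_cols)
  out <- tibble::as_tibble(cells)
  attr(out, "n_rows") <- as.integer(n_rows)
  attr(out, "n_cols") <- as.integer(n_cols)
  attr(out, "cell_size_km") <- cell_size_km
  attr(out, "crops") <- crops
  class(out) <- c("landscape_grid", class(tibble::tibble()))
  out
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "<landscape_grid> %d x %d cells (%.1f km), crops: %s\n",
    attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "cell_size_km"),
    paste(attr(x, "crops"), collapse = ", ")
  ))
  NextMethod()
}

grid_dims <- function(grid) c(attr(grid, "n_rows"), attr(grid, "n_cols"))

grid_layer_names <- function(grid) {
  setdiff(names(grid), c("row", "col", "x_km", "y_km",
                         "latitude_like", "longitude_like"))
}

#' Extract one grid layer as a matrix
#'
#' @param grid a [landscape_grid()].
#' @param name layer column name.
#' @return numeric matrix indexed `[row, col]`.
#' @export
grid_layer <- function(grid, name) {
  if (!name %in% names(grid)) {
    abort(sprintf("missing layer '%s'; available: %s", name,
                  paste(grid_layer_names(grid), collapse = ", ")))
  }
  d <- grid_dims(grid)
  m <- matrix(NA_real_, d[1], d[2])
  m[cbind(grid$row, grid$col)] <- grid[[name]]
  m
}

# replace a layer from a matrix
set_grid_layer <- function(grid, name, mat) {
  grid[[name]] <- mat[cbind(grid$row, grid$col)]
  grid
}

#' Write / read a landscape grid
#'
#' The grid is stored as a long-format CSV of cell values plus a JSON
#' sidecar (`<path>.json`) recording grid shape, cell size, crop list and
#' the layer names. The round trip preserves values, layer names and any
#' missing-data mask.
#'
#' @param grid a [landscape_grid()].
#' @param path CSV file path.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns
#'   the reconstructed grid.
#' @export
write_grid <- function(grid, path) {
  readr::write_csv(tibble::as_tibble(grid), path, na = "NA")
  meta <- list(
    n_rows = attr(grid, "n_rows"), n_cols = attr(grid, "n_cols"),
    cell_size_km = attr(grid, "cell_size_km"), crops = attr(grid, "crops"),
    layers = grid_layer_names(grid)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    abort(sprintf("grid sidecar '%s' with layer names not found", side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_layers <- setdiff(meta$layers, names(cells))
  if (length(missing_layers) > 0) {
    abort(sprintf("grid file lacks declared layers: %s",
                  paste(missing_layers, collapse = ", ")))
  }
  landscape_grid(cells, meta$n_rows, meta$n_cols, meta$cell_size_km, meta$crops)
}

# mean over available Moore neighbours for every cell, as a matrix
moore_neighbour_mean <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mat
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    shifted <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    ok <- !is.na(shifted)
    acc[ok] <- acc[ok] + shifted[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Bilinear resampling utility
#'
#' Resamples a matrix to a new shape by bilinear interpolation of cell-centre
#' values. Provided for users aligning real raster inputs; the tested
#' pipeline assumes grids are born co-registered.
#'
#' @param mat numeric matrix.
#' @param n_rows,n_cols target shape.
#' @return resampled matrix.
#' @export
bilinear_resample <- function(mat, n_rows, n_cols) {
  sr <- nrow(mat); sc <- ncol(mat)
  rr <- (seq_len(n_rows) - 0.5) / n_rows * sr + 0.5
  cc <- (seq_len(n_cols) - 0.5) / n_cols * sc + 0.5
  r0 <- pmin(pmax(floor(rr), 1L), sr); r1 <- pmin(r0 + 1L, sr)
  c0 <- pmin(pmax(floor(cc), 1L), sc); c1 <- pmin(c0 + 1L, sc)
  fr <- pmin(pmax(rr - r0, 0), 1); fc <- pmin(pmax(cc - c0, 0), 1)
  out <- matrix(NA_real_, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    top <- mat[r0, c0[j]] * (1 - fc[j]) + mat[r0, c1[j]] * fc[j]
    bot <- mat[r1, c0[j]] * (1 - fc[j]) + mat[r1, c1[j]] * fc[j]
    out[, j] <- top * (1 - fr) + bot * fr
  }
  out
}
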