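# shared small synthetic world, built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 42) {
  sim_config(grid_rows = 30, grid_cols = 30, n_studies = 10,
             blocks_per_study = 2, sites_per_block = 10, seed = seed)
}

small_grid <- function() {
  if (is.null(.fixture_env$grid)) {
    .fixture_env$grid <- generate_landscape_grid(small_config())
  }
  .fixture_env$grid
}

small_sites <- function() {
  if (is.null(.fixture_env$gen)) {
    .fixture_env$gen <- generate_sites(small_grid(), config = small_config())
  }
  .fixture_env$gen
}

small_dataset <- function() {
  if (is.null(.fixture_env$dataset)) {
    .fixture_env$dataset <- small_sites()$dataset
  }
  .fixture_env$dataset
}

# a hand-built converged Gaussian-identity "fit" with known coefficients,
# for oracle tests that must not depend on an estimation backend
fake_fit <- function(coefficients,
                     xlevels = list(land_use = c("primary vegetation",
                                                 "cropland"),
                                    region = c("non_tropical", "tropical")),
                     response_scale = "identity",
                     vcov = NULL) {
  fixed <- setdiff(names(coefficients), "(Intercept)")
  # translate design-column names back to term labels for factors
  fixed <- unique(gsub("land_usecropland", "land_use",
                       gsub("regiontropical", "region", fixed)))
  spec <- bd_model_spec("bd", fixed = fixed, family = "gaussian",
                        weights_column = NULL)
  spec$response_scale <- response_scale
  structure(list(
    spec = spec, coefficients = coefficients,
    vcov = vcov %||% diag(0, length(coefficients)),
    loglik = 0, df = length(coefficients),
    re_variances = c(study = 0, block = 0),
    sigma = 1, theta = NA_real_, family = "gaussian",
    link = "identity", converged = TRUE, diagnostic = NA_character_,
    n_obs = 1L, xlevels = xlevels, covariate_specs = NULL, fit = NULL
  ), class = "bd_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
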