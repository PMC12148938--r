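#' Pipeline configuration
#'
#' Bundles the simulation (or input paths), thresholds, scenario settings
#' and output directory for [run_pipeline()]. Thresholds default to the
#' pipeline's standard values: 30%/70% landscape classification, a 23.5
#' degree tropic boundary, correlation screening at 0.6 and a selection
#' alpha of 0.05.
#'
#' @param out_dir output directory for stage artefacts.
#' @param sim a [sim_config()] describing the synthetic world.
#' @param crop focal crop for modelling and scenarios.
#' @param delta scenario production increase.
#' @param pattern intensification pattern.
#' @param select run backward model selection (otherwise fit the initial
#'   structure as-is).
#' @param initial_terms initial fixed-effects structure; `NULL` builds the
#'   default set (retained covariates, land use, region, and the yield and
#'   natural-habitat interactions) from the screened dataset.
#' @param alpha selection threshold.
#' @param n_draws fixed-effect draws for effect summaries.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), crop = NULL,
                            delta = 0.01, pattern = "uniform",
                            select = TRUE, initial_terms = NULL,
                            alpha = 0.05, n_draws = 1000) {
  cfg <- list(out_dir = out_dir, sim = sim, crop = crop %||% sim$focal_crop,
              delta = delta, pattern = pattern, select = select,
              initial_terms = initial_terms, alpha = alpha,
              n_draws = n_draws)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (with `sim` holding [sim_config()] arguments).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$re_sd)) sim_args$re_sd <- unlist(sim_args$re_sd)
  if (!is.null(sim_args$cropland_range)) {
    sim_args$cropland_range <- unlist(sim_args$cropland_range)
  }
  if (!is.null(sim_args$true_beta)) {
    sim_args$true_beta <- purrr::map(sim_args$true_beta, unlist)
  }
  sim <- do.call(sim_config, sim_args)
  pipeline_config(
    out_dir = y$out_dir %||% ".", sim = sim, crop = y$crop,
    delta = y$delta %||% 0.01, pattern = y$pattern %||% "uniform",
    select = y$select %||% TRUE,
    initial_terms = unlist(y$initial_terms),
    alpha = y$alpha %||% 0.05, n_draws = y$n_draws %||% 1000
  )
}

default_initial_terms <- function(dataset) {
  cont <- attr(dataset, "continuous")
  terms <- c(cont, "land_use", "region")
  ints <- c("yield:natural", "yield:land_use", "yield:region",
            "natural:land_use", "natural:region")
  if ("subsist" %in% cont) {
    ints <- c(ints, "yield:subsist", "natural:subsist")
  }
  keep_int <- vapply(ints, function(tm) {
    all(term_vars(tm) %in% terms)
  }, logical(1))
  c(terms, ints[keep_int])
}

#' Run the full pipeline on a synthetic world
#'
#' Chains the stages simulate (landscape grid and survey sites with known
#' ground truth), prepare (model dataset with transforms, standardization,
#' weights and correlation screening), fit (the three weighted
#' mixed-effects models, optionally with backward LRT selection), project
#' (closing yield gaps and per-metric change maps) and compare
#' (production-matched expansion versus intensification). Every stage
#' writes its artefacts under `config$out_dir`, and a manifest records the
#' configuration hash, seed and artefact list; rerunning with the same
#' configuration reproduces the deterministic artefacts bit for bit. A
#' stage failure aborts with the stage name; artefacts of completed stages
#' are left in place.
#'
#' @param config a [pipeline_config()].
#' @return list with the grid, dataset, fits, change maps, scenario result
#'   and manifest (invisibly returns file paths in `manifest$artefacts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artefacts <- character(0)
  emit <- function(name) {
    artefacts[[length(artefacts) + 1L]] <<- name
    file.path(config$out_dir, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- simulate --------------------------------------------------------
  sim_out <- stage("simulate", {
    grid <- generate_landscape_grid(config$sim)
    gen <- generate_sites(grid, config = config$sim)
    write_grid(grid, emit("grid.csv")); emit("grid.csv.json")
    readr::write_csv(gen$sites, emit("sites.csv"))
    list(grid = grid, gen = gen)
  })
  grid <- sim_out$grid

  # --- prepare ---------------------------------------------------------
  dataset <- stage("prepare", {
    ds <- assemble_model_dataset(sim_out$gen$sites, grid, config$crop)
    ab <- rescale_log_abundance(
      tibble::tibble(site_id = ds$site_id, study_id = ds$study_id,
                     abundance = ds$abundance))
    ds$log_abundance <- ab$log_abundance
    ds$log10_rcar <- log10(ds$rcar)
    readr::write_csv(tibble::as_tibble(ds), emit("model_dataset.csv"))
    specs_json <- purrr::map(attr(ds, "covariate_specs"), function(s) {
      list(kind = s$transform$kind, offset = s$transform$offset,
           C = s$transform$C, mean = s$standardizer$mean,
           sd = s$standardizer$sd, train_range = s$train_range)
    })
    jsonlite::write_json(specs_json, emit("covariate_specs.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    sl <- attr(ds, "screen_log")
    if (nrow(sl) > 0) readr::write_csv(sl, emit("screen_log.csv"))
    ds
  })

  # --- fit -------------------------------------------------------------
  fits <- stage("fit", {
    init <- config$initial_terms %||% default_initial_terms(dataset)
    init <- init[vapply(init, function(tm) {
      all(term_vars(tm) %in% names(dataset))
    }, logical(1))]
    out <- list()
    traces <- list()
    for (resp in c("richness", "log_abundance", "log10_rcar")) {
      spec <- bd_model_spec(resp, fixed = init, alpha = config$alpha)
      if (config$select) {
        sel <- backward_select(spec, dataset)
        out[[resp]] <- sel$fit
        if (nrow(sel$trace) > 0) {
          traces[[resp]] <- dplyr::mutate(sel$trace, response = resp)
        }
      } else {
        out[[resp]] <- fit_glmm(spec, dataset)
      }
      check_converged(out[[resp]])
      write_bd_fit(out[[resp]], emit(paste0("model_", resp, ".json")))
    }
    if (length(traces) > 0) {
      readr::write_csv(dplyr::bind_rows(traces), emit("selection_trace.csv"))
    }
    r2 <- purrr::imap(out, function(f, nm) {
      cbind(response = nm, pseudo_r2(f, dataset))
    })
    readr::write_csv(dplyr::bind_rows(r2), emit("pseudo_r2.csv"))
    out
  })
  metric_of <- c(richness = "richness", log_abundance = "abundance",
                 log10_rcar = "rcar")

  # --- project (closing yield gaps) ------------------------------------
  projection <- stage("project", {
    crops <- attr(grid, "crops")
    attain <- lapply(setNames(crops, crops), function(cp) {
      attainable_yield(grid, cp)
    })
    closed <- close_yield_gaps(grid, attain)
    maps <- list(); summaries <- list()
    for (resp in names(fits)) {
      metric <- metric_of[[resp]]
      base <- project_grid_bd(grid, fits[[resp]])
      new <- project_grid_bd(closed, fits[[resp]])
      cm <- pct_change_map(new, base, metric = metric)
      maps[[metric]] <- cm
      summaries[[metric]] <- cbind(metric = metric, summarize_changes(cm))
      readr::write_csv(tibble::as_tibble(cm),
                       emit(paste0("change_map_", metric, ".csv")))
    }
    summary_tbl <- dplyr::bind_rows(summaries)
    jsonlite::write_json(summary_tbl, emit("gap_closing_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(maps = maps, summary = summary_tbl, closed = closed)
  })

  # --- compare ---------------------------------------------------------
  scenario <- stage("compare", {
    metric_fits <- setNames(fits, metric_of[names(fits)])
    res <- compare_strategies(grid, config$crop, metric_fits,
                              delta = config$delta,
                              pattern = config$pattern)
    readr::write_csv(tibble::as_tibble(res), emit("scenario_result.csv"))
    jsonlite::write_json(
      list(summary = attr(res, "summary"),
           masked_pct = attr(res, "masked_pct"), crop = config$crop,
           pattern = config$pattern),
      emit("scenario_summary.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL   # the hash identifies the science, not paths
  manifest <- list(
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$sim$seed,
    package_version = as.character(utils::packageVersion("cropbiodiv")),
    artefacts = artefacts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(grid = grid, dataset = dataset, fits = fits,
                 projection = projection, scenario = scenario,
                 manifest = manifest))
}
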