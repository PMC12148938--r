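# dataset with all random-effect variances at zero, for GLM-limit oracles
zero_re_dataset <- function(seed = 9) {
  cfg <- sim_config(grid_rows = 30, grid_cols = 30, n_studies = 10,
                    blocks_per_study = 2, sites_per_block = 15,
                    re_sd = c(study = 0, block = 0, site = 0),
                    seed = seed)
  generate_sites(generate_landscape_grid(cfg), config = cfg)$dataset
}

test_that("the GLMM reduces to a weighted GLM when RE variances are zero", {
  ds <- zero_re_dataset()
  fixed <- c("yield", "natural", "land_use")

  # Poisson richness (no OLRE so both routes estimate the same model);
  # the zero-variance limit is taken by constraint, since a freely
  # estimated variance under a true zero can sit just above the boundary
  spec <- bd_model_spec("richness", fixed = fixed, family = "poisson",
                        olre = FALSE)
  f <- fit_glmm(spec, ds, constrain_re_zero = TRUE)
  oracle <- stats::glm(richness ~ yield + natural + land_use, data = ds,
                       family = stats::poisson(), weights = ds$weight)
  expect_equal(unname(f$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)

  # Gaussian log-abundance against weighted least squares
  spec_g <- bd_model_spec("log_abundance", fixed = fixed)
  fg <- fit_glmm(spec_g, ds, constrain_re_zero = TRUE)
  oracle_g <- stats::lm(log_abundance ~ yield + natural + land_use,
                        data = ds, weights = ds$weight)
  expect_equal(unname(fg$coefficients), unname(coef(oracle_g)),
               tolerance = 1e-4)
})

test_that("weights enter only relatively", {
  ds <- small_dataset()
  spec <- bd_model_spec("log_abundance", fixed = c("yield", "natural"),
                        weights_column = "weight")
  f1 <- fit_glmm(spec, ds)
  ds2 <- dplyr::mutate(ds, weight = weight * 2)
  f2 <- fit_glmm(spec, ds2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("model specification guards its invariants", {
  expect_error(bd_model_spec("log_abundance", "yield", family = "gaussian",
                             olre = TRUE), "site-level")
  sp <- bd_model_spec("richness", "yield")
  expect_equal(sp$family, "poisson")
  expect_true(sp$olre)
  ds <- small_dataset()
  expect_error(fit_glmm(bd_model_spec("richness", "no_such_col"), ds),
               "no_such_col")
  one_study <- dplyr::filter(ds, study_id == ds$study_id[1])
  expect_error(fit_glmm(sp, one_study), "2 studies")
})

test_that("likelihood-ratio test matches the chi-square reference", {
  mk <- function(fixed, loglik, df) {
    structure(list(spec = list(fixed = fixed, response = "y"),
                   loglik = loglik, df = df, n_obs = 100L),
              class = "bd_fit")
  }
  full <- mk(c("a", "b"), -100, 4L)
  same <- mk(c("a", "b"), -100, 4L)
  expect_equal(lrt(full, same)$statistic, 0)
  expect_equal(lrt(full, same)$p, 1)

  red <- mk("a", -101.92, 3L)
  out <- lrt(full, red)
  expect_equal(out$statistic, 3.84)
  expect_equal(out$df, 1L)
  expect_equal(out$p, pchisq(3.84, 1, lower.tail = FALSE))
  expect_lt(abs(out$p - 0.05), 1e-3)

  # floor at zero against optimizer noise
  red2 <- mk("a", -99.9999, 2L)
  expect_equal(lrt(full, red2)$statistic, 0)
  expect_equal(lrt(full, red2)$p, 1)

  other <- mk(c("z"), -50, 3L)
  expect_error(lrt(full, other), "nested")
})

test_that("backward selection respects marginality and the alpha contract", {
  ds <- small_dataset()
  # alpha = 1: everything droppable goes, down to the intercept
  spec <- bd_model_spec("log_abundance",
                        fixed = c("yield", "natural", "land_use"),
                        alpha = 1)
  sel <- backward_select(spec, ds)
  expect_equal(sel$spec$fixed, character(0))
  expect_equal(nrow(sel$trace), 3)
  expect_true(all(sel$trace$p > 0 | sel$trace$statistic == 0))

  # an interaction locks its parents while it is retained
  spec2 <- bd_model_spec("log_abundance",
                         fixed = c("yield", "natural", "crop_div",
                                   "yield:natural"),
                         alpha = 0.05)
  sel2 <- backward_select(spec2, ds)
  retained <- sel2$spec$fixed
  if ("yield:natural" %in% retained) {
    expect_true(all(c("yield", "natural") %in% retained))
  }
  # every dropped term had p above alpha at its drop step
  if (nrow(sel2$trace) > 0) expect_true(all(sel2$trace$p > 0.05))
})

test_that("pseudo-R2 partitions variance as advertised", {
  ds <- zero_re_dataset()
  spec <- bd_model_spec("log_abundance", fixed = c("yield", "natural"),
                        weights_column = NULL)
  f <- fit_glmm(spec, ds)
  r2 <- pseudo_r2(f, ds)
  # with RE variances ~0, both values equal the classical R2 of the fixed part
  lp <- cropbiodiv:::fixed_linear_predictor(f, ds)
  rss <- sum((ds$log_abundance - lp)^2)
  tss <- sum((ds$log_abundance - mean(ds$log_abundance))^2)
  expect_equal(r2$marginal, 1 - rss / tss, tolerance = 1e-6)
  expect_equal(r2$conditional, r2$marginal, tolerance = 1e-6)

  # intercept-only model explains nothing marginally
  f0 <- fit_glmm(bd_model_spec("log_abundance", character(0),
                               weights_column = NULL), ds)
  r20 <- pseudo_r2(f0, ds)
  expect_equal(r20$marginal, 0, tolerance = 1e-12)

  # strong random effects open a wide marginal-conditional gap
  cfg <- sim_config(grid_rows = 30, grid_cols = 30, n_studies = 15,
                    blocks_per_study = 2, sites_per_block = 10,
                    re_sd = c(study = 1.5, block = 0.5, site = 0),
                    seed = 12)
  ds_re <- generate_sites(generate_landscape_grid(cfg), config = cfg)$dataset
  f_re <- fit_glmm(bd_model_spec("log_abundance", c("yield", "natural")),
                   ds_re)
  r2_re <- pseudo_r2(f_re, ds_re)
  expect_gt(r2_re$conditional - r2_re$marginal, 0.3)
  expect_lte(r2_re$conditional, 1)
  expect_gte(r2_re$marginal, 0)
})

test_that("fixed-effect sampling reproduces the stated distribution", {
  beta <- c(`(Intercept)` = 1, yield = -0.5)
  f0 <- fake_fit(beta, vcov = diag(0, 2))
  d0 <- sample_fixed_effects(f0, n_draws = 10, seed = 1)
  expect_true(all(d0[, 1] == 1) && all(d0[, 2] == -0.5))

  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  f1 <- fake_fit(beta, vcov = V)
  d1 <- sample_fixed_effects(f1, n_draws = 1e5, seed = 2)
  expect_equal(stats::cov(d1), V, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(colMeans(d1), beta, tolerance = 0.01)

  # determinism under the seed
  expect_identical(d1, sample_fixed_effects(f1, n_draws = 1e5, seed = 2))

  bad <- fake_fit(beta, vcov = matrix(c(1, 2, 2, 1), 2))
  expect_error(sample_fixed_effects(bad), "PSD")
})

test_that("effect summaries convert contrasts to percentage changes", {
  draws <- cbind(`(Intercept)` = rep(1, 500),
                 cat = rep(log(0.89), 500))
  out <- effect_summary_pct_change(draws, list(degraded = "cat"),
                                   link = "log", reference = "pristine")
  deg <- out[out$category == "degraded", ]
  expect_equal(deg$median, -11, tolerance = 1e-10)
  expect_equal(deg$lo, deg$hi)  # zero-width for degenerate draws
  ref <- out[out$category == "pristine", ]
  expect_equal(c(ref$median, ref$lo, ref$hi), c(0, 0, 0))

  # interval endpoints are ordered for random draws
  set.seed(3)
  draws2 <- cbind(`(Intercept)` = rnorm(1000), cat = rnorm(1000))
  out2 <- effect_summary_pct_change(draws2, list(x = "cat"), link = "log")
  expect_true(all(out2$lo <= out2$median & out2$median <= out2$hi))

  # log10 link
  draws3 <- cbind(cat = rep(1, 10))
  out3 <- effect_summary_pct_change(draws3, list(x = "cat"), link = "log10")
  expect_equal(out3$median[out3$category == "x"], 900)
})

test_that("population-level predictions honour links and flag extrapolation", {
  ds <- zero_re_dataset()
  spec <- bd_model_spec("log_abundance", fixed = c("yield", "natural"),
                        weights_column = NULL)
  f <- fit_glmm(spec, ds)
  # prediction at a training row equals the fixed-part fitted value
  p <- predict_response(f, ds[3, ], scale = "link")
  lp <- cropbiodiv:::fixed_linear_predictor(f, ds[3, ])
  expect_equal(as.numeric(p), lp)
  # response scale exponentiates the log_e-scale abundance model
  expect_equal(as.numeric(predict_response(f, ds[3, ])), exp(lp))

  dsr <- small_dataset()
  fp <- fit_glmm(bd_model_spec("richness", fixed = c("yield", "natural"),
                               weights_column = NULL), dsr)
  nd <- dsr[1, ]; nd$yield <- 0; nd$natural <- 0
  expect_equal(as.numeric(predict_response(fp, nd)),
               exp(unname(fp$coefficients["(Intercept)"])))
  expect_error(predict_response(fp, nd[, "yield", drop = FALSE]),
               "missing covariate")
})

test_that("extrapolation flags match a brute-force range scan", {
  gen <- small_sites(); g <- small_grid()
  ds <- assemble_model_dataset(gen$sites, g, "maize")
  ab <- rescale_log_abundance(
    tibble::tibble(site_id = ds$site_id, study_id = ds$study_id,
                   abundance = ds$abundance))
  ds$log_abundance <- ab$log_abundance
  f <- fit_glmm(bd_model_spec("log_abundance", c("yield", "natural")), ds)
  specs <- f$covariate_specs
  nd <- cropbiodiv:::cell_covariates(g, g$row, g$col, "maize")
  nd$land_use <- "cropland"
  nd$region <- "tropical"
  p <- predict_response(f, nd)
  flag <- attr(p, "extrapolated")
  brute <- rep(FALSE, nrow(nd))
  for (v in names(specs)) {
    x <- apply_transform(nd[[v]], specs[[v]]$transform)
    x <- cropbiodiv:::apply_standardizer(as.numeric(x),
                                         specs[[v]]$standardizer)
    rng <- specs[[v]]$train_range
    brute <- brute | x < rng[1] | x > rng[2]
  }
  expect_identical(flag, brute)
  expect_gt(sum(flag), 0)  # the full grid reaches beyond the site sample
})

test_that("serialized models reproduce predictions and metadata", {
  gen <- small_sites(); g <- small_grid()
  ds <- assemble_model_dataset(gen$sites, g, "maize")
  f <- fit_glmm(bd_model_spec("richness",
                              c("yield", "natural", "land_use", "region")),
                ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_bd_fit(f, path)
  f2 <- read_bd_fit(path)
  expect_equal(f2$coefficients, f$coefficients)
  expect_equal(f2$vcov, f$vcov, ignore_attr = TRUE)
  expect_equal(f2$re_variances, f$re_variances)
  nd <- cropbiodiv:::cell_covariates(g, 1:20, 1:20, "maize")
  nd$land_use <- "cropland"; nd$region <- "non_tropical"
  expect_equal(as.numeric(predict_response(f2, nd)),
               as.numeric(predict_response(f, nd)), tolerance = 1e-12)
})

test_that("non-converged fits are blocked downstream", {
  f <- fake_fit(c(`(Intercept)` = 1))
  f$converged <- FALSE
  f$diagnostic <- "synthetic failure"
  expect_error(predict_response(f, tibble::tibble(x = 1)), "converge")
  expect_error(sample_fixed_effects(f), "converge")
})

test_that("conversion models summarize category effects versus reference", {
  gen <- small_sites(); g <- small_grid()
  ds <- filter_conversion_sites(assemble_model_dataset(gen$sites, g, "maize"))
  expect_false("excluded_intermediate" %in% ds$lu_landscape)
  ds$log10_rcar <- log10(ds$rcar)
  spec <- conversion_model_spec("log10_rcar", ds)
  # category-by-region cells can be empty at this fixture size, so the
  # interactions are dropped before fitting (rank deficiency is an error)
  spec$fixed <- setdiff(spec$fixed, c("lu_landscape:duration",
                                      "lu_landscape:region"))
  f <- fit_glmm(spec, ds)
  eff <- conversion_effects(f, n_draws = 500, seed = 4)
  expect_true("PV_natural" %in% eff$category)
  ref <- eff[eff$category == "PV_natural", ]
  expect_equal(c(ref$median, ref$lo, ref$hi), c(0, 0, 0))
  expect_true(all(eff$lo <= eff$median & eff$median <= eff$hi))
  # category medians sit near the direct coefficient transform (the
  # median over draws converges to the point estimate's transform)
  for (cat in setdiff(eff$category, "PV_natural")) {
    co <- unname(f$coefficients[paste0("lu_landscape", cat)])
    point <- 100 * (10^co - 1)
    expect_lt(abs(eff$median[eff$category == cat] - point),
              0.25 * max(abs(point), 10))
  }
})

test_that("Poisson-with-OLRE and negative-binomial agree in sign", {
  ds <- small_dataset()
  fixed <- c("yield", "natural", "land_use")
  fp <- fit_glmm(bd_model_spec("richness", fixed, family = "poisson"), ds)
  fn <- fit_glmm(bd_model_spec("richness", fixed, family = "nbinom2",
                               olre = FALSE), ds)
  expect_true(fp$converged && fn$converged)
  expect_equal(sign(unname(fp$coefficients)), sign(unname(fn$coefficients)))
})
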