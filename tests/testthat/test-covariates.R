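test_that("Shannon crop diversity matches direct evaluation", {
  expect_equal(shannon_crop_diversity(c(1, 0, 0)), 0)
  expect_equal(shannon_crop_diversity(c(0.5, 0.5)), log(2))
  expect_equal(shannon_crop_diversity(rep(1 / 175, 175)), log(175))
  # invariant to rescaling all areas by a constant
  a <- c(2, 3, 7, 0.5)
  expect_equal(shannon_crop_diversity(a), shannon_crop_diversity(a * 13.7))
  expect_lte(shannon_crop_diversity(a), log(4))
  expect_error(shannon_crop_diversity(c(0, 0)), "zero")
  expect_error(shannon_crop_diversity(c(-1, 2)), "non-negative")
})

test_that("site weights are proportional to relative area with mean 1", {
  w <- site_weights(c(0.2, 0.4), c(1, 1))
  expect_equal(w$weight, c(2 / 3, 4 / 3))
  expect_equal(mean(w$weight), 1, tolerance = 1e-15)

  w2 <- site_weights(rep(0.3, 5), rep(0.6, 5))
  expect_equal(w2$weight, rep(1, 5))

  set.seed(1)
  for (i in 1:20) {
    n <- sample(2:200, 1)
    tot <- runif(n, 0.1, 1)
    foc <- tot * runif(n)
    w3 <- site_weights(foc, tot)
    expect_lt(abs(mean(w3$weight) - 1), 1e-12)
    expect_equal(sum(w3$weight), n)          # sum equals N_sites exactly
    expect_true(all(w3$ra >= 0 & w3$ra <= 1))
  }
  expect_error(site_weights(c(0, 0), c(1, 1)), "zero")
  expect_error(site_weights(c(2), c(1)), "exceeds")
})

test_that("left-skew constant rule rounds up max plus margin", {
  expect_equal(make_left_skew_constant(28.5, 1), 30)
  expect_equal(make_left_skew_constant(0, 1), 1)
  # the plain ceiling rule gives 2002 for the duration variable; the
  # conventional published constant 2005 must be supplied as an override
  expect_equal(make_left_skew_constant(1981.6, 20), 2002)
  sp <- transform_spec("left_skew_log", C = 2005)
  expect_equal(apply_transform(1981.6, sp), log(2005 - 1981.6),
               ignore_attr = TRUE)
})

test_that("skew transforms evaluate, invert and order as stated", {
  left <- transform_spec("left_skew_log", C = 30)
  expect_equal(apply_transform(28.5, left), log(1.5), ignore_attr = TRUE)
  right <- transform_spec("right_skew_log", offset = 0.01)
  expect_equal(apply_transform(0, right), log(0.01), ignore_attr = TRUE)
  # left-skew reverses ranking; right-skew preserves it
  expect_gt(apply_transform(10, left), apply_transform(20, left))
  expect_lt(apply_transform(10, right), apply_transform(20, right))
  # bijection: inverse recovers inputs to 1e-10
  v <- runif(50, 0, 29)
  expect_equal(invert_transform(as.numeric(apply_transform(v, left)), left),
               v, tolerance = 1e-10)
  expect_equal(invert_transform(as.numeric(apply_transform(v, right)),
                                right), v, tolerance = 1e-10)
  # domain violations name the offending value
  expect_error(apply_transform(31, left), "31")
  expect_error(apply_transform(-0.02, right), "-0.02")
})

test_that("landscape and region classification honour the thresholds", {
  expect_equal(as.character(classify_landscape(c(0.2, 0.5, 0.8))),
               c("modified", "intermediate", "natural"))
  # boundaries fall in the excluded band (strict inequalities)
  expect_equal(as.character(classify_landscape(c(0.30, 0.70))),
               rep("intermediate", 2))
  expect_error(classify_landscape(1.2), "1.2")

  expect_equal(
    as.character(combine_lu_landscape("primary vegetation",
                                      classify_landscape(0.8))),
    "PV_natural")
  expect_equal(
    as.character(combine_lu_landscape("cropland", classify_landscape(0.2))),
    "crop_modified")
  # totality over {primary, cropland} x [0, 1]
  fr <- seq(0, 1, by = 0.05)
  for (lu in c("primary vegetation", "cropland")) {
    out <- combine_lu_landscape(rep(lu, length(fr)), classify_landscape(fr))
    expect_false(any(is.na(out)))
  }
  expect_error(combine_lu_landscape("pasture", classify_landscape(0.5)),
               "pasture")

  expect_equal(as.character(geographic_region(c(0, 45, 23.5, -23.5, -60))),
               c("tropical", "non_tropical", "tropical", "tropical",
                 "non_tropical"))
  expect_error(geographic_region(91), "latitude")
})

test_that("buffer-focal difference averages the Moore ring", {
  m <- matrix(5, 3, 3)
  expect_equal(buffer_focal_difference(m, 2, 2), 0)
  m2 <- matrix(c(1, 2, 3, 4, 0, 5, 6, 7, 8), 3, 3)
  expect_equal(buffer_focal_difference(m2, 2, 2), mean(1:8))
  # corner cell: only the available neighbours
  m3 <- matrix(0, 2, 2)
  m3[1, 1] <- 4; m3[1, 2] <- 2; m3[2, 1] <- 4; m3[2, 2] <- 6
  expect_equal(buffer_focal_difference(m3, 1, 1), mean(c(2, 4, 6)) - 4)
  # single-cell grid has no neighbour
  expect_warning(out <- buffer_focal_difference(matrix(1), 1, 1),
                 "neighbour")
  expect_true(is.na(out))
})

test_that("duration of modification uses the first threshold crossing", {
  expect_equal(duration_of_modification(0, 0.4, reference_year = 2000), 2000)
  expect_equal(duration_of_modification(c(1900, 1950), c(0.1, 0.2)), 0)
  expect_equal(
    duration_of_modification(c(1900, 1950, 1960), c(0.2, 0.35, 0.5),
                             reference_year = 2000), 50)
  expect_error(duration_of_modification(numeric(0), numeric(0)), "empty")
})

test_that("correlation screening removes by priority and cleans all pairs", {
  set.seed(4)
  n <- 400
  yield <- rnorm(n)
  d <- tibble::tibble(
    yield = yield,
    yield_bfd = 0.95 * yield + 0.1 * rnorm(n),   # r ~ 0.99 with yield
    natural = rnorm(n),
    temperature = rnorm(n)
  )
  sc <- correlation_screen(d, names(d))
  expect_true("yield" %in% sc$retained)
  expect_true("yield_bfd" %in% sc$removed)
  expect_equal(nrow(sc$log), 1)
  expect_gt(abs(sc$log$r), 0.6)

  clean <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(correlation_screen(clean, names(clean))$removed, character(0))

  # three mutually correlated: greedy removal until brute-force clean
  z <- rnorm(n)
  tri <- tibble::tibble(yield = z + 0.3 * rnorm(n),
                        natural = z + 0.3 * rnorm(n),
                        crop_div = z + 0.3 * rnorm(n))
  sc3 <- correlation_screen(tri, names(tri))
  cm <- abs(stats::cor(as.data.frame(tri[sc3$retained])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.6)
  # priority variables survive non-priority ones
  expect_true("yield" %in% sc3$retained)
})

test_that("agricultural year selection is nearest with earlier ties", {
  expect_equal(select_agri_year(2003), 2005)
  expect_equal(select_agri_year(2002.5), 2000)
  expect_equal(select_agri_year(2011), 2010)
  expect_equal(select_agri_year(c(1990, 2007.5)), c(2000, 2005))
})

test_that("model dataset assembly filters, standardizes and freezes specs", {
  gen <- small_sites()
  g <- small_grid()
  ds <- assemble_model_dataset(gen$sites, g, "maize")
  # crop filter: all retained sites sit in cells with maize area > 0
  area <- grid_layer(g, "area_maize")
  loc <- gen$sites[match(ds$site_id, gen$sites$site_id), ]
  expect_true(all(area[cbind(loc$row, loc$col)] > 0))
  # standardized columns have mean 0, sd 1
  for (v in attr(ds, "continuous")) {
    expect_lt(abs(mean(ds[[v]])), 1e-9)
    expect_lt(abs(sd(ds[[v]]) - 1), 1e-9)
  }
  expect_equal(mean(ds$weight), 1, tolerance = 1e-12)
  # no retained pair correlates above the threshold
  cm <- abs(stats::cor(as.data.frame(ds[attr(ds, "continuous")])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.6)

  # a site placed in a cell without the crop is excluded and logged
  empty_cell <- which(g$area_maize == 0)[1]
  extra <- gen$sites[1, ]
  extra$site_id <- "ghost"
  extra$row <- g$row[empty_cell]; extra$col <- g$col[empty_cell]
  ds2 <- assemble_model_dataset(dplyr::bind_rows(gen$sites, extra), g,
                                "maize")
  expect_true("ghost" %in% attr(ds2, "excluded"))
  expect_false("ghost" %in% ds2$site_id)
})

test_that("stored transform and standardization specs reproduce the columns", {
  gen <- small_sites()
  g <- small_grid()
  ds <- assemble_model_dataset(gen$sites, g, "maize")
  specs <- attr(ds, "covariate_specs")
  raw <- cropbiodiv:::cell_covariates(
    g, gen$sites$row[match(ds$site_id, gen$sites$site_id)],
    gen$sites$col[match(ds$site_id, gen$sites$site_id)], "maize")
  for (v in attr(ds, "continuous")) {
    x <- apply_transform(raw[[v]], specs[[v]]$transform)
    x <- cropbiodiv:::apply_standardizer(as.numeric(x),
                                         specs[[v]]$standardizer)
    expect_identical(x, ds[[v]])   # bit-for-bit round trip
  }
})
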