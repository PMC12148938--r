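#' Specify a weighted mixed-effects biodiversity model
#'
#' Describes one of the three response models: species richness (Poisson,
#' log link, with an observation-level random intercept for site to absorb
#' overdispersion; a negative-binomial alternative drops that random
#' effect), or the Gaussian models of log_e rescaled abundance and log10
#' RCAR. All models carry random intercepts for study identity and for
#' spatial block nested within study, are estimated by maximum likelihood
#' (likelihood-ratio tests on fixed effects require ML), and weight
#' observations by the per-site crop-area weights.
#'
#' @param response response column name (`richness`, `log_abundance`,
#'   `log10_rcar`, or any column of the data).
#' @param fixed character vector of fixed-effect terms (main effects and
#'   `a:b` interactions).
#' @param family `"poisson"`, `"nbinom2"` or `"gaussian"`; `"auto"` picks
#'   Poisson for `richness` and Gaussian otherwise.
#' @param olre include the observation-level (site) random intercept;
#'   defaults to `TRUE` for Poisson and `FALSE` otherwise.
#' @param weights_column name of the weights column (`NULL` for
#'   unweighted).
#' @param alpha significance threshold for backward selection.
#' @return a `bd_model_spec` list.
#' @export
bd_model_spec <- function(response, fixed,
                          family = c("auto", "poisson", "nbinom2",
                                     "gaussian"),
                          olre = NULL, weights_column = "weight",
                          alpha = 0.05) {
  family <- match.arg(family)
  if (family == "auto") {
    family <- if (response == "richness") "poisson" else "gaussian"
  }
  olre <- olre %||% (family == "poisson")
  if (family == "gaussian" && olre) {
    abort("Gaussian responses never carry the site-level random effect")
  }
  response_scale <- switch(response,
                           richness = "exp",
                           log_abundance = "exp",
                           log10_rcar = "pow10",
                           "identity")
  structure(list(response = response, fixed = fixed, family = family,
                 olre = olre, weights_column = weights_column,
                 alpha = alpha, response_scale = response_scale),
            class = "bd_model_spec")
}

spec_formula <- function(spec) {
  fixed <- if (length(spec$fixed) == 0L) "1" else
    paste(spec$fixed, collapse = " + ")
  re <- "(1 | study_id) + (1 | block_id)"
  if (spec$olre) re <- paste(re, "+ (1 | site_id)")
  as.formula(paste(spec$response, "~", fixed, "+", re))
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Fit a weighted generalized linear mixed model
#'
#' Fits the model described by a [bd_model_spec()] with glmmTMB (maximum
#' likelihood, Laplace approximation for the Poisson family). The returned
#' object keeps the fixed-effect estimates, their variance-covariance
#' matrix, the random-effect variances, the log-likelihood and the frozen
#' covariate transform/standardization state of the training data (when
#' the data carries one, as produced by [assemble_model_dataset()]), so
#' projections can run from a serialized model without refitting.
#' Non-converged fits are returned flagged (`converged = FALSE`) with a
#' diagnostic message; downstream consumers refuse them.
#'
#' @param spec a [bd_model_spec()].
#' @param data model dataset with the response, covariates, `study_id`,
#'   `block_id`, `site_id` and the weights column.
#' @param constrain_re_zero fix all random-effect standard deviations at
#'   (numerically) zero instead of estimating them. In that limit the
#'   weighted mixed model reduces exactly to a weighted GLM, which is how
#'   the reduction is verified against an independent oracle; a freely
#'   estimated variance under a true zero routinely lands slightly above
#'   the boundary and shifts the fixed effects by more than the reduction
#'   identity allows.
#' @return a `bd_fit` object.
#' @export
fit_glmm <- function(spec, data, constrain_re_zero = FALSE) {
  stopifnot(inherits(spec, "bd_model_spec"))
  need <- unique(c(spec$response, unlist(lapply(spec$fixed, term_vars)),
                   "study_id", "block_id", "site_id"))
  need <- setdiff(need, "1")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("data lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (dplyr::n_distinct(data$study_id) < 2L) {
    abort("at least 2 studies are required to fit the random effects")
  }
  covariate_specs <- attr(data, "covariate_specs")
  data <- as.data.frame(data)
  w <- if (is.null(spec$weights_column)) rep(1, nrow(data)) else
    data[[spec$weights_column]]
  if (any(w < 0) || all(w == 0)) abort("weights must be non-negative")
  # weights act as frequency weights in the likelihood; rescaling to mean 1
  # keeps the apparent sample size equal to the real one, so only relative
  # weights matter
  data$.w <- w / mean(w)

  fam <- switch(spec$family,
                poisson = stats::poisson(link = "log"),
                nbinom2 = glmmTMB::nbinom2(link = "log"),
                gaussian = stats::gaussian())
  fit <- if (constrain_re_zero) {
    n_theta <- 2L + as.integer(spec$olre)   # study, block, optional site
    suppressWarnings(
      glmmTMB::glmmTMB(spec_formula(spec), data = data, family = fam,
                       weights = .w, REML = FALSE,
                       start = list(theta = rep(log(1e-6), n_theta)),
                       map = list(theta = factor(rep(NA, n_theta))))
    )
  } else {
    suppressWarnings(
      glmmTMB::glmmTMB(spec_formula(spec), data = data, family = fam,
                       weights = .w, REML = FALSE)
    )
  }

  beta <- glmmTMB::fixef(fit)$cond
  V <- as.matrix(stats::vcov(fit)$cond)
  ll <- logLik(fit)
  vc <- glmmTMB::VarCorr(fit)$cond
  re_var <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  names(re_var) <- sub("^site_id$", "site",
                       sub("^block_id$", "block",
                           sub("^study_id$", "study", names(re_var))))
  pdhess <- isTRUE(fit$sdr$pdHess)
  conv <- isTRUE(fit$fit$convergence == 0) && pdhess &&
    all(is.finite(beta)) && all(is.finite(diag(V)))
  diagnostic <- if (conv) NA_character_ else {
    paste0("optimizer code ", fit$fit$convergence,
           if (!pdhess) "; non-positive-definite Hessian" else "")
  }
  if (any(is.na(beta))) {
    abort(sprintf("rank-deficient fixed-effect design; aliased: %s",
                  paste(names(beta)[is.na(beta)], collapse = ", ")))
  }

  factors <- names(data)[vapply(data, is.factor, logical(1))]
  used <- unique(unlist(lapply(spec$fixed, term_vars)))
  xlevels <- lapply(data[intersect(factors, used)], levels)

  structure(list(
    spec = spec, coefficients = beta, vcov = V,
    loglik = as.numeric(ll), df = attr(ll, "df"),
    re_variances = re_var,
    sigma = if (spec$family == "gaussian") stats::sigma(fit) else NA_real_,
    theta = if (spec$family == "nbinom2") stats::sigma(fit) else NA_real_,
    family = spec$family,
    link = if (spec$family == "gaussian") "identity" else "log",
    converged = conv, diagnostic = diagnostic,
    n_obs = nrow(data), xlevels = xlevels,
    covariate_specs = covariate_specs,
    fit = fit
  ), class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("<bd_fit> %s ~ %s\n", x$spec$response,
              paste(x$spec$fixed, collapse = " + ")))
  cat(sprintf("  family %s, n = %d, logLik = %.2f, converged: %s\n",
              x$family, x$n_obs, x$loglik, x$converged))
  invisible(x)
}

check_converged <- function(fit) {
  if (!isTRUE(fit$converged)) {
    abort(sprintf("model did not converge (%s); refusing downstream use",
                  fit$diagnostic))
  }
  invisible(fit)
}

#' Likelihood-ratio test between nested fits
#'
#' Twice the log-likelihood difference (floored at zero against optimizer
#' noise), with degrees of freedom equal to the difference in parameter
#' counts, referred to the upper tail of the chi-square distribution.
#'
#' @param full,reduced `bd_fit` objects on the same data and random
#'   structure, `reduced` nested in `full`.
#' @return tibble with `statistic`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$spec$fixed %in% full$spec$fixed) ||
      full$spec$response != reduced$spec$response ||
      full$n_obs != reduced$n_obs) {
    abort("models are not nested on the same data")
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- max(full$df - reduced$df, 0L)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p = p)
}

droppable_terms <- function(fixed) {
  is_int <- grepl(":", fixed, fixed = TRUE)
  locked <- unique(unlist(lapply(fixed[is_int], term_vars)))
  fixed[is_int | !(fixed %in% locked)]
}

#' Backward stepwise selection by likelihood-ratio tests
#'
#' Starting from the full fixed-effects structure, repeatedly refits the
#' model without each currently droppable term (marginality is respected:
#' a main effect is not droppable while an interaction containing it is
#' retained), and removes the term with the largest likelihood-ratio
#' p-value above `alpha`. Ties prefer the higher-order term, then the
#' lexicographically earlier name, so selection is deterministic. If the
#' initial model does not converge, the interactions listed in
#' `fallback_drop` are removed up front before selection begins (the
#' documented remedy for convergence failures of data-poor responses);
#' persistent non-convergence aborts with the trace so far.
#'
#' @param spec initial [bd_model_spec()].
#' @param data model dataset.
#' @param fallback_drop interaction terms to remove if the initial fit
#'   fails to converge.
#' @return list with `fit` (final `bd_fit`), `trace` (tibble of drop
#'   steps) and `spec` (final model spec).
#' @export
backward_select <- function(spec, data, fallback_drop = character()) {
  current <- fit_glmm(spec, data)
  if (!current$converged && length(fallback_drop) > 0) {
    spec$fixed <- setdiff(spec$fixed, fallback_drop)
    current <- fit_glmm(spec, data)
  }
  trace <- list()
  if (!current$converged) {
    abort(sprintf("initial model failed to converge (%s)",
                  current$diagnostic))
  }
  repeat {
    cand <- droppable_terms(current$spec$fixed)
    if (length(cand) == 0L) break
    tests <- purrr::map(cand, function(tm) {
      red_spec <- current$spec
      red_spec$fixed <- setdiff(red_spec$fixed, tm)
      red <- fit_glmm(red_spec, data)
      if (red$loglik > current$loglik + 1e-4) {
        warn(sprintf(
          "log-likelihood rose by %.2g after dropping '%s' (optimizer noise)",
          red$loglik - current$loglik, tm))
      }
      cbind(lrt(current, red), term = tm, order = length(term_vars(tm)),
            converged = red$converged)
    })
    tests <- dplyr::bind_rows(tests) |>
      dplyr::filter(.data$converged)
    if (nrow(tests) == 0L) break
    tests <- tests |>
      dplyr::arrange(dplyr::desc(.data$p), dplyr::desc(.data$order),
                     .data$term)
    best <- tests[1L, ]
    # alpha >= 1 is the degenerate threshold: no term can be significant,
    # so everything droppable goes
    if (best$p <= current$spec$alpha && current$spec$alpha < 1) break
    new_spec <- current$spec
    new_spec$fixed <- setdiff(new_spec$fixed, best$term)
    nxt <- fit_glmm(new_spec, data)
    if (!nxt$converged) {
      warn(sprintf("refit without '%s' failed to converge; stopping",
                   best$term))
      break
    }
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = length(trace) + 1L, dropped = best$term,
      statistic = best$statistic, df = best$df, p = best$p
    )
    current <- nxt
  }
  list(fit = current, trace = dplyr::bind_rows(trace), spec = current$spec)
}

fixed_linear_predictor <- function(fit, data) {
  X <- fixed_design(fit, data)
  unname(drop(X %*% fit$coefficients))
}

fixed_design <- function(fit, data) {
  fixed <- fit$spec$fixed
  data <- as.data.frame(data)
  for (v in names(fit$xlevels)) {
    if (!v %in% names(data)) abort(sprintf("missing covariate column '%s'", v))
    data[[v]] <- factor(data[[v]], levels = fit$xlevels[[v]])
  }
  used <- setdiff(unique(unlist(lapply(fixed, term_vars))), "1")
  missing <- setdiff(used, names(data))
  if (length(missing) > 0) {
    abort(sprintf("missing covariate column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  form <- if (length(fixed) == 0L) ~1 else
    stats::reformulate(fixed, intercept = TRUE)
  X <- model.matrix(form, data = data)
  bad <- setdiff(names(fit$coefficients), colnames(X))
  if (length(bad) > 0) {
    abort(sprintf("design lacks coefficient column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  X[, names(fit$coefficients), drop = FALSE]
}

#' Marginal and conditional pseudo-R-squared
#'
#' Variance-partitioning pseudo-R2 for mixed models: the marginal value is
#' the variance of the fixed-effect linear predictor over the total of
#' fixed-effect variance, summed random-effect variances and the
#' distribution-specific variance; the conditional value adds the
#' random-effect variances to the numerator. For the Gaussian family the
#' distribution-specific variance is the residual variance; for the
#' log-link count families a lognormal approximation
#' `ln(1 + 1/lambda)` with `lambda = exp(beta_0 + sigma_re^2 / 2)` is used
#' (plus `1/theta` for the negative binomial).
#'
#' @param fit a converged `bd_fit`.
#' @param data the training data.
#' @return tibble with `marginal` and `conditional`.
#' @export
pseudo_r2 <- function(fit, data) {
  check_converged(fit)
  lp <- fixed_linear_predictor(fit, data)
  var_f <- mean((lp - mean(lp))^2)
  var_re <- sum(fit$re_variances)
  var_d <- switch(fit$family,
                  gaussian = fit$sigma^2,
                  poisson = {
                    b0 <- unname(fit$coefficients["(Intercept)"])
                    log1p(1 / exp(b0 + var_re / 2))
                  },
                  nbinom2 = {
                    b0 <- unname(fit$coefficients["(Intercept)"])
                    log1p(1 / exp(b0 + var_re / 2) + 1 / fit$theta)
                  })
  tot <- var_f + var_re + var_d
  tibble::tibble(marginal = var_f / tot,
                 conditional = (var_f + var_re) / tot)
}

#' Sample fixed effects from their estimated distribution
#'
#' Multivariate-normal draws centred at the fixed-effect estimates with
#' the model's variance-covariance matrix, via symmetric eigendecomposition
#' with small negative eigenvalues (>= -1e-10 relative) clipped to zero;
#' anything more negative is an error.
#'
#' @param fit a converged `bd_fit`.
#' @param n_draws number of draws (the effect summaries use 1,000).
#' @param seed random seed.
#' @return `n_draws` x `n_coefficients` matrix.
#' @export
sample_fixed_effects <- function(fit, n_draws = 1000, seed = 1L) {
  check_converged(fit)
  V <- (fit$vcov + t(fit$vcov)) / 2
  e <- eigen(V, symmetric = TRUE)
  tol <- 1e-10 * max(1, abs(e$values[1]))
  if (any(e$values < -tol)) {
    abort(sprintf("variance-covariance matrix is not PSD (min eigenvalue %g)",
                  min(e$values)))
  }
  lam <- pmax(e$values, 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- length(fit$coefficients)
  Z <- matrix(rnorm(n_draws * p), n_draws, p)
  draws <- Z %*% (t(e$vectors) * sqrt(lam)) |> sweep(2, fit$coefficients, `+`)
  colnames(draws) <- names(fit$coefficients)
  draws
}

#' Summarize effects as percentage change versus a reference category
#'
#' Converts draws of the fixed effects into per-category percentage changes
#' on the response scale relative to the reference category (whose change
#' is identically 0), and reports the median and the 2.5th and 97.5th
#' percentiles over draws. For log-link models a linear-predictor contrast
#' `d` maps to `100 (e^d - 1)` percent; for the log10-scale Gaussian RCAR
#' model to `100 (10^d - 1)`.
#'
#' @param draws matrix from [sample_fixed_effects()].
#' @param contrasts named list mapping category name to either a single
#'   coefficient name or a numeric contrast vector over coefficients.
#' @param link `"log"`, `"log10"` or `"identity"`; for `"identity"` a
#'   `reference_value` (response-scale baseline) is required.
#' @param reference name of the reference category (reported as 0 change).
#' @param reference_value baseline for the identity link.
#' @return a `bd_effect_summary` tibble: category, median, lo, hi, n_draws.
#' @export
effect_summary_pct_change <- function(draws, contrasts,
                                      link = c("log", "log10", "identity"),
                                      reference = "reference",
                                      reference_value = NULL) {
  link <- match.arg(link)
  p <- ncol(draws)
  rows <- purrr::imap(contrasts, function(ctr, nm) {
    if (is.character(ctr)) {
      if (!ctr %in% colnames(draws)) {
        abort(sprintf("no coefficient '%s' in draws", ctr))
      }
      d <- draws[, ctr]
    } else {
      stopifnot(length(ctr) == p)
      d <- drop(draws %*% ctr)
    }
    pct <- switch(link,
                  log = 100 * (exp(d) - 1),
                  log10 = 100 * (10^d - 1),
                  identity = {
                    if (is.null(reference_value)) {
                      abort("identity link needs reference_value")
                    }
                    100 * (d / reference_value)
                  })
    q <- quantile(pct, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(category = nm, median = q[2], lo = q[1], hi = q[3],
                   n_draws = nrow(draws))
  })
  out <- dplyr::bind_rows(
    tibble::tibble(category = reference, median = 0, lo = 0, hi = 0,
                   n_draws = nrow(draws)),
    dplyr::bind_rows(unname(rows))
  )
  class(out) <- c("bd_effect_summary", class(out))
  out
}

#' Population-level response-scale predictions
#'
#' Predicts the response on its natural scale from the fixed effects alone
#' (random effects at zero, the population level used by all projections).
#' When the fit carries frozen covariate transform/standardization state,
#' raw covariates in `newdata` are transformed and standardized with it;
#' rows whose standardized covariates fall outside the training range are
#' flagged as extrapolations (attribute `"extrapolated"`), but predictions
#' are not clamped.
#'
#' @param fit a converged `bd_fit`.
#' @param newdata covariate tibble (raw scale if the fit has covariate
#'   specs, otherwise already standardized).
#' @param scale `"response"` (default) or `"link"`.
#' @return numeric predictions with attribute `extrapolated`.
#' @export
predict_response <- function(fit, newdata, scale = c("response", "link")) {
  scale <- match.arg(scale)
  check_converged(fit)
  newdata <- as.data.frame(newdata)
  extrap <- rep(FALSE, nrow(newdata))
  specs <- fit$covariate_specs
  if (!is.null(specs)) {
    for (v in names(specs)) {
      if (!v %in% names(newdata)) next
      x <- apply_transform(newdata[[v]], specs[[v]]$transform)
      x <- apply_standardizer(as.numeric(x), specs[[v]]$standardizer)
      rng <- specs[[v]]$train_range
      extrap <- extrap | x < rng[1] | x > rng[2]
      newdata[[v]] <- x
    }
  }
  eta <- fixed_linear_predictor(fit, newdata)
  out <- if (scale == "link") eta else
    switch(fit$spec$response_scale,
           exp = exp(eta),
           pow10 = 10^eta,
           identity = eta)
  attr(out, "extrapolated") <- extrap
  out
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores everything projections need (coefficients, variance-covariance
#' matrix, random-effect variances, family and link, factor levels, the
#' model spec and the frozen covariate specs) in a plain JSON file, so the
#' scenario engines can run without refitting. The underlying glmmTMB
#' object is not stored.
#'
#' @param fit a `bd_fit`.
#' @param path JSON file path.
#' @return `write_bd_fit()` returns `path` invisibly; `read_bd_fit()` a
#'   `bd_fit` (without the backend fit object).
#' @export
write_bd_fit <- function(fit, path) {
  specs <- fit$covariate_specs
  specs_json <- purrr::map(specs, function(s) {
    list(kind = s$transform$kind, offset = s$transform$offset,
         C = s$transform$C, margin = s$transform$margin,
         mean = s$standardizer$mean, sd = s$standardizer$sd,
         train_range = s$train_range)
  })
  obj <- list(
    spec = unclass(fit$spec),
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov, loglik = fit$loglik, df = fit$df,
    re_variances = as.list(fit$re_variances),
    sigma = fit$sigma, theta = fit$theta,
    family = fit$family, link = fit$link,
    converged = fit$converged, diagnostic = fit$diagnostic,
    n_obs = fit$n_obs, xlevels = fit$xlevels,
    covariate_specs = specs_json
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_bd_fit
#' @export
read_bd_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- obj$spec
  spec$fixed <- as.character(spec$fixed)
  class(spec) <- "bd_model_spec"
  specs <- purrr::map(obj$covariate_specs, function(s) {
    list(transform = transform_spec(s$kind, offset = s$offset %||% 0.01,
                                    C = s$C, margin = s$margin %||% 1),
         standardizer = list(mean = s$mean, sd = s$sd),
         train_range = as.numeric(s$train_range))
  })
  if (length(specs) == 0L) specs <- NULL
  structure(list(
    spec = spec,
    coefficients = unlist(obj$coefficients),
    vcov = matrix(unlist(obj$vcov), nrow = length(obj$coefficients)),
    loglik = obj$loglik, df = obj$df,
    re_variances = unlist(obj$re_variances),
    sigma = obj$sigma %||% NA_real_, theta = obj$theta %||% NA_real_,
    family = obj$family, link = obj$link,
    converged = obj$converged, diagnostic = obj$diagnostic %||% NA_character_,
    n_obs = obj$n_obs,
    xlevels = purrr::map(obj$xlevels, as.character),
    covariate_specs = specs, fit = NULL
  ), class = "bd_fit")
}

#' Land-conversion model: spec, data filter and effect summaries
#'
#' The land-conversion analysis models each biodiversity response against
#' the combined land-use-landscape categories (with primary vegetation in
#' natural landscapes as reference) plus duration of modification, climate
#' and geographic region, including the category interactions with
#' duration and region. Sites in the intermediate landscape band (30-70%
#' natural vegetation) are excluded first. `conversion_model_spec()`
#' intersects the term set with the columns the screened dataset actually
#' retains.
#'
#' @param response response column name.
#' @param dataset the assembled model dataset (used to drop screened-out
#'   covariates from the term set).
#' @param alpha selection threshold.
#' @return a [bd_model_spec()].
#' @export
conversion_model_spec <- function(response, dataset, alpha = 0.05) {
  mains <- intersect(c("duration", "temperature", "precipitation"),
                     names(dataset))
  fixed <- c("lu_landscape", mains, "region",
             if ("duration" %in% mains) "lu_landscape:duration",
             "lu_landscape:region")
  bd_model_spec(response, fixed = fixed, alpha = alpha)
}

#' @rdname conversion_model_spec
#' @export
filter_conversion_sites <- function(dataset) {
  keep_attrs <- attributes(dataset)[c("covariate_specs", "continuous",
                                      "screen_log", "crop")]
  out <- dataset[dataset$lu_landscape != "excluded_intermediate", ,
                 drop = FALSE]
  out$lu_landscape <- droplevels(out$lu_landscape)
  for (a in names(keep_attrs)) attr(out, a) <- keep_attrs[[a]]
  out
}

#' @rdname conversion_model_spec
#' @param fit a converged `bd_fit` from a conversion model.
#' @param n_draws fixed-effect draws.
#' @param seed random seed for the draws.
#' @return `conversion_effects()`: a `bd_effect_summary` of percentage
#'   change per land-use-landscape category relative to primary vegetation
#'   in natural landscapes.
#' @export
conversion_effects <- function(fit, n_draws = 1000, seed = 1L) {
  draws <- sample_fixed_effects(fit, n_draws = n_draws, seed = seed)
  cats <- grep("^lu_landscape", colnames(draws), value = TRUE)
  cats <- cats[!grepl(":", cats)]
  if (length(cats) == 0L) {
    abort("fit has no land-use-landscape category coefficients")
  }
  contrasts <- setNames(as.list(cats), sub("^lu_landscape", "", cats))
  link <- switch(fit$spec$response_scale, exp = "log", pow10 = "log10",
                 "identity")
  effect_summary_pct_change(draws, contrasts, link = link,
                            reference = "PV_natural")
}
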