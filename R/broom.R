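#' Tidy a fitted biodiversity model
#'
#' One row per fixed-effect coefficient with its standard error, Wald z
#' statistic and p-value.
#'
#' @param x a `bd_fit`.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.bd_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(abs(z), lower.tail = FALSE))
  )
}

#' Glance at a fitted biodiversity model
#'
#' @param x a `bd_fit`.
#' @param ... unused.
#' @return a one-row tibble: family, number of observations,
#'   log-likelihood, parameter count, random-effect variances and
#'   convergence flag.
#' @export
glance.bd_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    nobs = x$n_obs,
    logLik = x$loglik,
    df = x$df,
    sigma_study = unname(x$re_variances["study"])^0.5,
    sigma_block = unname(x$re_variances["block"])^0.5,
    sigma_site = unname(x$re_variances["site"])^0.5,
    converged = x$converged
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
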