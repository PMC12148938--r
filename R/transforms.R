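#' Skew-correcting transforms
#'
#' Two log transforms are used on the covariates before standardization:
#' right-skewed variables get `log_e(V + offset)` (offset 0.01 where zeros
#' occur), and left-skewed variables get `V_t = log_e(C - V)`, where `C`
#' exceeds every observed value so the argument stays positive. The
#' left-skew transform flips the order of the values (largest becomes
#' smallest), and hence the sign of downstream effects. Both transforms are
#' bijections on their valid domain.
#'
#' @param kind one of `"right_skew_log"`, `"left_skew_log"`, `"none"`.
#' @param offset additive offset for the right-skew transform.
#' @param C left-skew constant; if `NULL` it is fitted from the data with
#'   [make_left_skew_constant()].
#' @param margin margin used when fitting `C`.
#' @return a `transform_spec` list.
#' @export
transform_spec <- function(kind = c("none", "right_skew_log", "left_skew_log"),
                           offset = 0.01, C = NULL, margin = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, offset = offset, C = C, margin = margin),
            class = "transform_spec")
}

#' Left-skew transform constant
#'
#' The constant `C` of the left-skew transform is obtained by adding a
#' small margin to the highest observed value and rounding up to the next
#' integer, guaranteeing `C - V > 0` for every observed `V`. For a variable
#' with maximum 28.5 and margin 1 this gives 30. Where an externally chosen
#' constant is preferred (rounding conventions differ), pass it directly as
#' `C` to [transform_spec()].
#'
#' @param max_value highest observed value.
#' @param margin positive margin added before rounding up.
#' @return integer-valued constant `C`.
#' @export
make_left_skew_constant <- function(max_value, margin = 1) {
  stopifnot(is_scalar_num(max_value), is_scalar_num(margin), margin > 0)
  ceiling(max_value + margin)
}

#' Apply (or invert) a skew transform
#'
#' @param values numeric vector.
#' @param spec a [transform_spec()]. A `NULL` `C` for the left-skew kind is
#'   fitted from `values` and returned in the `"spec"` attribute.
#' @return transformed vector with attribute `"spec"` (the possibly-fitted
#'   spec).
#' @export
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  out <- switch(
    spec$kind,
    none = values,
    right_skew_log = {
      bad <- values + spec$offset <= 0
      if (any(bad, na.rm = TRUE)) {
        abort(sprintf(
          "right-skew log undefined for value %g (offset %g)",
          values[which(bad)[1]], spec$offset))
      }
      log(values + spec$offset)
    },
    left_skew_log = {
      if (is.null(spec$C)) {
        spec$C <- make_left_skew_constant(max(values, na.rm = TRUE),
                                          spec$margin)
      }
      bad <- spec$C - values <= 0
      if (any(bad, na.rm = TRUE)) {
        abort(sprintf("left-skew log undefined: C = %g <= value %g",
                      spec$C, values[which(bad)[1]]))
      }
      log(spec$C - values)
    }
  )
  attr(out, "spec") <- spec
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
         none = values,
         right_skew_log = exp(values) - spec$offset,
         left_skew_log = {
           if (is.null(spec$C)) abort("cannot invert: C not set")
           spec$C - exp(values)
         })
}

# standardization state frozen at fit time; reused verbatim for projections
standardizer <- function(values) {
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s < .Machine$double.eps) s <- 1
  list(mean = m, sd = s)
}

apply_standardizer <- function(values, std) (values - std$mean) / std$sd
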