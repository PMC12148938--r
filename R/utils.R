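#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm rpois rlnorm runif dnorm pnorm pchisq var sd
#'   quantile median setNames coef logLik model.matrix as.formula terms
#' @importFrom utils head
NULL

# deterministic sub-stream seeds: one master seed, one stream per stage name;
# kept below 2^31 - 1 so they remain valid R integers
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% (.Machine$integer.max - 1L))
}

#' Weighted quantile (lower interpolation)
#'
#' Quantile of `x` under sampling weights `w`, defined as the smallest
#' observed value whose cumulative weight reaches `p` of the total weight.
#' This "lower interpolation" rule is pinned so that area-weighted yield
#' percentiles are reproducible.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @param p probability in (0, 1].
#' @return a single numeric value.
#' @examples
#' weighted_quantile(1:100, rep(1, 100), 0.95)
#' @export
weighted_quantile <- function(x, w, p) {
  stopifnot(length(x) == length(w), all(w >= 0), p > 0, p <= 1)
  keep <- !is.na(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) abort("weighted_quantile: no observations with positive weight")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= p * cw[length(cw)])[1L]]
}

# gaussian-kernel smoothing of a matrix, separable, edge-normalized;
# scale 0 returns the input untouched
smooth_field <- function(mat, scale) {
  if (scale <= 0) return(mat)
  r <- max(1L, ceiling(3 * scale))
  k <- dnorm(seq(-r, r), sd = scale)
  k <- k / sum(k)
  sm1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  mat <- apply(mat, 2L, sm1)
  t(apply(mat, 1L, sm1))
}

# smoothed random field mapped monotonically into (0, 1)
rfield01 <- function(n_rows, n_cols, scale) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- smooth_field(z, scale)
  s <- sd(z)
  if (s < .Machine$double.eps) return(matrix(0.5, n_rows, n_cols))
  pnorm((z - mean(z)) / s)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
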