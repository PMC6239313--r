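
# shared input checks -------------------------------------------------------

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, format(min)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_odd_edge <- function(x, name, min = 1L) {
  x <- assert_count(x, name, min = min)
  if (x %% 2L == 0L) {
    abort(sprintf("`%s` must be odd (got %d).", name, x))
  }
  x
}

assert_pixels <- function(pixels, name = "pixels") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 numeric array.", name))
  }
  invisible(pixels)
}

#' Numerically stable softplus
#'
#' The transfer function of the background-model autoencoder,
#' \eqn{\sigma(x) = \log(1 + e^x)}. Evaluated as
#' \eqn{x + \log(1 + e^{-x})} for positive `x` so large inputs neither
#' overflow nor lose precision; strictly positive for all finite inputs.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @examples
#' softplus(0)    # log(2)
#' softplus(100)  # ~100, no overflow
#' @export
softplus <- function(x) {
  out <- ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  if (is.matrix(x) || is.array(x)) {
    dim(out) <- dim(x)
  }
  out
}

# Separable bilinear resampling of a matrix onto an out_h x out_w grid,
# sampling source coordinates at output pixel centres (edge-clamped).
bilinear_resize <- function(m, out_h, out_w) {
  wmat <- function(n_in, n_out) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    interp_weights(s, n_in)
  }
  wy <- wmat(nrow(m), out_h)
  wx <- wmat(ncol(m), out_w)
  wy %*% m %*% t(wx)
}

# Dense 1-D linear interpolation matrix: rows are output positions, columns
# source samples at integer coordinates 0..n_in-1; positions outside the
# sample range replicate the nearest sample.
interp_weights <- function(s, n_in) {
  i0 <- pmin(pmax(floor(s), 0), n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  w <- pmin(pmax(s - i0, 0), 1)
  out <- matrix(0, length(s), n_in)
  out[cbind(seq_along(s), i0 + 1)] <- 1 - w
  out[cbind(seq_along(s), i1 + 1)] <- out[cbind(seq_along(s), i1 + 1)] + w
  out
}

# Sliding-window box sum (all-ones kernel, zero padding outside the image),
# computed exactly with an integral image.
box_sum <- function(m, kernel_edge) {
  h <- (kernel_edge - 1L) %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  integral <- matrix(0, nr + 1L, nc + 1L)
  integral[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  y1 <- pmax(seq_len(nr) - h, 1L)
  y2 <- pmin(seq_len(nr) + h, nr)
  x1 <- pmax(seq_len(nc) - h, 1L)
  x2 <- pmin(seq_len(nc) + h, nc)
  out <- integral[y2 + 1L, x2 + 1L, drop = FALSE] -
    integral[y1, x2 + 1L, drop = FALSE] -
    integral[y2 + 1L, x1, drop = FALSE] +
    integral[y1, x1, drop = FALSE]
  pmax(out, 0)
}
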