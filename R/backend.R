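## Numeric backends for secret shares.
##
## Two encodings of real numbers are supported:
##
##  * `field_backend()` -- fixed-point elements of the prime field Z_p.  A real
##    x is embedded as round(x * 2^frac_bits) mod p, with negatives mapped to
##    the upper half of the field.  The default modulus is the largest prime
##    below 2^53 so every field element is exactly representable in an R
##    double; modular products are computed through 128-bit integer
##    arithmetic in C (see src/modarith.cpp).
##
##  * `real_backend()` -- plain double-precision shares masked with uniform
##    noise of configurable half-width.  This backend exists because the
##    exact-sigmoid path exponentiates shares directly, which has no meaning
##    over a fixed-point ring; its hiding is only as wide as the mask.

#' Prime-field fixed-point backend
#'
#' @param modulus prime modulus; must be below 2^53 so elements are exactly
#'   representable in doubles. Default 9007199254740881 = 2^53 - 111.
#' @param frac_bits number of fractional bits of the fixed-point encoding.
#' @return an object of class `mpc_backend`.
#' @export
field_backend <- function(modulus = 9007199254740881, frac_bits = 20L) {
  stopifnot(modulus > 2, modulus < 2^53, frac_bits >= 0)
  structure(list(mode = "prime_field", modulus = modulus,
                 frac_bits = as.integer(frac_bits),
                 scale = 2^as.integer(frac_bits)),
            class = "mpc_backend")
}

#' Real-number backend with uniform masking
#'
#' @param mask_width half-width of the uniform masking noise added to the
#'   n - 1 random shares. Kept small (default 2): the exact sigmoid path
#'   must exponentiate individual shares, and floating-point noise injected
#'   per secure product grows with the square of the mask width.
#' @return an object of class `mpc_backend`.
#' @export
real_backend <- function(mask_width = 2) {
  stopifnot(mask_width > 0)
  structure(list(mode = "real", mask_width = mask_width),
            class = "mpc_backend")
}

is_field <- function(backend) backend$mode == "prime_field"

#' @export
print.mpc_backend <- function(x, ...) {
  if (is_field(x))
    cat(sprintf("<mpc_backend: prime_field, p = %.0f, frac_bits = %d>\n",
                x$modulus, x$frac_bits))
  else
    cat(sprintf("<mpc_backend: real, mask_width = %g>\n", x$mask_width))
  invisible(x)
}

#' Encode real numbers into the backend representation
#'
#' Fixed-point embedding for the field backend (round to frac_bits fractional
#' bits, negatives in the upper half of the field); identity for the real
#' backend.
#'
#' @param x numeric vector/matrix of reals.
#' @param backend an `mpc_backend`.
#' @return backend elements with the shape of `x`.
#' @export
encode <- function(x, backend) {
  if (!is_field(backend)) return(x)
  p <- backend$modulus
  lim <- p / (2 * backend$scale)
  if (any(abs(x) >= lim))
    stop("encode: value outside representable fixed-point range (|x| < ",
         format(lim), ")")
  v <- round(x * backend$scale) %% p
  .keep_dim(v, x)
}

#' Decode backend elements back to real numbers
#'
#' @param v backend elements.
#' @param backend an `mpc_backend`.
#' @return numeric values with the shape of `v`.
#' @export
decode <- function(v, backend) {
  if (!is_field(backend)) return(v)
  p <- backend$modulus
  centred <- ifelse(v > p / 2, v - p, v)
  .keep_dim(centred / backend$scale, v)
}

.keep_dim <- function(out, template) {
  if (!is.null(dim(template))) dim(out) <- dim(template)
  out
}

## Exact field addition in doubles: x, y in [0, p).  (x - p) + y lies in
## (-p, p) and every intermediate has magnitude < 2^53, so no rounding occurs.
bk_add <- function(x, y, backend) {
  if (!is_field(backend)) return(x + y)
  z <- (x - backend$modulus) + y
  .keep_dim(ifelse(z < 0, z + backend$modulus, z), x)
}

bk_sub <- function(x, y, backend) {
  if (!is_field(backend)) return(x - y)
  z <- x - y
  .keep_dim(ifelse(z < 0, z + backend$modulus, z), x)
}

bk_neg <- function(x, backend) {
  if (!is_field(backend)) return(-x)
  .keep_dim((backend$modulus - x) %% backend$modulus, x)
}

bk_mul <- function(x, y, backend) {
  if (!is_field(backend)) return(x * y)
  .keep_dim(field_mulmod_cpp(as.numeric(x), as.numeric(y), backend$modulus), x)
}

bk_zero <- function(backend) 0

## Sum a list of equal-shape arrays in the backend.
bk_sum <- function(pieces, backend)
  Reduce(function(a, b) bk_add(a, b, backend), pieces)

## Row sums of a matrix in the backend (field addition must stay mod p).
bk_rowsum <- function(mat, backend) {
  if (!is_field(backend)) return(rowSums(mat))
  out <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) out <- bk_add(out, mat[, j], backend)
  out
}
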