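## Secure sigmoid evaluation.
##
## Exact path (real backend only): exp(z) factors as the product of the
## exponentials of the additive shares, exp(z) = prod_i exp(z_i).  Each party
## exponentiates its own share locally, secret-shares that factor, and the
## parties multiply the shared factors with the secure multiplication
## protocol.  1/(1 + exp(-z)) is then obtained with the scalar Newton
## reciprocal iteration (the 1x1 case of the secure matrix inversion).
##
## Approximate path: least-squares polynomials of the sigmoid on [-8, 8],
## evaluated in u = z/8 with an odd-power ladder (u^2 shared once, then
## u^3 = u * u^2, u^5 = u^3 * u^2, u^7 = u^5 * u^2) to minimize secure
## multiplications: 2 for degree 3, 3 for degree 5, 4 for degree 7.

## Least-squares sigmoid coefficients on [-8, 8], by odd power of (x/8).
.sigmoid_ls_coef <- list(
  g3 = c(`0` = 0.5, `1` = 1.20096, `3` = -0.81562),
  g5 = c(`0` = 0.5, `1` = 1.53048, `3` = -2.3533056, `5` = 1.3511295),
  g7 = c(`0` = 0.5, `1` = 1.73496, `3` = -4.19407, `5` = 5.43402, `7` = -2.50739)
)

#' Least-squares sigmoid polynomial, plaintext evaluation
#'
#' @param z numeric input.
#' @param mode `"g3"`, `"g5"` or `"g7"`.
#' @return polynomial approximation of `plogis(z)`.
#' @export
sigmoid_ls <- function(z, mode = c("g3", "g5", "g7")) {
  mode <- match.arg(mode)
  co <- .sigmoid_ls_coef[[mode]]
  u <- z / 8
  out <- 0
  for (k in names(co)) out <- out + co[[k]] * u^as.numeric(k)
  out
}

#' Secure exponentiation of a shared value (real backend)
#'
#' Each party exponentiates its own share locally, secret-shares that factor
#' among all parties, and the factors are combined with n - 1 secure
#' multiplications; the result reconstructs to exp(z).  Meaningless over a
#' prime field, where it is refused.
#'
#' @param z a `shared_matrix` over the real backend.
#' @param session the session.
#' @return a `shared_matrix` reconstructing to exp(z) element-wise.
#' @export
secure_exp <- function(z, session) {
  bk <- z$backend
  if (is_field(bk))
    stop("secure_exp: exponentiation of prime-field shares is undefined; ",
         "use the real backend for the exact sigmoid path")
  n <- session$n_parties
  L <- z$nrow * z$ncol
  z <- .renorm_real(z, session)  # bound share magnitudes before exponentiating
  factors <- vector("list", n)
  for (i in seq_len(n)) {
    f_i <- exp(as.numeric(z$shares[[i]]))
    if (any(!is.finite(f_i)))
      stop("secure_exp: share exponential overflowed; input out of the representable range")
    ## party i secret-shares its local factor with the other parties
    sh <- .split_values(f_i, n, bk, session$party_rng[[i]])
    for (j in seq_len(n)) if (j != i)
      queue_send(session, i, j, sh[[j]], L, "exp_share")
    factors[[i]] <- new_shared_matrix(
      lapply(sh, function(v) matrix(v, z$nrow, z$ncol)),
      z$nrow, z$ncol, bk)
  }
  P <- factors[[1L]]
  for (i in seq_len(n - 1L) + 1L) P <- mult_shared(P, factors[[i]], session)
  P
}

#' Exact secure sigmoid (real backend)
#'
#' Computes shares of 1/(1 + exp(-z)) via secure exponentiation followed by
#' the element-wise scalar Newton reciprocal with a fixed public scaling
#' constant c = (1 + exp(-z_min))/2, valid for all z >= z_min (quadratic
#' convergence makes the residual vanish for any value in (0, 2c)).
#'
#' @param z a `shared_matrix` over the real backend.
#' @param session the session.
#' @param z_min public lower bound of the admissible input domain; fixes the
#'   reciprocal's scaling constant. Default -20.
#' @param recip_steps reciprocal iteration count (default 60; enough for the
#'   default domain at double precision).
#' @return a `shared_matrix` reconstructing to the sigmoid of z.
#' @export
sigmoid_exact <- function(z, session, z_min = -20, recip_steps = 60L) {
  E <- secure_exp(neg_shared(z), session)       # exp(-z)
  t_sh <- add_public(E, 1)                      # 1 + exp(-z) in (1, inf)
  cc <- (1 + exp(-z_min)) / 2
  ## element-wise scalar specialization of the matrix-inversion iteration
  B <- share_public(matrix(1 / cc, z$nrow, z$ncol), session)
  M <- scale_shared(t_sh, 1 / cc, session)
  for (s in seq_len(recip_steps)) {
    BM <- mult_shared(B, M, session)
    MM <- mult_shared(M, M, session)
    B <- .renorm_real(sub_shared(scale_shared(B, 2, session), BM), session)
    M <- .renorm_real(sub_shared(scale_shared(M, 2, session), MM), session)
  }
  B
}

#' Secure least-squares polynomial sigmoid
#'
#' Evaluates the degree 3/5/7 least-squares approximation of the sigmoid on
#' shares, in either backend.
#'
#' @param z a `shared_matrix`.
#' @param session the session.
#' @param mode `"g3"`, `"g5"` or `"g7"`.
#' @param clip if `TRUE`, inputs are clamped to [-8, 8] by the dealer gate
#'   before evaluation (the approximation interval); off by default -- the
#'   polynomials are simply evaluated as printed, and diverge outside the
#'   interval.
#' @return a `shared_matrix` reconstructing to g_d(z).
#' @export
sigmoid_poly <- function(z, session, mode = c("g3", "g5", "g7"), clip = FALSE) {
  mode <- match.arg(mode)
  co <- .sigmoid_ls_coef[[mode]]
  if (isTRUE(clip)) z <- .clip_gate(z, session, -8, 8)
  u <- scale_shared(z, 1 / 8, session)
  u2 <- mult_shared(u, u, session)
  pow <- list(`1` = u)
  if ("3" %in% names(co)) pow[["3"]] <- mult_shared(u2, u, session)
  if ("5" %in% names(co)) pow[["5"]] <- mult_shared(pow[["3"]], u2, session)
  if ("7" %in% names(co)) pow[["7"]] <- mult_shared(pow[["5"]], u2, session)
  acc <- scale_shared(pow[["1"]], co[["1"]], session)
  for (k in setdiff(names(co), c("0", "1")))
    acc <- add_shared(acc, scale_shared(pow[[k]], co[[k]], session))
  add_public(acc, co[["0"]])
}

## Dealer clamp of a shared value to [lo, hi] (idealized; secure comparison
## is outside the protocol suite).
.clip_gate <- function(sm, session, lo, hi) {
  v <- pmin(pmax(as.numeric(reconstruct_matrix(sm)), lo), hi)
  sh <- .fresh_split(encode(v, sm$backend), session)
  new_shared_matrix(lapply(sh, function(x) matrix(x, sm$nrow, sm$ncol)),
                    sm$nrow, sm$ncol, sm$backend)
}

#' Secure sigmoid with the mode chosen by name
#'
#' @param z a `shared_matrix`.
#' @param session the session.
#' @param mode `"exact"`, `"g3"`, `"g5"` or `"g7"`.
#' @param ... passed on to [sigmoid_exact()] or [sigmoid_poly()].
#' @export
secure_sigmoid <- function(z, session, mode = c("exact", "g3", "g5", "g7"), ...) {
  mode <- match.arg(mode)
  if (mode == "exact") sigmoid_exact(z, session, ...)
  else sigmoid_poly(z, session, mode = mode, ...)
}
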