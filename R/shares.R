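## n-out-of-n additive secret sharing.
##
## A secret x is distributed as n fragments that sum to x (in the backend):
## n - 1 fragments are random (uniform over the field, or uniform masking
## noise in the real backend) and the last is x minus their sum.  Any n - 1
## fragments are independent of the secret.
##
## `shared_matrix` is the workhorse container: one value block per
## computation party, element-wise summing (in the backend) to the plaintext.

## Core splitter: plaintext numeric vector -> list of n share vectors.
.split_values <- function(x, n, backend, rng) {
  enc <- encode(x, backend)
  L <- length(enc)
  shares <- vector("list", n)
  if (is_field(backend)) {
    acc <- numeric(L)
    for (i in seq_len(n - 1L)) {
      shares[[i]] <- stream_field_unif(rng, L, backend$modulus)
      acc <- bk_add(acc, shares[[i]], backend)
    }
    shares[[n]] <- bk_sub(as.numeric(enc), acc, backend)
  } else {
    acc <- numeric(L)
    W <- backend$mask_width
    for (i in seq_len(n - 1L)) {
      shares[[i]] <- stream_runif(rng, L, -W, W)
      acc <- acc + shares[[i]]
    }
    shares[[n]] <- as.numeric(enc) - acc
  }
  shares
}

#' Additively secret-share a scalar or vector
#'
#' Splits each element of `x` into `n_parties` additive shares: the first
#' n - 1 are random and the last is the encoded secret minus their sum.
#'
#' @param x numeric secret(s).
#' @param n_parties number of shares (>= 2).
#' @param backend an `mpc_backend`.
#' @param rng an `rng_stream` supplying the share randomness.
#' @return a `share_tuple`: list of per-party numeric vectors with the
#'   backend attached.
#' @export
split_secret <- function(x, n_parties, backend, rng) {
  if (n_parties < 2) stop("split_secret: need at least 2 parties")
  structure(list(shares = .split_values(as.numeric(x), n_parties, backend, rng),
                 backend = backend, n_parties = as.integer(n_parties)),
            class = "share_tuple")
}

#' Reconstruct a secret from a full share tuple
#'
#' @param shares a `share_tuple` (or plain list of equal-length share
#'   vectors when `backend` is given).
#' @param backend backend, required when `shares` is a bare list.
#' @param decode_result decode field elements back to reals (default TRUE).
#' @return numeric secret(s).
#' @export
reconstruct <- function(shares, backend = NULL, decode_result = TRUE) {
  if (inherits(shares, "shared_matrix")) return(reconstruct_matrix(shares, decode_result))
  if (inherits(shares, "share_tuple")) {
    backend <- shares$backend
    shares <- shares$shares
  }
  if (is.null(backend)) stop("reconstruct: backend required")
  L <- unique(vapply(shares, length, 1L))
  if (length(L) != 1L) stop("reconstruct: malformed share tuple (unequal lengths)")
  tot <- bk_sum(shares, backend)
  if (decode_result) decode(tot, backend) else tot
}

## ------------------------------------------------------------------------
## shared_matrix

new_shared_matrix <- function(shares, nrow, ncol, backend) {
  structure(list(shares = shares, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), backend = backend),
            class = "shared_matrix")
}

#' Secret-share a plaintext matrix across the computation parties
#'
#' @param x numeric matrix (or vector, treated as a column).
#' @param session an `mpc_session`.
#' @param rng stream supplying the share randomness; defaults to the first
#'   input party's stream.
#' @return a `shared_matrix`.
#' @export
share_matrix <- function(x, session, rng = session$input_rng[[1L]]) {
  x <- as.matrix(x)
  sh <- .split_values(as.numeric(x), session$n_parties, session$backend, rng)
  sh <- lapply(sh, function(v) matrix(v, nrow(x), ncol(x)))
  new_shared_matrix(sh, nrow(x), ncol(x), session$backend)
}

#' Share a public (non-secret) matrix
#'
#' Party 1 holds the encoded value; all other shares are zero.  Used for
#' public constants such as the initial inverse guess of the iterative
#' matrix inversion.
#'
#' @param x numeric matrix or vector.
#' @param session an `mpc_session`.
#' @return a `shared_matrix`.
#' @export
share_public <- function(x, session) {
  x <- as.matrix(x)
  sh <- vector("list", session$n_parties)
  sh[[1L]] <- matrix(encode(as.numeric(x), session$backend), nrow(x), ncol(x))
  for (i in seq_len(session$n_parties - 1L) + 1L)
    sh[[i]] <- matrix(0, nrow(x), ncol(x))
  new_shared_matrix(sh, nrow(x), ncol(x), session$backend)
}

#' Reconstruct the plaintext of a shared matrix
#'
#' @param sm a `shared_matrix`.
#' @param decode_result decode field elements back to reals.
#' @return numeric matrix.
#' @export
reconstruct_matrix <- function(sm, decode_result = TRUE) {
  tot <- bk_sum(sm$shares, sm$backend)
  out <- if (decode_result) decode(tot, sm$backend) else tot
  matrix(out, sm$nrow, sm$ncol)
}

#' @export
print.shared_matrix <- function(x, ...) {
  cat(sprintf("<shared_matrix %d x %d over %d parties (%s backend)>\n",
              x$nrow, x$ncol, length(x$shares), x$backend$mode))
  invisible(x)
}

#' @export
dim.shared_matrix <- function(x) c(x$nrow, x$ncol)

#' One party's share block
#' @param sm a `shared_matrix`.
#' @param party party index.
#' @export
get_share <- function(sm, party) sm$shares[[party]]

.check_same <- function(a, b) {
  if (!identical(c(a$nrow, a$ncol), c(b$nrow, b$ncol)))
    stop("shared_matrix: shape mismatch")
  if (!identical(a$backend$mode, b$backend$mode))
    stop("shared_matrix: backend mismatch")
}

#' Local addition of shared matrices (zero communication)
#'
#' @param a,b `shared_matrix` values of identical shape and backend.
#' @return a `shared_matrix` reconstructing to the element-wise sum.
#' @export
add_shared <- function(a, b) {
  .check_same(a, b)
  sh <- Map(function(x, y) bk_add(x, y, a$backend), a$shares, b$shares)
  new_shared_matrix(sh, a$nrow, a$ncol, a$backend)
}

#' Local subtraction of shared matrices (zero communication)
#' @param a,b `shared_matrix` values of identical shape and backend.
#' @export
sub_shared <- function(a, b) {
  .check_same(a, b)
  sh <- Map(function(x, y) bk_sub(x, y, a$backend), a$shares, b$shares)
  new_shared_matrix(sh, a$nrow, a$ncol, a$backend)
}

#' Local negation of a shared matrix
#' @param a a `shared_matrix`.
#' @export
neg_shared <- function(a) {
  sh <- lapply(a$shares, function(x) bk_neg(x, a$backend))
  new_shared_matrix(sh, a$nrow, a$ncol, a$backend)
}

#' Multiply a shared matrix by a public scalar (local)
#'
#' Integer scalars multiply shares directly (no rescaling needed); general
#' reals multiply by the fixed-point encoding followed by truncation in the
#' field backend.
#'
#' @param a a `shared_matrix`.
#' @param k public numeric scalar.
#' @param session session (needed for field truncation randomness).
#' @export
scale_shared <- function(a, k, session = NULL) {
  bk <- a$backend
  if (!is_field(bk)) {
    sh <- lapply(a$shares, function(x) x * k)
    return(new_shared_matrix(sh, a$nrow, a$ncol, bk))
  }
  if (k == round(k)) {
    ke <- k %% bk$modulus
    sh <- lapply(a$shares, function(x) bk_mul(x, ke, bk))
    return(new_shared_matrix(sh, a$nrow, a$ncol, bk))
  }
  if (is.null(session)) stop("scale_shared: session required for non-integer field scaling")
  ke <- encode(k, bk)
  sh <- lapply(a$shares, function(x) bk_mul(x, ke, bk))
  trunc_gate(new_shared_matrix(sh, a$nrow, a$ncol, bk), session)
}

#' Add a public constant to a shared matrix (local; party 1 only)
#' @param a a `shared_matrix`.
#' @param k public numeric scalar or conformable matrix.
#' @export
add_public <- function(a, k) {
  sh <- a$shares
  sh[[1L]] <- bk_add(sh[[1L]], encode(matrix(k, a$nrow, a$ncol), a$backend), a$backend)
  new_shared_matrix(sh, a$nrow, a$ncol, a$backend)
}

#' Transpose a shared matrix (local)
#' @param a a `shared_matrix`.
#' @export
t_shared <- function(a)
  new_shared_matrix(lapply(a$shares, t), a$ncol, a$nrow, a$backend)

## ------------------------------------------------------------------------
## Ideal dealer gates.
##
## Two maintenance operations are performed by the simulation's dealer role
## rather than by an interactive sub-protocol: (i) fixed-point truncation
## after a field multiplication (exact division by 2^frac_bits with
## probabilistic rounding, then a fresh re-share), and (ii) fresh re-sharing
## in the real backend, which keeps share magnitudes within the mask width --
## a requirement of the share-exponentiation trick.  Neither gate sends
## protocol messages, so per-multiplication ledger constants are unaffected.

.fresh_split <- function(values_encoded, session) {
  n <- session$n_parties
  bk <- session$backend
  L <- length(values_encoded)
  shares <- vector("list", n)
  if (is_field(bk)) {
    acc <- numeric(L)
    for (i in seq_len(n - 1L)) {
      shares[[i]] <- stream_field_unif(session$dealer_rng, L, bk$modulus)
      acc <- bk_add(acc, shares[[i]], bk)
    }
    shares[[n]] <- bk_sub(values_encoded, acc, bk)
  } else {
    acc <- numeric(L)
    W <- bk$mask_width
    for (i in seq_len(n - 1L)) {
      shares[[i]] <- stream_runif(session$dealer_rng, L, -W, W)
      acc <- acc + shares[[i]]
    }
    shares[[n]] <- values_encoded - acc
  }
  shares
}

#' Fixed-point truncation gate (field backend)
#'
#' Divides a shared value whose encoding carries 2 * frac_bits fractional
#' bits (the result of a fixed-point product) by 2^frac_bits with
#' probabilistic rounding, and re-shares it freshly.  Idealized: performed by
#' the dealer role, zero ledger cost.
#'
#' @param sm a `shared_matrix` at double scale.
#' @param session the session.
#' @return a `shared_matrix` at single scale.
#' @keywords internal
trunc_gate <- function(sm, session) {
  bk <- sm$backend
  if (!is_field(bk)) return(sm)
  p <- bk$modulus
  tot <- bk_sum(sm$shares, bk)
  centred <- ifelse(tot > p / 2, tot - p, tot)
  q <- centred / bk$scale
  fl <- floor(q)
  frac <- q - fl
  up <- stream_runif(session$dealer_rng, length(q)) < frac
  v <- (fl + as.numeric(up)) %% p
  sh <- .fresh_split(v, session)
  sh <- lapply(sh, function(x) matrix(x, sm$nrow, sm$ncol))
  new_shared_matrix(sh, sm$nrow, sm$ncol, bk)
}

#' Open a shared value to all parties
#'
#' Every party broadcasts its share to every other party; the plaintext
#' becomes public.  Costs n * (n - 1) messages per element.
#'
#' @param sm a `shared_matrix`.
#' @param session the session.
#' @param label ledger label.
#' @return the decoded plaintext matrix.
#' @export
open_shared <- function(sm, session, label = "open") {
  n <- session$n_parties
  L <- sm$nrow * sm$ncol
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    queue_send(session, i, j, sm$shares[[i]], L, label)
  reconstruct_matrix(sm)
}
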