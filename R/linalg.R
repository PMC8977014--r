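## Secure linear algebra on shared matrices.
##
## Matrix products use the naive cubic schedule -- rows * cols * inner secure
## scalar multiplications -- so the communication ledger is a predictable
## multiple of the per-multiplication protocol constant.  Matrix inversion is
## the Newton-Raphson iteration
##
##     B_{s+1} = 2 B_s - B_s M_s,   B_0 = c^{-1} I
##     M_{s+1} = 2 M_s - M_s^2,     M_0 = c^{-1} X
##
## which converges quadratically to B = X^{-1} for symmetric positive
## definite X whenever the spectral radius of (I - c^{-1} X) is below 1;
## c = trace(X) guarantees this (trace >= lambda_max for SPD X).

#' Secure matrix product of two shared matrices
#'
#' Naive schedule: every scalar product A[i,l] * B[l,j] is one secure
#' multiplication, so the ledger grows by rows * cols * inner times the
#' per-multiplication protocol cost.
#'
#' @param A,B `shared_matrix` values with conforming inner dimensions.
#' @param session the session.
#' @param triples optional pre-dealt triples (dishonest-majority setting).
#' @return a `shared_matrix` of the product.
#' @export
matmul_shared <- function(A, B, session, triples = NULL) {
  if (A$ncol != B$nrow) stop("matmul_shared: inner dimensions do not agree")
  if (!identical(A$backend$mode, B$backend$mode))
    stop("matmul_shared: backend mismatch")
  r <- A$nrow; k <- A$ncol; cc <- B$ncol
  bk <- A$backend
  out <- replicate(session$n_parties, matrix(0, r, cc), simplify = FALSE)
  ## vectorized over one output column at a time: all r * k element products
  ## of that column go through the protocol as one batch
  Aflat <- new_shared_matrix(lapply(A$shares, function(s) matrix(as.numeric(s), r * k, 1L)),
                             r * k, 1L, bk)
  for (j in seq_len(cc)) {
    Bcol <- new_shared_matrix(lapply(B$shares, function(s) matrix(rep(s[, j], each = r), r * k, 1L)),
                              r * k, 1L, bk)
    w <- mult_shared(Aflat, Bcol, session, triples)
    for (pp in seq_along(out))
      out[[pp]][, j] <- bk_rowsum(matrix(as.numeric(w$shares[[pp]]), r, k), bk)
  }
  new_shared_matrix(out, r, cc, bk)
}

#' State of the iterative (Newton-Raphson) matrix inversion
#'
#' @param X a square SPD `shared_matrix` to invert.
#' @param c public positive scaling constant; `B_0 = c^-1 I`, `M_0 = c^-1 X`.
#' @param session the session.
#' @return a `nardi_state` with components `B`, `M`, `s`, `c`.
#' @export
nardi_init <- function(X, c, session) {
  if (X$nrow != X$ncol) stop("nardi_init: matrix must be square")
  stopifnot(c > 0)
  structure(list(B = share_public(diag(1 / c, X$nrow), session),
                 M = scale_shared(X, 1 / c, session),
                 s = 0L, c = c),
            class = "nardi_state")
}

#' One step of the iterative matrix inversion
#'
#' Updates `B <- 2B - BM` and `M <- 2M - M^2` with two secure matrix
#' products.
#'
#' @param state a `nardi_state`.
#' @param session the session.
#' @return the advanced `nardi_state`.
#' @export
nardi_step <- function(state, session) {
  B <- state$B; M <- state$M
  BM <- matmul_shared(B, M, session)
  MM <- matmul_shared(M, M, session)
  state$B <- .renorm_real(sub_shared(scale_shared(B, 2, session), BM), session)
  state$M <- .renorm_real(sub_shared(scale_shared(M, 2, session), MM), session)
  state$s <- state$s + 1L
  state
}

#' Reveal the trace of a shared square matrix as a public scalar
#'
#' Each party sums its diagonal locally; the scalar sharing is then opened
#' to all parties.  A deliberate, documented leakage used to pick the
#' inversion scaling constant.
#'
#' @param X a square `shared_matrix`.
#' @param session the session.
#' @return the trace as a public number.
#' @export
reveal_trace <- function(X, session) {
  bk <- X$backend
  tr_sh <- lapply(X$shares, function(s) {
    acc <- bk_zero(bk)
    for (i in seq_len(min(X$nrow, X$ncol))) acc <- bk_add(acc, s[i, i], bk)
    matrix(acc, 1L, 1L)
  })
  tr <- new_shared_matrix(tr_sh, 1L, 1L, bk)
  drop(open_shared(tr, session, label = "open_trace"))
}

#' Invert a shared SPD matrix by Newton-Raphson iteration
#'
#' @param X a `shared_matrix` reconstructing to a symmetric positive
#'   definite matrix.
#' @param session the session.
#' @param n_steps number of iterations (default 30; quadratic convergence
#'   makes this ample for condition numbers up to ~1e4 in double precision).
#' @param c public scaling constant; by default the trace of X, revealed
#'   through the protocol.
#' @param debug_check if `TRUE`, reconstruct intermediate residuals and stop
#'   on divergence (plaintext debugging aid; leaks, never used in protocol
#'   runs).
#' @return a `shared_matrix` approximating X^-1.
#' @export
invert_shared <- function(X, session, n_steps = 30L, c = NULL,
                          debug_check = FALSE) {
  if (is.null(c)) c <- reveal_trace(X, session)
  if (!is.finite(c) || c <= 0)
    stop("invert_shared: scaling constant must be positive (is X SPD?)")
  st <- nardi_init(X, c, session)
  resid_prev <- Inf
  for (s in seq_len(n_steps)) {
    st <- nardi_step(st, session)
    if (debug_check) {
      Mnow <- reconstruct_matrix(st$M)
      resid <- max(abs(Mnow - diag(nrow(Mnow))))
      if (resid > resid_prev * 1.5 && resid > 1)
        stop("invert_shared: divergence at step ", s,
             " (bad conditioning or bad scaling constant c)")
      resid_prev <- resid
    }
  }
  st$B
}
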