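## Newton-Raphson logistic regression training, secure and plaintext.
##
## Model: P(y = 1 | x) = sigmoid(beta' x).  Updates follow
##
##     beta_new = beta_old - H^{-1} grad,   grad = X'(y - pi)
##
## with the fixed-Hessian approximation H ~ Htilde = -X'X / 4 (the Bohning
## bound on -X'WX, since W = diag(pi(1-pi)) <= I/4), so the inverse is
## computed once, before the iteration loop, by the secure Newton-Raphson
## matrix inversion.  No convergence test is performed: the loop runs for
## exactly n_iter iterations so that nothing about the data leaks through
## an adaptive stopping time.

#' Training configuration
#'
#' @param setting `"honest3"` or `"dishonest2"`.
#' @param algorithm `"accurate"` (exact secure sigmoid) or `"approx"`
#'   (least-squares polynomial sigmoid).
#' @param sigmoid sigmoid mode; must be `"exact"` for the accurate
#'   algorithm and one of `"g3"`, `"g5"`, `"g7"` for the approximate one.
#' @param n_iter fixed number of Newton iterations (default 10).
#' @param nardi_steps iterations of the secure matrix inversion (default 30).
#' @param seed top-level seed for all party streams.
#' @param backend an `mpc_backend`; default [real_backend()] for the accurate
#'   algorithm (whose exponentiation trick needs real shares) and
#'   [field_backend()] for the approximate one.
#' @param add_intercept prepend an all-ones column (default TRUE).
#' @param z_min,recip_steps exact-sigmoid reciprocal parameters, see
#'   [sigmoid_exact()].
#' @return a `train_config`.
#' @export
train_config <- function(setting = c("honest3", "dishonest2"),
                         algorithm = c("accurate", "approx"),
                         sigmoid = NULL,
                         n_iter = 10L,
                         nardi_steps = 30L,
                         seed = 1L,
                         backend = NULL,
                         add_intercept = TRUE,
                         z_min = -20,
                         recip_steps = 60L) {
  setting <- match.arg(setting)
  algorithm <- match.arg(algorithm)
  if (is.null(sigmoid)) sigmoid <- if (algorithm == "accurate") "exact" else "g3"
  sigmoid <- match.arg(sigmoid, c("exact", "g3", "g5", "g7"))
  if (algorithm == "accurate" && sigmoid != "exact")
    stop("train_config: the accurate algorithm uses the exact sigmoid")
  if (algorithm == "approx" && sigmoid == "exact")
    stop("train_config: the approximate algorithm needs a polynomial sigmoid (g3/g5/g7)")
  if (is.null(backend))
    backend <- if (algorithm == "accurate") real_backend() else field_backend()
  if (algorithm == "accurate" && is_field(backend))
    stop("train_config: the exact sigmoid path requires the real backend")
  stopifnot(n_iter >= 1, nardi_steps >= 1)
  structure(list(setting = setting, algorithm = algorithm, sigmoid = sigmoid,
                 n_iter = as.integer(n_iter), nardi_steps = as.integer(nardi_steps),
                 seed = as.integer(seed), backend = backend,
                 add_intercept = isTRUE(add_intercept),
                 z_min = z_min, recip_steps = as.integer(recip_steps)),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config: %s / %s (sigmoid %s), n_iter = %d, backend %s>\n",
              x$setting, x$algorithm, x$sigmoid, x$n_iter, x$backend$mode))
  invisible(x)
}

#' Secure gradient of the logistic log-likelihood
#'
#' Shares of X'(y - pi(X beta)) with the configured sigmoid path.
#'
#' @param X shared n x m design matrix.
#' @param y shared n x 1 label vector.
#' @param beta shared m x 1 coefficient vector.
#' @param session the session.
#' @param sigmoid sigmoid mode.
#' @param ... further arguments to the sigmoid.
#' @return a shared m x 1 gradient.
#' @export
gradient_shared <- function(X, y, beta, session, sigmoid = "exact", ...) {
  if (X$ncol != beta$nrow || X$nrow != y$nrow || y$ncol != 1L || beta$ncol != 1L)
    stop("gradient_shared: dimension mismatch")
  z <- matmul_shared(X, beta, session)
  pi_sh <- secure_sigmoid(z, session, mode = sigmoid, ...)
  matmul_shared(t_shared(X), sub_shared(y, pi_sh), session)
}

#' Secure inverse of the fixed Hessian
#'
#' Computes shares of (-X'X / 4)^{-1} once, via one secure matrix product
#' and the iterative inversion of the SPD matrix X'X / 4 (scaling constant:
#' its trace, revealed).  Reused across all Newton iterations.
#'
#' @param X shared n x m design matrix (full column rank).
#' @param session the session.
#' @param nardi_steps inversion iteration count.
#' @return a shared m x m matrix reconstructing to -4 (X'X)^{-1}.
#' @export
fixed_hessian_inverse <- function(X, session, nardi_steps = 30L) {
  XtX <- matmul_shared(t_shared(X), X, session)
  Q <- scale_shared(XtX, 0.25, session)          # +X'X/4, SPD
  neg_shared(invert_shared(Q, session, n_steps = nardi_steps))
}

#' One Newton coefficient update
#'
#' `beta_new = beta_old - Hinv %*% grad`, one shared matrix-vector product
#' plus a local subtraction.
#'
#' @param beta shared m x 1 coefficients.
#' @param Hinv shared m x m (fixed) Hessian inverse.
#' @param grad shared m x 1 gradient.
#' @param session the session.
#' @return the updated shared coefficients.
#' @export
newton_update <- function(beta, Hinv, grad, session) {
  sub_shared(beta, matmul_shared(Hinv, grad, session))
}

#' Train a logistic regression model under MPC
#'
#' Runs the full secure training loop on shared data: the fixed-Hessian
#' inverse is computed once, then exactly `n_iter` Newton updates are applied
#' (no convergence check), and the coefficient shares are revealed to the
#' result party.
#'
#' @param data a list with shared matrices `X` (n x m) and `y` (n x 1), as
#'   produced by [distribute_inputs()].
#' @param config a [train_config()].
#' @param session the session the data were shared under; created from the
#'   config if omitted (only possible when `data` is plaintext, see
#'   [mpc_logreg()] for the end-to-end pipeline).
#' @return an `mpc_model` with elements `beta` (revealed numeric vector),
#'   `n_iter_used`, `ledger` (snapshot) and `config`.
#' @export
train <- function(data, config, session) {
  stopifnot(inherits(config, "train_config"),
            inherits(data$X, "shared_matrix"), inherits(data$y, "shared_matrix"))
  X <- data$X; y <- data$y
  m <- X$ncol
  Hinv <- fixed_hessian_inverse(X, session, nardi_steps = config$nardi_steps)
  beta <- share_public(matrix(0, m, 1L), session)
  sig_args <- if (config$sigmoid == "exact")
    list(z_min = config$z_min, recip_steps = config$recip_steps) else list()
  for (it in seq_len(config$n_iter)) {
    grad <- do.call(gradient_shared,
                    c(list(X, y, beta, session, sigmoid = config$sigmoid), sig_args))
    beta <- .renorm_real(newton_update(beta, Hinv, grad, session), session)
    bad <- vapply(beta$shares, function(s) any(!is.finite(s)), logical(1))
    if (any(bad))
      stop("train: non-finite coefficient shares at iteration ", it)
  }
  reveal_result(beta, session, config = config)
}

#' Plaintext reference trainer (no MPC)
#'
#' The same formulas without secret sharing: the oracle every secure run is
#' verified against.  `variant = "full_newton"` recomputes the exact Hessian
#' -X'WX each iteration; `variant = "fixed_hessian"` uses the constant
#' -X'X/4 bound, matching the secure protocols.
#'
#' @param X plaintext n x m design matrix (intercept column included by the
#'   caller if wanted).
#' @param y plaintext 0/1 labels.
#' @param variant `"full_newton"` or `"fixed_hessian"`.
#' @param n_iter number of iterations (0 returns the initial coefficients).
#' @param sigmoid `"exact"` for the true sigmoid or a polynomial mode, so
#'   the oracle can mirror the approximate secure algorithm formula-for-formula.
#' @return an `mpc_model` (with an empty ledger).
#' @export
train_plaintext <- function(X, y, variant = c("fixed_hessian", "full_newton"),
                            n_iter = 10L, sigmoid = "exact") {
  variant <- match.arg(variant)
  X <- as.matrix(X); y <- as.numeric(y)
  m <- ncol(X)
  beta <- rep(0, m)
  sig <- if (sigmoid == "exact") function(z) stats::plogis(z)
         else function(z) sigmoid_ls(z, sigmoid)
  Hinv_fixed <- if (variant == "fixed_hessian") -4 * solve(crossprod(X)) else NULL
  for (it in seq_len(n_iter)) {
    p <- sig(drop(X %*% beta))
    g <- drop(crossprod(X, y - p))
    Hinv <- if (variant == "fixed_hessian") Hinv_fixed
            else { W <- p * (1 - p); -solve(crossprod(X, X * W)) }
    beta <- beta - drop(Hinv %*% g)
    if (any(!is.finite(beta)))
      stop("train_plaintext: divergence (separation?) at iteration ", it)
  }
  structure(list(beta = beta, n_iter_used = as.integer(n_iter),
                 ledger = NULL, config = list(variant = variant, sigmoid = sigmoid)),
            class = "mpc_model")
}

#' @export
print.mpc_model <- function(x, ...) {
  cat(sprintf("<mpc_model: %d coefficients, %d iterations>\n",
              length(x$beta), x$n_iter_used))
  print(round(x$beta, 5))
  invisible(x)
}

#' Coefficients of a trained model
#' @param object an `mpc_model`.
#' @param ... ignored.
#' @export
coef.mpc_model <- function(object, ...) object$beta
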