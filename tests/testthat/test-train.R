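test_that("the secure gradient matches the plaintext gradient", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  y <- rbinom(20, 1, 0.5)
  beta <- c(0.3, -0.2, 0.1)
  s <- mpc_session("honest3", real_backend(), seed = 1)
  g <- drop(reconstruct_matrix(gradient_shared(
    share_matrix(X, s), share_matrix(matrix(y), s),
    share_matrix(matrix(beta), s), s, sigmoid = "exact")))
  expect_lt(max(abs(g - drop(crossprod(X, y - plogis(drop(X %*% beta)))))), 1e-5)
})

test_that("a residual of zero yields a zero gradient", {
  # beta = 0 gives pi = 0.5 everywhere; 'labels' of 0.5 annihilate the residual
  s <- mpc_session("honest3", real_backend(), seed = 2)
  X <- matrix(rnorm(30), 10, 3)
  g <- drop(reconstruct_matrix(gradient_shared(
    share_matrix(X, s), share_matrix(matrix(rep(0.5, 10)), s),
    share_matrix(matrix(0, 3, 1), s), s, sigmoid = "exact")))
  expect_lt(max(abs(g)), 1e-7)
})

test_that("the fixed-Hessian inverse has its closed forms and matches the oracle", {
  s <- mpc_session("honest3", real_backend(), seed = 3)
  # X = 2I: (-X'X/4)^-1 = -I
  H <- reconstruct_matrix(fixed_hessian_inverse(share_matrix(2 * diag(3), s), s))
  expect_equal(H, -diag(3), tolerance = 1e-6)
  # orthonormal columns: X'X = I so the inverse is -4I
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  H2 <- reconstruct_matrix(fixed_hessian_inverse(share_matrix(Q, s), s))
  expect_equal(H2, -4 * diag(3), tolerance = 1e-6)
  # random design against the direct-inverse oracle
  X <- matrix(rnorm(200), 50, 4)
  H3 <- reconstruct_matrix(fixed_hessian_inverse(share_matrix(X, s), s))
  expect_lt(max(abs(H3 - (-4 * solve(crossprod(X))))), 1e-5)
})

test_that("the Newton update is correct and fixed at stationary points", {
  s <- mpc_session("honest3", real_backend(), seed = 4)
  beta <- share_matrix(matrix(c(1, -1)), s)
  Hinv <- share_matrix(-diag(2), s)
  zero <- share_matrix(matrix(0, 2, 1), s)
  expect_equal(drop(reconstruct_matrix(newton_update(beta, Hinv, zero, s))),
               c(1, -1), tolerance = 1e-9)
  # scalar hand computation: beta - Hinv*grad = 0.5 - (-2)*0.25 = 1
  up <- newton_update(share_matrix(0.5, s), share_matrix(-2, s),
                      share_matrix(0.25, s), s)
  expect_equal(drop(reconstruct_matrix(up)), 1, tolerance = 1e-9)
})

test_that("the plaintext trainer agrees with an off-the-shelf logistic fit", {
  d <- make_logit_data(400, c(0.8, -0.6), intercept = 0.3, seed = 5)
  Xd <- cbind(1, d$X)
  fit <- train_plaintext(Xd, d$y, "full_newton", n_iter = 25)
  ref <- suppressWarnings(glm.fit(Xd, d$y, family = binomial()))
  expect_lt(max(abs(coef(fit) - ref$coefficients)), 1e-3)
  # fixed-Hessian variant reaches the same optimum, more slowly
  fixed <- train_plaintext(Xd, d$y, "fixed_hessian", n_iter = 200)
  expect_lt(max(abs(coef(fixed) - coef(fit))), 1e-4)
  # zero iterations return the zero initialization
  expect_identical(coef(train_plaintext(Xd, d$y, n_iter = 0)), rep(0, 3))
})

test_that("secure training equals same-formula plaintext training in every combination", {
  d <- make_logit_data(120, c(1, -0.5, 0.25), seed = 6)
  Xd <- cbind(1, d$X)
  for (setting in c("honest3", "dishonest2")) for (alg in c("accurate", "approx")) {
    sig <- if (alg == "accurate") "exact" else "g3"
    cfg <- train_config(setting, alg, sigmoid = sig, backend = real_backend(),
                        n_iter = 5, seed = 21)
    fit <- mpc_logreg(d$parts, cfg)
    ref <- train_plaintext(Xd, d$y, "fixed_hessian", n_iter = 5, sigmoid = sig)
    expect_lt(max(abs(coef(fit) - coef(ref))), 1e-4)
  }
})

test_that("fixed-point training tracks the plaintext run at field tolerance", {
  d <- make_logit_data(120, c(1, -0.5, 0.25), seed = 7)
  Xd <- cbind(1, d$X)
  for (setting in c("honest3", "dishonest2")) for (sig in c("g3", "g7")) {
    cfg <- train_config(setting, "approx", sigmoid = sig,
                        backend = field_backend(), n_iter = 5, seed = 22)
    fit <- mpc_logreg(d$parts, cfg)
    ref <- train_plaintext(Xd, d$y, "fixed_hessian", n_iter = 5, sigmoid = sig)
    expect_lt(max(abs(coef(fit) - coef(ref))), 1e-2)
  }
})

test_that("the two security settings produce the same coefficients", {
  d <- make_logit_data(120, c(0.7, -0.4), seed = 8)
  fits <- lapply(c("honest3", "dishonest2"), function(setting)
    coef(mpc_logreg(d$parts, train_config(setting, "accurate", n_iter = 5, seed = 30))))
  expect_equal(fits[[1]], fits[[2]], tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  d <- make_logit_data(80, c(0.5, 0.5), seed = 9)
  cfg <- train_config("honest3", "accurate", n_iter = 3, seed = 17)
  f1 <- mpc_logreg(d$parts, cfg)
  f2 <- mpc_logreg(d$parts, cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$ledger$messages, f2$ledger$messages)
})

test_that("invalid algorithm/sigmoid combinations are rejected", {
  expect_error(train_config(algorithm = "accurate", sigmoid = "g3"), "exact")
  expect_error(train_config(algorithm = "approx", sigmoid = "exact"), "polynomial")
  expect_error(train_config(algorithm = "accurate", backend = field_backend()),
               "real backend")
})
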