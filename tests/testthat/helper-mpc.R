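# Shared fixtures: everything is generated in code at test time.

# Random symmetric positive definite matrix with eigenvalues in [lo, hi].
rand_spd <- function(m, lo = 0.5, hi = 5) {
  Q <- qr.Q(qr(matrix(rnorm(m * m), m)))
  Q %*% diag(runif(m, lo, hi), m) %*% t(Q)
}

# Centered representative of v mod p (the value decode() returns at frac_bits = 0).
centered_mod <- function(v, p) {
  r <- v %% p
  ifelse(r > p / 2, r - p, r)
}

# Small synthetic logistic dataset as a single plaintext block.
make_logit_data <- function(n, beta, intercept = 0, seed = 1) {
  spec <- synthetic_spec(n, length(beta), beta, intercept = intercept, seed = seed)
  dat <- generate_synthetic(spec)
  df <- do.call(rbind, dat$parts)
  X <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  list(parts = dat$parts, X = X, y = df$y, truth = dat$truth)
}

expect_ledger_delta <- function(session, expr, messages) {
  before <- ledger_messages(session$ledger)
  force(expr)
  expect_equal(ledger_messages(session$ledger) - before, messages)
}
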