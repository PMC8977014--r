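test_that("synthetic generation respects the partition and records the truth", {
  spec <- synthetic_spec(2000, 3, c(0.5, -0.5, 0), partition = c(700, 700, 600),
                         seed = 1)
  dir <- withr::local_tempdir()
  dat <- generate_synthetic(spec, dir = dir)
  expect_length(dat$parts, 3)
  expect_identical(sapply(dat$parts, nrow), c(700L, 700L, 600L))
  hdr <- lapply(dat$parts, names)
  expect_true(all(sapply(hdr, identical, hdr[[1]])))
  expect_identical(dat$truth$true_beta, c(0.5, -0.5, 0))
  expect_true(file.exists(file.path(dir, "party_2.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$true_beta), c(0.5, -0.5, 0))
  # written CSVs reload to the in-memory partitions
  back <- utils::read.csv(file.path(dir, "party_3.csv"))
  expect_equal(back$y, dat$parts[[3]]$y)
})

test_that("a null model yields balanced labels and a strong signal is recoverable", {
  dat0 <- generate_synthetic(synthetic_spec(4000, 2, c(0, 0), seed = 2))
  prev <- mean(do.call(rbind, dat0$parts)$y)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 4000))
  # single strong coefficient: plaintext refit recovers it within 3 SE
  dat <- generate_synthetic(synthetic_spec(2000, 1, 2, seed = 3))
  df <- do.call(rbind, dat$parts)
  fit <- suppressWarnings(glm(y ~ x1, binomial, data = df))
  se <- sqrt(diag(vcov(fit)))["x1"]
  expect_lt(abs(coef(fit)[["x1"]] - 2), 3 * se)
})

test_that("degenerate label draws are caught", {
  spec <- synthetic_spec(50, 1, 0, intercept = -40, seed = 4, strict = TRUE)
  expect_error(generate_synthetic(spec), "degenerate")
})

test_that("distributed inputs reconstruct to the concatenated plaintext", {
  d <- make_logit_data(90, c(1, -1), seed = 5)
  spec <- synthetic_spec(90, 2, c(1, -1), partition = c(40, 30, 20), seed = 5)
  dat <- generate_synthetic(spec)
  s <- mpc_session("honest3", real_backend(), seed = 5, n_input_parties = 3)
  shared <- distribute_inputs(dat$parts, s, add_intercept = TRUE)
  df <- do.call(rbind, dat$parts)
  expect_equal(reconstruct_matrix(shared$X),
               unname(cbind(1, as.matrix(df[, c("x1", "x2")]))), tolerance = 1e-9)
  expect_equal(drop(reconstruct_matrix(shared$y)), df$y, tolerance = 1e-9)
  expect_identical(dim(get_share(shared$X, 2)), c(90L, 3L))
  # schema mismatch across input parties is refused
  bad <- dat$parts
  names(bad[[2]])[1] <- "z1"
  expect_error(distribute_inputs(bad, s), "schema")
})

test_that("input-party order changes row order but not the fitted model", {
  spec <- synthetic_spec(120, 2, c(0.8, -0.3), partition = c(60, 60), seed = 6)
  dat <- generate_synthetic(spec)
  cfg <- train_config("honest3", "approx", sigmoid = "g5",
                      backend = real_backend(), n_iter = 5, seed = 13)
  f1 <- coef(mpc_logreg(dat$parts, cfg))
  f2 <- coef(mpc_logreg(rev(dat$parts), cfg))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("result revelation sums the coefficient shares and is share-sensitive", {
  s <- mpc_session("honest3", real_backend(), seed = 7)
  beta <- share_matrix(matrix(c(0.25, -1.5, 3)), s)
  expect_ledger_delta(s, model <- reveal_result(beta, s), messages = 3 * 3)
  expect_equal(model$beta, c(0.25, -1.5, 3), tolerance = 1e-12)
  # tampering with a single party's share shifts the revealed result
  beta$shares[[2]][1, 1] <- beta$shares[[2]][1, 1] + 1
  expect_equal(reveal_result(beta, s)$beta[1], 1.25, tolerance = 1e-12)
})

test_that("the analytic communication report reproduces the protocol totals", {
  rep3 <- comm_report("honest3", n_iter = 10, mults_per_iter = 100)
  expect_equal(rep3$analytic$total_kb, 420)
  expect_equal(rep3$analytic$bits_per_mult, 420)
  rep2 <- comm_report("dishonest2", n_iter = 10, mults_per_iter = 100)
  expect_equal(rep2$analytic$total_kb, 125)
  expect_equal(rep2$analytic$bits_per_mult, 128)
  expect_equal(rep3$analytic$message_ratio, 3.75)
})

test_that("measured ledger figures flow into the report and serialize", {
  s <- mpc_session("honest3", real_backend(), seed = 8)
  invisible(mult_honest3(share_matrix(1, s), share_matrix(2, s), s))
  rep <- comm_report("honest3", ledger = s$ledger)
  expect_equal(rep$measured$messages, 15)
  expect_equal(rep$measured$bits, 480)
  lines <- report_lines(rep)
  expect_true(any(grepl("measured.messages = 15", lines)))
})

test_that("no party's view contains a reconstructed input secret", {
  spec <- synthetic_spec(40, 2, c(1, -1), seed = 9)
  dat <- generate_synthetic(spec)
  cfg <- train_config("honest3", "approx", sigmoid = "g3",
                      backend = real_backend(), n_iter = 2, seed = 19)
  fit <- mpc_logreg(dat$parts, cfg, record_views = TRUE)
  secrets <- c(as.matrix(dat$parts[[1]][, c("x1", "x2")]))
  for (p in 1:3) {
    seen <- unlist(lapply(party_view(fit$session, p), `[[`, "values"))
    expect_false(any(seen %in% secrets))
  }
})

test_that("the end-to-end pipeline is reproducible and writes its outputs", {
  spec <- synthetic_spec(60, 2, c(0.6, -0.6), seed = 10)
  dat <- generate_synthetic(spec)
  cfg <- train_config("dishonest2", "approx", sigmoid = "g5", n_iter = 3, seed = 23)
  f1 <- mpc_logreg(dat$parts, cfg)
  f2 <- mpc_logreg(dat$parts, cfg)
  expect_identical(coef(f1), coef(f2))
  dir <- withr::local_tempdir()
  paths <- write_model(f1, dir, feature_names = f1$feature_names)
  expect_true(all(file.exists(paths)))
  cf <- utils::read.csv(file.path(dir, "coefficients.csv"))
  expect_equal(cf$estimate, unname(coef(f1)), tolerance = 1e-12)
})
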