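## Partitioned-data I/O, input distribution and result revelation.

#' Read or accept horizontally partitioned input data
#'
#' @param parts list of data frames, or character vector of CSV paths (one
#'   per input party). Each must carry the identical header, numeric feature
#'   columns and a 0/1 label column named `y`.
#' @return list of data frames.
#' @keywords internal
read_parts <- function(parts) {
  if (is.character(parts)) parts <- lapply(parts, utils::read.csv)
  stopifnot(length(parts) >= 1L)
  hdr <- lapply(parts, names)
  if (!all(vapply(hdr, identical, logical(1), hdr[[1L]])))
    stop("distribute_inputs: input parties have mismatching schemas")
  if (!"y" %in% hdr[[1L]])
    stop("distribute_inputs: no label column 'y'")
  for (p in parts) if (!all(p$y %in% c(0, 1)))
    stop("distribute_inputs: labels must be 0/1")
  parts
}

#' Secret-share partitioned inputs across the computation parties
#'
#' Every cell of every input party's block is split into one share per
#' computation party; computation parties hold row-aligned blocks
#' concatenated in the canonical order (input-party index ascending, then
#' file row order).
#'
#' @param parts list of data frames or CSV paths, one per input party.
#' @param session the session (its `n_input_parties` should cover
#'   `length(parts)`; extra input streams are derived if not).
#' @param add_intercept prepend an all-ones column to the design matrix.
#' @return a list with shared matrices `X` (n x m(+1)) and `y` (n x 1) and
#'   the plaintext column names.
#' @export
distribute_inputs <- function(parts, session, add_intercept = TRUE) {
  parts <- read_parts(parts)
  k <- length(parts)
  if (length(session$input_rng) < k)
    session$input_rng <- c(session$input_rng,
                           rng_streams(session$seed + 1000L,
                                       k - length(session$input_rng)))
  xcols <- setdiff(names(parts[[1L]]), "y")
  Xb <- vector("list", k); yb <- vector("list", k)
  for (i in seq_len(k)) {
    Xi <- as.matrix(parts[[i]][, xcols, drop = FALSE])
    if (add_intercept) Xi <- cbind(`(Intercept)` = 1, Xi)
    Xb[[i]] <- share_matrix(Xi, session, rng = session$input_rng[[i]])
    yb[[i]] <- share_matrix(matrix(parts[[i]]$y, ncol = 1L), session,
                            rng = session$input_rng[[i]])
  }
  rbind_shared <- function(blocks) {
    n <- sum(vapply(blocks, function(b) b$nrow, 1L))
    sh <- lapply(seq_len(session$n_parties), function(p)
      do.call(rbind, lapply(blocks, function(b) b$shares[[p]])))
    new_shared_matrix(sh, n, blocks[[1L]]$ncol, session$backend)
  }
  list(X = rbind_shared(Xb), y = rbind_shared(yb),
       feature_names = c(if (add_intercept) "(Intercept)", xcols))
}

#' Reveal the trained coefficients to the result party
#'
#' Each computation party sends its coefficient-share vector to the result
#' party, which sums and decodes them.  Nothing else is ever reconstructed
#' during training.
#'
#' @param beta_shares shared m x 1 coefficient vector.
#' @param session the session.
#' @param config optional `train_config` echoed into the model object.
#' @return an `mpc_model`.
#' @export
reveal_result <- function(beta_shares, session, config = NULL) {
  stopifnot(inherits(beta_shares, "shared_matrix"))
  m <- beta_shares$nrow * beta_shares$ncol
  for (i in seq_len(session$n_parties))
    queue_send(session, i, 0L, beta_shares$shares[[i]], m, "reveal")
  beta <- drop(reconstruct_matrix(beta_shares))
  structure(list(beta = beta,
                 n_iter_used = if (!is.null(config)) config$n_iter else NA_integer_,
                 ledger = ledger_snapshot(session$ledger),
                 config = config),
            class = "mpc_model")
}

#' Write a trained model to disk
#'
#' Coefficients as CSV (one row per feature) plus a key-value run report
#' (iterations, ledger totals, configuration echo).
#'
#' @param model an `mpc_model`.
#' @param dir output directory.
#' @param feature_names optional coefficient names.
#' @return invisibly, the written paths.
#' @export
write_model <- function(model, dir, feature_names = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(feature_names))
    feature_names <- paste0("beta", seq_along(model$beta))
  cf <- file.path(dir, "coefficients.csv")
  utils::write.csv(data.frame(feature = feature_names, estimate = model$beta),
                   cf, row.names = FALSE)
  rp <- file.path(dir, "run_report.txt")
  led <- model$ledger
  lines <- c(sprintf("n_iter = %s", model$n_iter_used),
             sprintf("messages = %.0f", if (is.null(led)) 0 else led$messages),
             sprintf("bits = %.0f", if (is.null(led)) 0 else led$bits))
  if (!is.null(model$config) && inherits(model$config, "train_config"))
    lines <- c(lines,
               sprintf("setting = %s", model$config$setting),
               sprintf("algorithm = %s", model$config$algorithm),
               sprintf("sigmoid = %s", model$config$sigmoid),
               sprintf("backend = %s", model$config$backend$mode),
               sprintf("seed = %d", model$config$seed))
  writeLines(lines, rp)
  invisible(c(cf, rp))
}

#' End-to-end secure training pipeline
#'
#' Convenience wrapper: opens a session from the configuration, secret-shares
#' the inputs, trains, and reveals the coefficients.
#'
#' @param parts partitioned inputs (list of data frames or CSV paths).
#' @param config a [train_config()].
#' @param record_views forwarded to [mpc_session()].
#' @return an `mpc_model` with `feature_names` attached.
#' @export
mpc_logreg <- function(parts, config = train_config(), record_views = FALSE) {
  parts <- read_parts(if (is.data.frame(parts)) list(parts) else parts)
  session <- mpc_session(config$setting, backend = config$backend,
                         seed = config$seed, n_input_parties = length(parts),
                         record_views = record_views)
  data <- distribute_inputs(parts, session, add_intercept = config$add_intercept)
  model <- train(data, config, session)
  model$feature_names <- data$feature_names
  model$session <- session
  model
}
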