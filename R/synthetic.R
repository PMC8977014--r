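## Synthetic horizontally partitioned data.
##
## Emulates the study setting: several input parties each hold a disjoint
## block of records over an identical schema; features are standard normal
## (optionally rescaled) and labels follow the Bernoulli-logistic model
## y ~ Bernoulli(sigmoid(intercept + X beta)) with a known coefficient
## vector, so estimator recovery can be checked against the truth.

#' Specification of a synthetic partitioned dataset
#'
#' @param n_records total number of records.
#' @param m_features number of features.
#' @param true_beta known feature coefficients (length `m_features`).
#' @param intercept known intercept (default 0).
#' @param feature_scale standard deviation of the standard-normal features.
#' @param partition integer vector of per-input-party record counts; must
#'   sum to `n_records`. Default: one input party holding everything.
#' @param seed generation seed.
#' @param strict if `TRUE`, a degenerate draw (all labels identical) is an
#'   error; otherwise it is regenerated with a warning.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records, m_features, true_beta,
                           intercept = 0, feature_scale = 1,
                           partition = n_records, seed = 1L,
                           strict = FALSE) {
  stopifnot(length(true_beta) == m_features, all(partition >= 1),
            sum(partition) == n_records)
  structure(list(n_records = as.integer(n_records),
                 m_features = as.integer(m_features),
                 true_beta = as.numeric(true_beta),
                 intercept = intercept, feature_scale = feature_scale,
                 partition = as.integer(partition), seed = as.integer(seed),
                 strict = isTRUE(strict)),
            class = "synthetic_spec")
}

#' Generate a synthetic horizontally partitioned dataset
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional directory; when given, one `party_<k>.csv` per input
#'   party (identical headers, label column `y`) plus a `truth.json` sidecar
#'   recording the true coefficients and seed are written there.
#' @return invisibly, a list with `parts` (per-party data frames), `truth`
#'   (true beta, intercept, seed) and `files` (paths, when written).
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- rng_streams(spec$seed, 1L)[[1L]]
  for (attempt in 1:5) {
    X <- matrix(stream_rnorm(rng, spec$n_records * spec$m_features,
                             sd = spec$feature_scale),
                spec$n_records, spec$m_features)
    pr <- stats::plogis(spec$intercept + drop(X %*% spec$true_beta))
    y <- stream_rbinom(rng, spec$n_records, 1L, pr)
    if (length(unique(y)) > 1L) break
    if (spec$strict)
      stop("generate_synthetic: degenerate draw (all labels identical)")
    warning("generate_synthetic: degenerate draw, regenerating")
  }
  if (length(unique(y)) == 1L)
    stop("generate_synthetic: could not generate non-degenerate labels")
  colnames(X) <- paste0("x", seq_len(spec$m_features))
  df <- as.data.frame(X)
  df$y <- y
  ends <- cumsum(spec$partition)
  starts <- c(1L, head(ends, -1L) + 1L)
  parts <- Map(function(a, b) df[a:b, , drop = FALSE], starts, ends)
  truth <- list(true_beta = spec$true_beta, intercept = spec$intercept,
                seed = spec$seed)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, sprintf("party_%d.csv", seq_along(parts)))
    Map(function(p, f) utils::write.csv(p, f, row.names = FALSE), parts, files)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, "truth.json"))
  }
  invisible(list(parts = parts, truth = truth, files = files))
}
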