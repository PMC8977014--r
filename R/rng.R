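## Deterministic per-party randomness.
##
## Every role in the simulation (computation parties, input parties, the
## trusted initializer / dealer) owns an independent L'Ecuyer-CMRG substream
## derived from a single top-level seed, so a run is reproducible and the
## randomness one party consumes never perturbs another party's draws.

#' Derive independent RNG substreams from one seed
#'
#' @param seed integer top-level seed.
#' @param n number of substreams to derive.
#' @return list of `rng_stream` objects.
#' @keywords internal
rng_streams <- function(seed, n) {
  old <- .hold_global_rng()
  on.exit(.release_global_rng(old), add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    e <- new.env(parent = emptyenv())
    e$state <- s
    class(e) <- "rng_stream"
    streams[[i]] <- e
  }
  streams
}

.hold_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    list(had = TRUE, seed = get(".Random.seed", envir = globalenv()),
         kind = RNGkind())
  else list(had = FALSE)
}

.release_global_rng <- function(old) {
  if (old$had)
    assign(".Random.seed", old$seed, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}

#' Evaluate a random-number call against a stream's private state
#' @keywords internal
stream_eval <- function(stream, fn, ...) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .hold_global_rng()
  on.exit(.release_global_rng(old), add = TRUE)
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- fn(...)
  stream$state <- get(".Random.seed", envir = globalenv())
  out
}

stream_runif <- function(stream, n, min = 0, max = 1)
  stream_eval(stream, stats::runif, n, min, max)

stream_rnorm <- function(stream, n, mean = 0, sd = 1)
  stream_eval(stream, stats::rnorm, n, mean, sd)

stream_rbinom <- function(stream, n, size, prob)
  stream_eval(stream, stats::rbinom, n, size, prob)

## Uniform field elements in [0, p).  Two 26/27-bit draws are combined so the
## full 53-bit range is covered; draws at or above the largest multiple of p
## below 2^53 are rejection-resampled (probability < p / 2^53), and the rest
## are reduced mod p, which is exact for integer doubles below 2^53.
stream_field_unif <- function(stream, n, p) {
  lim <- floor(2^53 / p) * p
  draw <- function(k) {
    hi <- floor(stream_runif(stream, k) * 67108864)   # 2^26
    lo <- floor(stream_runif(stream, k) * 134217728)  # 2^27
    hi * 134217728 + lo
  }
  v <- draw(n)
  bad <- which(v >= lim)
  while (length(bad)) {
    v[bad] <- draw(length(bad))
    bad <- bad[v[bad] >= lim]
  }
  v %% p
}
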