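## The MPC session: party topology, per-role RNG streams, the instrumented
## message queue, the Beaver-triple store and the communication ledger.
##
## Parties are simulated in-process.  All communication flows through
## `queue_send()`, the single choke point where the ledger is incremented and
## (optionally) the receiving party's view is logged, so measured
## communication counts are exact by construction.

#' Open an MPC session
#'
#' Sets up the simulated party topology for one protocol execution:
#' three computation parties for the honest-majority setting, or two
#' computation parties plus a trusted initializer (Beaver-triple dealer) for
#' the dishonest-majority setting.
#'
#' @param setting `"honest3"` (3 computation parties, re-sharing
#'   multiplication) or `"dishonest2"` (2 parties + Beaver triples from a
#'   trusted initializer).
#' @param backend an `mpc_backend`; defaults to [real_backend()].
#' @param seed top-level seed from which every role's private RNG substream
#'   is derived.
#' @param n_input_parties number of data-holding input parties.
#' @param record_views if `TRUE`, every received payload is appended to the
#'   receiving party's view log (used to audit that no secret other than the
#'   opened Beaver differences and final results is ever seen in the clear).
#' @return an `mpc_session` object (mutable environment).
#' @export
mpc_session <- function(setting = c("honest3", "dishonest2"),
                        backend = real_backend(),
                        seed = 1L,
                        n_input_parties = 1L,
                        record_views = FALSE) {
  setting <- match.arg(setting)
  stopifnot(inherits(backend, "mpc_backend"), n_input_parties >= 1)
  n_parties <- if (setting == "honest3") 3L else 2L
  streams <- rng_streams(seed, n_parties + n_input_parties + 2L)
  s <- new.env(parent = emptyenv())
  s$setting <- setting
  s$n_parties <- n_parties
  s$backend <- backend
  s$seed <- as.integer(seed)
  s$ledger <- comm_ledger()
  s$party_rng <- streams[seq_len(n_parties)]
  s$input_rng <- streams[n_parties + seq_len(n_input_parties)]
  s$ti_rng <- streams[[n_parties + n_input_parties + 1L]]     # trusted initializer
  s$dealer_rng <- streams[[n_parties + n_input_parties + 2L]] # ideal gates
  s$record_views <- isTRUE(record_views)
  s$views <- replicate(n_parties, list(), simplify = FALSE)
  s$triples <- NULL
  class(s) <- "mpc_session"
  s
}

#' @export
print.mpc_session <- function(x, ...) {
  cat(sprintf("<mpc_session: %s (%d computation parties%s), backend %s>\n",
              x$setting, x$n_parties,
              if (x$setting == "dishonest2") " + trusted initializer" else "",
              x$backend$mode))
  print(x$ledger)
  invisible(x)
}

## Predecessor index on the 3-party ring: p(1) = 3, p(2) = 1, p(3) = 2.
ring_prev <- function(i) ifelse(i == 1L, 3L, i - 1L)

#' Send a payload through the instrumented queue
#'
#' @param session the session.
#' @param from,to party indices (0 = trusted initializer / result party).
#' @param payload numeric payload.
#' @param n_messages how many accounting messages this transmission counts
#'   as (a bundled payload may count as fewer messages than elements).
#' @param label ledger label.
#' @keywords internal
queue_send <- function(session, from, to, payload, n_messages, label) {
  ledger_record(session$ledger, n_messages, label)
  if (session$record_views && to >= 1 && to <= session$n_parties) {
    k <- length(session$views[[to]])
    session$views[[to]][[k + 1L]] <-
      list(from = from, label = label, values = as.numeric(payload))
  }
  invisible(payload)
}

#' One party's logged view of the protocol
#'
#' @param session a session opened with `record_views = TRUE`.
#' @param party party index.
#' @return list of received payload records.
#' @export
party_view <- function(session, party) {
  stopifnot(party >= 1, party <= session$n_parties)
  session$views[[party]]
}
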