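## Communication ledger.
##
## The ledger counts protocol messages; bits are derived as
## messages * message_size_bits (32 by default, matching the accounting
## convention used for the protocols' published cost figures, independent of
## the actual share width in memory).

#' Create a communication ledger
#'
#' @param message_size_bits accounting size of one message in bits.
#' @return a mutable `comm_ledger` object.
#' @export
comm_ledger <- function(message_size_bits = 32L) {
  e <- new.env(parent = emptyenv())
  e$messages <- 0
  e$message_size_bits <- as.numeric(message_size_bits)
  e$by_label <- list()
  class(e) <- "comm_ledger"
  e
}

#' Record messages on a ledger
#'
#' @param ledger a `comm_ledger`.
#' @param n_messages number of messages to add.
#' @param label protocol label for the per-protocol breakdown.
#' @keywords internal
ledger_record <- function(ledger, n_messages, label = "misc") {
  ledger$messages <- ledger$messages + n_messages
  prev <- ledger$by_label[[label]]
  ledger$by_label[[label]] <- (if (is.null(prev)) 0 else prev) + n_messages
  invisible(ledger)
}

#' Number of messages recorded on a ledger
#' @param ledger a `comm_ledger`.
#' @export
ledger_messages <- function(ledger) ledger$messages

#' Number of bits recorded on a ledger (messages x message size)
#' @param ledger a `comm_ledger`.
#' @export
ledger_bits <- function(ledger) ledger$messages * ledger$message_size_bits

#' Immutable snapshot of a ledger
#'
#' @param ledger a `comm_ledger`.
#' @return flat list with `messages`, `bits`, `message_size_bits` and the
#'   per-protocol message breakdown.
#' @export
ledger_snapshot <- function(ledger) {
  list(messages = ledger$messages,
       bits = ledger_bits(ledger),
       message_size_bits = ledger$message_size_bits,
       by_label = ledger$by_label)
}

#' @export
print.comm_ledger <- function(x, ...) {
  cat(sprintf("<comm_ledger: %.0f messages, %.0f bits (%d-bit messages)>\n",
              x$messages, ledger_bits(x), as.integer(x$message_size_bits)))
  if (length(x$by_label)) {
    lab <- vapply(x$by_label, identity, numeric(1))
    for (nm in names(lab)) cat(sprintf("  %-14s %.0f\n", nm, lab[[nm]]))
  }
  invisible(x)
}
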