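## Communication reporting.
##
## Two views are reported side by side:
##
##  * measured -- exact message/bit counts from a run's ledger;
##  * analytic -- the published accounting convention: a per-multiplication
##    bit constant (420 bits honest majority, 128 bits dishonest-majority
##    online), a multiplications-per-iteration bound (the protocols perform
##    between 100 and 300 per iteration at the published scale) and the
##    iteration count.  Totals use the convention that reproduces the
##    published lower bounds: decimal kilobits (/1000) for the
##    honest-majority total, 1024-bit kilobits (/1024) for the
##    dishonest-majority one.

HONEST_BITS_PER_MULT <- 420
DISHONEST_BITS_PER_MULT <- 128
HONEST_MSGS_PER_MULT <- 15
DISHONEST_MSGS_PER_MULT <- 4

#' Communication-cost report
#'
#' @param setting `"honest3"` or `"dishonest2"`.
#' @param n_iter iterations of the training protocol (default 10).
#' @param mults_per_iter analytic multiplications-per-iteration figure
#'   (default 100, the lower end of the 100-300 bound; actual measured
#'   counts depend on n, m and the inversion step count and are reported
#'   separately from the ledger).
#' @param ledger optional `comm_ledger` (or snapshot) of a completed run for
#'   the measured section.
#' @return a `comm_report` list with `analytic` and (optionally) `measured`
#'   components.
#' @export
comm_report <- function(setting = c("honest3", "dishonest2"),
                        n_iter = 10L, mults_per_iter = 100L, ledger = NULL) {
  setting <- match.arg(setting)
  honest <- setting == "honest3"
  bits_per_mult <- if (honest) HONEST_BITS_PER_MULT else DISHONEST_BITS_PER_MULT
  msgs_per_mult <- if (honest) HONEST_MSGS_PER_MULT else DISHONEST_MSGS_PER_MULT
  total_bits <- bits_per_mult * n_iter * mults_per_iter
  kb <- if (honest) total_bits / 1000 else total_bits / 1024
  analytic <- list(setting = setting,
                   bits_per_mult = bits_per_mult,
                   messages_per_mult = msgs_per_mult,
                   message_ratio = HONEST_MSGS_PER_MULT / DISHONEST_MSGS_PER_MULT,
                   n_iter = n_iter, mults_per_iter = mults_per_iter,
                   total_bits = total_bits, total_kb = kb)
  measured <- NULL
  if (!is.null(ledger)) {
    snap <- if (inherits(ledger, "comm_ledger")) ledger_snapshot(ledger) else ledger
    measured <- list(messages = snap$messages, bits = snap$bits,
                     by_label = snap$by_label)
  }
  structure(list(analytic = analytic, measured = measured),
            class = "comm_report")
}

#' @export
print.comm_report <- function(x, ...) {
  a <- x$analytic
  cat(sprintf("Communication report (%s)\n", a$setting))
  cat(sprintf("  analytic: %d bits/mult x %d mults/iter x %d iters = %.0f bits (%.0f Kb)\n",
              a$bits_per_mult, a$mults_per_iter, a$n_iter, a$total_bits, a$total_kb))
  cat(sprintf("  per-mult messages: %d (honest/dishonest ratio %.2f)\n",
              a$messages_per_mult, a$message_ratio))
  if (!is.null(x$measured))
    cat(sprintf("  measured: %.0f messages, %.0f bits\n",
                x$measured$messages, x$measured$bits))
  invisible(x)
}

#' Flat key-value serialization of a report or ledger snapshot
#'
#' @param x a `comm_report` or ledger snapshot.
#' @param path optional file to write to.
#' @return character vector of `key = value` lines.
#' @export
report_lines <- function(x, path = NULL) {
  flat <- if (inherits(x, "comm_report")) {
    c(unlist(x$analytic), if (!is.null(x$measured))
      c(measured.messages = x$measured$messages, measured.bits = x$measured$bits))
  } else unlist(x[c("messages", "bits", "message_size_bits")])
  lines <- sprintf("%s = %s", names(flat), as.character(flat))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
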