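## Secure multiplication protocols.
##
## Honest majority (3 parties): the classical re-share / rotate / re-share
## protocol.  Writing p(i) for the predecessor on the party ring
## (p(1) = 3, p(2) = 1, p(3) = 2), each party computes
##
##     w_i = x_i * y_i + x_{p(i)} * y_i + x_i * y_{p(i)}
##
## after receiving its predecessor's (re-shared) input shares; summed over i
## this telescopes to (x1+x2+x3)(y1+y2+y3) = x * y.  Message accounting per
## scalar multiplication: joint re-share of the two inputs (each party sends
## one bundled mask to each other party: 6) + transfer of the input-share
## bundle to the next party (3) + re-share of the output (6) = 15 messages.
##
## Dishonest majority (2 parties): Beaver-triple multiplication.  With a
## pre-dealt triple (a, b, c = a*b), parties open d = x - a and e = y - b
## (2 messages each, 4 messages / 128 bits at the 32-bit accounting size) and
## locally form w_i = c_i + e*b_i + d*a_i, with the public e*d correction
## added by party 1 only.  Triples are single-use; reuse is rejected.

#' Re-share a 3-party additive sharing
#'
#' Each party sends one fresh mask to each other party (6 messages per
#' element) and re-randomizes its share, so transferred shares carry no
#' usable history.  The reconstruction is unchanged.
#'
#' @param sm a `shared_matrix` over 3 parties.
#' @param session an honest-majority session.
#' @return a re-randomized `shared_matrix`.
#' @export
reshare <- function(sm, session) {
  if (session$n_parties != 3L)
    stop("reshare: the re-sharing protocol is defined for 3 parties")
  .reshare_blocks(sm$shares, sm$nrow * sm$ncol, session, label = "reshare") |>
    (\(sh) new_shared_matrix(lapply(sh, function(v) matrix(v, sm$nrow, sm$ncol)),
                             sm$nrow, sm$ncol, sm$backend))()
}

## Genuine mask-exchange re-share of a list of share blocks (as vectors).
## `bundle_with` allows a second set of blocks to ride along in the same
## messages (used for the joint input re-share of a multiplication, which is
## what makes one multiplication cost exactly 15 messages).
.reshare_blocks <- function(blocks, L, session, label, bundle_with = NULL) {
  bk <- session$backend
  n <- session$n_parties
  blocks <- lapply(blocks, as.numeric)
  bundle <- if (is.null(bundle_with)) NULL else lapply(bundle_with, as.numeric)
  rand1 <- function(i) if (is_field(bk))
    stream_field_unif(session$party_rng[[i]], L, bk$modulus)
  else stream_runif(session$party_rng[[i]], L, -bk$mask_width, bk$mask_width)

  out <- blocks
  out2 <- bundle
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- rand1(i)
      r2 <- if (is.null(bundle)) NULL else rand1(i)
      payload <- if (is.null(r2)) r else c(r, r2)
      queue_send(session, i, j, payload, L, label)
      out[[i]] <- bk_sub(out[[i]], r, bk)
      out[[j]] <- bk_add(out[[j]], r, bk)
      if (!is.null(bundle)) {
        out2[[i]] <- bk_sub(out2[[i]], r2, bk)
        out2[[j]] <- bk_add(out2[[j]], r2, bk)
      }
    }
  }
  if (is.null(bundle)) out else list(x = out, y = out2)
}

## Output re-randomization after a multiplication.  Field backend: genuine
## mask exchange.  Real backend: the dealer re-splits the value freshly (same
## 6-message pattern on the ledger); this keeps real share magnitudes within
## the mask width, which both the share-exponentiation trick and the
## floating-point error analysis require (round-off in a product scales with
## the share magnitudes, so unbounded shares would inject growing noise).
.output_reshare <- function(blocks, L, session) {
  bk <- session$backend
  if (is_field(bk))
    return(.reshare_blocks(blocks, L, session, label = "mult_honest3"))
  n <- session$n_parties
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    queue_send(session, i, j, numeric(L), L, "mult_honest3")
  .fresh_split(Reduce(`+`, lapply(blocks, as.numeric)), session)
}

## Real-backend share renormalization (dealer gate, zero ledger cost):
## local linear operations between multiplications (e.g. the 2B - BM update)
## can grow share magnitudes without bound; values are re-split freshly so
## shares stay within the mask width before they enter products or local
## exponentiation.  No-op over the field, where share magnitude is moot.
.renorm_real <- function(sm, session) {
  if (is_field(sm$backend)) return(sm)
  sh <- .fresh_split(Reduce(`+`, lapply(sm$shares, as.numeric)), session)
  new_shared_matrix(lapply(sh, function(v) matrix(v, sm$nrow, sm$ncol)),
                    sm$nrow, sm$ncol, sm$backend)
}

#' Honest-majority 3-party multiplication
#'
#' Element-wise secure product of two shared matrices; 15 ledger messages per
#' element.
#'
#' @param x,y `shared_matrix` values of identical shape.
#' @param session an honest-majority (`"honest3"`) session.
#' @return a `shared_matrix` reconstructing to the element-wise product.
#' @export
mult_honest3 <- function(x, y, session) {
  if (session$setting != "honest3" || session$n_parties != 3L)
    stop("mult_honest3: requires the 3-party honest-majority setting")
  .check_same(x, y)
  bk <- session$backend
  L <- x$nrow * x$ncol

  ## 1) joint re-share of both inputs (bundled masks): 6 messages / element.
  ##    Field: genuine mask exchange.  Real: dealer re-split with the same
  ##    message pattern, bounding share magnitudes (see .renorm_real).
  if (is_field(bk)) {
    rs <- .reshare_blocks(x$shares, L, session, label = "mult_honest3",
                          bundle_with = y$shares)
    xs <- rs$x; ys <- rs$y
  } else {
    for (i in 1:3) for (j in 1:3) if (i != j)
      queue_send(session, i, j, numeric(L), L, "mult_honest3")
    xs <- .fresh_split(Reduce(`+`, lapply(x$shares, as.numeric)), session)
    ys <- .fresh_split(Reduce(`+`, lapply(y$shares, as.numeric)), session)
  }

  ## 2) each party passes its input-share bundle to the next party on the
  ##    ring (the receiver's predecessor is the sender): 3 messages / element
  for (i in 1:3) {
    recv <- which(ring_prev(1:3) == i)  # party that needs shares of party i
    queue_send(session, i, recv, c(xs[[i]], ys[[i]]), L, "mult_honest3")
  }

  ## 3) local cross products
  w <- vector("list", 3L)
  for (i in 1:3) {
    pi <- ring_prev(i)
    w[[i]] <- bk_add(bk_add(bk_mul(xs[[i]], ys[[i]], bk),
                            bk_mul(xs[[pi]], ys[[i]], bk), bk),
                     bk_mul(xs[[i]], ys[[pi]], bk), bk)
  }

  ## 4) re-share the output: 6 messages / element
  w <- .output_reshare(w, L, session)
  out <- new_shared_matrix(lapply(w, function(v) matrix(v, x$nrow, x$ncol)),
                           x$nrow, x$ncol, bk)

  ## 5) fixed-point products carry 2 * frac_bits fractional bits; truncate
  if (is_field(bk)) out <- trunc_gate(out, session) else out
}

## ------------------------------------------------------------------------
## Beaver triples

#' Deal Beaver multiplication triples (offline phase)
#'
#' The trusted initializer draws random (a, b), sets c = a * b, and
#' additively shares all three between the two computation parties.  Dealing
#' happens before any input-dependent message and costs nothing on the
#' online ledger.  Each triple may be consumed exactly once.
#'
#' @param count number of triples.
#' @param session a dishonest-majority (`"dishonest2"`) session.
#' @return a `beaver_triples` batch.
#' @export
generate_triples <- function(count, session) {
  if (session$setting != "dishonest2")
    stop("generate_triples: Beaver triples belong to the dishonest-majority setting")
  stopifnot(count >= 1)
  bk <- session$backend
  rng <- session$ti_rng
  if (is_field(bk)) {
    a <- stream_field_unif(rng, count, bk$modulus)
    b <- stream_field_unif(rng, count, bk$modulus)
    cc <- bk_mul(a, b, bk)
  } else {
    W <- bk$mask_width
    a <- stream_runif(rng, count, -W, W)
    b <- stream_runif(rng, count, -W, W)
    cc <- a * b
  }
  e <- new.env(parent = emptyenv())
  ## share the raw backend elements directly (a, b, c are already encoded)
  split_raw <- function(v) {
    r <- if (is_field(bk)) stream_field_unif(rng, count, bk$modulus)
         else stream_runif(rng, count, -bk$mask_width, bk$mask_width)
    list(r, bk_sub(v, r, bk))
  }
  e$a <- split_raw(a); e$b <- split_raw(b); e$c <- split_raw(cc)
  e$used <- rep(FALSE, count)
  class(e) <- "beaver_triples"
  e
}

#' @export
print.beaver_triples <- function(x, ...) {
  cat(sprintf("<beaver_triples: %d dealt, %d used>\n",
              length(x$used), sum(x$used)))
  invisible(x)
}

#' Reconstruct a dealt triple (testing/debug only)
#' @param triples a `beaver_triples` batch.
#' @param backend the backend the triples were dealt for.
#' @export
triple_values <- function(triples, backend) {
  dec <- function(sh) bk_add(sh[[1L]], sh[[2L]], backend)
  list(a = dec(triples$a), b = dec(triples$b), c = dec(triples$c))
}

#' Dishonest-majority 2-party Beaver multiplication
#'
#' Element-wise secure product using one fresh triple per element; 4 ledger
#' messages (128 bits) per element in the online phase.
#'
#' @param x,y `shared_matrix` values of identical shape.
#' @param session a dishonest-majority session.
#' @param triples optional pre-dealt `beaver_triples` batch with at least as
#'   many unused triples as elements; by default fresh triples are drawn from
#'   the trusted initializer on demand.
#' @return a `shared_matrix` reconstructing to the element-wise product.
#' @export
mult_beaver2 <- function(x, y, session, triples = NULL) {
  if (session$setting != "dishonest2" || session$n_parties != 2L)
    stop("mult_beaver2: requires the 2-party dishonest-majority setting")
  .check_same(x, y)
  bk <- session$backend
  L <- x$nrow * x$ncol
  if (is.null(triples)) triples <- generate_triples(L, session)
  idx <- which(!triples$used)
  if (length(idx) < L) {
    if (any(triples$used))
      stop("mult_beaver2: triple reuse rejected (", sum(triples$used),
           " of the supplied triples were already consumed)")
    stop("mpclogit: not enough Beaver triples supplied")
  }
  idx <- idx[seq_len(L)]
  triples$used[idx] <- TRUE
  if (!is_field(bk)) { x <- .renorm_real(x, session); y <- .renorm_real(y, session) }

  a <- lapply(triples$a, function(v) v[idx])
  b <- lapply(triples$b, function(v) v[idx])
  cc <- lapply(triples$c, function(v) v[idx])
  xs <- lapply(x$shares, as.numeric)
  ys <- lapply(y$shares, as.numeric)

  d_sh <- Map(function(xi, ai) bk_sub(xi, ai, bk), xs, a)
  e_sh <- Map(function(yi, bi) bk_sub(yi, bi, bk), ys, b)

  ## opening: each party sends its d-share and e-share to the other
  queue_send(session, 1L, 2L, d_sh[[1L]], L, "mult_beaver2")
  queue_send(session, 1L, 2L, e_sh[[1L]], L, "mult_beaver2")
  queue_send(session, 2L, 1L, d_sh[[2L]], L, "mult_beaver2")
  queue_send(session, 2L, 1L, e_sh[[2L]], L, "mult_beaver2")
  d <- bk_add(d_sh[[1L]], d_sh[[2L]], bk)
  e <- bk_add(e_sh[[1L]], e_sh[[2L]], bk)

  ## x*y = (a + d)(b + e) = c + e*a + d*b + e*d
  w <- vector("list", 2L)
  for (i in 1:2)
    w[[i]] <- bk_add(bk_add(cc[[i]], bk_mul(e, a[[i]], bk), bk),
                     bk_mul(d, b[[i]], bk), bk)
  ## the public e*d correction enters exactly once
  w[[1L]] <- bk_add(w[[1L]], bk_mul(e, d, bk), bk)

  if (!is_field(bk)) w <- .fresh_split(Reduce(`+`, w), session)
  out <- new_shared_matrix(lapply(w, function(v) matrix(v, x$nrow, x$ncol)),
                           x$nrow, x$ncol, bk)
  if (is_field(bk)) trunc_gate(out, session) else out
}

#' Element-wise secure multiplication (protocol chosen by the session)
#'
#' @param x,y `shared_matrix` values of identical shape.
#' @param session the session; its `setting` selects the protocol.
#' @param triples optional pre-dealt triples (dishonest-majority only).
#' @return a `shared_matrix` of the element-wise product.
#' @export
mult_shared <- function(x, y, session, triples = NULL) {
  switch(session$setting,
         honest3 = mult_honest3(x, y, session),
         dishonest2 = mult_beaver2(x, y, session, triples))
}
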