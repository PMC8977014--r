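---
title: "Secure logistic regression on secret shares: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure logistic regression on secret shares: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpclogit)
```

## The model and the trust assumptions

`mpclogit` trains a binary logistic regression model,
$P(y_i = 1 \mid x_i) = \sigma(\beta^\top x_i)$ with
$\sigma(z) = (1 + e^{-z})^{-1}$, over data that is horizontally partitioned:
several *input parties* hold disjoint records over an identical schema. The
input parties additively secret-share every cell of their data among a set of
*computation parties* — three in the honest-majority setting (at most one
corrupted), two plus a triple-dealing *trusted initializer* in the
dishonest-majority setting — and a *result party* reconstructs the final
coefficient vector. Corrupted parties are honest-but-curious: they follow the
protocol but try to infer secrets from their view. Parties are assumed not to
collude; the package makes no attempt to prevent collusion, and it simulates
all parties in one process with deterministic sequential scheduling, every
transmission passing through one instrumented queue where communication is
counted.

Training is Newton–Raphson with the Böhning fixed-Hessian bound
$\tilde H = -\tfrac14 X^\top X$, whose inverse is computed once by an
iterative (multiply-and-add only) matrix inversion; the gradient is
$X^\top(y - \pi)$ with $\pi$ evaluated either exactly (the *accurate*
algorithm) or by least-squares sigmoid polynomials (the *approximate*
algorithm). The loop runs exactly `n_iter` iterations with no convergence
test, so the iteration count cannot leak anything about the data. The
coefficient vector is initialized at zero (making every first-iteration
probability exactly 0.5), and only the final $\beta$ is ever reconstructed.

## Numeric backends

Secret shares need a number system, and the two halves of the package pull in
opposite directions.

**Prime field with fixed-point encoding** (`field_backend()`). A real $x$ is
embedded as $\mathrm{round}(x \cdot 2^{f}) \bmod p$ with $f = 20$ fractional
bits; negatives occupy the upper half of the field. The modulus defaults to
$p = 2^{53} - 111$, the largest prime below $2^{53}$: every field element is
then exactly representable in an R double, field addition can be arranged to
be exact in double arithmetic, and the one operation that overflows 53 bits —
the modular product — is computed in C through 128-bit integers. Shares drawn
in this backend are uniform over $[0, p)$, so any $n-1$ of them are
statistically independent of the secret. After each fixed-point product the
result carries $2f$ fractional bits and is truncated back to $f$ bits by
probabilistic rounding (round down with probability equal to one minus the
fractional part), which keeps the expected value unbiased and the
per-product error below $2^{-f}$.

**Real backend** (`real_backend()`). Plain double shares, with the $n-1$
random shares drawn uniformly from $(-W, W)$, $W$ = `mask_width` = 2 by
default. This backend exists because the exact-sigmoid path exponentiates
individual shares — an operation with no meaning over a residue ring — and it
is the default for the accurate algorithm. Its hiding is only as wide as the
mask: a share of a value $v$ lies within $v \pm (n-1)W$. The mask width is a
genuine trade-off, *not* a free parameter: exponentiation needs
$e^{|\text{share}|}$ representable, and the floating-point noise injected by
one secure product grows with the square of the share magnitudes. $W = 2$
keeps that noise near $10^{-15}$, comfortably below every intermediate the
training loop produces.

### Idealized dealer gates (and why they exist)

Three maintenance operations are performed by the simulation's dealer role
rather than by an interactive sub-protocol: fixed-point truncation, real-share
re-randomization, and the optional polynomial-input clamp. All are "ideal
functionality" gates — the dealer reconstructs, adjusts, and freshly
re-shares — and none of them sends protocol messages, so the
per-multiplication ledger constants are untouched.

Truncation is idealized because, at $p \approx 2^{53}$ and $f = 20$, the
cheap local-truncation trick wraps with non-negligible probability. Real-share
re-randomization exists because local linear steps such as $B \leftarrow 2B -
BM$ double share magnitudes; left unchecked, shares grow as $2^s$ across $s$
iterations and double-precision round-off grows with them until it swamps the
iterate (the effect is dramatic: the reciprocal iteration diverges around
step 50 without it). Shares are therefore re-split freshly whenever they
enter a product, an exponentiation, or leave an iteration's update. In a
deployment these gates would be interactive sub-protocols with their own
communication; here they are part of the simulator, and the communication
ledger deliberately reflects only the published message patterns of the two
multiplication protocols.

## The multiplication protocols

**Honest majority (3 parties).** Writing $p(i)$ for the predecessor on the
party ring ($p(1)=3$, $p(2)=1$, $p(3)=2$), each party computes
$w_i = x_i y_i + x_{p(i)} y_i + x_i y_{p(i)}$ after receiving its
predecessor's input shares; the nine cross terms sum to $xy$. Transferred
shares are re-randomized before and after. The package counts 15 messages per
product: a joint re-share of both inputs (each party sends one bundled mask
to each of the two others: 6), the transfer of each party's input-share
bundle to its successor (3), and a re-share of the output (6). The published
total of 15 is not itemized anywhere we know of; this decomposition was
chosen because bundling the two input masks and the two transferred shares
into single messages is the natural reading of "transfers the shares of
inputs x and y", and it reproduces the total exactly.

**Dishonest majority (2 parties).** Beaver triples $(a, b, c = ab)$ are dealt
offline by the trusted initializer from its own RNG stream, at zero online
cost; each triple is single-use and reuse is rejected at run time. Online,
each party opens its shares of $d = x - a$ and $e = y - b$ (2 messages each:
4 messages, 128 bits at the 32-bit accounting size) and locally forms
$w_i = c_i + e\,a_i + d\,b_i$, with the public correction $e\cdot d$ added by
party 1 only — added at both parties it would be counted twice in the
reconstruction. Note the cross-term pairing: with $d = x-a$ and $e = y-b$,
correctness requires $e\,a_i + d\,b_i$ (from $(a+d)(b+e)$), and the test
suite verifies this by exhaustive enumeration over a small field.

**Accounting conventions.** The ledger counts messages and derives bits as
messages × 32, so one honest-majority product measures 480 bits. The
published per-product figure of 420 bits does not follow from 15 × 32; the
analytic report (`comm_report()`) therefore treats 420 (and 128) as given
per-product constants, multiplies by 10 iterations × 100 products, and
converts with decimal kilobits (÷1000) for the honest-majority total but
1024-bit kilobits (÷1024) for the dishonest-majority one — the only pair of
conventions under which both published totals (420 Kb and 125 Kb) come out.
Measured and analytic views are reported side by side and never reconciled.

## Iterative matrix inversion

For SPD $X$, the Newton–Raphson iteration
$B_{s+1} = 2B_s - B_s M_s$, $M_{s+1} = 2M_s - M_s^2$ with
$B_0 = c^{-1}I$, $M_0 = c^{-1}X$ converges quadratically to $X^{-1}$ whenever
the spectral radius of $I - c^{-1}X$ is below 1. The scaling constant is
nowhere specified in the protocol literature we follow; the package uses
$c = \mathrm{tr}(X)$, computed under MPC and *revealed* — a deliberate,
documented leakage, justified because $\mathrm{tr}(X) \ge \lambda_{\max}$
guarantees convergence for SPD input. The default of 30 steps is ample for
condition numbers up to about $10^4$ at double precision (quadratic
convergence squares the residual each step). Rank-deficient input manifests
as divergence; an optional `debug_check` mode reconstructs residuals and
stops with a conditioning error, and is never used inside protocol runs
because it reveals intermediates. Matrix products use the naive cubic
schedule — rows × cols × inner scalar products — so ledger counts are exact
multiples of the per-product constants.

## The two sigmoid paths

**Exact** (real backend only). Since $e^{z} = \prod_i e^{z_i}$ over additive
shares, each party exponentiates its own share, shares the factor, and the
factors are multiplied securely; $1 + e^{-z}$ is then inverted element-wise
with the scalar case of the inversion iteration. A scalar reciprocal with
fixed public scaling $c$ converges for any value in $(0, 2c)$, so $c$ is set
from a public domain bound: $c = (1 + e^{-z_{\min}})/2$ with
$z_{\min} = -20$ by default, and 60 reciprocal steps. The step count matters:
for $z$ near $+20$ the scaled value starts around $4 \cdot 10^{-9}$ and needs
~30 doubling steps before the quadratic phase begins. A tighter bound such as
$z_{\min} = -8$ would converge faster but makes the iteration diverge (to
±∞, not to a wrong-but-finite value) the moment a linear predictor drops
below it mid-training; $-20$ is a safety margin chosen once for the data
scales the package targets. Inputs below $z_{\min}$ are the user's
responsibility; the iteration does not test for them (a secure comparison
would be required).

**Approximate** (either backend). The degree-3/5/7 least-squares polynomials
of $\sigma$ on $[-8, 8]$, evaluated in $u = z/8$:

$$g_3(z) = 0.5 + 1.20096\,u - 0.81562\,u^3$$
$$g_5(z) = 0.5 + 1.53048\,u - 2.3533056\,u^3 + 1.3511295\,u^5$$
$$g_7(z) = 0.5 + 1.73496\,u - 4.19407\,u^3 + 5.43402\,u^5 - 2.50739\,u^7$$

The odd-power ladder ($u^2$ once, then $u^3 = u\cdot u^2$,
$u^5 = u^3\cdot u^2$, $u^7 = u^5\cdot u^2$) costs 2, 3 and 4 secure products
per element respectively. All three are $0.5$ plus an odd function, so
$g_d(z) + g_d(-z) = 1$ identically. No clipping is applied by default — the
polynomials are evaluated as printed and diverge outside $[-8, 8]$; an
optional `clip` flag clamps inputs through the dealer gate for users whose
linear predictors stray.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n_iter` | 10 | fixed Newton iterations; matches the whole-protocol communication accounting and recovers coefficients within sampling error at the package's data scales |
| `nardi_steps` | 30 | inversion iterations; quadratic convergence makes more redundant |
| `frac_bits` | 20 | fixed-point resolution $2^{-20} \approx 10^{-6}$ per product |
| `modulus` | $2^{53}-111$ | largest double-exact prime |
| `mask_width` | 2 | real-share mask half-width (see trade-off above) |
| `z_min` / `recip_steps` | −20 / 60 | exact-sigmoid reciprocal domain bound and step count |
| `message_size_bits` | 32 | ledger accounting size, independent of in-memory width |
| `add_intercept` | TRUE | prepend an all-ones column at the data layer |

Backend defaults per algorithm: real for *accurate* (the exponentiation trick
requires it), prime field for *approximate*; both overridable. Labels are
secret-shared exactly like features — the conservative reading of a protocol
description that could be taken to append them in the clear.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws standard-normal features (optionally rescaled),
labels from $\mathrm{Bernoulli}(\sigma(\beta_0 + X\beta))$ with a known
coefficient vector, and splits records across input parties in stated
proportions, writing one CSV per party plus a truth sidecar. Draws in which
all labels coincide are regenerated with a warning (or rejected under
`strict`). This emulates the *structure* of the multi-institution setting —
identical schemas, disjoint records, known ground truth — but not the
*content* of real clinical data: no correlated or heavy-tailed features, no
separation-prone categorical predictors, no class imbalance beyond what the
intercept induces, no missingness. Tests passing on this generator therefore
demonstrate protocol correctness (secure runs equal same-formula plaintext
runs) and estimator sanity (recovery of the generating coefficients within
sampling error), not robustness of logistic regression to difficult real
data, which is a property of the statistical method rather than of the
protocols.

Canonical record order after distribution is input-party index ascending,
then file row order; the fitted model is invariant to input-party
permutation (the likelihood does not depend on row order), and the test
suite checks this.

## Problem sizes and seeds

The test suite exercises: exhaustive multiplication over the field of 31
elements (961 pairs, both protocols); 1000 random real products; 50 random
SPD 5×5 inversions (eigenvalues in [0.5, 5], residual tolerance $10^{-6}$); a
dense sigmoid grid on $[-8, 8]$ at step 0.05 (tolerance $10^{-6}$ for the
exact path); training equivalence at $n = 500$, $m = 4$ for all four
setting × algorithm combinations (tolerance $10^{-4}$ on the real backend,
$10^{-2}$ on the fixed-point field); and coefficient recovery at $n = 2000$,
$m = 5$ over 20 seeded replicates (all coefficients within 3 plaintext
standard errors in at least 95% of replicates). Every random draw in the
package flows from one top-level seed through per-role L'Ecuyer-CMRG
substreams, so runs are bit-reproducible and one party's consumption of
randomness never perturbs another's.

## Known limitations

* The real backend's hiding is bounded by the mask width; in particular the
  exponentiated factors $e^{z_i}$ are shared with masks that are negligible
  relative to the factors themselves, and the opened Beaver differences
  $d = x - a$, $e = y - b$ reveal values to within the mask. This is inherent
  to running the exponentiation trick outside a finite field; the prime-field
  backend has information-theoretic share hiding but cannot run the exact
  sigmoid.
* The inversion scaling constant (the trace) is revealed by design.
* Truncation, real-share re-randomization and the optional clamp are ideal
  dealer gates, not interactive sub-protocols; their (zero) communication
  cost is a modelling choice.
* No secure comparison exists in the protocol suite, so nothing input-
  dependent can branch: no convergence tests, no clipping without the dealer,
  divergence for linear predictors outside the declared domain.
* Single-machine simulation only: no networking, no serialization hardening,
  no malicious security, no collusion resistance.
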