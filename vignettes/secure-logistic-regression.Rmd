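---
title: "Methods: secure two-party logistic regression over additive shares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secure two-party logistic regression over additive shares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(securelr)
```

## The problem and the model

Two data processors (Alice and Bob) hold additive secret shares of a training
table — in the motivating setting, gene-expression profiles with a binary
outcome, contributed by several data owners who must not reveal their records
to anyone. The processors jointly run full-batch gradient descent on a
logistic-regression-like model whose activation is the clipped ReLU

$$\rho(z) = \min(1, \max(0, z + 1/2)),$$

an MPC-friendly surrogate for the sigmoid: it needs no exponentials or
division, only comparisons against $\pm 1/2$, and this package evaluates even
those without a general secure-comparison protocol. The update rule is

$$w \leftarrow w + \eta \, X^\top\!\big(t - \rho(Xw)\big),$$

run for a fixed, public number of iterations. The iteration count is fixed in
advance deliberately: an early-stopping rule would make the running time
depend on the data and leak information. The update uses the plain sum of
per-sample gradients (no division by the sample count); any normalization is
the caller's to fold into $\eta$, which is how the learning-rate/iteration
pairs in this package's examples are stated.

All arithmetic happens in the ring $\mathbb{Z}_{2^\lambda}$ on fixed-point
encodings $Q(x)$: $a$ fractional bits, $b$ integer bits, two's-complement
sign, with the magnitude truncated toward zero (not rounded) so the encoding
is bit-exact and reproducible. Encoded labels are $t_d 2^a$, which puts
$t_d - o_d$ on the same $2^a$ scale as the activation output — the scale
bookkeeping the gradient step relies on.

## Protocol stack

* **Sharing.** $x = x_A + x_B \bmod 2^\lambda$ with $x_A$ uniform. Addition,
  subtraction, scaling by a public constant and adding a public constant are
  local; the package asserts in tests that none of them touches the channel.
* **Multiplication** (scalars, inner products, matrices) uses one Beaver
  triple per product: the parties open the masked differences $D = X - U$ and
  $E = Y - V$ in a single simultaneous exchange and locally assemble
  $W + DV + UE + DE$. Any one multiplication — and any batch of independent
  multiplications issued together — costs exactly one round. The asymmetric
  $DE$ term is assigned to Alice by convention; any single-party assignment is
  correct, and fixing it makes runs reproducible.
* **Truncation** after a fixed-point product is share-local: Alice keeps
  $\lfloor x_A/2^a \rfloor$, Bob $-\lfloor(-x_B)/2^a\rfloor$. It costs no
  messages, errs by at most one least-significant bit — except with
  probability $2^{a+1-\lambda}$, when the result is arbitrary. At the default
  operating point ($a = 12$, $\lambda = 64$) that is $2^{-51}$. Truncation is
  deferred wherever possible: once per inner product, once per gradient
  product, once per learning-rate scaling — three events per iteration.
* **Bit decomposition** enters each party's share bits as trivial $Z_2$
  sharings and evaluates a binary adder with secure ANDs. Two circuits are
  provided and cross-checked for identical openings: a literal ripple-carry
  reference ($k-1$ rounds for $k$ positions — the correctness anchor) and a
  Kogge–Stone carry-lookahead prefix network
  ($1 + \lceil\log_2(k-1)\rceil$ rounds — the round-efficient path). Batch
  size never changes the round count because each gate layer is issued as one
  call.
* **Bit-to-ring conversion** uses the masked-bit construction: open
  $c = b \oplus r$ and output $c + (1-2c)[r]_{2^\lambda}$ locally.
* **Activation.** With $z' = z + 1/2$ (a local constant addition), a
  *partial* decomposition of the low $k = a + b + 1$ positions suffices,
  because every bit above the fixed-point window replicates the sign.
  `pos` is the negated $(a\!+\!b\!+\!1)$-th bit; `geq1` is the OR of the $b$
  integer bits, computed by De Morgan as a balanced AND tree; both are
  converted to ring sharings in one shared round, and
  $o = P \odot (z' + G \odot (2^a - z'))$ finishes in two sequential
  multiplications. $P$ and $G$ are unscaled 0/1 integers, so the activation
  involves **no truncation at all** and its output is exact on the
  $2^{-a}$-quantized input grid — the property the test suite checks point by
  point over $[-4, 4]$. `geq1` is computed even when `pos` masks it to zero:
  there is no data-dependent control flow anywhere in the stack, and the
  message transcript of a whole training run is a function of the public
  dimensions only (also tested).

## Trusted initializer and randomness hygiene

A trusted initializer pre-distributes everything the online phase consumes:
matrix triples for the two matrix products of each iteration (in consumption
order, with shape checks), pooled scalar ring triples, pooled $Z_2$ triples
and masked-bit pairs. The pools are sized by a closed-form tally
(`count_secure_multiplications()`) that the tests cross-check against the
instrumented live counters, gate for gate. Streams are generated once from a
seed, are byte-reproducible, are consumed strictly in order at most once, and
deplete with an explicit error — never a silent reuse. The generator is a
seedable statistical RNG: the artifact's goal is protocol fidelity and
testability, not production-grade cryptographic randomness, and a
cryptographic offline phase could replace the TI without changing the online
protocols. Streams can be handed over as files (`write_ti_streams()`) or
generated in-process; the package treats up-front pre-delivery as canonical.

$Z_2$ shares are stored as plain 0/1 vectors for clarity; the *channel
accounting* models the packed wire format (bits packed into $\lambda$-bit
words along the batch axis), which is what matters for the traffic
contracts. This was a deliberate trade of storage realism for auditability —
the tests pin the byte counts, not the in-memory layout.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `frac_bits` ($a$) | 12 | fractional precision; 12 bits make fixed-point CV accuracy indistinguishable from float in the package's paired runs |
| `int_bits` ($b$) | 15 | integer range $|x| < 2^{15}$; generous for normalized expression values |
| `ring_bits` ($\lambda$) | 64 | machine word; must be $\ge 2(a+b)$ so one product fits before truncation; widths 8/16 exist for exhaustive testing |
| `learning_rate` ($\eta$) | job-specific | public constant, applied as $Q(\eta)$ by a local scale + local truncation; need not be a power of two |
| `iterations` | job-specific | fixed and public (leakage-free stopping rule) |
| `variant` | ripple | decomposition circuit; lookahead gives $\Theta(\log k)$ rounds at $\sim\!2\times$ the AND gates |

## The synthetic generator, and what passing tests show

Real gene-expression benchmarks of the intended shape are distributed only on
request, so all tests run on `synth_lr_data()`: clamped-normal features
bounded by `feature_scale` (default 1, well inside the $2^b$ window), a
sparse unit-norm true weight vector, and labels that are either the sign of
the score with an enforced margin (separable mode) or sigmoid draws, plus an
optional label-flip rate. It reproduces the *shape* that matters to the
protocols — bounded reals, high dimension, binary labels, hundreds of samples
(the dimension scan in the tests goes to $470 \times 17{,}814$) — but not the
correlation structure or class geometry of real tumor data. Passing tests
therefore certify protocol correctness and secure/clear equivalence, not
clinical-grade accuracy on any particular data set.

## Oracles

Three independent references pin the implementation:

* brute-force modular arithmetic at $\lambda = 8$, exhaustive over the ring;
* `train_lr_clear()`, double-precision clipped-ReLU gradient descent;
* `train_lr_fixed()`, a single-machine simulation of the exact ring pipeline.
  With `trunc_model = "split"` it draws fresh share splits at each truncation
  (weak oracle: secure weights must agree within $\pm 1$ LSB per truncation
  event, three events per iteration). Fed the recorded splits of a secure run
  (`record_truncations = TRUE`) it reproduces the secure weights **bit for
  bit** (strong oracle).

The truncation failure law is exercised at $\lambda = 16$, $a = 4$, where
$2^{a+1-\lambda} = 2^{-11}$ is large enough to observe: a million draws with
value magnitudes below $2^a$ (the regime in which the stated bound applies)
must show an outside-$\{-1,0,1\}$ rate under three times the bound.

## Numerical choices and degenerate inputs

* Encoding truncates magnitudes toward zero; decode errors on ring values
  outside the representable window.
* Weights initialize to the all-zeros sharing (data-independent, and makes
  `iterations = 0` a trivial invariant).
* Boundary inputs $z = \pm 1/2$ follow the branch limits of $\rho$ exactly
  ($z' = 0$ gives `pos` $=1$, `geq1` $=0$, output $0$; $z' = 2^a$ gives
  `geq1` $=1$, output $2^a$).
* `iterations = 0`, single-owner partitions, and $(v, 0)$ share splits (which
  make truncation exact integer division for positive values) are all covered
  by tests.
* Ownership partitioning (horizontal / vertical / arbitrary) cannot affect
  the model: sharing masks are drawn in canonical cell order, and the tests
  require bit-identical weights across modes.

## Problem sizes

The test suite and the acceptance script run, among others: the full
$65{,}536$-pair multiplication square at $\lambda = 8$; the full
$32{,}769$-point activation grid at the operating point; a
$10^6$-draw truncation Monte Carlo; and training equivalence at
$n = 100$, $m = 50$, $50$ iterations with a $100$-sample held-out set. These
sizes were chosen to make every contract either exhaustive or tightly
concentrated while keeping a full run in tens of seconds on one CPU.

## Known limitations

* Honest-but-curious, two computing parties only; no malicious security, no
  authenticated transport. The channel is an instrumented in-process object,
  not a socket layer.
* The RNG is statistical, not cryptographic (see above).
* No regularization (ridge would be a cheap extension — it only adds a local
  linear term to the update; lasso would require secure comparisons), no
  mini-batching, no early stopping, no inference API beyond what the
  equivalence tests need.
* The truncation failure probability is taken as $2^{a+1-\lambda}$ with $a$
  the fractional width; the bound is really governed by the magnitude of the
  value being truncated, and the package's Monte Carlo accordingly tests the
  regime where the two coincide.
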