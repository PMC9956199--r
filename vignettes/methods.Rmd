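---
title: "Privacy-preserving disease detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving disease detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phecare)
```

# Overview

`phecare` implements a smart-healthcare workflow with two largely
independent halves. The *storage* half keeps patient feature vectors under
partially homomorphic encryption (PHE), so a curator can hold — and to a
limited extent compute on — records it cannot read. The *detection* half is
a centered convolutional restricted Boltzmann machine (CCRBM) with
probabilistic max-pooling that maps a record's features to a binary disease
label, with its initial parameters chosen by the whale optimization
algorithm (WOA). A synthetic cohort generator, an evaluation module and a
pipeline orchestrator tie the halves together.

This vignette explains each model, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
experiments can show.

# Homomorphic storage

## Two schemes behind one interface

A *partially* homomorphic scheme supports one arithmetic operation on
ciphertexts an unlimited number of times. No single PHE scheme is both
additively and multiplicatively homomorphic, so the package provides one of
each behind a common interface:

* **Paillier** (additive): `E(m) = g^m r^n mod n^2` with `g = n + 1` and
  fresh random `r` coprime to `n`. Multiplying ciphertexts adds plaintexts:
  `D(E(m1) E(m2) mod n^2) = m1 + m2 mod n`. Encryption is randomized, so
  two encryptions of the same value differ — the scheme is semantically
  secure against ciphertext matching.
* **Textbook RSA** (multiplicative): `E(m) = m^e mod n`. Multiplying
  ciphertexts multiplies plaintexts. It is deterministic and unpadded, and
  is included as a demonstration of the multiplicative contract only; it is
  *not* secure against the dictionary adversary below, which the security
  analysis makes visible rather than hiding.

Key generation draws prime candidates from R's seeded RNG and advances
each candidate to the next prime under a Miller–Rabin test, so keys are a
deterministic function of the seed — a property the reproducibility
guarantees of the pipeline depend on. The default modulus is 512 bits,
which keeps the test suite fast; 2048 bits is the documented choice for
anything resembling deployment. All big-integer arithmetic is done by an
internal Rcpp layer over OpenSSL's BIGNUM, with values crossing the R
boundary as decimal strings.

## Fixed-point encoding

Real features are encoded as `round(x * 10^6)` (six decimal digits by
default), with negatives stored as `n - |m|` and decoded by the `n/2`
threshold. The synthetic generator snaps its features to the same `1e-6`
grid, which makes encryption *exactly* lossless rather than lossless to a
tolerance: the decrypted cohort is bit-identical to the generated one, and
the encrypted and plaintext pipelines therefore produce byte-identical
model files under the same master seed. This is the strongest form of the
claim that secured storage must not perturb learning.

## Timing and the simulated adversary

Encryption, decryption and key-generation times (AT, CT, BT) are measured
as wall-clock millisecond differences and reported, never asserted against
fixed values: they are hardware facts, not model properties.

The "security analysis" score SA is defined as the fraction of records an
adversary recovers. A ratio needs an adversary model to be computable, so
the package defines a concrete one: the adversary holds the public key,
the ciphertext store and a finite dictionary of candidate plaintext
values; it encrypts every candidate and counts a record as recovered when
all of its ciphertexts match dictionary encryptions. Against Paillier the
attack recovers nothing even with a complete dictionary (fresh randomness
defeats matching); against deterministic textbook RSA or an unencrypted
store a covering dictionary recovers everything. The reported security
level is `100 * (1 - SA)`.

# The CCRBM

## Architecture

Records are 1-D feature vectors (5 features by default), so the model is a
1-D convolutional RBM. A bank of `L = 2` filters of width 3 is correlated
(valid mode) with the visible vector, giving a detection layer of length
`5 - 3 + 1 = 3` per filter. Detection units are grouped into pooling
blocks of size `B = 3`; within a block at most one unit may fire, and the
pooled unit above the block reports whether any did (probabilistic
max-pooling). With the defaults each filter owns exactly one block, so the
pooled representation has `L = 2` dimensions. If `B` does not divide the
detection length, the final block is simply smaller — no padding.

Visible units hold min–max-scaled values in [0, 1] treated with
Bernoulli-probability semantics, the standard real-valued relaxation of a
binary RBM; the model itself is silent on feature distributions, so the
generator produces data matching this assumption (see below).

## Energy, conditionals and centering

The plain energy couples each hidden unit to its filter window and adds
per-filter hidden biases and a single shared visible bias. The *centered*
variant subtracts running offsets from every unit state — `v - alpha_v`
and `h - alpha_h` throughout the energy and gradients — which removes the
large common component of the activations from the learning signal and is
the established cure for the gradient instability of deep/convolutional
Boltzmann stacks. With zero offsets the centered model reduces exactly
(bitwise) to the plain one, and the test suite holds it to that.

Within each pooling block the conditional over hidden states is a softmax
with an explicit "all off" outcome:

* `P(h_k = 1 | v) = exp(S_k) / (1 + sum_block exp(S))`,
* `P(block off | v) = 1 / (1 + sum_block exp(S))`,

with `S_k = beta + (omega * (v - alpha_v))_k`. The implementation guards
the softmax with a log-sum-exp shift, so probabilities are finite for any
finite signal. The visible conditional is a logistic function of the
full-mode correlation of the filters with the centered hidden maps plus
the shared bias.

Offsets are initialised to the sigmoid of the corresponding biases and
refreshed after every update by an exponential moving average of the batch
mean activations (rate 0.01 per batch). The offsets are treated as data
statistics, not gradient-trained parameters: they are excluded from the
"zero learning rate changes nothing" contract and updated on the data side
only.

## Training

Training is centered contrastive divergence (CD-k, default k = 1) at
learning rate 0.1, full batch. The gradient is the data-minus-model
difference of the centered sufficient statistics, with the model term
estimated from a k-step Gibbs chain. Full-batch updates keep a run exactly
reproducible for a given seed and are cheap at these problem sizes;
reconstruction error (deterministic mean-field, one step) is logged per
epoch.

An exact-enumeration oracle (`enumerate_joint`, `exact_gradient`) computes
the full Boltzmann distribution and exact log-likelihood gradient of any
model with at most 2^16 joint states. It exists for validation only: the
tests require conditionals to match enumerated posteriors to 1e-10, Gibbs
frequencies to match the joint within total variation 0.02 at 1e5 sweeps,
and the CD direction to align with the exact gradient (mean cosine
similarity above 0.9).

## The supervised head

The generative model ends in pooled activation probabilities
`P(block on | v)`; a logistic readout on these features produces the
confidence score, and the label is 1 when the confidence is at least 0.5
(a tie goes to class 1 — an arbitrary, documented choice). The readout is
fit by a ridge-stabilised Newton iteration (IRLS) with at most 25 steps
and ridge 1e-4: on two or three features this converges essentially to the
maximum-likelihood solution, is deterministic, and the small ridge keeps
the weights bounded when the pooled features separate the classes
perfectly.

# Whale optimization

WOA is a population metaheuristic mimicking humpback bubble-net hunting.
Each iteration, every whale either (with probability 1/2) spirals around
the incumbent best — `G' = |G* - G| e^{ds} cos(2 pi s) + G*` with
`s ~ U(-1, 1)` and spiral constant `d = 1` — or applies the encircling
move `G' = G* - F |R G* - G|`, where the coefficient `F = 2 f y - f`
shrinks with the linearly decaying `f: 2 -> 0`. Early on, when
`max|F| >= 1`, encircling is redirected at a random other whale
(exploration); the random partner excludes the whale itself whenever the
population allows. A draw of exactly `p = 0.5` takes the spiral branch
(measure-zero; documented). Positions are clipped to the search box after
every move, the incumbent best is replaced only by a strictly better
fitness (elitism), and minimization is the internal convention.

Defaults are a population of 20 and 100 iterations. The benchmark the
package holds itself to: on the 10-D sphere over [-5, 5]^10 the median
best fitness over 20 seeds is below 1e-2 and beats uniform random search
at the same evaluation budget.

# The pipeline

`run_full_pipeline()` chains: synthesize → key generation → encrypt →
store → decrypt → stratified 80/20 split → WOA selection of CCRBM initial
parameters → final CD training → prediction → evaluation. Every stage
derives its own seed from the master seed by hashing a stage tag, so
disabling one stage (e.g. `encrypt = FALSE`) cannot shift another stage's
randomness — this is what makes the encrypted and plaintext paths produce
identical models.

The optimizer searches the flattened initial-parameter vector (filters
row-major, then hidden biases, then the visible bias; 9 dimensions at the
default structure) in the box [-1, 1] per dimension — RBM weights of
useful magnitude are small, and CD can grow them afterwards. The fitness
of a position is the *negative validation accuracy* after a short training
run: 5 CD epochs on the inner training split (80% of the training data),
readout fit, scored on the inner validation split (20%, stratified). A
reconstruction-error fitness is available as a config option for purely
generative use. Fitness evaluations share one derived seed (common random
numbers), so fitness is a deterministic function of position and the
optimizer's comparisons are not corrupted by sampling noise. A failed
training run returns the worst fitness with a warning instead of killing
the optimizer. The final model is trained from the best position for 50
CD epochs on the full training split, and the readout is refit on all
training records.

# The synthetic generator

The generator emulates a two-class cohort of fixed-length real-valued
records: class 0 features are baseline Gaussians, class 1 features are
shifted by `effect_size * noise_sd` on an informative subset (defaults:
5 features, the first two informative, effect size 2, unit noise, balanced
classes, 2000 records in the pipeline default). Features are min–max
scaled to [0, 1] — the range the CCRBM's visible units assume — and
snapped to the 1e-6 fixed-point grid of the encrypted store. Labels are
i.i.d. Bernoulli draws at the configured balance, so realised class
fractions vary within binomial error, and the train/test split is
stratified so small cohorts cannot lose a class from either side.

What this emulates is the statistical skeleton the classifier assumes:
conditionally Gaussian features, a mean-shift class signal, no missing
values. What it deliberately does not emulate: feature correlations,
non-Gaussian clinical measurements, label noise, missingness, class
imbalance beyond the configured rate, or any real UCI disease table.
Passing tests therefore demonstrate that the machinery is correct and that
the optimizer genuinely improves over random initialisation under the
assumed data model — not that the classifier reaches any particular
accuracy on real clinical data.

# Numerical choices and degenerate inputs

* Block softmax: log-sum-exp guarded; `NaN` signals raise an error rather
  than propagate.
* A feature with zero range min–max scales to the constant 0.5.
* Undefined metric ratios (e.g. precision with no positive predictions)
  are reported as `NA` with a warning, never silently coerced to 0.
* Fixed-point mantissas beyond `n/2` (or doubles beyond 2^53) are refused
  at encode time.
* A partial final pooling block is a smaller softmax block; no padding.
* Confidence ties at exactly 0.5 classify as 1.
* Prime search advances an odd seeded candidate by 2 until prime; the top
  two candidate bits are forced so the modulus reaches its nominal length.

# Problem sizes used by the checks

The packaged checks run at sizes chosen to exercise the study conditions
while staying comfortably runnable on one CPU: 1000 random pairs per
homomorphic property at 512 bits; 1000 random models for block
normalization; 1e5 Gibbs sweeps on the enumerable toy model; 500-record
cohorts over 5 seeds for training progress; the full WOA budget
(20 x 100) on the 10-D sphere over 20 seeds; and the complete encrypted
pipeline at 2000 records. The model-equality check between the encrypted
and plaintext paths uses a reduced optimizer budget, since the property
being checked — that the storage layer is invisible to learning — does not
depend on how long the optimizer runs.

# Known limitations

* **Edge coverage of the convolutional readout.** With width-3 filters
  over 5 positions, the pooled feature in the small-weight regime is a
  linear functional of the input confined to the rank-3 span of the
  coverage map `w -> (w1, w1+w2, w1+w2+w3, w2+w3, w3)`. A class signal
  concentrated on the *edge* features (the generator's default places it
  on features 1–2) is not exactly representable in that span — its best
  projection retains cos θ ≈ 0.87 of the discriminant — so the CCRBM's
  ceiling sits roughly 3 accuracy points below an unconstrained linear
  classifier on the same cohort. A signal on central features (2–3) is
  exactly representable. This is a structural property of valid-mode
  convolution with shared biases, worth knowing before reading accuracy
  comparisons.
* Textbook RSA is demonstration-grade; nothing here is hardened
  cryptography (no padding, no constant-time arithmetic, no key
  rotation).
* The dictionary adversary is one concrete, bounded attacker; SA says
  nothing about stronger adversaries (chosen-plaintext with side channels,
  lattice attacks, etc.).
* The classifier trains on decrypted features. Homomorphic operations are
  provided and tested, but prediction *on ciphertexts* is not implemented:
  the two homomorphic operations available (addition under one scheme,
  multiplication under another) cannot express the CCRBM's nonlinear
  forward pass.
* Unsupervised CD drift: the final training stage optimizes data
  likelihood, not label accuracy, so long final runs can drift away from
  the discriminative initialisation the optimizer selected. The fitness
  and the final budget are both configurable where this matters.
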