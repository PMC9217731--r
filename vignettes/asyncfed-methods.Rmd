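---
title: "Asynchronous staleness-aware federated optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asynchronous staleness-aware federated optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asyncfed)
```

## The problem

`asyncfed` simulates federated training of a binary text classifier — the
motivating application is screening social-media users for depression risk
from their posts — under the constraint that raw user data never leave the
device. Only model parameters travel. The package implements two trainers
over a shared discrete-event core:

* **FedAvg** — the synchronous baseline: each round, participating devices
  train locally from the current global model and the server replaces it
  by the shard-size-weighted average of the returned models.
* **An asynchronous, staleness-aware trainer** (the package's main
  subject, `cafed_run()`): the server applies each device's contribution
  the moment it arrives, damped per parameter entry by how stale that
  entry is, with an optional Gaussian randomization of the update for
  privacy and a Bernoulli "push gate" that thins uploads.

Everything runs single-process in virtual time and is a pure function of
one master seed, so every run log is exactly replayable.

## The update rule

Parameters live in a flat vector with a stable global index $k$
(`param_vector`). A device $i$ pulls the global model $w_\tau$ at epoch
$\tau$; the server stores that snapshot in its *w-back* store. After a
local round the device holds $w_{\mathrm{new}}^i$ and the server
reconstructs the **pseudo-gradient**

$$g = w_{\mathrm{back}}^i - w_{\mathrm{new}}^i,$$

never seeing a raw gradient. For each entry $k$, the **staleness** $s_k$
counts the global updates applied to entry $k$ between the pull and the
push, i.e. updates $u \in [\tau, t-1]$ with $|g_u^k| > \vartheta$
(zero-tolerance $\vartheta$, default 0). It is computed incrementally as a
difference of cumulative counts, and clamped at a cap $M$ (default $10n$)
so the theory's bounded-age assumption holds mechanically. The
**adaptive weight** is

$$\partial_k = \begin{cases} 1/s_k & s_k \neq 0 \\ 1 & s_k = 0,\end{cases}$$

always in $(0, 1]$ and non-increasing in $s_k$, and the global update is

$$w_{t+1}^k = w_t^k - \partial_k\,\bigl(g^k + \beta\,N_k(0, \sigma^2)\bigr).$$

Noise choices that needed fixing where the algorithm text leaves room:

* the Gaussian draw is **independent per entry** of each accepted update;
* noise enters the *update* but not the staleness history — the history
  counts use the clean $g^k$, otherwise every entry would count as
  touched by every update and the adaptive weights would collapse;
* $\sigma$ defaults to 1 (unit-variance white noise); $\beta$ is the
  tunable magnitude, with $\{0, 10^{-4}, 10^{-3}, 10^{-2}, 5\cdot10^{-2}\}$
  the magnitudes used in the randomization study.

A device about to push draws $r \sim U(0,1)$ and transmits only if
$r < \operatorname{sigmoid}(v)$; otherwise the round is **dropped**: the
worker discards its local delta, re-pulls the current global model, and
starts a fresh round (re-pulling keeps its staleness bounded; whether a
dropped worker should instead retrain from its stale model was open, and
re-pull is the choice made here). The gate is evaluated once per
completed local round, not per parameter.

## The simulation core

Asynchrony is modeled with a virtual-time event queue. Each worker's
local round lasts a seeded log-normal duration (heterogeneous compute is
the reason asynchrony pays off; the timing model itself is a free choice,
and scripted delay functions can replace it in tests). Arrivals are
processed strictly in (arrival time, device id) order — the server
accepts one update per instant, and simultaneous arrivals resolve
deterministically by device id. Every random draw (per-worker
minibatches, per-worker delays, the gate, the noise) comes from its own
stream derived from the master seed, so changing how often one component
draws never desynchronizes the others; this is what makes degenerate
configurations *bit-comparable* to sequential SGD.

Two exact-equivalence properties anchor the implementation and are
enforced in the test suite:

* with one worker, an open gate ($v = \infty$), no noise and one local
  step per round, the global trajectory equals plain sequential SGD on
  the same shard with the same seed (every staleness is 0);
* the incremental staleness counter equals a brute-force recount over
  the stored update log on randomized multi-worker runs.

## Models

The classifier of the application is a **text CNN**: embedding lookup
$\to$ 1-D convolutions with ReLU (filter lengths 3/4/5) $\to$
max-over-time pooling $\to$ concatenation $\to$ dropout $\to$ one fully
connected sigmoid output. The fully connected layer maps the pooled
vector directly to the single output (no hidden layer — the narrowest
reading of the architecture, kept as the package's choice). Binary
cross-entropy plus an $l_2$ penalty on all non-embedding trainables is
the loss; the $l_2$ coefficient and layer widths are configuration
defaults, not reported facts. The forward/backward pass is written
directly in matrix algebra (no deep-learning framework is involved) and
is verified against central finite differences in every embedding mode.

Embedding modes follow the usual fine-tuning taxonomy: `rand` (seeded
random init, trainable), `static` (pre-trained table, frozen; unknown
tokens get seeded random rows), `nostatic` (pre-trained, fine-tuned). The
padding row is pinned to zero in every mode, and in `static` mode the
embedding matrix lives outside the federated parameter vector entirely,
so updates can never touch it.

Because the CNN is non-convex and relatively slow in pure R, the package
also ships an analytically tractable **logistic stand-in**
(`make_logistic_model()`) over min-max-normalized bag-of-words features,
and a **quadratic objective** (`make_quadratic_problem()`) with a
closed-form optimum. The federated convergence and privacy-noise studies
run on the logistic stand-in; the CNN demonstrates the end-to-end text
pipeline at reduced dimensions. This split keeps every study inside a
desk-scale compute budget while each claim is still checked on the model
class it concerns.

## Synthetic data: what it emulates and what it does not

No public corpus exists for the motivating cohort (the original data are
private crawler output), so `gen_corpus()` generates one with the same
*shape*: default 900 users at prevalence $327/900$, several posts per
user, Zipf-like token frequencies, and a set of signal tokens whose
log-weight is shifted by `signal_strength` in the positive class only —
so the ground-truth per-token log-odds are known exactly, and
`signal_strength = 0` yields provably null signal. `gen_vectors()` makes
a balanced 10-class Gaussian-blob dataset (60,000 records by default) for
the partitioning experiments, and `partition_data()` implements the IID,
pathological label-sorted shard, and power-law-imbalanced schemes.

What the generator does **not** emulate: real language (no syntax, no
segmentation — corpora are pre-tokenized by construction), behavioral
features, label noise, or temporal drift. Passing tests therefore
demonstrate the *mechanics* of the optimization and pipeline, not
clinical validity on real social-media text.

## Study configurations and numerical choices

Chosen once, documented here:

* **Reduced-scale federated text study** (`corpus_study()`): 2,000 users,
  10 devices (IID), 80/20 stratified split, vocabulary 500, 40 signal
  tokens at strength 1.2, logistic stand-in with $l_2 = 10^{-4}$,
  $\gamma = 0.3$, minibatch 16; asynchronous runs use $T = 150$ global
  epochs at $v = 2$, FedAvg 30 rounds with full participation. Sequence
  length for CNN runs defaults to a few hundred tokens — corpus-specific
  constants of the original application (e.g. a 27,941-token
  concatenation length at $d = 300$) are configuration, never hard-coded.
* **Convex benchmark**: four local quadratics
  $F_i(w) = \tfrac12 (w - c_i)^\top A_i (w - c_i)$ with SPD $A_i$
  (eigenvalues $\geq 1$) and centers of spread 0.5; the global optimum is
  closed-form. Constant learning rates leave asynchronous SGD with an
  $O(\gamma)$ noise floor from device heterogeneity, so convex
  convergence runs use the diminishing schedule
  $\eta_t = \gamma\,t_0/(t + t_0)$ with $\gamma = 0.5, t_0 = 4$
  (effective rate $2/(t+4)$, satisfying the usual $a\mu > 1$ condition).
  The algorithm-path default remains a constant rate. The final iterate
  of a $1/t$-rate run still fluctuates at the scale of the last step
  size, so convergence is assessed by the best gap reached within the
  update budget (the final iterate is additionally checked under the
  suite's fixed seed).
* **Privacy-noise study**: common random numbers across $\beta$ (same
  data, schedule and gate draws; only the injected noise differs), mean
  over 3 seeds. At this scale the accuracy differences between
  $\beta \leq 10^{-2}$ magnitudes sit near the Monte-Carlo resolution of
  3 seeds × 400 test users; the degradation at $\beta = 0.05$ is the
  robust signal.
* **Ties and degenerate inputs**: simultaneous arrivals resolve by device
  id; a fully closed gate raises an explicit stall error after a
  configurable number of consecutive drops; constant feature columns
  min-max-normalize to 0; out-of-range values under pre-fitted
  normalization stats clip to $[0,1]$ with a warning; all-pad sequences
  are legal inputs and flow through the bias path only; metric ratios
  with zero denominators are `NA`, never silent zeros.
* **Rounding**: metrics are kept at full precision and displayed
  half-up at 2 decimals in percent (`round_half_up()`), matching how
  evaluation tables are conventionally printed (R's own `round()` is
  half-to-even and would disagree on boundary cases).

## A worked micro-example

```{r}
st <- corpus_study(seed = 1, n_users = 400, n_devices = 4)
ca <- cafed_run(st$model, st$shards, st$test, T = 40,
                config = cafed_config(v = 2, gamma = 0.3), seed = 1)
fa <- fedavg_run(st$model, st$shards, st$test, T = 10, gamma = 0.3, seed = 1)
glance(ca)
glance(fa)
communication_summary(ca)
epochs_to_accuracy(ca, 0.8)
```

One asynchronous upload produces one global epoch, while each FedAvg
round costs one upload per participant; `compare_runs()` and
`plot_convergence(..., x_axis = "uploads")` put both on the
communication-matched axis.

```{r, fig.width = 6, fig.height = 3.5}
plot_convergence(cafed = ca, fedavg = fa, x_axis = "uploads")
```

## Known limitations

* Single-process virtual time: no real networking, stragglers beyond the
  delay distribution, device failures, or mid-round dropouts.
* The privacy mechanism is noise injection only — no $(\epsilon,
  \delta)$ accounting, clipping, or secure aggregation; $\beta$ is a
  magnitude knob, not a privacy budget.
* Pure-R training loops: fine at the shipped study scales, not meant for
  300-dimensional embeddings over tens of thousands of tokens.
* The convex-run learning-rate schedule and all study sizes above are the
  package's own calibration; they demonstrate qualitative properties
  (convergence, communication advantage, noise degradation), not any
  particular published accuracy.
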