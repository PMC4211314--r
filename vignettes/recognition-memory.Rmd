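---
title: "A hypergraph model of recognition memory for lifelong categorical streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hypergraph model of recognition memory for lifelong categorical streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypermem)
```

## The problem

A cognitive agent living in a nonstationary world keeps meeting situations
it may or may not have seen before. The first step of acting on an event is
*familiarity judgment* — deciding old versus new — followed, when the event
is only partially observed, by *pattern completion*: filling in the missing
context from memory. Both are functions of recognition memory in the
dual-process tradition, and both must work *incrementally*: events arrive
one at a time, the alphabet of each attribute grows over a lifetime, and
re-training from scratch is not an option.

`hypermem` implements an associative memory for this setting. Events are
low-dimensional multivariate categorical records — think of a phone log
with time of day, cell tower, place, application, contact, call direction,
call type and duration class. The memory is content-addressable: events are
stored as they are, subsampled into overlapping fragments, and recognition
emerges from how fragments of a probe reconnect through the store.

## The model

### Encoding

An event instance $X = (x_1, \dots, x_d)$ is subsampled into *hyperedges*:
subsets of attribute–value pairs of order $k$, one anchored at each
attribute position. With a **ring** topology (contextual data with no
serial order) the edge at anchor $t$ covers the contiguous window
$t, t+1, \dots, t+k_t-1$ with indices wrapping modulo $d$, so one instance
yields $d$ edges forming a closed cycle. A **line** topology (serial data,
e.g. letter strings) anchors edges only where the window fits, giving an
open chain. Three sampling modes are supported (`edge_config()`): a fixed
order $k$; a *random order* drawn uniformly from $\{r_1..r_2\}$ per anchor
on every sampling call; and a *random combination* which keeps the anchor
attribute but draws the remaining $k-1$ attributes uniformly without
replacement.

Edges accumulate across instances into a layered *hypernetwork*. An edge's
identity is the triple (anchor, attribute set, values); re-encountered
edges are deduplicated, and every pair of edges at adjacent anchors sampled
from the same pass is joined by a *link* whose co-occurrence count
accumulates. The count $l_{ij}$ maps to a weight through a half sigmoid

$$\varphi_{ij} = \frac{2}{1 + e^{-l_{ij}/C}} - 1,$$

the affine rescaling of the logistic that is zero at no evidence, strictly
increasing, and saturating at 1. Only the qualitative constraints of this
curve (half sigmoid, maximum 1.0, monotone slope) are dictated by the
model; this closed form is the unique logistic rescaling satisfying them
and is the package's chosen realization. The slope constant $C$ stretches
the curve — a larger $C$ slows saturation, preserving resolution between
often-repeated links. The default $C = 10$ keeps single observations at
$\varphi \approx 0.05$ while links seen tens of times approach 1; it is a
configurable default, chosen to avoid early convergence.

Nothing is ever deleted. Memory decay (forgetting, aging) is deliberately
out of scope, which makes one property exact rather than statistical: **an
encoded instance is always judged old** — the model produces false alarms
but never misses.

### Scale

With alphabet sizes $C_1, \dots, C_d$ the instance space is $\prod_i C_i$,
while the anchored order-$k$ edge space is only
$\sum_{t} \prod_{i=t}^{t+k-1} C_i$ (`capacity_bound()`). In the uniform
case the ratio collapses to $d\,C^{k-d}$, far below 1 whenever $k < d$: the
store grows much more slowly than the space of events it can represent,
which is what makes lifelong accumulation feasible.

### Judgment

A probe is subsampled into edges exactly like an encoding pass. A stored
edge at the same anchor is *activated* when, over the attributes the two
edges share and the probe observes, at least one value matches
(strictly more than `n_m`, default 0) and none mismatch; attributes absent
from either edge, or missing in the probe, are not compared. The probe is
judged **old** exactly when some selection of one activated edge per anchor
is joined by stored links into a full chain — closed around the ring, or
spanning the line. The package enumerates these routes by backtracking over
anchors with link-adjacency pruning (exact, worst-case exponential;
a cap, default `max_routes = 10000`, guards pathological stores and is
flagged in the output when hit).

Because subsets are shared between instances, chains can recombine
fragments of different events into a route that was never encoded as a
whole — a *false alarm*, and deliberately so: the model treats such
confusions as the signature of subset-based familiarity. Their frequency
is governed by the *connectivity* (links per edge): low orders produce few,
densely shared edges and high connectivity; high orders produce many
specific edges and low connectivity.

### Similarity and ROC

The binary verdict is complemented by a graded strength: the sum of link
weights along a route, maximized over routes. For probes with no closed
route the best *open* chain is scored, with inactivated adjacencies
contributing zero weight (on a ring, every rotation of the anchor order is
swept, which covers all open chains exactly). Sweeping a threshold over
this similarity yields ROC curves (`roc_curve()`) in the signal-detection
sense; the sum is not normalized by route length, so similarity scales are
comparable only within one topology and dimension.

### Pattern completion

A partial probe (at least one observed and one missing attribute) follows
the same activation-and-route mechanics with two refinements. First, the
selected edges must be mutually consistent — any attribute covered by two
selected edges must carry one value — and must agree with the probe's
observed values; without this a "completion" could contradict itself.
Second, a probe edge that covers *no* observed attribute carries no
evidence: it cannot activate any particular stored edge, but neither
should it veto reconstruction, so its anchor is left unconstrained and its
slot in the route is filled from memory subject to the link and
consistency requirements. This reading is what produces the
characteristic tradeoff — low orders, with their dense connectivity,
complete best — and it matters in practice: with $d = 8$, three masked
attributes and $k = 2$, most masks leave some window fully hidden, and a
veto rule would cap completeness near 29% and invert the tradeoff.
Every route then induces a completion (observed values plus the values
read off its edges); `complete` records whether any exists, `expected`
whether the true original is among them.

### Study duration

Repetition acts on both sides of the memory. Encoding the same instance
`repetitions` times re-samples edges each pass; under random modes this
enriches the store (expected distinct edges per anchor grow as
$2 - 2^{1-r}$ for $r$ passes over two candidate orders), raising
connectivity and completion at the cost of more false alarms. Judging a
probe `observations` times re-samples probe edges and combines verdicts by
*unanimity*: old only if every observation says old. Unanimity is the only
aggregation consistent with the no-miss guarantee — a truly encoded probe
is old under every sampling, so repeated observation can only retract
false alarms. Majority voting could flip a truly old probe and is
rejected.

## The synthetic stream generator

The package ships a generator (`stream_spec()`, `generate_stream()`)
emulating the statistical structure of long-horizon behavioural logs, so
every harness runs without any external data. It reproduces three
phenomena:

* **routine repetition** — with probability `repeat_prob` an event exactly
  replays a past event, drawn with exponential recency weighting; the
  cumulative old ratio grows toward roughly one third. The defaults
  (`repeat_prob = 0.3`, first-section Dirichlet concentration 0.5) were
  calibrated once, over seeds 1–10, to land the 7,000-event old ratio
  inside [0.28, 0.38] (observed mean 0.332);
* **distribution drift** — each of `n_sections` sections re-draws every
  attribute's categorical distribution from a Dirichlet centred on the
  previous section's with total concentration `drift_strength` (default
  50; `Inf` freezes the distributions and makes sections exchangeable);
* **novel values** — fresh events inject never-seen tokens at a small
  per-section rate, peaking mid-stream, after which the newcomer keeps a
  2% share of its attribute's mass.

What the generator does **not** emulate: within-section temporal
autocorrelation (events inside a section are exchangeable apart from
replays), cross-attribute dependence beyond what replays induce, and any
semantic structure in the tokens. Passing tests on these streams therefore
demonstrates the mechanics of the memory under realistic marginals and
drift, not performance on any particular real dataset.

## Experiment harnesses

All harnesses follow the judge-then-encode protocol — an event is probed
against the memory of strictly earlier events before being encoded — and
derive per-event sub-seeds from the experiment seed, with separate
sub-streams for masking/completion, judgment and encoding. Paired settings
(1 vs 5 observations, sweeps over $k$) therefore share masks and encoding
draws exactly, so a manipulation affects only the stage it belongs to; in
particular the observation count provably cannot move completion rates or
the store itself.

* `incremental_judgment()` — per-section confusion counts and AUC along a
  stream;
* `configuration_sweep()` — scale, judgment and completion metrics across
  edge configurations (`default_config_grid()` reconstructs a
  representative 13-category grid: fixed $k = 2..7$, random orders
  $(2,3)..(2,6)$, random combinations $(2,4), (2,6), (2,7)$; the grid is a
  package choice, overridable);
* `completion_experiment()` — completeness and expectation with `n_missing`
  masked attributes (default 3 of 8);
* `study_duration_experiment()` — the encodings × observations grid;
* `online_offline_expectation()` — immediate versus interval-frozen
  updating; the offline store batch-encodes each block of `update_interval`
  events at its boundary, so probes inside a block face a stale memory.
  Under drift and novelty the online trajectory ends above the offline
  one; without drift the gap shrinks as blocks catch up.

The experiment harnesses evaluate the completion flags with first-hit
route searches (does any consistent closed route exist; does one
consistent with the truth exist) — exact answers that avoid enumerating
all routes; `complete_pattern()` itself returns the enumerated,
deduplicated completion set, subject to `max_routes`.

## Numerical choices and degenerate inputs

* Weights are recomputed from integer counts on demand; snapshots store
  counts only, so reloading under a different $C$ re-weights the store
  without information loss.
* In double precision $\varphi$ saturates to exactly 1.0 near counts of
  $34\,C$; the analytic strict monotonicity is asserted below that point
  and non-decrease beyond it.
* Connectivity of an empty network is defined as 0; ROC requires at least
  one old and one new label and section AUCs are `NA` where a section is
  single-class.
* Unseen probe tokens are coded to a sentinel that matches nothing, so a
  probe with a novel value activates no edge at the anchors observing it.
* Judgment and completion never mutate the store
  (`network_digest()` certifies this); the hypernetwork is a reference
  object, and `encode()` grows it in place.
* Test and vignette problem sizes are desk-scale by design: streams of
  500–7,000 events, $d = 8$, 10–50 seeds per property; each analytic
  identity is checked exactly, each stochastic regularity over a fixed
  seed grid.

## A worked micro-example

```{r example}
net <- hypernetwork(4, topology = "line")
cfg <- edge_config("fixed", k = 2)
encode(net, c("1", "2", "3", "4"), cfg)
encode(net, c("5", "2", "3", "6"), cfg)

# the recombination false alarm: never encoded, yet judged old
judge(net, c("1", "2", "3", "6"), cfg)

# completion of a partial probe recovers both consistent candidates
complete_pattern(net, c("1", "2", "3", NA), cfg,
                 truth = c("1", "2", "3", "4"))
```

## Limitations

Only low-dimensional categorical data are supported: numerical attributes
would need their own discretization, and for high-dimensional data the
ring/line anchoring leaves distant attributes only weakly coupled. There is
no forgetting — the no-miss guarantee is bought by monotone growth — and no
recollection (association across domains); both are explicit non-goals.
Route search is exact and can be exponential in adversarial stores; the
route cap bounds the work and is surfaced in the results.
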