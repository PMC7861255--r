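---
title: "Modelling message cascades with latent dual-process agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling message cascades with latent dual-process agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgcascade)
```

## The model

msgcascade simulates the spread of one message through a fixed social
network. The theoretical frame is a latent-process view of attitudes: an
external stimulus triggers an unobservable internal evaluation with an
affective and a cognitive component, and only the combined evaluation is
expressed as behaviour (here: forwarding). The simulator's job is to make
the consequences of that micro-model observable at the network scale.

**Messages** carry two unit-interval stimulus values, affective and
cognitive. Four archetypes are used: *affective* (0.8, 0.2), *cognitive*
(0.2, 0.8), *both* (0.8, 0.8) and *weak* (0.2, 0.2), so "strong" always
means 0.8 and "weak" 0.2.

**Agents** hold four latent unit-interval quantities: an affective attitude,
a cognitive attitude, a noticing threshold and a posting threshold. On
receipt of the message an agent

1. notices it iff the message's *affective* stimulus strictly exceeds its
   noticing threshold — attention is treated as purely affectively driven;
2. if noticed, computes the affective process value (mean of message
   stimulus and own attitude) and the cognitive process value (likewise),
   combines them by their *geometric* mean, and forwards iff that score
   strictly exceeds the posting threshold.

The geometric mean is the substantive choice: both processes must be
activated for behaviour to follow; a near-zero cognitive process vetoes
forwarding no matter how strong the affective one is. The arithmetic mean
inside each process has the opposite character — a strong message can
partly compensate a lukewarm attitude.

A forwarding agent averages its attitudes toward the message values
("adapting" its attitude) and sends the message to all neighbours exactly
once. Agents never re-send, and an agent's decision inputs never change
after its first evaluation, which has a useful structural consequence
discussed below.

## Agent parameterisation

Two agent models are provided.

*Random agents* draw all four latent fields independently from U(0,1).
Thresholds therefore have mean 0.5 and standard deviation
√(1/12) ≈ 0.289.

*Personality agents* are parameterised through Big Five traits. A
five-dimensional standard normal vector is drawn with correlation matrix

```{r}
big_five_correlation()
```

(`chol()`-factorised sampling; unit variances, since only the correlation
structure is specified) and squashed coordinate-wise onto (0,1) by
`(tanh(x)+1)/2`. Then

* noticing threshold = (U + (1 − openness)) / 2 — more open agents notice
  more easily;
* posting threshold = (U′ + conscientiousness) / 2 — more conscientious
  agents forward less readily;
* extraversion governs placement: agents ranked by extraversion are matched
  to nodes ranked by degree, so sociable agents occupy the well-connected
  positions.

The two uniform admixtures U, U′ are independent draws; whether the same
draw should feed both thresholds is genuinely open, and independence is the
weaker assumption. Agreeableness and neuroticism are sampled (so that the
full correlation structure, e.g. its effect on the openness–extraversion
coupling, is honoured) but do not enter the dynamics.

Relative to random agents, the personality thresholds are concentrated
around 0.5 (each is the mean of two spread-out components), which raises
the noticing probability for strong stimuli (P(t < 0.8) ≈ 0.91 vs 0.80)
and, together with extraversion-rank placement, is what makes personality
populations spread strong content further.

An alternative attitude distribution (`attitude_dist = "squashed_normal"`)
replaces the uniform attitudes by `squash(rnorm(n))`; note that the squashed
normal is *more* dispersed than U(0,1) (sd ≈ 0.31), because tanh saturates
beyond |z| = 1.

## Network environments

Six environments are supported, all undirected simple graphs; defaults
target a mean degree of 4 (edge count 2n) except where the generator fixes
it structurally.

| generator | parameters | edges |
|---|---|---|
| Erdős–Rényi G(n,m) | m = 2n | exactly m |
| Barabási–Albert | 1 edge per new node, grown from one node | n − 1 (a tree) |
| Watts–Strogatz | k = 4, β = 0.1 | nk/2 |
| static scale-free | α = 2, weights i^(−1/(α−1)) | exactly m = 2n |
| stochastic block model | 20 blocks | ≈ 0.8n (see below) |
| SNAP edge list | — | as on disk |

β = 0.1 is the classic small-world regime (high clustering, short paths)
and α = 2 a common heavy-tail exponent; neither is pinned by theory here,
and both are exposed as configuration. At α = 2 the top-weight node is
extreme: its expected degree at n = 1000, m = 2000 is in the hundreds, so
the forced hub seed alone reaches a quarter of the network in one step —
worth remembering when comparing scale-free cells with others.

The SBM recipe: block sizes are proportional to 20 uniform draws
(largest-remainder rounding); the symmetric weight matrix has diagonal
entries U(0.01, 0.05) × block size and off-diagonal entries
U(0.0001, 0.01), with 60% of off-diagonal pairs zeroed. Entries are read as
expected per-node neighbour counts between blocks and converted to per-pair
Bernoulli probabilities (averaging the two directional rates, which differ
slightly because block sizes do). Under this convention the expected mean
degree is ≈ 1.6, the graph is almost always disconnected (that is the
point of the zeroed blocks), and the expected edge count at n = 1000 is
≈ 800. Community count is reported as the number of connected components
(a Louvain-based count is available behind `method = "modularity"`), which
is the reading consistent with "communities" produced by deliberate
disconnection; a BA tree has exactly one.

Vertex centrality for seeding is degree centrality (the cheapest reading of
"opinion leader"; betweenness is available as an option), ties broken by
smallest id.

## The cascade engine

Stepping is synchronous: all pending senders deliver simultaneously, and
simultaneous deliveries to one agent count as a single receipt. States are
absorbing (unaware → ignored / declined / pending → sent), so the three
cumulative series (received, noticed, forwarded) are non-decreasing and
nested by construction. The seed is counted in all three.

Two policies are deliberately *neutral* and exist as explicit options only
so their neutrality can be asserted:

* **Evaluation policy.** Agents are evaluated on first receipt only. Since
  thresholds and (for non-forwarders) attitudes never change, re-evaluating
  an ignored or declined agent on every later receipt returns the same
  decision; `evaluate_on = "every"` implements it and the tests assert
  trajectory identity.
* **Adaptation rule.** Attitude adaptation happens only at forwarding time,
  and a forwarding agent never evaluates again, so the rule (averaging,
  overwriting, or none) cannot alter any trajectory. Averaging is the
  default because it is the same operator the process evaluation uses.

This also yields an independent correctness oracle: the final forwarder set
equals the connected cluster, containing the seed, of agents whose fixed
decision is "forward" in the subgraph they induce; receivers are that
cluster plus its neighbourhood. The test suite checks the engine against
this reachability characterisation on a thousand randomized small graphs.

Strict inequalities are used at both thresholds; under continuous draws
ties have probability zero, so the choice only matters for hand-built
cases. Each step retires at least one sender permanently, so a cascade on
n nodes terminates within n steps; the engine still takes a `max_steps`
cap as a guard and flags (never silently truncates) a capped run.

## Replication harness

A configuration cell is network × size × agent model × content ×
placement. Replicate *r* seeds R's RNG with `base_seed + r − 1` and then
draws a fresh network and a fresh population — the natural design when the
quantity of interest is the marginal spread distribution over both sources
of randomness. Sharing `base_seed` across cells gives matched initial
randomness (same network and population per replicate index for generated
networks), which sharpens between-cell contrasts. Everything is
reproducible byte-for-byte from the configuration.

The analysis model is an ordinary Gaussian GLM of the final sent count on
the three factors, dummy-coded against the random network, random agents
and weak content. With 1000-replicate cells the factor structure is heavily
overdetermined; the model is descriptive, not inferential machinery.

## What the generator emulates — and what it does not

The synthetic populations emulate: heterogeneous, statistically
independent attitudes; attention gated by affect; behaviour gated by a
conjunction of processes; trait correlations; and the degree–extraversion
association. They do *not* emulate: homophily or any attitude clustering on
the network; repeated exposure effects (a declined message stays declined);
competing messages; directed or weighted ties; or dynamic networks. Passing
tests therefore show that the implementation realises this model faithfully
— not that the model reproduces empirical sharing behaviour on real
platforms.

One quantitative consequence deserves emphasis because it bounds everything
the simulator can produce: for random agents the probability that a
receiver of a (0.8, 0.8) message forwards it is
P(U < 0.8) · P(score > U′) ≈ 0.8 × 0.64 ≈ 0.51, an upper bound on the
forwarded fraction that holds *even if every agent receives the message*.
Denominators matter correspondingly; the package reports both the fraction
of all agents and the fraction among receivers, per run and per summary.

## Problem sizes and numerical choices

The bundled tests run the full grid (five generated networks × two agent
models × four contents) at n = 1000 with 200 replicates per cell, sharing
the network and population draw across contents within a replicate (valid
because the engine consumes no RNG), plus 1000 small-graph oracle
instances; the whole suite completes in a few minutes on one core. Edge
cases pinned by tests include: degree-< 2 nodes contribute zero to average
clustering; empty graphs are rejected rather than defaulted; SNAP loading
drops self-loops and duplicate edges and reports the first malformed line;
and all generators are deterministic under a fixed seed.

## Known limitations

* The stated SBM affinity convention cannot simultaneously match an
  exact-edge-count target; its draws are sparse (mean degree ≈ 1.6) and
  highly disconnected by design.
* At α = 2 the static scale-free hub dominates; cells seeded there are
  sensitive to that single node's degree draw.
* The Barabási–Albert environment is a tree: every non-seed agent has
  exactly one path to the seed, so spread is limited by single-point
  failures — by far the most fragile topology in the set.
* Personality affects dynamics only through openness, conscientiousness
  and extraversion; the other two traits shape the sampling distribution
  but not behaviour.
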