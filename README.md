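# msgcascade

An agent-based simulator of how a single message spreads through an online
social network. It is aimed at computational social scientists who want to
study, under controlled conditions, how **content type**, **network
topology** and **user personality** interact to determine how far a piece of
content travels.

## The model

A message is a stimulus tuple *(m\_aff, m\_cog)* ∈ [0,1]², one of four
archetypes: *affective* (0.8, 0.2), *cognitive* (0.2, 0.8), *both*
(0.8, 0.8), *weak* (0.2, 0.2).

Each agent *i* holds latent attitudes *a\_aff, a\_cog* ~ U(0,1) and two
thresholds. On receiving the message it

1. **notices** it iff *m\_aff > t\_noticing*, and if so
2. **forwards** it iff the dual-process score exceeds the posting
   threshold:

   √( (m\_aff + a\_aff)/2 · (m\_cog + a\_cog)/2 ) > *t\_posting*.

A forwarding agent averages its attitudes toward the message values and
sends the message once to all neighbours; agents never re-send. The cascade
starts at the most degree-central node (an "opinion leader", which sends
unconditionally) and proceeds in synchronous steps until no active senders
remain.

Two agent models are available:

* **random** — both thresholds ~ U(0,1);
* **personality** — Big Five traits are drawn from a correlated
  multivariate normal (e.g. cor(extraversion, openness) = 0.41), squashed
  onto (0,1) by (tanh x + 1)/2; then
  *t\_noticing = (U + (1 − openness))/2*,
  *t\_posting = (U′ + conscientiousness)/2*, and agents are placed on nodes
  by extraversion rank (most extraverted on the best-connected node).

Networks: Erdős–Rényi G(n,m), Barabási–Albert (one edge per node, a tree),
Watts–Strogatz (k = 4, β = 0.1), static scale-free (α = 2), a stochastic
block model with 20 communities, or any SNAP-format edge list (e.g. the
Stanford ego-Facebook network).

## Worked example

```r
library(msgcascade)
set.seed(42)
g  <- generate_watts_strogatz(1000, k = 4, beta = 0.1)
ag <- make_agents(1000, "personality")
pl <- assign_agents(ag, g, "extraversion_rank")
run <- run_cascade(g, ag, pl, make_message("both"))
run
#> <cascade: 1000 agents, 17 steps; received 92.4%, noticed 85.1%,
#>  forwarded 62.4% of agents (67.5% of receivers)>
head(run$trajectory)
#>   step received noticed forwarded
#> 1    0        1       1         1
#> 2    1        9       7         5
#> 3    2       22      20        15
#> 4    3       49      44        33
#> 5    4       88      79        55
#> 6    5      133     122        83
```

One draw of a small-world network of 1,000 personality agents: the combined
affective-and-cognitive message reaches 92% of agents within 17 synchronous
steps, 85% attend to it, and 62% pass it on. The per-step table is the
cumulative trajectory (step 0 is the seeded opinion leader).

Replicated experiments use the seeded harness (replicate *r* reseeds with
`base_seed + r - 1`, with a fresh network and population each time):

```r
cfg <- simulation_config("watts_strogatz", n = 1000,
                         agent_model = "personality", content = "both",
                         replications = 50, base_seed = 1)
rec <- run_replications(cfg)
summarize_runs(rec)
#>                                                   config reps
#> 1 watts_strogatz/1000/personality/both/extraversion_rank   50
#>   mean_frac_received se_frac_received mean_frac_forwarded se_frac_forwarded
#> 1              0.898          0.00377                0.58           0.00386
```

`fit_glm(rec)` regresses the final sent count on agent model, network type
and content type (Gaussian GLM, reference levels: random network, random
agents, weak content).

A command line wraps the same functions:

```sh
Rscript inst/cli/msgcascade simulate --network watts_strogatz --n 1000 \
    --agents personality --content both --reps 10 --seed 7 --out results/
Rscript inst/cli/msgcascade netinfo --network barabasi_albert --n 1000 --seed 1
```

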