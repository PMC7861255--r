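# Independent oracle for the cascade engine: final states derived by graph
# reachability, not by stepping. An agent would forward iff it notices and
# its score beats the posting threshold; the forwarders are then exactly the
# connected cluster of would-forward nodes (plus the unconditional seed) that
# contains the seed in the subgraph induced by those nodes; receivers are the
# forwarders and their neighbours; noticers are the receivers that notice.
oracle_final_sets <- function(g, agents, placement, msg, seed) {
  n <- igraph::vcount(g)
  ag <- agents[placement, , drop = FALSE]
  would_notice <- msg$affective > ag$t_noticing
  score <- sqrt(((msg$affective + ag$a_affective) / 2) *
                  ((msg$cognitive + ag$a_cognitive) / 2))
  would_forward <- would_notice & score > ag$t_posting
  keep <- sort(unique(c(which(would_forward), seed)))
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  fwd <- keep[comp$membership == comp$membership[match(seed, keep)]]
  nb <- unlist(igraph::as_adj_list(g)[fwd], use.names = FALSE)
  received <- sort(unique(c(fwd, nb)))
  noticed <- sort(unique(c(seed, received[would_notice[received]])))
  list(forwarded = sort(fwd), received = received, noticed = noticed)
}

# hand-parameterised agent table (no RNG): explicit latent fields
fixed_agents <- function(a_aff, a_cog, t_not, t_post) {
  n <- length(a_aff)
  structure(
    data.frame(id = seq_len(n), a_affective = a_aff, a_cognitive = a_cog,
               t_noticing = t_not, t_posting = t_post,
               openness = NA_real_, conscientiousness = NA_real_,
               extraversion = NA_real_, agreeableness = NA_real_,
               neuroticism = NA_real_),
    model = "random", class = c("agent_population", "data.frame"))
}

random_instance <- function(n_max = 6) {
  n <- sample(2:n_max, 1)
  g <- igraph::sample_gnp(n, runif(1, 0.2, 0.9))
  agents <- fixed_agents(runif(n), runif(n), runif(n), runif(n))
  msg <- make_message(sample(names(content_types), 1))
  seed <- sample.int(n, 1)
  list(g = g, agents = agents, placement = seq_len(n), msg = msg,
       seed = seed)
}

# final node sets from a finished engine run's internal state
run_final_sets <- function(g, agents, placement, msg, seed, ...) {
  state <- init_cascade(g, agents, placement, msg, seed, ...)
  while (length(active_senders(state))) state <- cascade_step(state, msg)
  st <- state$node_state
  list(forwarded = which(st == 4L),
       received = which(st != 0L),
       noticed = which(st %in% c(2L, 4L)))
}
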