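.ST <- c(UNAWARE = 0L, RECEIVED_IGNORED = 1L, RECEIVED_DECLINED = 2L,
         PENDING_SEND = 3L, SENT = 4L)

#' Agent decision rules
#'
#' `notices()` tests whether the message's affective stimulus strictly
#' exceeds each agent's noticing threshold. `forwarding_score()` is the
#' dual-process evaluation: the affective process value is the mean of the
#' message's affective stimulus and the agent's affective attitude, likewise
#' for the cognitive process; both are combined by their geometric mean.
#' `decides_to_forward()` tests whether that score strictly exceeds the
#' posting threshold (it presumes the agent noticed the message).
#'
#' @param msg A `cascade_message`.
#' @param agents An `agent_population` (or any data frame with the agent
#'   columns); all three functions are vectorised over its rows.
#' @return `notices()` / `decides_to_forward()`: logical vector;
#'   `forwarding_score()`: numeric vector in `[0, 1]`.
#' @examples
#' ag <- data.frame(a_affective = 0.6, a_cognitive = 0.4,
#'                  t_noticing = 0.5, t_posting = 0.5)
#' forwarding_score(make_message("cognitive"), ag)  # sqrt(0.4 * 0.6)
#' @export
notices <- function(msg, agents) {
  msg$affective > agents$t_noticing
}

#' @rdname notices
#' @export
forwarding_score <- function(msg, agents) {
  sqrt(((msg$affective + agents$a_affective) / 2) *
         ((msg$cognitive + agents$a_cognitive) / 2))
}

#' @rdname notices
#' @export
decides_to_forward <- function(msg, agents) {
  notices(msg, agents) & forwarding_score(msg, agents) > agents$t_posting
}

#' Adapt an agent's attitude toward a message
#'
#' Applied when an agent decides to forward. The default rule replaces each
#' attitude by the mean of its old value and the message's stimulus (the same
#' averaging operator used in the process evaluation); `"overwrite"` copies
#' the message values; `"none"` leaves attitudes untouched. Thresholds are
#' never changed. Because agents forward at most once and are evaluated with
#' their pre-forwarding attitudes, the rule cannot alter the spread (see the
#' package vignette).
#'
#' @param agents Agent rows to adapt (vectorised).
#' @param msg A `cascade_message`.
#' @param rule `"average"`, `"overwrite"` or `"none"`.
#' @return `agents` with updated `a_affective`, `a_cognitive`.
#' @export
adapt_attitude <- function(agents, msg,
                           rule = c("average", "overwrite", "none")) {
  rule <- match.arg(rule)
  if (rule == "average") {
    agents$a_affective <- (agents$a_affective + msg$affective) / 2
    agents$a_cognitive <- (agents$a_cognitive + msg$cognitive) / 2
  } else if (rule == "overwrite") {
    agents$a_affective <- msg$affective
    agents$a_cognitive <- msg$cognitive
  }
  agents
}

#' Initialise a cascade
#'
#' Sets up the cascade state: the seed node is an unconditional sender
#' (it introduces the content, bypassing its own noticing and posting
#' checks) and is counted in the received, noticed and forwarded series;
#' every other node is unaware.
#'
#' @param g An igraph graph.
#' @param agents An `agent_population`, one agent per node.
#' @param placement Integer vector mapping node to agent id (see
#'   [assign_agents()]).
#' @param msg A `cascade_message`.
#' @param seed_node Vertex id of the initial sender.
#' @param adapt Attitude adaptation rule, see [adapt_attitude()].
#' @param evaluate_on `"first"` (default): each agent is evaluated on its
#'   first receipt only; `"every"`: agents that ignored or declined are
#'   re-evaluated on later receipts. Because every decision input is fixed
#'   per agent, the two policies yield identical trajectories.
#' @return A `cascade_state` object.
#' @export
init_cascade <- function(g, agents, placement, msg, seed_node,
                         adapt = c("average", "overwrite", "none"),
                         evaluate_on = c("first", "every")) {
  adapt <- match.arg(adapt)
  evaluate_on <- match.arg(evaluate_on)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  if (length(seed_node) != 1 || is.na(seed_node) || seed_node < 1 ||
      seed_node > n) {
    stop("seed node is not a vertex of the graph", call. = FALSE)
  }
  stopifnot(nrow(agents) == n, length(placement) == n)
  node_state <- rep(.ST[["UNAWARE"]], n)
  node_state[seed_node] <- .ST[["PENDING_SEND"]]
  structure(list(
    adj = igraph::as_adj_list(g),
    agents = as.data.frame(agents),
    placement = as.integer(placement),
    node_state = node_state,
    n_agents = n,
    step = 0L,
    received = 1L, noticed = 1L, forwarded = 1L,
    trajectory = list(c(step = 0L, received = 1L, noticed = 1L,
                        forwarded = 1L)),
    adapt = adapt,
    evaluate_on = evaluate_on
  ), class = "cascade_state")
}

#' Active senders of a cascade state
#'
#' @param state A `cascade_state`.
#' @return Integer vector of nodes in the pending-send state.
#' @export
active_senders <- function(state) {
  which(state$node_state == .ST[["PENDING_SEND"]])
}

#' Advance a cascade by one synchronous step
#'
#' Every active sender delivers the message to all its neighbours and moves
#' to the sent state. Each unaware recipient is evaluated exactly once
#' (simultaneous deliveries count as a single receipt): agents that do not
#' notice are marked received-ignored, agents that notice but decline are
#' marked received-declined, and agents that notice and decide to forward
#' adapt their attitude and become active senders of the next step. Agents
#' in any non-unaware state are unaffected by new deliveries (under the
#' `"every"` evaluation policy they are re-evaluated, with provably
#' identical outcomes).
#'
#' @param state A `cascade_state` with at least one active sender.
#' @param msg The `cascade_message` being spread.
#' @return The updated `cascade_state`.
#' @export
cascade_step <- function(state, msg) {
  frontier <- active_senders(state)
  if (!length(frontier)) {
    stop("cascade_step() called with no active senders", call. = FALSE)
  }
  st <- state$node_state
  st[frontier] <- .ST[["SENT"]]
  contacts <- unique(unlist(state$adj[frontier], use.names = FALSE))

  fresh <- contacts[st[contacts] == .ST[["UNAWARE"]]]
  cand <- if (state$evaluate_on == "first") fresh else {
    contacts[st[contacts] %in% c(.ST[["UNAWARE"]], .ST[["RECEIVED_IGNORED"]],
                                 .ST[["RECEIVED_DECLINED"]])]
  }

  if (length(cand)) {
    idx <- state$placement[cand]
    ag <- state$agents[idx, , drop = FALSE]
    ntc <- notices(msg, ag)
    fwd <- ntc & forwarding_score(msg, ag) > ag$t_posting
    st[cand[!ntc]] <- .ST[["RECEIVED_IGNORED"]]
    st[cand[ntc & !fwd]] <- .ST[["RECEIVED_DECLINED"]]
    st[cand[fwd]] <- .ST[["PENDING_SEND"]]
    if (any(fwd)) {
      state$agents[idx[fwd], ] <-
        adapt_attitude(state$agents[idx[fwd], , drop = FALSE], msg,
                       state$adapt)
    }
    is_fresh <- cand %in% fresh
    state$received <- state$received + sum(is_fresh)
    state$noticed <- state$noticed + sum(ntc & is_fresh)
    state$forwarded <- state$forwarded + sum(fwd)
  }

  state$node_state <- st
  state$step <- state$step + 1L
  state$trajectory[[length(state$trajectory) + 1L]] <-
    c(step = state$step, received = state$received,
      noticed = state$noticed, forwarded = state$forwarded)
  state
}

#' Run a full cascade
#'
#' Iterates [cascade_step()] from the seeded initial state until no active
#' senders remain (or a safety cap on steps is hit; since each agent sends
#' at most once the cap can only bind if set below the natural termination).
#'
#' @inheritParams init_cascade
#' @param seed_node Vertex id of the initial sender; defaults to the most
#'   degree-central node ([pick_seed()]).
#' @param max_steps Safety cap on steps (default: number of nodes).
#' @return A `cascade_run` object: a list with the per-step cumulative
#'   `trajectory` data frame (`step`, `received`, `noticed`, `forwarded`),
#'   `n_agents`, `n_steps`, the final counts, the final fractions of all
#'   agents (`frac_received`, `frac_noticed`, `frac_forwarded`), the
#'   `forwarded_among_received` ratio, and the `capped` flag.
#' @examples
#' set.seed(7)
#' g <- generate_watts_strogatz(200, 4, 0.1)
#' ag <- make_agents(200, "random")
#' run <- run_cascade(g, ag, assign_agents(ag, g), make_message("both"))
#' run$frac_forwarded
#' @export
run_cascade <- function(g, agents, placement, msg,
                        seed_node = pick_seed(g),
                        max_steps = igraph::vcount(g),
                        adapt = c("average", "overwrite", "none"),
                        evaluate_on = c("first", "every")) {
  stopifnot(max_steps >= 1)
  state <- init_cascade(g, agents, placement, msg, seed_node,
                        adapt = adapt, evaluate_on = evaluate_on)
  while (length(active_senders(state)) && state$step < max_steps) {
    state <- cascade_step(state, msg)
  }
  capped <- length(active_senders(state)) > 0
  traj <- as.data.frame(do.call(rbind, state$trajectory))
  n <- state$n_agents
  structure(list(
    trajectory = traj,
    n_agents = n,
    n_steps = state$step,
    final_received = state$received,
    final_noticed = state$noticed,
    final_forwarded = state$forwarded,
    frac_received = state$received / n,
    frac_noticed = state$noticed / n,
    frac_forwarded = state$forwarded / n,
    forwarded_among_received = state$forwarded / state$received,
    capped = capped
  ), class = "cascade_run")
}

#' @export
print.cascade_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<cascade: %d agents, %d steps; received %.1f%%, noticed %.1f%%, ",
    "forwarded %.1f%% of agents (%.1f%% of receivers)%s>\n"),
    x$n_agents, x$n_steps, 100 * x$frac_received, 100 * x$frac_noticed,
    100 * x$frac_forwarded, 100 * x$forwarded_among_received,
    if (x$capped) "; step cap hit" else ""))
  invisible(x)
}

#' Serialise a cascade trajectory to CSV
#'
#' One row per step with the cumulative counts and the corresponding
#' fractions of all agents; the run-level summary is available from the
#' `cascade_run` object itself.
#'
#' @param run A `cascade_run`.
#' @param path File path.
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "cascade_run"))
  d <- run$trajectory
  d$frac_received <- d$received / run$n_agents
  d$frac_noticed <- d$noticed / run$n_agents
  d$frac_forwarded <- d$forwarded / run$n_agents
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
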