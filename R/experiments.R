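.NETWORKS <- c("random", "barabasi_albert", "watts_strogatz", "scale_free",
               "sbm", "facebook")

#' Build a simulation configuration
#'
#' Bundles and validates everything one experimental cell needs: the network
#' specification, the agent model, the message content, the placement mode
#' and the replication/seed policy. Replicate `r` of any configuration uses
#' the RNG seed `base_seed + r - 1`, so configurations sharing a `base_seed`
#' receive matched initial randomness; a fresh network and population is
#' generated for every replicate.
#'
#' @param network One of `"random"`, `"barabasi_albert"`,
#'   `"watts_strogatz"`, `"scale_free"`, `"sbm"`, `"facebook"`.
#' @param n Number of agents / nodes (default 1000).
#' @param agent_model `"random"` or `"personality"`.
#' @param content Message archetype label.
#' @param assignment Placement mode; default `"extraversion_rank"` for
#'   personality agents, `"identity"` otherwise.
#' @param replications Number of Monte-Carlo replicates (default 1000).
#' @param base_seed Base RNG seed (default 1).
#' @param max_steps Step cap per cascade (default `n`).
#' @param ws_k,ws_beta Watts-Strogatz lattice degree and rewiring
#'   probability.
#' @param sf_alpha Static scale-free exponent.
#' @param target_edges Edge count for the Erdos-Renyi and scale-free
#'   generators (default `2 n`).
#' @param sbm_blocks Number of stochastic-block-model communities.
#' @param facebook_path Path to a SNAP edge list (required when
#'   `network = "facebook"`); when the file holds more than `n` nodes each
#'   replicate uses a fresh induced subsample of `n` nodes.
#' @param attitude_dist Attitude distribution, see [make_agents()].
#' @param adapt,evaluate_on Cascade engine policies, see [run_cascade()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(network, n = 1000,
                              agent_model = c("random", "personality"),
                              content = "both",
                              assignment = NULL,
                              replications = 1000,
                              base_seed = 1,
                              max_steps = NULL,
                              ws_k = 4, ws_beta = 0.1,
                              sf_alpha = 2,
                              target_edges = NULL,
                              sbm_blocks = 20,
                              facebook_path = NULL,
                              attitude_dist = "uniform",
                              adapt = "average",
                              evaluate_on = "first") {
  network <- match.arg(network, .NETWORKS)
  agent_model <- match.arg(agent_model)
  if (!content %in% names(content_types)) {
    stop("unknown content label; valid labels: ",
         paste(names(content_types), collapse = ", "), call. = FALSE)
  }
  if (is.null(assignment)) {
    assignment <- if (agent_model == "personality") "extraversion_rank"
                  else "identity"
  }
  assignment <- match.arg(assignment, c("identity", "extraversion_rank"))
  if (assignment == "extraversion_rank" && agent_model != "personality") {
    stop("extraversion_rank placement requires personality agents",
         call. = FALSE)
  }
  if (network == "facebook" && is.null(facebook_path)) {
    stop("facebook network requires facebook_path", call. = FALSE)
  }
  stopifnot(replications >= 1, n >= 2)
  cfg <- list(network = network, n = as.integer(n),
              agent_model = agent_model, content = content,
              assignment = assignment,
              replications = as.integer(replications),
              base_seed = as.integer(base_seed),
              max_steps = if (is.null(max_steps)) as.integer(n)
                          else as.integer(max_steps),
              ws_k = ws_k, ws_beta = ws_beta, sf_alpha = sf_alpha,
              target_edges = if (is.null(target_edges)) 2L * as.integer(n)
                             else as.integer(target_edges),
              sbm_blocks = as.integer(sbm_blocks),
              facebook_path = facebook_path,
              attitude_dist = attitude_dist,
              adapt = adapt, evaluate_on = evaluate_on)
  cfg$id <- paste(cfg$network, cfg$n, cfg$agent_model, cfg$content,
                  cfg$assignment, sep = "/")
  structure(cfg, class = "simulation_config")
}

#' Seed of one replicate
#'
#' The documented seed policy: replicate `r` (1-based) of a configuration
#' with base seed `s` uses `set.seed(s + r - 1)`.
#'
#' @param base_seed Integer base seed.
#' @param r Replicate index.
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, r) {
  as.integer(base_seed) + as.integer(r) - 1L
}

.build_network <- function(cfg, fb_graph = NULL) {
  switch(cfg$network,
    random = generate_random_graph(cfg$n, cfg$target_edges),
    barabasi_albert = generate_barabasi_albert(cfg$n),
    watts_strogatz = generate_watts_strogatz(cfg$n, cfg$ws_k, cfg$ws_beta),
    scale_free = generate_scale_free(cfg$n, cfg$target_edges, cfg$sf_alpha),
    sbm = generate_sbm(cfg$n, cfg$sbm_blocks)$graph,
    facebook = {
      if (igraph::vcount(fb_graph) > cfg$n) {
        induced_subsample(fb_graph, cfg$n)
      } else {
        fb_graph
      }
    })
}

#' Run the replicates of one configuration
#'
#' Executes `cfg$replications` independent cascades. Each replicate seeds
#' the RNG with [replicate_seed()], generates a fresh network and agent
#' population, places the agents, seeds the message at the most
#' degree-central node and runs the cascade to termination.
#'
#' @param cfg A `simulation_config`.
#' @param keep_trajectories If `TRUE` the long per-step trajectory table is
#'   attached as attribute `"trajectories"`.
#' @return A data frame (one row per replicate) with the configuration
#'   identifiers, replicate index and seed, network metrics (edges, average
#'   clustering, components), cascade length and the final counts and
#'   fractions.
#' @export
run_replications <- function(cfg, keep_trajectories = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  fb <- if (cfg$network == "facebook") load_edge_list(cfg$facebook_path)
  msg <- make_message(cfg$content)
  rows <- vector("list", cfg$replications)
  trajs <- if (keep_trajectories) vector("list", cfg$replications)

  for (r in seq_len(cfg$replications)) {
    seed <- replicate_seed(cfg$base_seed, r)
    set.seed(seed)
    g <- tryCatch(.build_network(cfg, fb), error = function(e) {
      stop(sprintf("network generation failed for %s (replicate %d): %s",
                   cfg$id, r, conditionMessage(e)), call. = FALSE)
    })
    agents <- make_agents(igraph::vcount(g), cfg$agent_model,
                          attitude_dist = cfg$attitude_dist)
    placement <- assign_agents(agents, g, cfg$assignment)
    run <- run_cascade(g, agents, placement, msg,
                       seed_node = pick_seed(g),
                       max_steps = cfg$max_steps,
                       adapt = cfg$adapt, evaluate_on = cfg$evaluate_on)
    rows[[r]] <- data.frame(
      config = cfg$id, network = cfg$network, n = igraph::vcount(g),
      agent_model = cfg$agent_model, content = cfg$content,
      assignment = cfg$assignment, replicate = r, seed = seed,
      edges = igraph::ecount(g), avg_clustering = avg_clustering(g),
      components = count_communities(g),
      n_steps = run$n_steps,
      final_received = run$final_received,
      final_noticed = run$final_noticed,
      final_forwarded = run$final_forwarded,
      frac_received = run$frac_received,
      frac_noticed = run$frac_noticed,
      frac_forwarded = run$frac_forwarded,
      forwarded_among_received = run$forwarded_among_received,
      capped = run$capped)
    if (keep_trajectories) {
      tr <- run$trajectory
      tr$config <- cfg$id
      tr$replicate <- r
      trajs[[r]] <- tr
    }
  }
  out <- do.call(rbind, rows)
  if (keep_trajectories) {
    attr(out, "trajectories") <- do.call(rbind, trajs)
  }
  out
}

#' Summarise replicate records
#'
#' Per configuration: the mean and standard error (sd / sqrt(reps)) of the
#' final fractions of agents that received and forwarded the message. When a
#' long trajectory table is supplied, per-step means and standard errors are
#' returned instead.
#'
#' @param records Replicate records from [run_replications()] or
#'   [sweep_configs()].
#' @param trajectories Optional long trajectory table (attribute
#'   `"trajectories"` of [run_replications()] output).
#' @return A data frame of summary rows.
#' @export
summarize_runs <- function(records, trajectories = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no records to summarise", call. = FALSE)
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  if (!is.null(trajectories)) {
    n_by_cfg <- tapply(records$n, records$config, max)
    agg <- do.call(rbind, lapply(
      split(trajectories, list(trajectories$config, trajectories$step),
            drop = TRUE),
      function(d) {
        n <- n_by_cfg[[d$config[1]]]
        data.frame(config = d$config[1], step = d$step[1],
                   reps_reaching_step = nrow(d),
                   mean_frac_received = mean(d$received / n),
                   se_frac_received = se(d$received / n),
                   mean_frac_forwarded = mean(d$forwarded / n),
                   se_frac_forwarded = se(d$forwarded / n))
      }))
    rownames(agg) <- NULL
    return(agg[order(agg$config, agg$step), ])
  }
  agg <- do.call(rbind, lapply(split(records, records$config), function(d) {
    data.frame(config = d$config[1], reps = nrow(d),
               mean_frac_received = mean(d$frac_received),
               se_frac_received = se(d$frac_received),
               mean_frac_forwarded = mean(d$frac_forwarded),
               se_frac_forwarded = se(d$frac_forwarded))
  }))
  rownames(agg) <- NULL
  agg
}

#' Run a grid of configurations
#'
#' Concatenates the replicate records of several configurations. When
#' `out_dir` is given each configuration's records are written to (and, if
#' already present, re-read from) a per-configuration CSV, making long
#' sweeps resumable.
#'
#' @param grid A list of `simulation_config` objects with distinct ids.
#' @param out_dir Optional directory for per-configuration result files.
#' @return A long data frame of replicate records.
#' @export
sweep_configs <- function(grid, out_dir = NULL) {
  stopifnot(length(grid) >= 1)
  ids <- vapply(grid, function(cfg) cfg$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate configuration ids in grid: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- lapply(grid, function(cfg) {
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0(gsub("/", "_", cfg$id), ".csv"))
      if (file.exists(f)) return(read_runs(f))
      rec <- run_replications(cfg)
      write_runs(rec, f)
      rec
    } else {
      run_replications(cfg)
    }
  })
  do.call(rbind, res)
}

#' Fit a general linear model to final spread
#'
#' Regresses the final count of sending agents on agent model, network type
#' and content type (dummy-coded; Gaussian family with identity link, i.e.
#' ordinary least squares, by default). Reference levels are the random
#' network, the random agent model and the weak content.
#'
#' @param records Replicate records covering at least two levels of every
#'   factor in the formula.
#' @param formula Model formula (default
#'   `final_forwarded ~ agent_model + network + content`).
#' @param family A [stats::family] object (default `gaussian()`).
#' @return An object of class `cascade_glm`: a list with the coefficient
#'   table (`estimate`, `std_error`, `t_value`, `p_value`), `null_deviance`,
#'   `deviance`, `df_null`, `df_residual` and `aic`.
#' @export
fit_glm <- function(records,
                    formula = final_forwarded ~ agent_model + network +
                      content,
                    family = stats::gaussian()) {
  d <- as.data.frame(records)
  for (fac in c("agent_model", "network", "content")) {
    if (!fac %in% names(d)) next
    if (!all(is.na(d[[fac]]))) d[[fac]] <- factor(d[[fac]])
  }
  refs <- c(agent_model = "random", network = "random", content = "weak")
  vars <- all.vars(formula[[3]])
  for (fac in vars) {
    if (!fac %in% names(d)) {
      stop("records lack predictor column: ", fac, call. = FALSE)
    }
    if (is.factor(d[[fac]])) {
      if (nlevels(d[[fac]]) < 2) {
        stop("factor '", fac, "' has fewer than two levels; ",
             "the model would be rank deficient", call. = FALSE)
      }
      if (fac %in% names(refs) && refs[[fac]] %in% levels(d[[fac]])) {
        d[[fac]] <- stats::relevel(d[[fac]], refs[[fac]])
      }
    }
  }
  fit <- stats::glm(formula, data = d, family = family)
  cf <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              std_error = cf[, 2], t_value = cf[, 3],
                              p_value = cf[, 4], row.names = NULL),
    null_deviance = fit$null.deviance,
    deviance = fit$deviance,
    df_null = fit$df.null,
    df_residual = fit$df.residual,
    aic = stats::AIC(fit)
  ), class = "cascade_glm")
}

#' @export
print.cascade_glm <- function(x, ...) {
  cat("General linear model of final sent count\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("null deviance %.6g on %d df; residual deviance %.6g on %d df; AIC %.6g\n",
              x$null_deviance, x$df_null, x$deviance, x$df_residual, x$aic))
  invisible(x)
}

.RUNS_VERSION <- "# msgcascade-runs v1"
.RUNS_SCHEMA <- c("config", "network", "n", "agent_model", "content",
                  "assignment", "replicate", "seed", "edges",
                  "avg_clustering", "components", "n_steps",
                  "final_received", "final_noticed", "final_forwarded",
                  "frac_received", "frac_noticed", "frac_forwarded",
                  "forwarded_among_received", "capped")

#' Write or read replicate records
#'
#' CSV round-trip for the replicate record table. Files start with a
#' version comment line; reading rejects files whose version line or column
#' set does not match the current schema.
#'
#' @param records Replicate records ([run_replications()] output, possibly
#'   empty).
#' @param path File path.
#' @param timestamp Optional timestamp comment written after the version
#'   line (`NULL` to omit).
#' @return `read_runs()` returns the record data frame.
#' @export
write_runs <- function(records, path, timestamp = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(
      matrix(nrow = 0, ncol = length(.RUNS_SCHEMA),
             dimnames = list(NULL, .RUNS_SCHEMA)))
  }
  if (!all(.RUNS_SCHEMA %in% names(records))) {
    stop("records lack required columns: ",
         paste(setdiff(.RUNS_SCHEMA, names(records)), collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.RUNS_VERSION, con)
  if (!is.null(timestamp)) writeLines(paste("# generated:", timestamp), con)
  utils::write.csv(records[, .RUNS_SCHEMA], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_runs
#' @export
read_runs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (!identical(first, .RUNS_VERSION)) {
    stop("not a msgcascade runs file (missing version line): ", path,
         call. = FALSE)
  }
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = c(capped = "logical"))
  if (!identical(names(d), .RUNS_SCHEMA)) {
    stop("runs file schema mismatch; missing or unexpected columns: ",
         paste(union(setdiff(.RUNS_SCHEMA, names(d)),
                     setdiff(names(d), .RUNS_SCHEMA)), collapse = ", "),
         call. = FALSE)
  }
  d
}
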