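#' Network generators
#'
#' Six network environments are available, all returned as undirected simple
#' igraph graphs with vertex ids `1..n`:
#'
#' * `generate_random_graph()`: uniform G(n, m) Erdos-Renyi graph with
#'   exactly `m` edges (default `2n`).
#' * `generate_barabasi_albert()`: preferential attachment growing from a
#'   single node, one edge per new node, hence a tree with `n - 1` edges.
#' * `generate_watts_strogatz()`: ring lattice with `k` nearest neighbours,
#'   each edge rewired with probability `beta` avoiding self-loops and
#'   duplicate edges; exactly `n k / 2` edges.
#' * `generate_scale_free()`: the static scale-free model; node `i` carries
#'   weight `i^(-1/(alpha - 1))` and edges are sampled proportional to weight
#'   products until exactly `m` distinct simple edges exist.
#' * `generate_sbm()`: stochastic block model, see its own help page.
#' * [load_edge_list()]: a SNAP-format edge list from disk.
#'
#' All generators consume R's global RNG, so `set.seed()` makes them
#' deterministic.
#'
#' @param n Number of nodes.
#' @param m Number of edges.
#' @param k Even lattice degree (default 4).
#' @param beta Rewiring probability in `[0, 1]` (default 0.1).
#' @param alpha Power-law exponent, `> 1` (default 2).
#' @return An igraph graph.
#' @name netgen
NULL

#' @rdname netgen
#' @export
generate_random_graph <- function(n, m = 2 * n) {
  stopifnot(n >= 1, m >= 0)
  if (m > n * (n - 1) / 2) {
    stop("m exceeds the number of possible edges n(n-1)/2", call. = FALSE)
  }
  igraph::sample_gnm(n, m)
}

#' @rdname netgen
#' @export
generate_barabasi_albert <- function(n) {
  stopifnot(n >= 2)
  igraph::sample_pa(n, power = 1, m = 1, directed = FALSE)
}

#' @rdname netgen
#' @export
generate_watts_strogatz <- function(n, k = 4, beta = 0.1) {
  stopifnot(n >= 3, beta >= 0, beta <= 1)
  if (k %% 2 != 0 || k <= 0 || k >= n) {
    stop("k must be a positive even number smaller than n", call. = FALSE)
  }
  igraph::sample_smallworld(dim = 1, size = n, nei = k / 2, p = beta,
                            loops = FALSE, multiple = FALSE)
}

#' @rdname netgen
#' @export
generate_scale_free <- function(n, m = 2 * n, alpha = 2) {
  stopifnot(n >= 2, alpha > 1)
  if (m > n * (n - 1) / 2) {
    stop("m exceeds the number of possible edges n(n-1)/2", call. = FALSE)
  }
  w <- seq_len(n)^(-1 / (alpha - 1))
  igraph::sample_fitness(m, fitness.out = w, loops = FALSE, multiple = FALSE)
}

#' Stochastic block model with community structure
#'
#' Partitions `n` nodes into `n_blocks` communities whose sizes are
#' proportional to uniform random numbers (largest-remainder rounding so they
#' sum to `n`). The block weight matrix `W` has diagonal entries drawn from
#' `U(0.01, 0.05)` times the block size and off-diagonal entries from
#' `U(0.0001, 0.01)`, with 60% of the off-diagonal entries (symmetrically)
#' set to zero so that disconnected communities appear. `W[a, b]` is read as
#' the expected number of neighbours a node of block `a` has in block `b`;
#' edges are then sampled independently with the implied per-pair
#' probabilities.
#'
#' @param n Number of nodes.
#' @param n_blocks Number of communities (default 20).
#' @return A list with elements `graph` (igraph, nodes grouped by block) and
#'   `spec` (list with `n`, `n_blocks`, `block_sizes`, `weight_matrix`).
#' @export
generate_sbm <- function(n, n_blocks = 20) {
  stopifnot(n_blocks >= 2)
  if (n_blocks > n) stop("n_blocks may not exceed n", call. = FALSE)

  u <- stats::runif(n_blocks)
  raw <- n * u / sum(u)
  sizes <- as.integer(floor(raw))
  short <- n - sum(sizes)
  if (short > 0) {
    top <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[top] <- sizes[top] + 1L
  }

  W <- matrix(0, n_blocks, n_blocks)
  diag(W) <- stats::runif(n_blocks, 0.01, 0.05) * sizes
  up <- which(upper.tri(W))
  W[up] <- stats::runif(length(up), 1e-4, 0.01)
  zeroed <- sample(up, floor(0.6 * length(up)))
  W[zeroed] <- 0
  W[lower.tri(W)] <- t(W)[lower.tri(W)]

  # expected-neighbour counts -> per-pair Bernoulli probabilities; with
  # unequal block sizes the two directional rates W[a,b]/size_b and
  # W[b,a]/size_a differ slightly, so their mean is used
  P <- (sweep(W, 2, pmax(sizes, 1), "/") +
          sweep(W, 1, pmax(sizes, 1), "/")) / 2
  diag(P) <- diag(W) / pmax(sizes - 1, 1)
  P[P > 1] <- 1
  g <- igraph::sample_sbm(n, pref.matrix = P, block.sizes = sizes)
  list(graph = g,
       spec = list(n = n, n_blocks = n_blocks, block_sizes = sizes,
                   weight_matrix = W))
}

#' Read or write a SNAP-format edge list
#'
#' The SNAP plain-text format holds one undirected edge per line as two
#' whitespace-separated integer node ids (0-based, no header). On reading,
#' duplicate edges and self-loops are dropped and ids are compacted to
#' vertices `1..n` in order of first appearance.
#'
#' @param path File path.
#' @param g An igraph graph (for writing; vertex `i` is written as id
#'   `i - 1`).
#' @return `load_edge_list()` returns an undirected simple igraph graph.
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty edge-list file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(vapply(toks, function(t) {
    length(t) != 2 || anyNA(suppressWarnings(as.integer(t)))
  }, logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d: '%s'",
                 keep[bad[1]], lines[keep[bad[1]]]), call. = FALSE)
  }
  a <- vapply(toks, function(t) as.integer(t[1]), integer(1))
  b <- vapply(toks, function(t) as.integer(t[2]), integer(1))
  ids <- unique(as.vector(rbind(a, b)))  # order of first appearance
  ai <- match(a, ids)
  bi <- match(b, ids)
  lo <- pmin(ai, bi)
  hi <- pmax(ai, bi)
  ok <- lo != hi & !duplicated(lo * (length(ids) + 1) + hi)
  igraph::make_graph(rbind(lo[ok], hi[ok]), n = length(ids),
                     directed = FALSE)
}

#' @rdname load_edge_list
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Induced subgraph on a uniform node sample
#'
#' Samples `n` nodes uniformly without replacement and returns the induced
#' subgraph with compacted vertex ids. Under uniform sampling an edge
#' survives with probability `n(n-1) / (N(N-1))`, so the expected edge count
#' is `m * n(n-1) / (N(N-1))`.
#'
#' @param g An igraph graph on `N` nodes.
#' @param n Sample size, `n <= N`.
#' @return An igraph graph on `n` nodes.
#' @export
induced_subsample <- function(g, n) {
  N <- igraph::vcount(g)
  stopifnot(n >= 1)
  if (n > N) stop("sample size exceeds the graph's node count", call. = FALSE)
  igraph::induced_subgraph(g, sample.int(N, n))
}

#' Structural metrics
#'
#' `avg_clustering()` is the mean local clustering coefficient over all
#' nodes, with nodes of degree < 2 contributing 0. `count_communities()`
#' counts connected components by default; `method = "modularity"` instead
#' counts Louvain modularity communities.
#'
#' @param g An igraph graph.
#' @param method `"components"` (default) or `"modularity"`.
#' @return A single number.
#' @export
avg_clustering <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' @rdname avg_clustering
#' @export
count_communities <- function(g, method = c("components", "modularity")) {
  method <- match.arg(method)
  switch(method,
         components = igraph::components(g)$no,
         modularity = length(igraph::cluster_louvain(g)))
}

#' Metrics row for a graph
#'
#' @param g An igraph graph.
#' @return A one-row data frame with `nodes`, `edges`, `avg_clustering`,
#'   `components`.
#' @export
network_metrics <- function(g) {
  data.frame(nodes = igraph::vcount(g), edges = igraph::ecount(g),
             avg_clustering = avg_clustering(g),
             components = count_communities(g))
}

#' Place agents on network nodes
#'
#' * `"identity"`: agent `i` lives on node `i`.
#' * `"extraversion_rank"`: agents sorted by extraversion are matched to
#'   nodes sorted by degree, so the most extraverted agent sits on the
#'   best-connected node; ties are broken by id.
#'
#' @param agents An `agent_population` with exactly one agent per node.
#' @param g An igraph graph.
#' @param mode Placement mode.
#' @return An integer vector `placement` with `placement[node] = agent id`.
#' @export
assign_agents <- function(agents, g,
                          mode = c("identity", "extraversion_rank")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(g)
  if (nrow(agents) != n) {
    stop("need exactly one agent per node: ", nrow(agents), " agents for ",
         n, " nodes", call. = FALSE)
  }
  if (mode == "identity") return(seq_len(n))
  if (anyNA(agents$extraversion)) {
    stop("extraversion_rank placement requires personality agents",
         call. = FALSE)
  }
  deg <- igraph::degree(g)
  node_rank <- order(-deg, seq_len(n))
  agent_rank <- order(-agents$extraversion, agents$id)
  placement <- integer(n)
  placement[node_rank] <- agents$id[agent_rank]
  placement
}

#' Pick the cascade seed node
#'
#' Returns the most central node: maximum degree by default (or maximum
#' betweenness), ties broken by smallest vertex id.
#'
#' @param g A non-empty igraph graph.
#' @param centrality `"degree"` (default) or `"betweenness"`.
#' @return A vertex id (integer in `1..n`).
#' @export
pick_seed <- function(g, centrality = c("degree", "betweenness")) {
  centrality <- match.arg(centrality)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  score <- switch(centrality,
                  degree = igraph::degree(g),
                  betweenness = igraph::betweenness(g))
  which.max(score)
}
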