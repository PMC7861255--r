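.TRAITS <- c("openness", "conscientiousness", "extraversion",
             "agreeableness", "neuroticism")

#' Build an agent population
#'
#' Constructs `n` agents with latent affective and cognitive attitudes and
#' the two behavioral thresholds. Two agent models are supported:
#'
#' * `"random"`: attitudes and both thresholds drawn independently from
#'   U(0, 1); no personality profile.
#' * `"personality"`: Big Five profiles sampled from the correlated
#'   multivariate normal (then squashed); the noticing threshold is the mean
#'   of a uniform draw and `1 - openness`, the posting threshold the mean of
#'   an independent uniform draw and conscientiousness. Attitudes are drawn
#'   as in the random model.
#'
#' All randomness flows through R's global RNG; call `set.seed()` first for
#' reproducible populations.
#'
#' @param n Number of agents.
#' @param model `"random"` or `"personality"`.
#' @param corr Trait correlation matrix for the personality model.
#' @param attitude_dist Distribution of the latent attitudes: `"uniform"`
#'   (default, U(0,1)) or `"squashed_normal"` (`squash(rnorm(n))`).
#' @return A data frame of class `agent_population` with columns `id`,
#'   `a_affective`, `a_cognitive`, `t_noticing`, `t_posting` and the five
#'   trait columns (NA for random agents). The agent model is stored in
#'   attribute `"model"`.
#' @examples
#' set.seed(42)
#' ag <- make_agents(4, "personality")
#' ag$t_noticing
#' @export
make_agents <- function(n, model = c("random", "personality"),
                        corr = big_five_correlation(),
                        attitude_dist = c("uniform", "squashed_normal")) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  model <- match.arg(model)
  attitude_dist <- match.arg(attitude_dist)
  n <- as.integer(n)

  draw_attitude <- function() {
    switch(attitude_dist,
           uniform = stats::runif(n),
           squashed_normal = squash(stats::rnorm(n)))
  }
  a_affective <- draw_attitude()
  a_cognitive <- draw_attitude()

  if (model == "random") {
    t_noticing <- stats::runif(n)
    t_posting <- stats::runif(n)
    traits <- as.data.frame(
      matrix(NA_real_, n, 5, dimnames = list(NULL, .TRAITS)))
  } else {
    traits <- sample_personalities(n, corr)
    t_noticing <- noticing_threshold(traits$openness)
    t_posting <- posting_threshold(traits$conscientiousness)
  }

  out <- cbind(
    data.frame(id = seq_len(n), a_affective = a_affective,
               a_cognitive = a_cognitive, t_noticing = t_noticing,
               t_posting = t_posting),
    traits)
  structure(out, model = model, class = c("agent_population", "data.frame"))
}

.AGENT_COLS <- c("id", "a_affective", "a_cognitive", "t_noticing",
                 "t_posting", .TRAITS)

#' Write or read an agent population as CSV
#'
#' The CSV holds one row per agent: id, the four latent fields, and the five
#' trait columns (empty for random agents). Round-trips losslessly.
#'
#' @param agents An `agent_population`.
#' @param path File path.
#' @return `read_agents()` returns an `agent_population`.
#' @export
write_agents <- function(agents, path) {
  stopifnot(inherits(agents, "agent_population"))
  utils::write.csv(as.data.frame(agents)[, .AGENT_COLS], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_agents
#' @export
read_agents <- function(path) {
  d <- utils::read.csv(path)
  if (!identical(names(d), .AGENT_COLS)) {
    stop("not an agent population file: expected columns ",
         paste(.AGENT_COLS, collapse = ", "), call. = FALSE)
  }
  model <- if (all(is.na(d$openness))) "random" else "personality"
  structure(d, model = model, class = c("agent_population", "data.frame"))
}
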