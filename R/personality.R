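#' Default Big Five trait correlation matrix
#'
#' The 5x5 correlation matrix among openness, conscientiousness,
#' extraversion, agreeableness and neuroticism used to sample personality
#' profiles. Off-diagonal values follow published population-level estimates
#' (e.g. extraversion-openness r = 0.41). The matrix is symmetric with unit
#' diagonal and is positive definite.
#'
#' @return A 5x5 numeric matrix with trait names as dimnames.
#' @export
big_five_correlation <- function() {
  M <- diag(5)
  dimnames(M) <- list(.TRAITS, .TRAITS)
  set <- function(a, b, v) {
    M[a, b] <<- v
    M[b, a] <<- v
  }
  set("extraversion", "agreeableness", 0.35)
  set("extraversion", "conscientiousness", 0.15)
  set("extraversion", "neuroticism", -0.24)
  set("extraversion", "openness", 0.41)
  set("agreeableness", "conscientiousness", 0.27)
  set("agreeableness", "neuroticism", -0.05)
  set("agreeableness", "openness", 0.22)
  set("conscientiousness", "neuroticism", -0.20)
  set("conscientiousness", "openness", 0.24)
  set("neuroticism", "openness", -0.09)
  M
}

.check_correlation <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != 5 || ncol(corr) != 5 ||
      !isTRUE(all.equal(corr, t(corr))) ||
      !isTRUE(all.equal(unname(diag(corr)), rep(1, 5)))) {
    stop("corr must be a symmetric 5x5 correlation matrix with unit diagonal",
         call. = FALSE)
  }
  R <- tryCatch(chol(corr), error = function(e) {
    stop("correlation matrix is not positive definite", call. = FALSE)
  })
  R
}

#' Sample correlated standard-normal trait vectors
#'
#' Draws `n` five-dimensional vectors from a zero-mean, unit-variance
#' multivariate normal with the given trait correlation, via the Cholesky
#' factor of the correlation matrix. These are the pre-squash trait scores;
#' [sample_personalities()] maps them to the unit interval.
#'
#' @param n Number of vectors to draw.
#' @param corr Trait correlation matrix (default [big_five_correlation()]).
#' @return An `n` x 5 numeric matrix with trait columns.
#' @export
sample_trait_normals <- function(n, corr = big_five_correlation()) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  R <- .check_correlation(corr)
  Z <- matrix(stats::rnorm(n * 5), nrow = n, ncol = 5) %*% R
  colnames(Z) <- colnames(corr)
  Z
}

#' Sample Big Five personality profiles
#'
#' Draws correlated standard-normal trait scores (see
#' [sample_trait_normals()]) and squashes each coordinate onto (0, 1) with
#' [squash()].
#'
#' @inheritParams sample_trait_normals
#' @return A data frame with `n` rows and the five unit-interval trait
#'   columns `openness`, `conscientiousness`, `extraversion`,
#'   `agreeableness`, `neuroticism`.
#' @examples
#' set.seed(1)
#' head(sample_personalities(5))
#' @export
sample_personalities <- function(n, corr = big_five_correlation()) {
  as.data.frame(squash(sample_trait_normals(n, corr)))
}

#' Personality-derived thresholds
#'
#' For personality agents the noticing threshold is the mean of a uniform
#' draw and the complement of openness (more open agents notice more), and
#' the posting threshold is the mean of an independent uniform draw and
#' conscientiousness (more conscientious agents post less).
#'
#' @param openness,conscientiousness Unit-interval trait vectors.
#' @param u Uniform draws; defaults to fresh `runif()` draws. Exposed so the
#'   threshold arithmetic can be checked deterministically.
#' @return Numeric vector of thresholds in `[0, 1]`.
#' @examples
#' noticing_threshold(openness = 0.6, u = 0.4)        # 0.4
#' posting_threshold(conscientiousness = 1, u = 1)    # 1
#' @export
noticing_threshold <- function(openness, u = stats::runif(length(openness))) {
  stopifnot(length(u) == length(openness))
  (u + (1 - openness)) / 2
}

#' @rdname noticing_threshold
#' @export
posting_threshold <- function(conscientiousness,
                              u = stats::runif(length(conscientiousness))) {
  stopifnot(length(u) == length(conscientiousness))
  (u + conscientiousness) / 2
}
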