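#' Message content archetypes
#'
#' The four stimulus tuples used throughout the simulations. Each message
#' carries an affective and a cognitive stimulus value on the unit interval:
#' a strong stimulus is coded 0.8 and a weak one 0.2.
#'
#' @format A named list mapping each archetype label to its
#'   `c(affective, cognitive)` tuple.
#' @export
content_types <- list(
  affective = c(affective = 0.8, cognitive = 0.2),
  cognitive = c(affective = 0.2, cognitive = 0.8),
  both      = c(affective = 0.8, cognitive = 0.8),
  weak      = c(affective = 0.2, cognitive = 0.2)
)

#' Construct a message stimulus
#'
#' Builds the fixed stimulus tuple for one of the four content archetypes:
#' `affective` (0.8, 0.2), `cognitive` (0.2, 0.8), `both` (0.8, 0.8) and
#' `weak` (0.2, 0.2).
#'
#' @param label One of `"affective"`, `"cognitive"`, `"both"`, `"weak"`.
#' @return An object of class `cascade_message`: a list with elements
#'   `affective`, `cognitive` and `label`.
#' @examples
#' make_message("affective")
#' @export
make_message <- function(label) {
  if (!is.character(label) || length(label) != 1 ||
      !label %in% names(content_types)) {
    stop("unknown content label; valid labels: ",
         paste(names(content_types), collapse = ", "), call. = FALSE)
  }
  val <- content_types[[label]]
  structure(list(affective = unname(val["affective"]),
                 cognitive = unname(val["cognitive"]),
                 label = label),
            class = "cascade_message")
}

#' @export
print.cascade_message <- function(x, ...) {
  cat(sprintf("<message '%s': affective=%.1f cognitive=%.1f>\n",
              x$label, x$affective, x$cognitive))
  invisible(x)
}

#' Squash a real value onto the unit interval
#'
#' The sigmoidal transform `(tanh(x) + 1) / 2`, a strictly increasing
#' bijection from the reals onto (0, 1). Used to map standard-normal trait
#' scores onto the unit interval.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of the same length, all values in (0, 1).
#' @examples
#' squash(0)    # 0.5
#' squash(1)    # 0.8807971
#' @export
squash <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("squash() requires finite numeric input", call. = FALSE)
  }
  (tanh(x) + 1) / 2
}
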