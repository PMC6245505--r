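#' Shannon entropy of a weighted categorical distribution
#'
#' Computes the Shannon entropy \eqn{H = -\sum_i p_i \ln p_i} (in nats) of a
#' set of nonnegative category weights, where \eqn{p_i} is the weight of
#' category *i* divided by the total weight. Weights may be durations
#' (seconds a display element was performed), counts (notes of a type), or
#' areas (pixels of a color cluster); only their proportions matter.
#'
#' @param weights Numeric vector of nonnegative weights, one per category.
#'   Zero-weight categories are ignored.
#' @return The entropy in nats, a single nonnegative number.
#' @seealso [numbers_equivalent()], [richness()], [complexity_score()]
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))   # log(4)
#' shannon_entropy(c(0.5, 0.25, 0.25))
#' @export
shannon_entropy <- function(weights) {
  check_weights(weights)
  w <- weights[weights > 0]
  p <- w / sum(w)
  -sum(p * log(p))
}

#' Numbers equivalent (Hill number of order 1) of a Shannon entropy
#'
#' Converts a Shannon entropy `H` to its numbers equivalent `exp(H)`: the
#' count of equally weighted categories that would produce the same entropy.
#' A distribution with numbers equivalent `2x` behaves as if it had twice as
#' many equally well-represented categories as one with value `x`.
#'
#' @param H Nonnegative Shannon entropy in nats.
#' @return A real number \eqn{\ge 1}.
#' @examples
#' numbers_equivalent(0)         # 1
#' numbers_equivalent(log(12))   # 12
#' @export
numbers_equivalent <- function(H) {
  if (!is.numeric(H) || anyNA(H) || any(H < 0)) {
    abort("`H` must be nonnegative Shannon entropy (nats).",
          class = "ornadiv_invalid_input")
  }
  exp(H)
}

#' Richness of a weighted categorical distribution
#'
#' @param weights Numeric vector of nonnegative weights, one per category.
#' @return Integer count of categories with strictly positive weight.
#' @examples
#' richness(c(3, 0, 2))  # 2
#' @export
richness <- function(weights) {
  check_weights(weights)
  sum(weights > 0)
}

check_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) == 0L || anyNA(weights)) {
    abort("`weights` must be a nonempty numeric vector without NA.",
          class = "ornadiv_invalid_input")
  }
  if (any(weights < 0)) {
    abort("`weights` must be nonnegative.", class = "ornadiv_invalid_input")
  }
  if (all(weights == 0)) {
    abort("All weights are zero: the distribution is unscorable.",
          class = "ornadiv_invalid_input")
  }
  invisible(weights)
}

#' Richness and diversity of a weighted distribution
#'
#' Convenience wrapper returning both complexity measures used throughout
#' the package: richness (number of categories with positive weight) and
#' diversity (the numbers equivalent of Shannon entropy). Diversity always
#' lies in `[1, richness]`, with equality at the top iff the positive
#' weights are uniform.
#'
#' @param data A data frame with one row per category.
#' @param weight Column of `data` holding the nonnegative weights
#'   (tidy-eval; default `weight`).
#' @return A one-row tibble with columns `richness` and `diversity`.
#' @examples
#' complexity_score(tibble::tibble(weight = c(50, 25, 25)))
#' @export
complexity_score <- function(data, weight = weight) {
  w <- dplyr::pull(data, {{ weight }})
  tibble::tibble(
    richness = richness(w),
    diversity = numbers_equivalent(shannon_entropy(w))
  )
}
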