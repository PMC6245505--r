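#' Receptor-noise-limited visual model
#'
#' Describes the chromatic receptor channels of the modeled viewer. Channel
#' noise follows the standard receptor-noise-limited construction: the most
#' abundant cone class is assigned the Weber fraction `nu`, and channel *i*
#' receives \eqn{\omega_i = \nu \sqrt{n_{ref}} / \sqrt{n_i}} where
#' \eqn{n_i} are relative cone densities. Defaults emulate a
#' violet-sensitive (VS) bird such as the pigeon: four chromatic channels
#' (uvs/vs, sws, mws, lws) with relative densities 1:2:2:4, `nu = 0.1` on
#' the long-wavelength channel, and an achromatic (double-cone) Weber
#' fraction of 0.1.
#'
#' @param densities Named positive numeric vector of relative cone
#'   densities, one per chromatic channel (2-4 channels).
#' @param nu Weber fraction of the most abundant chromatic channel, in
#'   (0, 1).
#' @param weber_achromatic Weber fraction of the achromatic (luminance)
#'   channel, in (0, 1).
#' @return An object of class `ornadiv_visual_model` with elements
#'   `channels`, `densities`, `omega` (per-channel noise) and
#'   `omega_lum`.
#' @examples
#' visual_model()            # tetrachromat defaults
#' visual_model(c(s = 1, l = 1), nu = 0.1)  # dichromat
#' @export
visual_model <- function(densities = c(uvs = 1, sws = 2, mws = 2, lws = 4),
                         nu = 0.1, weber_achromatic = 0.1) {
  if (length(densities) < 2 || length(densities) > 4 || any(densities <= 0)) {
    abort("`densities` must hold 2-4 positive relative cone densities.",
          class = "ornadiv_invalid_input")
  }
  if (nu <= 0 || nu >= 1 || weber_achromatic <= 0 || weber_achromatic >= 1) {
    abort("Weber fractions must lie in (0, 1).", class = "ornadiv_invalid_input")
  }
  if (is.null(names(densities))) {
    names(densities) <- paste0("ch", seq_along(densities))
  }
  omega <- nu * sqrt(max(densities)) / sqrt(densities)
  structure(list(channels = names(densities), densities = densities,
                 omega = omega, omega_lum = weber_achromatic),
            class = "ornadiv_visual_model")
}

#' @export
print.ornadiv_visual_model <- function(x, ...) {
  cat("Receptor-noise-limited visual model (", length(x$omega),
      " chromatic channels)\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  omega:   ", paste(signif(x$omega, 4), collapse = ", "), "\n")
  cat("  omega_L: ", x$omega_lum, "\n")
  invisible(x)
}

# Coefficients of the RNL quadratic form for n = 2..4 channels:
# dS^2 = sum_{i<j} (prod_{k != i,j} w_k)^2 (df_i - df_j)^2
#        / sum_i (prod_{k != i} w_k)^2
rnl_coefs <- function(omega) {
  n <- length(omega)
  pairs <- utils::combn(n, 2)
  num <- apply(pairs, 2, function(ij) prod(omega[-ij])^2)
  den <- sum(vapply(seq_len(n), function(i) prod(omega[-i])^2, 0))
  list(pairs = pairs, num = num, den = den)
}

#' Chromatic just-noticeable distance (log model)
#'
#' Perceptual distance between two receptor quantum-catch vectors under the
#' receptor-noise-limited model with logarithmic transduction
#' (\eqn{f_i = \ln q_i}). Distance is driven by the pairwise differences of
#' log-catch contrasts weighted by channel noise, so any uniform intensity
#' scaling of one stimulus leaves the distance at zero.
#'
#' @param qa,qb Positive numeric vectors of quantum catches (one value per
#'   chromatic channel), or matrices with one row per stimulus pair.
#' @param model A [visual_model()].
#' @return Chromatic distance in JND units (vector if matrices supplied).
#' @examples
#' m <- visual_model(c(s = 1, l = 1), nu = 0.1)  # omega = (0.1, 0.1)
#' chromatic_jnd(c(2, 1), c(1, 1), m)            # ~ log(2)/(0.1*sqrt(2))
#' @export
chromatic_jnd <- function(qa, qb, model) {
  qa <- rbind(qa); qb <- rbind(qb)
  if (ncol(qa) != length(model$omega) || ncol(qb) != length(model$omega)) {
    abort("Catch vectors must match the model's channel count.",
          class = "ornadiv_invalid_input")
  }
  if (any(qa <= 0) || any(qb <= 0)) {
    abort("Quantum catches must be positive (log model).",
          class = "ornadiv_invalid_input")
  }
  d <- log(qa) - log(qb)
  cf <- rnl_coefs(model$omega)
  ss <- rep(0, nrow(d))
  for (p in seq_len(ncol(cf$pairs))) {
    i <- cf$pairs[1, p]; j <- cf$pairs[2, p]
    ss <- ss + cf$num[p] * (d[, i] - d[, j])^2
  }
  unname(sqrt(ss / cf$den))
}

#' Achromatic just-noticeable distance (log model)
#'
#' @param qLa,qLb Positive luminance (double-cone) catches; vectorized.
#' @param model A [visual_model()].
#' @return Achromatic distance in JND units:
#'   \eqn{|\ln q_{La} - \ln q_{Lb}| / \omega_L}.
#' @export
achromatic_jnd <- function(qLa, qLb, model) {
  if (any(qLa <= 0) || any(qLb <= 0)) {
    abort("Luminance catches must be positive (log model).",
          class = "ornadiv_invalid_input")
  }
  unname(abs(log(qLa) - log(qLb)) / model$omega_lum)
}

#' Composite threshold-scaled distance
#'
#' Chromatic and achromatic JNDs are each divided by their threshold so the
#' two perceptual dimensions are weighted equally, then combined as a
#' Euclidean distance.
#'
#' @param dS Chromatic JND (nonnegative, vectorized).
#' @param dL Achromatic JND (nonnegative, vectorized).
#' @param params A [cluster_params()].
#' @return `sqrt((dS/T_c)^2 + (dL/T_l)^2)`.
#' @export
composite_distance <- function(dS, dL, params) {
  sqrt((dS / params$chrom_threshold)^2 + (dL / params$lum_threshold)^2)
}

#' Parameters of the spatial color-clustering algorithm
#'
#' @param chrom_threshold Chromatic merge threshold `T_c` in JND, default 3
#'   (a conventional supra-threshold discriminability cut for uncontrolled
#'   viewing conditions).
#' @param lum_threshold Achromatic merge threshold `T_l` in JND, default 3.
#' @param initial_radius Chebyshev pixel radius of the first clustering
#'   pass, default 1 (8-connected neighbors).
#' @param radius_increment Radius growth per pass in pixels, default 1.
#' @param max_passes Hard cap on passes; reaching it before quiescence
#'   returns the partial clustering with a warning.
#' @param min_area_frac Clusters smaller than this fraction of the
#'   foreground are dropped before scoring (default 0, off); guards against
#'   dust specks.
#' @return An object of class `ornadiv_cluster_params`.
#' @export
cluster_params <- function(chrom_threshold = 3, lum_threshold = 3,
                           initial_radius = 1, radius_increment = 1,
                           max_passes = 500, min_area_frac = 0) {
  if (chrom_threshold <= 0 || lum_threshold <= 0) {
    abort("Thresholds must be positive.", class = "ornadiv_invalid_input")
  }
  if (initial_radius < 1) abort("`initial_radius` must be >= 1.",
                                class = "ornadiv_invalid_input")
  structure(list(chrom_threshold = chrom_threshold,
                 lum_threshold = lum_threshold,
                 initial_radius = initial_radius,
                 radius_increment = radius_increment,
                 max_passes = max_passes,
                 min_area_frac = min_area_frac),
            class = "ornadiv_cluster_params")
}
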