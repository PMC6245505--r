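# Trait-evolution covariance structures used by simulation and imputation.
# All take the BM covariance (shared root-to-MRCA path lengths, ape::vcv)
# and/or the patristic distance matrix of the full tree.

trait_model_cov <- function(model, Cbm, D, par) {
  switch(model,
    BM = Cbm,
    OU = {  # stationary OU: correlation exp(-alpha d), unit-ish scale
      C <- exp(-par * D); diag(C) <- 1; C
    },
    EB = {  # early burst: rate sigma2 * exp(r t); integral over shared path
      if (abs(par) < 1e-12) Cbm else (exp(par * Cbm) - 1) / par
    },
    lambda = {  # Pagel's lambda: scale off-diagonals
      C <- par * Cbm; diag(C) <- diag(Cbm); C
    },
    abort(paste0("Unknown trait model: ", model),
          class = "ornadiv_invalid_input"))
}

trait_model_bounds <- function(model, height) {
  switch(model,
    BM = NULL,
    OU = c(1e-6, 50 / height),
    EB = c(-10 / height, -1e-8),
    lambda = c(0, 1))
}

# single-trait Gaussian ML on observed tips with mean and scale profiled out
trait_ml <- function(yobs, V) {
  n <- length(yobs)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(logLik = -Inf))
  one <- backsolve(L, rep(1, n), transpose = TRUE)
  wy <- backsolve(L, yobs, transpose = TRUE)
  mu <- sum(one * wy) / sum(one^2)
  rq <- sum((wy - mu * one)^2)
  s2 <- rq / n
  ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + n)
  list(logLik = ll, mu = mu, sigma2 = s2)
}

fit_one_trait_model <- function(model, yobs, Cbm_o, D_o, height) {
  bounds <- trait_model_bounds(model, height)
  if (is.null(bounds)) {
    f <- trait_ml(yobs, Cbm_o)
    return(list(model = model, par = NA_real_, mu = f$mu, sigma2 = f$sigma2,
                logLik = f$logLik, k = 2))
  }
  obj <- function(p) trait_ml(yobs, trait_model_cov(model, Cbm_o, D_o, p))$logLik
  opt <- optimize(obj, lower = bounds[1], upper = bounds[2], maximum = TRUE,
                  tol = 1e-8)
  # compare with the bounds themselves (optimize can miss boundary optima)
  cand <- c(opt$maximum, bounds)
  lls <- c(opt$objective, vapply(bounds, obj, 0))
  p_star <- cand[which.max(lls)]
  f <- trait_ml(yobs, trait_model_cov(model, Cbm_o, D_o, p_star))
  list(model = model, par = p_star, mu = f$mu, sigma2 = f$sigma2,
       logLik = f$logLik, k = 3)
}

#' Impute missing species trait values on a phylogeny
#'
#' For each trait column containing missing species, fits candidate
#' trait-evolution models (Brownian motion, Ornstein-Uhlenbeck, early
#' burst, Pagel's lambda) to the observed tips by maximum likelihood,
#' selects the model with the lowest AIC, and imputes each missing tip as
#' the conditional expectation of the joint multivariate normal given the
#' observed tips under the selected model.
#'
#' @param traits Data frame with a `species` column matching the tree tips
#'   and numeric trait columns; `NA` marks missing species values.
#' @param tree Ultrametric `phylo` tree.
#' @param models Candidate models, subset of `c("BM", "OU", "EB",
#'   "lambda")`.
#' @param trait_cols Columns to impute; default: all numeric columns with
#'   at least one `NA`.
#' @return An object of class `ornadiv_imputation`: list with `traits`
#'   (completed tibble), `report` (per trait x model: parameter, logLik,
#'   AIC, `selected`), and `imputed` (logical tibble marking filled cells).
#' @export
impute_missing <- function(traits, tree, models = c("BM", "OU", "EB", "lambda"),
                           trait_cols = NULL) {
  df <- dplyr::as_tibble(traits)
  if (!all(df$species %in% tree$tip.label) ||
      !all(tree$tip.label %in% df$species)) {
    abort("`traits$species` must match the tree tips one-to-one.",
          class = "ornadiv_invalid_input")
  }
  df <- df[match(tree$tip.label, df$species), , drop = FALSE]
  if (is.null(trait_cols)) {
    num <- names(df)[vapply(df, is.numeric, TRUE)]
    trait_cols <- num[vapply(df[num], anyNA, TRUE)]
  }
  height <- check_ultrametric(tree, warn_only = TRUE)
  Cbm <- ape::vcv(tree)[df$species, df$species]
  D <- ape::cophenetic.phylo(tree)[df$species, df$species]
  report <- list()
  imputed <- df[, "species", drop = FALSE]
  for (tr in trait_cols) {
    y <- df[[tr]]
    obs <- !is.na(y)
    if (sum(obs) < 3) abort(paste0("Trait ", tr, " has fewer than 3 observed tips."),
                            class = "ornadiv_invalid_input")
    fits <- lapply(models, fit_one_trait_model, yobs = y[obs],
                   Cbm_o = Cbm[obs, obs], D_o = D[obs, obs], height = height)
    aics <- vapply(fits, function(f) 2 * f$k - 2 * f$logLik, 0)
    best <- fits[[which.min(aics)]]
    report[[tr]] <- tibble::tibble(
      trait = tr, model = models, parameter = vapply(fits, `[[`, 0, "par"),
      logLik = vapply(fits, `[[`, 0, "logLik"), AIC = aics,
      selected = seq_along(models) == which.min(aics))
    if (any(!obs)) {
      V <- trait_model_cov(best$model, Cbm, D, best$par)
      Voo <- V[obs, obs, drop = FALSE]
      Vmo <- V[!obs, obs, drop = FALSE]
      y[!obs] <- best$mu +
        as.numeric(Vmo %*% solve(Voo, y[obs] - best$mu))
      df[[tr]] <- y
    }
    imputed[[tr]] <- !obs
  }
  structure(list(traits = df, report = dplyr::bind_rows(report),
                 imputed = imputed),
            class = "ornadiv_imputation")
}

#' @export
print.ornadiv_imputation <- function(x, ...) {
  n_imp <- sum(vapply(x$imputed[-1], sum, 0L))
  cat("Phylogenetic imputation:", n_imp, "value(s) filled.\n")
  sel <- x$report[x$report$selected, c("trait", "model", "AIC")]
  print(as.data.frame(sel), digits = 5)
  invisible(x)
}

#' @export
tidy.ornadiv_imputation <- function(x, ...) x$report

#' Simulate correlated traits on a phylogeny
#'
#' Draws `n_traits` traits jointly from a matrix normal with covariance
#' (trait correlation) x (phylogenetic covariance): under Brownian motion
#' the phylogenetic part is the shared-path-length matrix; under the
#' stationary Ornstein-Uhlenbeck model it is `exp(-alpha d)`.
#'
#' @param tree A `phylo` tree.
#' @param n_traits Number of traits.
#' @param model `"BM"` or `"OU"`.
#' @param sigma2 Evolutionary rate (trait variance scale).
#' @param alpha OU decay rate (required for `model = "OU"`).
#' @param cross_corr Either a single correlation applied to every trait
#'   pair or a full trait correlation matrix.
#' @param means Trait means (recycled).
#' @param seed Optional integer seed (local to this call).
#' @return Tibble with `species` and `trait_1 ... trait_k` columns.
#' @export
simulate_traits <- function(tree, n_traits = 3, model = c("BM", "OU"),
                            sigma2 = 1, alpha = NULL, cross_corr = 0,
                            means = 0, seed = NULL) {
  model <- match.arg(model)
  local_seed(seed)
  n <- length(tree$tip.label)
  if (is.matrix(cross_corr)) {
    R <- cross_corr
  } else {
    if (abs(cross_corr) > 1) abort("`cross_corr` must lie in [-1, 1].",
                                   class = "ornadiv_invalid_input")
    R <- matrix(cross_corr, n_traits, n_traits); diag(R) <- 1
  }
  eg <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < -1e-10) abort("Trait correlation matrix is not PSD.",
                              class = "ornadiv_invalid_input")
  C <- if (model == "BM") {
    ape::vcv(tree)
  } else {
    if (is.null(alpha)) abort("`alpha` required for the OU model.",
                              class = "ornadiv_invalid_input")
    ou_correlation(tree, alpha)
  }
  Lc <- t(chol(C + diag(1e-10, n)))
  Lr <- chol(R + diag(1e-10, n_traits))
  Z <- matrix(rnorm(n * n_traits), n, n_traits)
  X <- sqrt(sigma2) * (Lc %*% Z %*% Lr)
  X <- sweep(X, 2, rep_len(means, n_traits), `+`)
  colnames(X) <- paste0("trait_", seq_len(n_traits))
  dplyr::bind_cols(tibble::tibble(species = tree$tip.label),
                   tibble::as_tibble(as.data.frame(X)))
}

#' Scaled per-modality diversity and the composite courtship score
#'
#' Min-max scales each modality's diversity to `[0, 1]` across species and
#' sums the three scaled scores into a composite metric of overall signal
#' diversity. A constant column scales to 0 with a warning.
#'
#' @param traits Species trait data frame.
#' @param cols Diversity columns to scale; default: all columns ending in
#'   `_diversity`.
#' @return Tibble with `species`, one `scaled_<col>` per input column, and
#'   `composite`.
#' @export
composite_diversity <- function(traits, cols = NULL) {
  df <- dplyr::as_tibble(traits)
  if (is.null(cols)) cols <- grep("_diversity$", names(df), value = TRUE)
  if (!length(cols)) abort("No diversity columns found.",
                           class = "ornadiv_invalid_input")
  out <- df[, "species", drop = FALSE]
  for (cl in cols) {
    v <- df[[cl]]
    rng <- range(v)
    if (diff(rng) == 0) {
      warn(paste0("Column ", cl, " is constant; scaled to 0."))
      sv <- rep(0, length(v))
    } else {
      sv <- (v - rng[1]) / diff(rng)
    }
    out[[paste0("scaled_", cl)]] <- sv
  }
  out$composite <- rowSums(out[, paste0("scaled_", cols), drop = FALSE])
  out
}

# seed the RNG when a seed is supplied; NULL leaves the stream untouched
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible()
}
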