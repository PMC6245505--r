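#' Ornstein-Uhlenbeck tip correlation matrix
#'
#' Martins-Hansen form on the patristic tip-distance matrix:
#' \eqn{C_{ij} = \exp(-\alpha d_{ij})} with unit diagonal. `alpha = 0`
#' yields the all-ones matrix; large `alpha` approaches the identity.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param alpha Nonnegative OU decay rate (per unit branch length).
#' @return Square correlation matrix with rows/columns in `tree$tip.label`
#'   order.
#' @export
ou_correlation <- function(tree, alpha) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object.",
                                      class = "ornadiv_invalid_input")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    abort("`alpha` must be a single nonnegative number.",
          class = "ornadiv_invalid_input")
  }
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]
  C <- exp(-alpha * D)
  diag(C) <- 1
  C
}

#' Check a tree is ultrametric within tolerance
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance on root-to-tip depth spread, default 1e-6
#'   (relative to tree height).
#' @param warn_only Emit a warning instead of an error when violated.
#' @return Invisibly, the tree height.
#' @export
check_ultrametric <- function(tree, tol = 1e-6, warn_only = FALSE) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (diff(range(depths)) > tol * max(h, 1)) {
    msg <- "Tree is not ultrametric within tolerance."
    if (warn_only) warn(msg) else abort(msg, class = "ornadiv_invalid_input")
  }
  invisible(h)
}

#' Generalized least squares with a known residual correlation
#'
#' Fits \eqn{y = X\beta + \varepsilon}, \eqn{\varepsilon \sim N(0, \sigma^2
#' C)} for a fixed correlation matrix `C`, via the closed form
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1} X'C^{-1} y}. The scale is estimated as
#' the residual quadratic form over `n - p`; standard errors come from
#' \eqn{\hat\sigma^2 (X'C^{-1}X)^{-1}} and p values from a t distribution
#' on `n - p` degrees of freedom. The reported log-likelihood is the
#' Gaussian ML profile (ML scale `rq/n`).
#'
#' @param y Numeric response vector.
#' @param X Design matrix (full column rank), rows aligned with `y` and
#'   `C`.
#' @param C Positive-definite correlation (or covariance up to scale)
#'   matrix.
#' @param extra_df Number of extra estimated covariance parameters counted
#'   in the AIC (e.g. 1 when an OU rate was profiled), default 0.
#' @return An object of class `ornadiv_gls` with a coefficient table,
#'   `sigma2`, `logLik`, `AIC`, `df.residual`, `nobs`.
#' @export
gls_fit <- function(y, X, C, extra_df = 0) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n) {
    abort("`y`, `X` and `C` dimensions do not align.",
          class = "ornadiv_invalid_input")
  }
  L <- tryCatch(chol(C), error = function(e)
    abort("`C` is not positive definite.", class = "ornadiv_singular"))
  # whiten: solve L' z = v  =>  z ~ iid
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  qr_wX <- qr(wX)
  if (qr_wX$rank < p) abort("`X` is rank deficient.", class = "ornadiv_singular")
  beta <- qr.coef(qr_wX, wy)
  res <- wy - wX %*% beta
  rq <- sum(res^2)
  sigma2 <- rq / (n - p)
  XtX_inv <- chol2inv(qr.R(qr_wX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  logdetC <- 2 * sum(log(diag(L)))
  s2_ml <- rq / n
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + logdetC + n)
  k <- p + 1 + extra_df
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  structure(list(
    coefficients = tibble::tibble(term = terms, estimate = as.numeric(beta),
                                  std.error = se,
                                  statistic = as.numeric(tval),
                                  p.value = as.numeric(pval)),
    sigma2 = sigma2, logLik = ll, AIC = 2 * k - 2 * ll,
    df.residual = n - p, nobs = n, alpha = NA_real_,
    vcov = sigma2 * XtX_inv, residuals = as.numeric(y - X %*% beta)
  ), class = "ornadiv_gls")
}

#' @export
print.ornadiv_gls <- function(x, ...) {
  cat("Phylogenetic GLS fit (n = ", x$nobs, ")\n", sep = "")
  if (!is.na(x$alpha)) cat("  OU alpha =", signif(x$alpha, 4), "\n")
  cat("  sigma2 =", signif(x$sigma2, 4), " logLik =", signif(x$logLik, 6),
      " AIC =", signif(x$AIC, 6), "\n")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @export
tidy.ornadiv_gls <- function(x, ...) x$coefficients

#' @export
glance.ornadiv_gls <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, sigma2 = x$sigma2, logLik = x$logLik,
                 AIC = x$AIC, df.residual = x$df.residual, nobs = x$nobs)
}

# profile likelihood over the OU rate: coarse log-spaced grid, then
# golden-section refinement (stats::optimize) in the bracketing interval.
# The default criterion is restricted ML, which is less biased for
# covariance parameters at comparative sample sizes; ML is available.
profile_ou_alpha <- function(y, X, tree, method = c("REML", "ML"),
                             lower = 1e-4, upper = NULL) {
  method <- match.arg(method)
  h <- check_ultrametric(tree, warn_only = TRUE)
  if (is.null(upper)) upper <- 50 / h
  D <- ape::cophenetic.phylo(tree)[names(y), names(y)]
  n <- length(y); p <- ncol(X)
  # finite floor rather than -Inf so the bracketing optimizer stays quiet
  floor_ll <- -1e10
  ll_of <- function(a) {
    C <- exp(-a * D); diag(C) <- 1
    L <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(L)) return(floor_ll)
    wy <- backsolve(L, y, transpose = TRUE)
    wX <- backsolve(L, X, transpose = TRUE)
    qrX <- qr(wX)
    if (qrX$rank < p) return(floor_ll)
    res <- wy - wX %*% qr.coef(qrX, wy)
    rq <- sum(res^2)
    ldC <- 2 * sum(log(diag(L)))
    if (method == "ML") {
      -0.5 * (n * log(2 * pi * rq / n) + ldC + n)
    } else {
      ldX <- as.numeric(determinant(crossprod(wX))$modulus)
      -0.5 * ((n - p) * log(2 * pi * rq / (n - p)) + ldC + ldX + (n - p))
    }
  }
  grid <- exp(seq(log(lower), log(upper), length.out = 25))
  lls <- vapply(grid, ll_of, 0)
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(la) ll_of(exp(la)), lower = log(lo),
                  upper = log(hi), maximum = TRUE, tol = 1e-6)
  a_star <- exp(opt$maximum)
  if (opt$objective < lls[i]) a_star <- grid[i]
  a_star
}

#' Multiple phylogenetic GLS for one courtship-complexity measure
#'
#' Regresses one species-level complexity measure on the two same-class
#' measures from the other signal modalities plus the two signal-
#' environment covariates, with residuals correlated under an
#' Ornstein-Uhlenbeck structure whose decay rate is estimated by profiled
#' maximum likelihood. Only "like" measures enter together (richness with
#' richness, diversity with diversity). All complexity measures are
#' natural-log transformed; display height is dummy coded with ground
#' displaying as the reference and display proximity with solitary
#' displaying as the reference.
#'
#' @param traits Species trait data frame: a `species` column matching the
#'   tree tips, the six measure columns (named `<modality>_<class>`, e.g.
#'   `color_diversity`), and optionally factors `display_height`
#'   (`ground`, `understory`, `canopy`) and `proximity` (`solitary`,
#'   `exploded_lek`, `lek`).
#' @param response Name of the response measure column.
#' @param tree Ultrametric `phylo` tree whose tips match `traits$species`.
#' @param predictors Optional character vector of predictor measure
#'   columns; default: every other column sharing the response's class
#'   suffix.
#' @param alpha Fixed OU rate; `NULL` (default) estimates it by profiled
#'   likelihood.
#' @param method Criterion for the profiled OU rate, `"REML"` (default)
#'   or `"ML"`.
#' @param log_transform Log-transform the measures (default `TRUE`; values
#'   must then be positive).
#' @return An `ornadiv_gls` fit (with `alpha` filled in) whose
#'   coefficients table is shaped like a standard mPGLS report.
#' @export
mpgls_model <- function(traits, response, tree, predictors = NULL,
                        alpha = NULL, method = c("REML", "ML"),
                        log_transform = TRUE) {
  if (!response %in% names(traits)) abort("Unknown response column.",
                                          class = "ornadiv_invalid_input")
  if (is.null(predictors)) {
    cls <- sub("^.*_", "", response)
    predictors <- setdiff(grep(paste0("_", cls, "$"), names(traits),
                               value = TRUE), response)
  }
  df <- dplyr::as_tibble(traits)
  if (!all(df$species %in% tree$tip.label)) {
    abort("Species in `traits` missing from the tree.",
          class = "ornadiv_invalid_input")
  }
  tree <- ape::keep.tip(tree, df$species)
  df <- df[match(tree$tip.label, df$species), , drop = FALSE]
  tf <- if (log_transform) function(v) {
    if (any(v <= 0)) abort("Log transform requires positive measures.",
                           class = "ornadiv_invalid_input")
    log(v)
  } else identity
  y <- setNames(tf(df[[response]]), df$species)
  Xl <- list(`(Intercept)` = rep(1, nrow(df)))
  for (p in predictors) Xl[[paste0("log(", p, ")")]] <- tf(df[[p]])
  if ("display_height" %in% names(df)) {
    dh <- check_level(df$display_height, c("ground", "understory", "canopy"),
                      "display_height")
    for (lev in intersect(c("understory", "canopy"), unique(dh))) {
      Xl[[paste0("display_height", lev)]] <- as.numeric(dh == lev)
    }
  }
  if ("proximity" %in% names(df)) {
    pr <- check_level(df$proximity, c("solitary", "exploded_lek", "lek"),
                      "proximity")
    for (lev in intersect(c("exploded_lek", "lek"), unique(pr))) {
      Xl[[paste0("proximity", lev)]] <- as.numeric(pr == lev)
    }
  }
  X <- do.call(cbind, Xl)
  rownames(X) <- df$species
  est_alpha <- is.null(alpha)
  if (est_alpha) alpha <- profile_ou_alpha(y, X, tree, method = method)
  C <- ou_correlation(tree, alpha)
  fit <- gls_fit(y, X, C, extra_df = if (est_alpha) 1 else 0)
  fit$alpha <- alpha
  fit$response <- response
  fit
}

check_level <- function(x, levels, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) abort(paste0("Unknown ", what, " level(s): ",
                                paste(bad, collapse = ", ")),
                         class = "ornadiv_invalid_input")
  factor(x, levels = levels)
}
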