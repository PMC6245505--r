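three_taxon <- ape::read.tree(text = "((A:1,B:1):1,C:2);")

sim_measure_table <- function(tree, cross_corr = 0, seed = NULL) {
  tr <- simulate_traits(tree, 3, "BM", cross_corr = cross_corr, seed = seed)
  tibble::tibble(species = tr$species,
                 color_diversity = exp(tr$trait_1),
                 behavior_diversity = exp(tr$trait_2),
                 acoustic_diversity = exp(tr$trait_3)) |>
    dplyr::left_join(gen_display_covariates(tr$species), by = "species")
}

test_that("OU correlation has the Martins-Hansen form", {
  C0 <- ou_correlation(three_taxon, 0)
  expect_equal(C0, matrix(1, 3, 3), ignore_attr = TRUE)
  Cinf <- ou_correlation(three_taxon, 1e6)
  expect_equal(Cinf, diag(3), ignore_attr = TRUE)
  a <- 0.3
  C <- ou_correlation(three_taxon, a)
  expect_equal(C["A", "B"], exp(-a * 2))  # d(A,B) = 2
  expect_equal(C["A", "C"], exp(-a * 4))  # d(A,C) = 4
  expect_error(ou_correlation(three_taxon, -1),
               class = "ornadiv_invalid_input")
})

test_that("gls_fit with identity correlation reproduces OLS", {
  set.seed(13)
  n <- 20
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 + 0.5 * X[, 2] + rnorm(n)
  f <- gls_fit(y, X, diag(n))
  ols <- summary(lm(y ~ X[, 2] + X[, 3]))
  expect_equal(f$coefficients$estimate, unname(coef(ols)[, 1]),
               tolerance = 1e-10)
  expect_equal(f$coefficients$std.error, unname(coef(ols)[, 2]),
               tolerance = 1e-10)
  expect_equal(f$coefficients$p.value, unname(coef(ols)[, 4]),
               tolerance = 1e-10)
})

test_that("gls_fit agrees with the explicit matrix-inverse oracle", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- rnorm(n)
    A <- matrix(rnorm(n * n, sd = 0.3), n)
    C <- crossprod(A) + diag(n)
    C <- stats::cov2cor(C)
    f <- gls_fit(y, X, C)
    o <- oracle_gls(y, X, C)
    expect_equal(f$coefficients$estimate, o$beta, tolerance = 1e-8)
    expect_equal(f$coefficients$std.error, o$se, tolerance = 1e-8)
    expect_equal(f$sigma2, o$sigma2, tolerance = 1e-8)
  }
})

test_that("noise-free responses are recovered exactly under any C", {
  set.seed(15)
  n <- 8
  X <- cbind(1, rnorm(n))
  beta <- c(1.5, -2)
  y <- as.numeric(X %*% beta)
  C <- ou_correlation(gen_tree(n, seed = 15), 0.2)
  f <- gls_fit(y, X, C)
  expect_equal(f$coefficients$estimate, beta, tolerance = 1e-9)
})

test_that("gls_fit rejects degenerate inputs", {
  expect_error(gls_fit(1:3, cbind(1, c(1, 2, 3), c(2, 4, 6)), diag(3)),
               class = "ornadiv_singular")
  expect_error(gls_fit(1:3, cbind(1, 1:3), matrix(1, 3, 3)),
               class = "ornadiv_singular")
})

test_that("mPGLS matches nlme::gls with the same fixed OU rate", {
  skip_if_not_installed("nlme")
  tree <- gen_tree(25, seed = 16)
  traits <- sim_measure_table(tree, seed = 16)
  a_fix <- 0.15
  ours <- mpgls_model(traits, "acoustic_diversity", tree, alpha = a_fix)
  df <- as.data.frame(traits[match(tree$tip.label, traits$species), ])
  rownames(df) <- df$species
  df$display_height <- factor(df$display_height,
                              levels = c("ground", "understory", "canopy"))
  df$proximity <- factor(df$proximity,
                         levels = c("solitary", "exploded_lek", "lek"))
  ref <- suppressWarnings(nlme::gls(
    log(acoustic_diversity) ~ log(color_diversity) +
      log(behavior_diversity) + display_height + proximity,
    data = df,
    correlation = ape::corMartins(a_fix, phy = tree, fixed = TRUE)))
  tab <- summary(ref)$tTable
  expect_equal(ours$coefficients$estimate, unname(tab[, "Value"]),
               tolerance = 1e-6)
  expect_equal(ours$coefficients$std.error, unname(tab[, "Std.Error"]),
               tolerance = 1e-6)
  expect_equal(ours$coefficients$p.value, unname(tab[, "p-value"]),
               tolerance = 1e-6)
})

test_that("mPGLS design uses reference coding and like measures", {
  tree <- gen_tree(12, seed = 17)
  traits <- sim_measure_table(tree, seed = 17)
  f <- mpgls_model(traits, "color_diversity", tree)
  terms <- tidy(f)$term
  expect_true("log(behavior_diversity)" %in% terms)
  expect_true("log(acoustic_diversity)" %in% terms)
  expect_false("log(color_diversity)" %in% terms)
  expect_false(any(grepl("ground|solitary", terms)))  # reference levels
  # all-reference covariates contribute no dummy columns
  tr2 <- dplyr::mutate(traits, display_height = "ground",
                       proximity = "solitary")
  f2 <- mpgls_model(tr2, "color_diversity", tree)
  expect_false(any(grepl("display_height|proximity", tidy(f2)$term)))
  expect_error(
    mpgls_model(dplyr::mutate(traits, display_height = "treetop"),
                "color_diversity", tree),
    class = "ornadiv_invalid_input")
})

test_that("the profiled OU rate sits at a local optimum", {
  tree <- gen_tree(30, seed = 18)
  traits <- sim_measure_table(tree, seed = 18)
  f <- mpgls_model(traits, "acoustic_diversity", tree, method = "ML")
  a <- f$alpha
  ll_at <- function(aa) {
    g <- mpgls_model(traits, "acoustic_diversity", tree, alpha = aa)
    g$logLik
  }
  expect_gte(ll_at(a) + 1e-6, ll_at(a * 1.2))
  expect_gte(ll_at(a) + 1e-6, ll_at(a / 1.2))
})

test_that("mPGLS results are invariant to tip-order permutation", {
  tree <- gen_tree(15, seed = 19)
  traits <- sim_measure_table(tree, seed = 19)
  f1 <- mpgls_model(traits, "behavior_diversity", tree)
  set.seed(19)
  f2 <- mpgls_model(traits[sample(nrow(traits)), ], "behavior_diversity",
                    tree)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-8)
})

test_that("trait simulation is seeded and respects its covariances", {
  tree <- gen_tree(20, seed = 20)
  a <- simulate_traits(tree, 3, "BM", cross_corr = 0.5, seed = 99)
  b <- simulate_traits(tree, 3, "BM", cross_corr = 0.5, seed = 99)
  expect_identical(a, b)
  # zero cross-correlation: empirical contrast correlation near zero
  set.seed(21)
  cors <- replicate(150, {
    tr <- simulate_traits(tree, 2, "BM", cross_corr = 0)
    p1 <- ape::pic(setNames(tr$trait_1, tr$species), tree)
    p2 <- ape::pic(setNames(tr$trait_2, tr$species), tree)
    cor(p1, p2)
  })
  expect_lt(abs(mean(cors)), 0.05)
  # strong alpha OU: tips near-independent, variance near sigma2
  big <- simulate_traits(tree, 1, "OU", alpha = 1e5, sigma2 = 1, seed = 5)
  expect_lt(abs(var(big$trait_1) - 1), 0.7)
  expect_error(simulate_traits(tree, 2, cross_corr = 2),
               class = "ornadiv_invalid_input")
})

test_that("star-tree BM imputation is the observed mean", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  star$tip.label <- paste0("S", 1:6)
  tr <- tibble::tibble(species = star$tip.label, x = c(1, 2, 3, 4, NA, NA))
  imp <- impute_missing(tr, star, models = "BM")
  expect_equal(imp$traits$x[5:6], c(2.5, 2.5), tolerance = 1e-10)
})

test_that("a zero-distance duplicate tip is imputed exactly", {
  t2 <- ape::read.tree(text = "((A:0,B:0):1,(C:1,D:1):0.5);")
  tr <- tibble::tibble(species = c("A", "B", "C", "D"),
                       x = c(1.7, NA, 0.3, 0.9))
  imp <- suppressWarnings(impute_missing(tr, t2, models = "BM"))
  expect_equal(imp$traits$x[2], 1.7, tolerance = 1e-8)
})

test_that("imputation beats the naive mean and AIC finds the model", {
  tree <- gen_tree(30, seed = 22)
  set.seed(22)
  err_imp <- err_naive <- numeric(40)
  for (r in 1:40) {
    y <- simulate_traits(tree, 1, "BM")$trait_1
    drop <- sample(length(y), 1)
    tr <- tibble::tibble(species = tree$tip.label, x = replace(y, drop, NA))
    imp <- impute_missing(tr, tree, models = c("BM", "OU"))
    err_imp[r] <- imp$traits$x[drop] - y[drop]
    err_naive[r] <- mean(y[-drop]) - y[drop]
  }
  expect_lt(sqrt(mean(err_imp^2)), sqrt(mean(err_naive^2)))
  # model recovery under strong-alpha OU data
  set.seed(23)
  wins <- replicate(30, {
    y <- simulate_traits(tree, 1, "OU", alpha = 1)$trait_1
    tr <- tibble::tibble(species = tree$tip.label,
                         x = replace(y, 1, NA))
    imp <- impute_missing(tr, tree, models = c("BM", "OU"))
    imp$report$model[imp$report$selected]
  })
  expect_gt(mean(wins == "OU"), 0.5)
  expect_error(impute_missing(
    tibble::tibble(species = tree$tip.label, x = NA_real_), tree),
    class = "ornadiv_invalid_input")
})

test_that("composite diversity is the sum of min-max scaled scores", {
  tr <- tibble::tibble(
    species = c("A", "B", "C"),
    color_diversity = c(1, 2, 3),
    behavior_diversity = c(10, 30, 20),
    acoustic_diversity = c(5, 5, 9))
  out <- composite_diversity(tr)
  expect_equal(out$scaled_color_diversity, c(0, 0.5, 1))
  expect_equal(out$scaled_behavior_diversity, c(0, 1, 0.5))
  expect_equal(out$scaled_acoustic_diversity, c(0, 0, 1))
  expect_equal(out$composite, c(0, 1.5, 2.5))
  # constant column warns and scales to zero
  tr$acoustic_diversity <- 4
  expect_warning(out2 <- composite_diversity(tr), "constant")
  expect_equal(out2$scaled_acoustic_diversity, c(0, 0, 0))
})
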