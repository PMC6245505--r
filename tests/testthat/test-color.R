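dichromat <- visual_model(c(s = 1, l = 1), nu = 0.1)

flat_image <- function(side = 8, catches = c(1, 1, 1, 1), lum = 1,
                       margin = 0) {
  grid <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))
  inside <- grid$x >= margin & grid$x < side - margin &
    grid$y >= margin & grid$y < side - margin
  df <- tibble::tibble(grid, mask = inside, lum = lum,
                       u = catches[1], s = catches[2], m = catches[3],
                       l = catches[4])
  cone_catch_image(df, channels = c("u", "s", "m", "l"))
}

test_that("channel noise follows the receptor-density rule", {
  m <- visual_model(c(uvs = 1, sws = 2, mws = 2, lws = 4), nu = 0.1)
  expect_equal(unname(m$omega), c(0.2, 0.1 * sqrt(2), 0.1 * sqrt(2), 0.1),
               tolerance = 1e-12)
  expect_error(visual_model(c(1, -1)), class = "ornadiv_invalid_input")
  expect_error(visual_model(nu = 1.5), class = "ornadiv_invalid_input")
})

test_that("chromatic JND matches closed forms for 2-4 channels", {
  # identical stimuli
  expect_equal(chromatic_jnd(c(1, 2, 3, 4), c(1, 2, 3, 4), visual_model()), 0)
  # dichromat closed form |d1 - d2| / sqrt(w1^2 + w2^2)
  expect_equal(chromatic_jnd(c(2, 1), c(1, 1), dichromat),
               log(2) / (0.1 * sqrt(2)), tolerance = 1e-12)
  # trichromat formula written out longhand
  m3 <- visual_model(c(a = 1, b = 2, c = 4), nu = 0.08)
  w <- unname(m3$omega)
  qa <- c(1.4, 0.8, 2.2); qb <- c(1.1, 1.0, 1.9)
  d <- log(qa) - log(qb)
  want <- sqrt((w[1]^2 * (d[3] - d[2])^2 + w[2]^2 * (d[3] - d[1])^2 +
                w[3]^2 * (d[1] - d[2])^2) /
               ((w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2))
  expect_equal(chromatic_jnd(qa, qb, m3), want, tolerance = 1e-12)
  # tetrachromat longhand
  m4 <- visual_model()
  w <- unname(m4$omega)
  qa <- c(1.2, 0.7, 1.9, 2.4); qb <- c(0.8, 1.1, 2.0, 2.2)
  d <- log(qa) - log(qb)
  num <- (w[1] * w[2])^2 * (d[4] - d[3])^2 + (w[1] * w[3])^2 * (d[4] - d[2])^2 +
    (w[1] * w[4])^2 * (d[3] - d[2])^2 + (w[2] * w[3])^2 * (d[4] - d[1])^2 +
    (w[2] * w[4])^2 * (d[3] - d[1])^2 + (w[3] * w[4])^2 * (d[2] - d[1])^2
  den <- (w[1] * w[2] * w[3])^2 + (w[1] * w[2] * w[4])^2 +
    (w[1] * w[3] * w[4])^2 + (w[2] * w[3] * w[4])^2
  expect_equal(chromatic_jnd(qa, qb, m4), sqrt(num / den), tolerance = 1e-12)
})

test_that("chromatic JND is a pseudometric on log-catch contrasts", {
  m <- visual_model()
  set.seed(3)
  for (i in 1:20) {
    qa <- exp(rnorm(4)); qb <- exp(rnorm(4))
    expect_equal(chromatic_jnd(qa, qb, m), chromatic_jnd(qb, qa, m))
    # uniform intensity scaling is invisible to the chromatic channel
    expect_equal(chromatic_jnd(qa, qa * runif(1, 0.1, 10), m), 0,
                 tolerance = 1e-10)
  }
  expect_error(chromatic_jnd(c(-1, 1, 1, 1), c(1, 1, 1, 1), m),
               class = "ornadiv_invalid_input")
})

test_that("achromatic JND is the noise-scaled log ratio", {
  m <- visual_model()
  expect_equal(achromatic_jnd(1, 1, m), 0)
  expect_equal(achromatic_jnd(2, 1, m), log(2) / 0.1, tolerance = 1e-12)
  expect_equal(achromatic_jnd(3, 7, m), achromatic_jnd(7, 3, m))
  expect_error(achromatic_jnd(0, 1, m), class = "ornadiv_invalid_input")
})

test_that("composite distance scales each component by its threshold", {
  p <- cluster_params(chrom_threshold = 2, lum_threshold = 4)
  expect_equal(composite_distance(0, 0, p), 0)
  expect_equal(composite_distance(2, 4, p), sqrt(2))
  p1 <- cluster_params(chrom_threshold = 1, lum_threshold = 1)
  expect_equal(composite_distance(3, 4, p1), 5)
})

test_that("median blur removes outliers and matches the direct oracle", {
  img <- flat_image(6)
  expect_equal(median_blur(img)$u, img$u)  # constant image unchanged
  # single aberrant pixel in a flat field is replaced
  img2 <- img
  hot <- which(img2$x == 3 & img2$y == 3)
  img2$u[hot] <- 50
  blurred <- median_blur(img2)
  expect_equal(blurred$u[hot], 1)
  # random image vs brute-force neighborhood median, every channel
  set.seed(9)
  img3 <- flat_image(7, margin = 1)
  for (ch in c("u", "s", "m", "l", "lum")) {
    img3[[ch]] <- exp(rnorm(nrow(img3), sd = 0.5))
  }
  img3 <- cone_catch_image(img3, channels = c("u", "s", "m", "l"))
  b3 <- median_blur(img3, radius = 1)
  for (ch in c("u", "s", "m", "l", "lum")) {
    want <- oracle_median_blur(img3, 1, ch)
    expect_equal(b3[[ch]][img3$mask], want[img3$mask], tolerance = 1e-12)
    expect_equal(b3[[ch]][!img3$mask], img3[[ch]][!img3$mask])
  }
})

test_that("flat images collapse to one cluster", {
  cm <- cluster_image(flat_image(10))
  expect_identical(nrow(cm$clusters), 1L)
  expect_equal(cm$clusters$area, 100L)
  sc <- color_complexity(cm)
  expect_equal(unlist(sc), c(richness = 1, diversity = 1))
})

test_that("supra-threshold patches stay separate, sub-threshold ones fuse", {
  img <- gen_cone_catch_image(2, size = 12, sep_jnd = 10, noise_sd = 0,
                              mask_margin = 0, seed = 1)
  cm <- cluster_image(img)
  expect_identical(nrow(cm$clusters), 2L)
  # same two colors but ~0.5 JND apart: single cluster
  img2 <- gen_cone_catch_image(2, size = 12, sep_jnd = 0.5, noise_sd = 0,
                               mask_margin = 0, seed = 1)
  cm2 <- cluster_image(img2)
  expect_identical(nrow(cm2$clusters), 1L)
})

test_that("threshold limits recover distinct values and full fusion", {
  # checkerboard of two colors
  side <- 8
  grid <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))
  chk <- (grid$x + grid$y) %% 2 == 0
  df <- tibble::tibble(grid, mask = TRUE, lum = 1,
                       u = ifelse(chk, 1, 1.4), s = 1,
                       m = ifelse(chk, 1.3, 1), l = 1)
  img <- cone_catch_image(df, channels = c("u", "s", "m", "l"))
  # tiny thresholds: only identical values merge -> 2 clusters
  cm0 <- cluster_image(img, params = cluster_params(1e-9, 1e-9))
  expect_identical(nrow(cm0$clusters), 2L)
  expect_equal(sort(cm0$clusters$area), c(32L, 32L))
  # huge thresholds: one cluster
  cminf <- cluster_image(img, params = cluster_params(1e9, 1e9))
  expect_identical(nrow(cminf$clusters), 1L)
})

test_that("clustering conserves pixel partition and catch mass", {
  set.seed(11)
  img <- gen_cone_catch_image(3, size = 16, noise_sd = 0.05, seed = 11)
  cm <- cluster_image(median_blur(img))
  blur <- median_blur(img)
  fg <- blur[blur$mask, ]
  expect_identical(sum(cm$clusters$area), nrow(fg))
  expect_identical(nrow(cm$pixels), nrow(fg))
  # area-weighted cluster means reproduce the total catch mass per channel
  for (ch in c("u", "s", "m", "l", "lum")) {
    expect_equal(sum(cm$clusters$area * cm$clusters[[ch]]),
                 sum(fg[[ch]]), tolerance = 1e-8)
  }
  # pixel labels and cluster table agree on areas
  expect_equal(sort(as.integer(table(cm$pixels$cluster))),
               sort(cm$clusters$area))
})

test_that("clustering is deterministic", {
  img <- gen_cone_catch_image(4, size = 14, seed = 21)
  a <- cluster_image(median_blur(img))
  b <- cluster_image(median_blur(img))
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$clusters, b$clusters)
})

test_that("color complexity scores cluster areas", {
  expect_equal(unlist(color_complexity(fake_cluster_map(c(50, 25, 25)))),
               c(richness = 3, diversity = 2 * sqrt(2)), tolerance = 1e-6)
  expect_equal(unlist(color_complexity(fake_cluster_map(rep(10, 4)))),
               c(richness = 4, diversity = 4))
  # min-area filter drops specks
  sc <- color_complexity(fake_cluster_map(c(96, 2, 2)), min_area_frac = 0.05)
  expect_equal(sc$richness, 1L)
})

test_that("view and specimen averaging is a two-level mean", {
  vs <- tibble::tibble(
    species = "X",
    specimen = rep(c("m1", "m2"), each = 3),
    view = rep(c("dorsal", "ventral", "angled"), 2),
    richness = c(2, 4, 6, 1, 1, 1),
    diversity = c(2, 2, 2, 1, 1, 4))
  out <- species_color_complexity(vs)
  expect_equal(out$value[out$metric == "richness"], mean(c(4, 1)))
  expect_equal(out$value[out$metric == "diversity"], mean(c(2, 2)))
  # single view passes through
  one <- species_color_complexity(vs[1, ])
  expect_equal(one$value[one$metric == "richness"], 2)
})
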