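#' Construct a cone-catch image from a per-pixel table
#'
#' A cone-catch image is stored in long/tidy form: one row per pixel with
#' 0-based integer coordinates `x` (column) and `y` (row), a logical
#' foreground `mask`, a positive luminance catch `lum`, and one positive
#' quantum-catch column per chromatic channel. Catches need only be
#' positive on foreground pixels.
#'
#' @param data Data frame with columns `x`, `y`, `mask`, `lum` and the
#'   channel columns.
#' @param channels Character vector naming the chromatic channel columns;
#'   default: every numeric column other than `x`, `y`, `lum`.
#' @return A tibble of class `ornadiv_cone_image` carrying a `channels`
#'   attribute.
#' @export
cone_catch_image <- function(data, channels = NULL) {
  need <- c("x", "y", "mask", "lum")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Image lacks column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "ornadiv_invalid_input")
  if (is.null(channels)) {
    channels <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                        c("x", "y", "lum"))
  }
  if (length(channels) < 2) abort("Need at least 2 chromatic channels.",
                                  class = "ornadiv_invalid_input")
  if (!any(data$mask)) abort("Mask selects no foreground pixels.",
                             class = "ornadiv_invalid_input")
  fg <- data[data$mask, , drop = FALSE]
  if (any(fg$lum <= 0) || any(as.matrix(fg[channels]) <= 0)) {
    abort("Foreground catches must be positive (log model).",
          class = "ornadiv_invalid_input")
  }
  out <- tibble::as_tibble(data)
  attr(out, "channels") <- channels
  class(out) <- c("ornadiv_cone_image", class(out))
  out
}

image_channels <- function(img) {
  ch <- attr(img, "channels")
  if (is.null(ch)) abort("Not a cone-catch image; use cone_catch_image().",
                         class = "ornadiv_invalid_input")
  ch
}

# long tibble -> list of H x W matrices (NA off the raster), plus geometry
image_to_planes <- function(img) {
  ch <- image_channels(img)
  W <- max(img$x) + 1L; H <- max(img$y) + 1L
  idx <- img$y + 1L + H * img$x  # column-major position for [y+1, x+1]
  plane <- function(v) {
    m <- matrix(NA_real_, H, W)
    m[idx] <- v
    m
  }
  mask <- matrix(FALSE, H, W)
  mask[idx] <- img$mask
  list(channels = lapply(img[ch], plane), lum = plane(img$lum),
       mask = mask, H = H, W = W, ch = ch)
}

#' Median blur of a cone-catch image
#'
#' Replaces every foreground pixel's catches (each chromatic channel and
#' luminance independently) with the median over the `(2r+1) x (2r+1)`
#' neighborhood restricted to foreground pixels, removing aberrant pixel
#' values (dust, dead pixels) before clustering. The mask is unchanged.
#'
#' @param img A [cone_catch_image()].
#' @param radius Neighborhood radius in pixels, default 1 (3x3).
#' @return A blurred `ornadiv_cone_image`.
#' @export
median_blur <- function(img, radius = 1) {
  if (radius < 1) abort("`radius` must be >= 1.", class = "ornadiv_invalid_input")
  pl <- image_to_planes(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  shift <- function(m, dy, dx) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(NA_real_, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  fgidx <- which(pl$mask)
  blur_plane <- function(m) {
    m[!pl$mask] <- NA_real_
    stack <- vapply(seq_len(nrow(offs)),
                    function(k) shift(m, offs$dy[k], offs$dx[k])[fgidx],
                    numeric(length(fgidx)))
    apply(stack, 1, median, na.rm = TRUE)
  }
  out <- img
  H <- pl$H
  ord <- match(img$y + 1L + H * img$x, fgidx)  # NA for background rows
  for (chn in pl$ch) {
    v <- blur_plane(pl$channels[[chn]])
    out[[chn]] <- ifelse(is.na(ord), img[[chn]], v[ord])
  }
  vl <- blur_plane(pl$lum)
  out$lum <- ifelse(is.na(ord), img$lum, vl[ord])
  out
}

# Unique neighboring cluster pairs (a < b) with any two pixels within
# Chebyshev radius r of each other, from the label matrix.
neighbor_pairs <- function(lab, r) {
  H <- nrow(lab); W <- ncol(lab)
  acc_a <- vector("list", 0L); acc_b <- vector("list", 0L)
  k <- 0L
  for (dy in 0:min(r, H - 1L)) {
    dx_range <- if (dy == 0) seq_len(min(r, W - 1L)) else -min(r, W - 1L):min(r, W - 1L)
    for (dx in dx_range) {
      ys <- 1:(H - dy)
      xs <- max(1, 1 + dx):min(W, W + dx)
      a <- lab[ys, xs, drop = FALSE]
      b <- lab[ys + dy, xs - dx, drop = FALSE]
      keep <- !is.na(a) & !is.na(b) & a != b
      if (any(keep)) {
        k <- k + 1L
        acc_a[[k]] <- a[keep]; acc_b[[k]] <- b[keep]
      }
    }
  }
  if (k == 0L) return(NULL)
  a <- unlist(acc_a); b <- unlist(acc_b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(lo * (max(hi) + 1) + hi)
  cbind(lo[keep], hi[keep])
}

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Cluster a cone-catch image into perceptually distinct color patches
#'
#' Agglomerative spatial-chromatic clustering. Every foreground pixel
#' starts as its own cluster; on each pass, clusters are compared with the
#' neighboring clusters that have pixels within the current Chebyshev
#' search radius (1 pixel initially, growing each pass), using the
#' composite of threshold-scaled chromatic and achromatic JNDs between
#' cluster mean catches. Each cluster is merged with its nearest neighbor
#' (by composite distance) when both component distances fall below their
#' thresholds; accepted merges chain transitively within a pass (if A is
#' nearest to B and B nearest to C, all three fuse). Cluster means are
#' recomputed as area-weighted means after each pass. The algorithm stops
#' when a pass merges nothing and the radius has reached the image
#' dimension, so identically colored but distant patches end up in one
#' cluster; clustering therefore operates over n + 2 dimensions (n channels
#' plus x and y).
#'
#' @param img A [cone_catch_image()], normally after [median_blur()].
#' @param model A [visual_model()] whose channel count matches the image.
#' @param params A [cluster_params()].
#' @return An object of class `ornadiv_cluster_map`: a list with `pixels`
#'   (tibble `x`, `y`, `cluster`), `clusters` (tibble `cluster`, `area`,
#'   mean catch per channel, `lum`), `passes` and `converged`.
#' @export
cluster_image <- function(img, model = visual_model(), params = cluster_params()) {
  pl <- image_to_planes(img)
  if (length(pl$ch) != length(model$omega)) {
    abort("Image channel count does not match the visual model.",
          class = "ornadiv_invalid_input")
  }
  fgidx <- which(pl$mask)
  P <- length(fgidx)
  if (P == 0L) abort("Empty foreground.", class = "ornadiv_invalid_input")
  lab <- matrix(NA_integer_, pl$H, pl$W)
  lab[fgidx] <- seq_len(P)
  # running per-cluster sums of linear catches; means = sums / area
  sums <- cbind(vapply(pl$channels, function(m) m[fgidx], numeric(P)),
                lum = pl$lum[fgidx])
  area <- rep(1L, P)
  alive <- rep(TRUE, P)
  maxdim <- max(pl$H, pl$W)
  r <- params$initial_radius
  passes <- 0L
  converged <- FALSE
  nch <- length(pl$ch)

  while (passes < params$max_passes) {
    passes <- passes + 1L
    merged_any <- FALSE
    if (sum(alive) > 1L) {
      prs <- neighbor_pairs(lab, min(r, maxdim))
      if (!is.null(prs)) {
        ma <- sums[prs[, 1], , drop = FALSE] / area[prs[, 1]]
        mb <- sums[prs[, 2], , drop = FALSE] / area[prs[, 2]]
        dS <- chromatic_jnd(ma[, seq_len(nch), drop = FALSE],
                            mb[, seq_len(nch), drop = FALSE], model)
        dL <- achromatic_jnd(ma[, nch + 1L], mb[, nch + 1L], model)
        comp <- composite_distance(dS, dL, params)
        ok <- dS < params$chrom_threshold & dL < params$lum_threshold
        # directed nearest neighbor per cluster; ties -> lowest neighbor id
        from <- c(prs[, 1], prs[, 2]); to <- c(prs[, 2], prs[, 1])
        cc <- c(comp, comp); oo <- c(ok, ok)
        ordix <- order(from, cc, to)
        first <- ordix[!duplicated(from[ordix])]
        ef <- from[first][oo[first]]
        et <- to[first][oo[first]]
        if (length(ef)) {
          parent <- seq_len(P)
          for (e in seq_along(ef)) {
            ra <- uf_find(parent, ef[e]); rb <- uf_find(parent, et[e])
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          }
          root <- vapply(seq_len(P), function(i)
            if (alive[i]) uf_find(parent, i) else i, integer(1))
          if (any(root[alive] != which(alive))) {
            merged_any <- TRUE
            for (i in which(alive)) {
              ri <- root[i]
              if (ri != i) {
                sums[ri, ] <- sums[ri, ] + sums[i, ]
                area[ri] <- area[ri] + area[i]
                alive[i] <- FALSE
              }
            }
            lab[fgidx] <- root[lab[fgidx]]
          }
        }
      }
    }
    if (!merged_any && (r >= maxdim || sum(alive) == 1L)) {
      converged <- TRUE
      break
    }
    r <- r + params$radius_increment
  }
  if (!converged) {
    warn("cluster_image() hit max_passes before quiescence; returning the partial clustering.")
  }
  ids <- which(alive)
  relab <- match(lab[fgidx], ids)
  means <- sums[ids, , drop = FALSE] / area[ids]
  clusters <- tibble::as_tibble(as.data.frame(means))
  names(clusters) <- c(pl$ch, "lum")
  clusters <- dplyr::bind_cols(
    tibble::tibble(cluster = seq_along(ids), area = as.integer(area[ids])),
    clusters)
  pixels <- tibble::tibble(
    x = (fgidx - 1L) %/% pl$H,
    y = (fgidx - 1L) %% pl$H,
    cluster = relab)
  structure(list(pixels = pixels, clusters = clusters, passes = passes,
                 converged = converged, channels = pl$ch),
            class = "ornadiv_cluster_map")
}

#' @export
print.ornadiv_cluster_map <- function(x, ...) {
  cat("Color cluster map: ", nrow(x$clusters), " cluster(s), ",
      sum(x$clusters$area), " foreground pixels, ", x$passes, " pass(es)",
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Color richness and diversity of a cluster map
#'
#' Richness is the number of clusters; diversity is the numbers equivalent
#' of the Shannon entropy of cluster area proportions. An optional minimum
#' area fraction discards speck clusters first.
#'
#' @param cm An `ornadiv_cluster_map` from [cluster_image()].
#' @param min_area_frac Minimum cluster area as a fraction of the
#'   foreground; default taken from the clustering parameters' companion
#'   setting (0 = keep everything).
#' @return One-row tibble with `richness` and `diversity`.
#' @export
color_complexity <- function(cm, min_area_frac = 0) {
  cl <- cm$clusters
  if (min_area_frac > 0) {
    cl <- cl[cl$area >= min_area_frac * sum(cl$area), , drop = FALSE]
    if (nrow(cl) == 0L) abort("All clusters fell below `min_area_frac`.",
                              class = "ornadiv_invalid_input")
  }
  complexity_score(cl, weight = area)
}

#' Average view scores into specimen and species color scores
#'
#' Museum specimens are photographed from several views (dorsal, ventral,
#' angled); each view yields a richness/diversity pair. Specimen scores are
#' the arithmetic mean over available views, and species scores the mean
#' over specimens.
#'
#' @param view_scores Tibble with columns `species`, `specimen`, `view`,
#'   `richness`, `diversity` (one row per scored view).
#' @return Tibble with columns `species`, `metric`, `value`, `n_specimens`.
#' @export
species_color_complexity <- function(view_scores) {
  view_scores |>
    tidyr::pivot_longer(c("richness", "diversity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("species", "specimen", "metric")) |>
    dplyr::summarise(n_specimens = dplyr::n_distinct(.data$specimen),
                     value = mean(.data$value),
                     .by = c("species", "metric")) |>
    dplyr::select("species", "metric", "value", "n_specimens")
}

#' Plot a color cluster map
#'
#' @param object An `ornadiv_cluster_map`.
#' @param ... Unused.
#' @return A ggplot raster of cluster membership.
#' @export
autoplot.ornadiv_cluster_map <- function(object, ...) {
  ggplot2::ggplot(object$pixels,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "cluster", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
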