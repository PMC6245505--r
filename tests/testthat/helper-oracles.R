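# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Exhaustive sliding-window maxima: plain loops, no dplyr, no shared helpers.
oracle_window_max <- function(events, window_len_s, step_s = 1,
                              event_weight_s = 1) {
  best_rich <- -Inf; best_div <- -Inf
  best_rich_at <- best_div_at <- NULL
  for (cl in unique(events$clip)) {
    toks <- events[events$clip == cl, , drop = FALSE]
    dur <- if ("clip_dur_s" %in% names(toks)) max(toks$clip_dur_s) else max(toks$end_s)
    if (dur <= window_len_s) {
      offsets <- 0; len <- dur
    } else {
      offsets <- seq(0, dur - window_len_s, by = step_s); len <- window_len_s
    }
    for (s in offsets) {
      wend <- s + len
      w <- c()
      for (i in seq_len(nrow(toks))) {
        lab <- toks$label[i]
        if (toks$kind[i] == "state") {
          ov <- min(toks$end_s[i], wend) - max(toks$start_s[i], s)
          if (ov > 0) w[lab] <- (if (lab %in% names(w)) w[lab] else 0) + ov
        } else {
          if (toks$start_s[i] >= s && toks$start_s[i] < wend) {
            w[lab] <- (if (lab %in% names(w)) w[lab] else 0) + event_weight_s
          }
        }
      }
      w <- w[w > 0]
      if (!length(w)) next
      p <- w / sum(w)
      rich <- length(w)
      div <- exp(-sum(p * log(p)))
      if (rich > best_rich) { best_rich <- rich; best_rich_at <- c(cl, s) }
      if (div > best_div + 1e-12) { best_div <- div; best_div_at <- c(cl, s) }
    }
  }
  list(richness = best_rich, diversity = best_div,
       richness_at = best_rich_at, diversity_at = best_div_at)
}

# Random timed sequences for oracle-equivalence checks.
random_sequence <- function(n_tokens, n_labels = 6, n_clips = 2,
                            clip_dur = 80) {
  per_clip <- ceiling(n_tokens / n_clips)
  out <- list()
  for (cl in seq_len(n_clips)) {
    k <- min(per_clip, n_tokens - (cl - 1) * per_clip)
    if (k <= 0) break
    kind <- sample(c("state", "event"), k, replace = TRUE)
    start <- round(runif(k, 0, clip_dur - 1), 2)
    len <- ifelse(kind == "state", round(runif(k, 0.5, 15), 2), 0)
    out[[cl]] <- data.frame(
      species = "X", individual = "X_I1", clip = paste0("c", cl),
      label = paste0("B", sample.int(n_labels, k, replace = TRUE)),
      kind = kind, start_s = start,
      end_s = pmin(start + len, clip_dur), clip_dur_s = clip_dur,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Dense-algebra GLS oracle via explicit inverses.
oracle_gls <- function(y, X, C) {
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  beta <- solve(XtCiX, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- as.numeric(t(r) %*% Ci %*% r) / (n - p)
  se <- sqrt(sigma2 * diag(solve(XtCiX)))
  list(beta = as.numeric(beta), se = as.numeric(se), sigma2 = sigma2)
}

# Foreground-restricted median filter by direct neighborhood gathering.
oracle_median_blur <- function(img, radius, channel) {
  out <- numeric(nrow(img))
  for (i in seq_len(nrow(img))) {
    if (!img$mask[i]) { out[i] <- img[[channel]][i]; next }
    nb <- abs(img$x - img$x[i]) <= radius & abs(img$y - img$y[i]) <= radius &
      img$mask
    out[i] <- median(img[[channel]][nb])
  }
  out
}

# A hand-built cluster map object for scoring tests.
fake_cluster_map <- function(areas) {
  structure(list(
    pixels = NULL,
    clusters = tibble::tibble(cluster = seq_along(areas),
                              area = as.integer(areas),
                              lum = 1),
    passes = 1L, converged = TRUE, channels = character()),
    class = "ornadiv_cluster_map")
}
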