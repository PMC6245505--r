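#' Standardize acoustic features and run a correlation-matrix PCA
#'
#' Each acoustic summary feature (duration, max/min frequency, bandwidth,
#' peak frequency, contour summaries, entropy measures, ...) is z-scored
#' and a principal component analysis is computed on the standardized
#' matrix. Zero-variance features are dropped with a warning. Component
#' signs follow the convention that the largest-magnitude loading of each
#' component is positive.
#'
#' @param notes Data frame with one row per note.
#' @param features Character vector of feature column names; default: all
#'   numeric columns except bookkeeping columns (`onset_s` and id columns).
#' @return An object of class `ornadiv_note_pca`: list with `scores`
#'   (tibble, `PC1..PCk`), `loadings` (orthonormal matrix), `sdev`,
#'   `variance_explained`, `features`, and `standardized` matrix.
#' @export
note_pca <- function(notes, features = NULL) {
  if (is.null(features)) {
    drop <- c("species", "individual", "clip", "onset_s", "clip_dur_s",
              "component", "cluster_id", "qual_code",
              "fm", "nonharmonic", "impulsive", "stochastic")
    features <- setdiff(names(notes)[vapply(notes, is.numeric, TRUE)], drop)
  }
  if (nrow(notes) < 2 || length(features) < 2) {
    abort("Need at least 2 notes and 2 features.", class = "ornadiv_invalid_input")
  }
  X <- as.matrix(notes[features])
  if (anyNA(X)) abort("Feature matrix contains missing values.",
                      class = "ornadiv_invalid_input")
  v <- apply(X, 2, var)
  if (any(v == 0)) {
    warn(paste0("Dropping zero-variance feature(s): ",
                paste(features[v == 0], collapse = ", ")))
    features <- features[v > 0]
    X <- X[, v > 0, drop = FALSE]
    if (ncol(X) < 2) abort("Fewer than 2 features left after dropping.",
                           class = "ornadiv_invalid_input")
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(
    scores = tibble::as_tibble(as.data.frame(p$x)),
    loadings = p$rotation,
    sdev = p$sdev,
    variance_explained = p$sdev^2 / sum(p$sdev^2),
    features = features,
    standardized = scale(X)
  ), class = "ornadiv_note_pca")
}

#' @export
print.ornadiv_note_pca <- function(x, ...) {
  cat("Note PCA:", length(x$features), "features,",
      nrow(x$scores), "notes\n")
  cat("  variance explained (first 3):",
      paste(signif(head(x$variance_explained, 3), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the loadings of a note PCA
#'
#' @param x An `ornadiv_note_pca`.
#' @param ... Unused.
#' @return Tibble `feature`, `component`, `loading` (long form, S9-style).
#' @export
tidy.ornadiv_note_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.ornadiv_note_pca <- function(x, ...) {
  tibble::tibble(n_notes = nrow(x$scores), n_features = length(x$features),
                 var_pc1 = x$variance_explained[1],
                 var_pc123 = sum(head(x$variance_explained, 3)))
}

#' Cluster notes in PC space
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage
#' by default) of notes placed in three-dimensional PCA sound space. The
#' tree is cut at `k` clusters when `k` is given; otherwise at the largest
#' relative gap between successive merge heights.
#'
#' @param scores Data frame of PC coordinates (the first up-to-3 columns
#'   are used), e.g. `note_pca(notes)$scores`.
#' @param k Optional integer number of clusters.
#' @param linkage One of `"ward"`, `"average"`, `"complete"`.
#' @param min_gap_ratio When cutting automatically, the winning
#'   merge-height ratio must exceed this value, else the notes are treated
#'   as a single unstructured cloud (k = 1). Default 2.
#' @return Integer vector of cluster ids, one per note.
#' @export
cluster_notes <- function(scores, k = NULL,
                          linkage = c("ward", "average", "complete"),
                          min_gap_ratio = 2) {
  linkage <- match.arg(linkage)
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  S <- as.matrix(scores)[, seq_len(min(3L, ncol(scores))), drop = FALSE]
  n <- nrow(S)
  if (n == 0L) abort("No notes to cluster.", class = "ornadiv_invalid_input")
  if (!is.null(k) && (k < 1 || k > n)) {
    abort("`k` must lie in [1, number of notes].", class = "ornadiv_invalid_input")
  }
  if (n == 1L) return(1L)
  hc <- hclust(dist(S), method = method)
  if (is.null(k)) {
    h <- hc$height
    if (length(h) < 2) {
      k <- 1L
    } else {
      # cut where successive merge heights jump the most, relatively;
      # restricted to merges above the median height, else near-zero early
      # heights dominate the ratio
      ratio <- h[-1] / pmax(h[-length(h)], .Machine$double.eps)
      eligible <- h[-1] > median(h)
      if (!any(eligible)) eligible <- rep(TRUE, length(ratio))
      k <- if (max(ratio[eligible]) < min_gap_ratio) 1L
           else n - which.max(ratio * eligible)
    }
  }
  unname(cutree(hc, k = k))
}

#' Encode the four qualitative note flags as an integer
#'
#' Binary encoding of the manually scored yes/no qualities, bit order
#' (frequency modulation, nonharmonic structure, impulsive, stochastic)
#' from most to least significant.
#'
#' @param fm,nonharmonic,impulsive,stochastic Logical vectors.
#' @return Integer vector in 0..15.
#' @examples
#' qualitative_code(TRUE, FALSE, FALSE, FALSE)  # 8
#' @export
qualitative_code <- function(fm, nonharmonic, impulsive, stochastic) {
  as.integer(fm) * 8L + as.integer(nonharmonic) * 4L +
    as.integer(impulsive) * 2L + as.integer(stochastic)
}

#' Assign full note identities
#'
#' Two-step semiautomated classification: notes are placed in PCA sound
#' space and clustered to obtain a partial (acoustic) identity, then each
#' note's qualitative code is appended; the full identity is the pair
#' (cluster, qualitative code).
#'
#' @param notes Note table with feature columns and logical flag columns
#'   `fm`, `nonharmonic`, `impulsive`, `stochastic`.
#' @param k Optional cluster count passed to [cluster_notes()].
#' @param features Optional feature column names for [note_pca()].
#' @param linkage Linkage passed to [cluster_notes()].
#' @return The note table with added columns `cluster_id`, `qual_code`,
#'   `full_id` (a string "cluster.code").
#' @export
assign_note_identity <- function(notes, k = NULL, features = NULL,
                                 linkage = "ward") {
  flags <- c("fm", "nonharmonic", "impulsive", "stochastic")
  miss <- setdiff(flags, names(notes))
  if (length(miss)) abort(paste0("Note table lacks flag column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "ornadiv_invalid_input")
  if (nrow(notes) == 1L) {
    cl <- 1L
  } else {
    pca <- note_pca(notes, features = features)
    cl <- cluster_notes(pca$scores, k = k, linkage = linkage)
  }
  notes |>
    dplyr::mutate(
      cluster_id = cl,
      qual_code = qualitative_code(.data$fm, .data$nonharmonic,
                                   .data$impulsive, .data$stochastic),
      full_id = paste(.data$cluster_id, .data$qual_code, sep = "."))
}

#' Species-level acoustic complexity from an identified note table
#'
#' Treats each note as an instantaneous event labeled by its full identity
#' and reuses the sliding-window machinery: per individual, the 10-second
#' window (default) of maximal richness and of maximal diversity is found
#' across all clips, and individual maxima are averaged within species.
#' Notes are weighted by count (one token each), being near-instantaneous
#' relative to the window.
#'
#' @param notes Note table with `species`, `individual`, `clip`, `onset_s`
#'   and `full_id` columns (see [assign_note_identity()]); an optional
#'   `clip_dur_s` column bounds the windows, else the last onset does.
#' @param window_len_s Window length in seconds, default 10.
#' @param step_s Window offset increment, default 1.
#' @param single_window_by See [sliding_max_complexity()].
#' @return Tibble `species`, `metric`, `value`, `n_individuals`.
#' @export
acoustic_complexity <- function(notes, window_len_s = 10, step_s = 1,
                                single_window_by = NULL) {
  if (!"full_id" %in% names(notes)) {
    abort("Notes lack `full_id`; run assign_note_identity() first.",
          class = "ornadiv_invalid_input")
  }
  ev <- notes |>
    dplyr::transmute(
      species = .data$species, individual = .data$individual,
      clip = .data$clip, label = .data$full_id, kind = "event",
      start_s = .data$onset_s, end_s = .data$onset_s,
      clip_dur_s = if ("clip_dur_s" %in% names(notes)) .data$clip_dur_s
                   else NA_real_)
  if (all(is.na(ev$clip_dur_s))) {
    ev$clip_dur_s <- NULL
  } else {
    ev <- ev |>
      dplyr::mutate(clip_dur_s = ifelse(is.na(.data$clip_dur_s),
                                        max(.data$start_s),
                                        .data$clip_dur_s),
                    .by = c("species", "individual", "clip"))
  }
  behavior_complexity(ev, window_len_s = window_len_s, step_s = step_s,
                      event_weight_s = 1, single_window_by = single_window_by)
}

#' Read a note-table CSV
#'
#' Header-driven: columns `species`, `individual`, `clip`, `onset_s`,
#' `duration_s`, the four flag columns (`fm`, `nonharmonic`, `impulsive`,
#' `stochastic`, parsed as logical) and any number of numeric acoustic
#' feature columns.
#'
#' @param path Path to the CSV file.
#' @return A note tibble.
#' @export
read_note_table <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("species", "individual", "clip", "onset_s", "duration_s",
            "fm", "nonharmonic", "impulsive", "stochastic")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Note table lacks column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "ornadiv_invalid_input")
  dplyr::mutate(df, dplyr::across(c("fm", "nonharmonic", "impulsive",
                                    "stochastic"), as.logical))
}
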