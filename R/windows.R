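#' Weights of display elements inside one time window
#'
#' Collapses the tokens of a timed sequence that fall inside a window
#' `[start_s, start_s + len_s)` into a weighted categorical distribution.
#' State tokens (with duration) contribute the duration of their overlap
#' with the window; event tokens (instantaneous) whose instant falls in the
#' half-open window contribute a nominal duration `event_weight_s`, making
#' counts and state durations commensurate in one time-proportion
#' distribution.
#'
#' @param tokens A data frame with one row per token and columns `label`,
#'   `kind` (`"state"` or `"event"`), `start_s`, `end_s`. Events must have
#'   `end_s == start_s`.
#' @param start_s Window start (seconds from clip start).
#' @param len_s Window length in seconds (> 0).
#' @param event_weight_s Nominal duration credited to each event token,
#'   default 1 second.
#' @return A tibble with columns `label`, `weight`; zero rows when nothing
#'   falls in the window (an unscorable window).
#' @export
window_weights <- function(tokens, start_s, len_s, event_weight_s = 1) {
  if (len_s <= 0) abort("`len_s` must be > 0.", class = "ornadiv_invalid_window")
  if (start_s < 0) abort("Window starts before the clip.", class = "ornadiv_invalid_window")
  check_tokens(tokens)
  wend <- start_s + len_s
  is_state <- tokens$kind == "state"
  ovl <- pmax(0, pmin(tokens$end_s, wend) - pmax(tokens$start_s, start_s))
  in_win <- tokens$start_s >= start_s & tokens$start_s < wend
  weight <- ifelse(is_state, ovl, ifelse(in_win, event_weight_s, 0))
  out <- tibble::tibble(label = tokens$label, weight = weight) |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::summarise(weight = sum(.data$weight), .by = "label")
  out
}

check_tokens <- function(tokens) {
  need <- c("label", "kind", "start_s", "end_s")
  miss <- setdiff(need, names(tokens))
  if (length(miss)) {
    abort(paste0("Token table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "ornadiv_invalid_input")
  }
  if (!all(tokens$kind %in% c("state", "event"))) {
    abort("`kind` must be \"state\" or \"event\".", class = "ornadiv_invalid_input")
  }
  bad <- tokens$kind == "event" & tokens$end_s != tokens$start_s
  if (any(bad)) abort("Event tokens must have end_s == start_s.",
                      class = "ornadiv_invalid_input")
  if (any(tokens$end_s < tokens$start_s)) {
    abort("Tokens must have end_s >= start_s.", class = "ornadiv_invalid_input")
  }
  invisible(tokens)
}

clip_window_offsets <- function(clip_dur, window_len_s, step_s) {
  if (clip_dur <= window_len_s) return(tibble::tibble(start = 0, len = clip_dur))
  tibble::tibble(start = seq(0, clip_dur - window_len_s, by = step_s),
                 len = window_len_s)
}

#' Maximal sliding-window complexity for one individual
#'
#' Slides a fixed-length window along every clip of one individual's timed
#' sequence, scores each window's richness and diversity, and returns the
#' window(s) of maximal complexity. Windows are placed at offsets
#' `0, step_s, 2 step_s, ...` and never span clip boundaries; a clip shorter
#' than the window contributes a single whole-clip window, so rare species
#' with short recordings still receive scores. Richness and diversity maxima
#' are located independently unless `single_window_by` names one metric, in
#' which case both scores are read from that metric's maximal window. Ties
#' go to the earliest clip (input order), then the earliest offset.
#'
#' @param events Data frame of tokens for a single individual, with columns
#'   `clip`, `label`, `kind`, `start_s`, `end_s`, and optionally
#'   `clip_dur_s` (else the clip's maximum `end_s` is used).
#' @param window_len_s Window length in seconds.
#' @param step_s Offset increment in seconds, default 1.
#' @param event_weight_s Nominal event duration, see [window_weights()].
#' @param single_window_by `NULL` (default, independent maxima) or one of
#'   `"richness"`, `"diversity"` to score both metrics from a single
#'   maximal window.
#' @return A tibble with columns `metric`, `value`, `clip`,
#'   `window_start_s`, `window_len_s` (one row per metric), or zero rows if
#'   no window is scorable.
#' @export
sliding_max_complexity <- function(events, window_len_s, step_s = 1,
                                   event_weight_s = 1,
                                   single_window_by = NULL) {
  scores <- window_scores(events, window_len_s, step_s, event_weight_s)
  if (nrow(scores) == 0L) return(scores_empty())
  if (!is.null(single_window_by)) {
    single_window_by <- match.arg(single_window_by, c("richness", "diversity"))
    top <- scores[which.max(scores[[single_window_by]]), , drop = FALSE]
    return(tibble::tibble(
      metric = c("richness", "diversity"),
      value = c(top$richness, top$diversity),
      clip = top$clip, window_start_s = top$start, window_len_s = top$len
    ))
  }
  pick <- function(metric) {
    top <- scores[which.max(scores[[metric]]), , drop = FALSE]
    tibble::tibble(metric = metric, value = top[[metric]], clip = top$clip,
                   window_start_s = top$start, window_len_s = top$len)
  }
  dplyr::bind_rows(pick("richness"), pick("diversity"))
}

scores_empty <- function() {
  tibble::tibble(metric = character(), value = double(), clip = character(),
                 window_start_s = double(), window_len_s = double())
}

# All window scores for one individual; which.max on the result honours the
# earliest-clip-then-earliest-offset tie-break because rows are emitted in
# clip input order and increasing offset. Weight accumulation matches
# window_weights() exactly but runs vectorized across offsets.
window_scores <- function(events, window_len_s, step_s, event_weight_s) {
  check_tokens(events)
  if (!"clip" %in% names(events)) abort("Token table lacks `clip`.",
                                        class = "ornadiv_invalid_input")
  clips <- unique(events$clip)
  purrr::map(clips, function(cl) {
    toks <- events[events$clip == cl, , drop = FALSE]
    dur <- if ("clip_dur_s" %in% names(toks)) max(toks$clip_dur_s) else max(toks$end_s)
    if (dur <= 0) return(NULL)
    offs <- clip_window_offsets(dur, window_len_s, step_s)
    labf <- factor(toks$label)
    is_state <- toks$kind == "state"
    ts <- toks$start_s; te <- toks$end_s
    nwin <- nrow(offs)
    rich <- div <- numeric(nwin)
    ok <- logical(nwin)
    for (i in seq_len(nwin)) {
      s <- offs$start[i]; wend <- s + offs$len[i]
      wt <- ifelse(is_state, pmax(0, pmin(te, wend) - pmax(ts, s)),
                   ifelse(ts >= s & ts < wend, event_weight_s, 0))
      ws <- rowsum(wt, labf)
      ws <- ws[ws > 0]
      if (!length(ws)) next
      ok[i] <- TRUE
      rich[i] <- length(ws)
      p <- ws / sum(ws)
      div[i] <- exp(-sum(p * log(p)))
    }
    if (!any(ok)) return(NULL)
    tibble::tibble(clip = as.character(cl), start = offs$start[ok],
                   len = offs$len[ok], richness = rich[ok],
                   diversity = div[ok])
  }) |> purrr::compact() |> dplyr::bind_rows()
}

#' Per-individual maximal complexity for a full event log
#'
#' Applies [sliding_max_complexity()] to every individual in a multi-species
#' event log and returns the per-individual maxima in long form.
#' Individuals with no scorable window are dropped (they propagate as
#' missing at the species level).
#'
#' @param events Event-log data frame with columns `species`, `individual`,
#'   `clip`, `label`, `kind`, `start_s`, `end_s`.
#' @inheritParams sliding_max_complexity
#' @return Tibble with columns `species`, `individual`, `metric`, `value`,
#'   `clip`, `window_start_s`, `window_len_s`.
#' @export
individual_complexity <- function(events, window_len_s = 50, step_s = 1,
                                  event_weight_s = 1, single_window_by = NULL) {
  events |>
    dplyr::group_by(.data$species, .data$individual) |>
    dplyr::group_modify(function(d, key) {
      sliding_max_complexity(d, window_len_s, step_s, event_weight_s,
                             single_window_by)
    }) |>
    dplyr::ungroup()
}

#' Average individual scores to species level
#'
#' Species scores are the unweighted arithmetic mean of per-individual
#' maximal-window scores; individuals without scores are excluded.
#'
#' @param ind_scores Output of [individual_complexity()].
#' @return Tibble with columns `species`, `metric`, `value`,
#'   `n_individuals`.
#' @export
aggregate_species <- function(ind_scores) {
  ind_scores |>
    dplyr::summarise(n_individuals = dplyr::n_distinct(.data$individual),
                     value = mean(.data$value),
                     .by = c("species", "metric")) |>
    dplyr::select("species", "metric", "value", "n_individuals")
}

#' Species-level behavioral complexity from an event log
#'
#' Full behavioral pipeline: per-individual maximal 50-second-window
#' richness and diversity, averaged within species.
#'
#' @inheritParams individual_complexity
#' @return Tibble with columns `species`, `metric`, `value`,
#'   `n_individuals`.
#' @examples
#' log <- gen_behavior_logs(gen_species_profiles(n_species = 2, seed = 1), seed = 1)
#' behavior_complexity(log, window_len_s = 20)
#' @export
behavior_complexity <- function(events, window_len_s = 50, step_s = 1,
                                event_weight_s = 1, single_window_by = NULL) {
  individual_complexity(events, window_len_s, step_s, event_weight_s,
                        single_window_by) |>
    aggregate_species()
}

#' Species scores across a sweep of window sizes
#'
#' Recomputes species-level complexity for each window length in
#' `window_sizes`, for robustness reporting (behavioral sweeps typically
#' cover 10-60 s, acoustic sweeps 5-50 s).
#'
#' @inheritParams individual_complexity
#' @param window_sizes Numeric vector of window lengths in seconds.
#' @return Tibble with columns `window_len_s`, `species`, `metric`, `value`,
#'   `n_individuals`.
#' @export
window_sweep <- function(events, window_sizes, step_s = 1, event_weight_s = 1) {
  purrr::map(window_sizes, function(w) {
    behavior_complexity(events, w, step_s, event_weight_s) |>
      dplyr::mutate(window_len_s = w, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Read a behavioral event-log CSV
#'
#' Expects a UTF-8 CSV with header columns `species`, `individual`, `clip`,
#' `behavior`, `kind`, `start_s`, `end_s`; the `behavior` column is renamed
#' to `label` internally.
#'
#' @param path Path to the CSV file.
#' @return Event-log tibble ready for [behavior_complexity()].
#' @export
read_event_log <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("species", "individual", "clip", "behavior", "kind", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Event log lacks column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "ornadiv_invalid_input")
  dplyr::rename(df, label = "behavior")
}
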