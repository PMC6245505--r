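# Synthetic-data generators. These emulate the field inputs with known
# ground truth: multi-clip behavior logs with species-specific repertoires,
# patchwise cone-catch images with supra-threshold between-patch contrasts
# and sub-threshold pixel noise, Gaussian-mixture note tables, and traits
# evolved on simulated trees. Every generator is deterministic under `seed`.

#' Simulate a pure-birth ultrametric phylogeny
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate per million years.
#' @param seed Optional integer seed.
#' @return A `phylo` tree with tips `S1 ... Sn` and branch lengths in
#'   million years.
#' @export
gen_tree <- function(n_species, birth_rate = 0.2, seed = NULL) {
  if (n_species < 2) abort("Need at least 2 species.",
                           class = "ornadiv_invalid_input")
  local_seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("S", seq_len(n_species))
  tree
}

#' Per-species ground-truth profiles for the generators
#'
#' Draws the species-level ground truth that the downstream generators
#' share: behavioral repertoire size, number of plumage color patches, and
#' number of acoustic note types.
#'
#' @param n_species Number of species.
#' @param repertoire_range Integer range of behavioral repertoire sizes.
#' @param patch_range Integer range of color patch counts.
#' @param note_type_range Integer range of note mixture components.
#' @param individuals Individuals recorded per species.
#' @param clips_per_individual Clips per individual.
#' @param clip_dur_s Clip duration in seconds.
#' @param seed Optional integer seed.
#' @return Tibble with one row per species.
#' @export
gen_species_profiles <- function(n_species, repertoire_range = c(2, 8),
                                 patch_range = c(1, 6),
                                 note_type_range = c(1, 5),
                                 individuals = 3, clips_per_individual = 2,
                                 clip_dur_s = 120, seed = NULL) {
  local_seed(seed)
  tibble::tibble(
    species = paste0("S", seq_len(n_species)),
    repertoire_size = sample(repertoire_range[1]:repertoire_range[2],
                             n_species, replace = TRUE),
    n_patches = sample(patch_range[1]:patch_range[2], n_species,
                       replace = TRUE),
    n_note_types = sample(note_type_range[1]:note_type_range[2], n_species,
                          replace = TRUE),
    individuals = individuals,
    clips_per_individual = clips_per_individual,
    clip_dur_s = clip_dur_s
  )
}

#' Generate behavioral event logs with known repertoires
#'
#' Each clip is a sequence of alternating state behaviors drawn uniformly
#' (no immediate self-transitions) from the species' state repertoire,
#' with log-normal durations truncated at the clip end, plus Poisson event
#' behaviors from the species' event repertoire. A fraction `event_frac`
#' of each repertoire is designated event-type (at least one state always
#' remains).
#'
#' @param profiles Output of [gen_species_profiles()].
#' @param state_meanlog,state_sdlog Log-normal parameters of state
#'   durations (seconds); defaults give a median 4 s state.
#' @param event_rate Poisson rate (events per second) of each event label.
#' @param event_frac Fraction of the repertoire that is event-type.
#' @param seed Optional integer seed.
#' @return Event-log tibble with columns `species`, `individual`, `clip`,
#'   `label`, `kind`, `start_s`, `end_s`, `clip_dur_s`.
#' @export
gen_behavior_logs <- function(profiles, state_meanlog = log(4),
                              state_sdlog = 0.5, event_rate = 0.05,
                              event_frac = 0.25, seed = NULL) {
  local_seed(seed)
  rows <- list()
  for (s in seq_len(nrow(profiles))) {
    pr <- profiles[s, ]
    R <- pr$repertoire_size
    n_events <- min(R - 1L, floor(R * event_frac))
    state_labs <- paste0("B", seq_len(R - n_events))
    event_labs <- if (n_events > 0) paste0("B", R - n_events + seq_len(n_events))
                  else character()
    for (ind in seq_len(pr$individuals)) {
      for (cl in seq_len(pr$clips_per_individual)) {
        dur <- pr$clip_dur_s
        # alternating states
        t <- 0; prev <- ""
        st <- list(); k <- 0L
        while (t < dur) {
          cand <- setdiff(state_labs, prev)
          lab <- if (length(cand)) cand[sample.int(length(cand), 1)] else prev
          len <- min(rlnorm(1, state_meanlog, state_sdlog), dur - t)
          k <- k + 1L
          st[[k]] <- tibble::tibble(label = lab, kind = "state",
                                    start_s = t, end_s = t + len)
          t <- t + len
          prev <- lab
        }
        ev <- purrr::map(event_labs, function(el) {
          m <- rpois(1, event_rate * dur)
          if (m == 0) return(NULL)
          tt <- sort(runif(m, 0, dur))
          tibble::tibble(label = el, kind = "event", start_s = tt, end_s = tt)
        }) |> purrr::compact()
        clip_rows <- dplyr::bind_rows(c(st, ev)) |>
          dplyr::arrange(.data$start_s)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(species = pr$species,
                         individual = paste0(pr$species, "_I", ind),
                         clip = paste0(pr$species, "_I", ind, "_C", cl)),
          clip_rows, tibble::tibble(clip_dur_s = dur))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a patchwise cone-catch image with known patch count
#'
#' Builds a rectangular foreground split into `n_patches` vertical stripes
#' of (near-)equal area. Patch mean log-catches advance along a fixed
#' chromatic contrast direction so that adjacent patches differ by
#' `sep_jnd` chromatic JNDs (luminance held flat), and i.i.d. Gaussian
#' pixel noise with standard deviation `noise_sd` is added in log-catch
#' space, where its perceptual size is distribution-stable.
#'
#' @param n_patches Number of perceptually distinct patches (>= 1).
#' @param size Image side length in pixels.
#' @param model A [visual_model()].
#' @param sep_jnd Chromatic JND between adjacent patch means.
#' @param noise_sd Pixel noise SD in log-catch space (use 0 for noiseless).
#' @param mask_margin Background margin (pixels) excluded by the mask.
#' @param seed Optional integer seed.
#' @return A [cone_catch_image()]; its `true_patches` attribute holds the
#'   per-pixel ground-truth patch index.
#' @export
gen_cone_catch_image <- function(n_patches, size = 28, model = visual_model(),
                                 sep_jnd = 8, noise_sd = 0.02,
                                 mask_margin = 2, seed = NULL) {
  local_seed(seed)
  nch <- length(model$omega)
  # contrast direction in log-catch space, orthogonal to uniform scaling
  v <- rep_len(c(1, -1), nch)
  v <- v - mean(v)
  unit <- chromatic_jnd(exp(v), rep(1, nch), model)
  delta <- sep_jnd / unit
  grid <- expand.grid(x = 0:(size - 1), y = 0:(size - 1))
  inside <- grid$x >= mask_margin & grid$x < size - mask_margin &
    grid$y >= mask_margin & grid$y < size - mask_margin
  # vertical stripes of near-equal width over the foreground columns
  fg_w <- size - 2 * mask_margin
  stripe <- as.integer(pmin(n_patches,
                            1 + ((grid$x - mask_margin) * n_patches) %/% fg_w))
  stripe[!inside] <- 1L
  n <- nrow(grid)
  f <- outer(stripe - 1, v) * delta +
    matrix(rnorm(n * nch, sd = noise_sd), n, nch)
  catches <- exp(f)
  colnames(catches) <- if (!is.null(names(model$densities)))
    names(model$densities) else paste0("ch", seq_len(nch))
  img <- dplyr::bind_cols(
    tibble::as_tibble(grid),
    tibble::tibble(mask = inside,
                   lum = exp(rnorm(n, sd = noise_sd))),
    tibble::as_tibble(as.data.frame(catches)))
  out <- cone_catch_image(img, channels = colnames(catches))
  attr(out, "true_patches") <- ifelse(inside, stripe, NA_integer_)
  out
}

#' Generate a Gaussian-mixture note table with known note types
#'
#' Feature vectors are drawn from `n_components` spherical Gaussian
#' components whose means sit on distinct feature axes separated by
#' `sep_sigma` within-component standard deviations, so classification can
#' be validated against the retained ground-truth `component` column.
#' Qualitative flags are independent Bernoulli draws (default probability
#' 0, i.e. constant flags, so the generating note-type count equals the
#' full-identity count).
#'
#' @param species Species id for the generated notes.
#' @param n_components Number of mixture components (note types).
#' @param individuals,clips_per_individual,notes_per_clip Sampling design.
#' @param clip_dur_s Clip duration in seconds.
#' @param n_features Number of acoustic feature columns (>= n_components).
#' @param sep_sigma Component mean separation in units of `feature_sd`.
#' @param feature_sd Within-component feature SD.
#' @param flag_prob Bernoulli probability of each qualitative flag.
#' @param seed Optional integer seed.
#' @return Note tibble with `species`, `individual`, `clip`, `onset_s`,
#'   `duration_s`, features `f1 ... fk`, the four flag columns, and the
#'   ground-truth `component`.
#' @export
gen_notes <- function(species, n_components, individuals = 2,
                      clips_per_individual = 2, notes_per_clip = 30,
                      clip_dur_s = 60, n_features = 15, sep_sigma = 10,
                      feature_sd = 1, flag_prob = 0, seed = NULL) {
  if (n_components > n_features) abort("Need n_features >= n_components.",
                                       class = "ornadiv_invalid_input")
  local_seed(seed)
  # spread the separation across all features (round-robin assignment) so
  # between-type contrast survives the per-feature standardization of the
  # downstream PCA; pairwise mean distance ~ sep_sigma * sd * sqrt(2p/m)
  mu <- matrix(0, n_components, n_features)
  if (n_components > 1) {
    owner <- rep_len(seq_len(n_components), n_features)
    for (c in seq_len(n_components)) {
      mu[c, owner == c] <- sep_sigma * feature_sd
    }
  }
  rows <- list()
  for (ind in seq_len(individuals)) {
    for (cl in seq_len(clips_per_individual)) {
      comp <- sample.int(n_components, notes_per_clip, replace = TRUE)
      X <- mu[comp, , drop = FALSE] +
        matrix(rnorm(notes_per_clip * n_features, sd = feature_sd),
               notes_per_clip, n_features)
      colnames(X) <- paste0("f", seq_len(n_features))
      onset <- sort(runif(notes_per_clip, 0, clip_dur_s))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(species = species,
                       individual = paste0(species, "_I", ind),
                       clip = paste0(species, "_I", ind, "_C", cl),
                       onset_s = onset,
                       duration_s = runif(notes_per_clip, 0.05, 0.5)),
        tibble::as_tibble(as.data.frame(X)),
        tibble::tibble(fm = rbinom(notes_per_clip, 1, flag_prob) == 1,
                       nonharmonic = rbinom(notes_per_clip, 1, flag_prob) == 1,
                       impulsive = rbinom(notes_per_clip, 1, flag_prob) == 1,
                       stochastic = rbinom(notes_per_clip, 1, flag_prob) == 1,
                       component = comp,
                       clip_dur_s = clip_dur_s))
    }
  }
  dplyr::bind_rows(rows)
}

#' Random display-environment covariates
#'
#' @param species Character vector of species ids.
#' @param seed Optional integer seed.
#' @return Tibble with `species`, `display_height`, `proximity`.
#' @export
gen_display_covariates <- function(species, seed = NULL) {
  local_seed(seed)
  tibble::tibble(
    species = species,
    display_height = sample(c("ground", "understory", "canopy"),
                            length(species), replace = TRUE),
    proximity = sample(c("solitary", "exploded_lek", "lek"),
                       length(species), replace = TRUE))
}
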