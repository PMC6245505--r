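#' Run the full courtship-complexity pipeline on synthetic data
#'
#' End-to-end orchestration: simulates a phylogeny and all three input
#' classes with known ground truth, scores species-level behavioral,
#' color, and acoustic richness and diversity, optionally blanks a
#' fraction of species and imputes them phylogenetically, fits the six
#' multiple-PGLS models (one per measure), and builds the scaled composite
#' diversity table. Every stage is a pure function of the configuration
#' and seed; rerunning with the same seed reproduces all outputs.
#'
#' @param n_species Number of species to simulate.
#' @param seed Integer seed driving every stage.
#' @param window_behavior Behavioral sliding-window length (s), default 50.
#' @param window_acoustic Acoustic sliding-window length (s), default 10.
#' @param step_s Window offset increment (s).
#' @param specimens_per_species Museum specimens imaged per species.
#' @param image_size Side length of the synthetic cone-catch images.
#' @param missing_frac Fraction of species whose behavioral and acoustic
#'   scores are blanked before imputation (0 disables imputation).
#' @param complete_case Drop blanked species from the PGLS fits instead of
#'   imputing them.
#' @param cluster_params,model Color-clustering parameters and visual
#'   model.
#' @param outdir Optional directory; when given, the species table, fit
#'   reports and composite table are written there as CSVs.
#' @return A list of class `ornadiv_pipeline`: `traits` (species x
#'   six-measure table with covariates), `fits` (named list of
#'   `ornadiv_gls`), `fit_table` (tidy coefficients of all fits),
#'   `composite`, `imputation` (or `NULL`), `tree`, `profiles` (ground
#'   truth), and the resolved `config`.
#' @export
run_pipeline <- function(n_species = 12, seed = 1, window_behavior = 50,
                         window_acoustic = 10, step_s = 1,
                         specimens_per_species = 1, image_size = 24,
                         missing_frac = 0, complete_case = FALSE,
                         cluster_params = ornadiv::cluster_params(),
                         model = visual_model(), outdir = NULL) {
  config <- as.list(environment())
  config$cluster_params <- cluster_params
  local_seed(seed)
  profiles <- gen_species_profiles(n_species)
  tree <- gen_tree(n_species)

  # behavior
  logs <- gen_behavior_logs(profiles)
  beh <- behavior_complexity(logs, window_len_s = window_behavior,
                             step_s = step_s)

  # color: specimens x 3 views per species
  view_scores <- purrr::map(seq_len(n_species), function(s) {
    purrr::map(seq_len(specimens_per_species), function(sp) {
      purrr::map(c("dorsal", "ventral", "angled"), function(vw) {
        img <- gen_cone_catch_image(profiles$n_patches[s], size = image_size,
                                    model = model)
        cm <- cluster_image(median_blur(img), model, cluster_params)
        dplyr::bind_cols(
          tibble::tibble(species = profiles$species[s],
                         specimen = paste0(profiles$species[s], "_M", sp),
                         view = vw),
          color_complexity(cm, cluster_params$min_area_frac))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  col <- species_color_complexity(view_scores)

  # acoustics: one global PCA/clustering across species, as in the field
  notes <- purrr::map(seq_len(n_species), function(s) {
    gen_notes(profiles$species[s], profiles$n_note_types[s])
  }) |> dplyr::bind_rows()
  # offset component ids so species' note types are distinct in truth
  offs <- c(0, cumsum(profiles$n_note_types))[seq_len(n_species)]
  notes$component <- notes$component + offs[match(notes$species,
                                                  profiles$species)]
  notes_id <- assign_note_identity(notes, k = sum(profiles$n_note_types))
  aco <- acoustic_complexity(notes_id, window_len_s = window_acoustic,
                             step_s = step_s)

  traits <- dplyr::bind_rows(
    dplyr::mutate(beh, modality = "behavior"),
    dplyr::mutate(col, modality = "color"),
    dplyr::mutate(aco, modality = "acoustic")) |>
    dplyr::transmute(.data$species,
                     name = paste0(.data$modality, "_", .data$metric),
                     .data$value) |>
    tidyr::pivot_wider() |>
    dplyr::right_join(tibble::tibble(species = tree$tip.label),
                      by = "species") |>
    dplyr::left_join(gen_display_covariates(tree$tip.label), by = "species")

  imputation <- NULL
  measure_cols <- c("behavior_richness", "behavior_diversity",
                    "acoustic_richness", "acoustic_diversity")
  blanked <- character()
  if (missing_frac > 0) {
    blanked <- sample(tree$tip.label, floor(missing_frac * n_species))
    traits[traits$species %in% blanked, measure_cols] <- NA_real_
  }
  fit_traits <- traits
  if (any(is.na(traits[measure_cols]))) {
    if (complete_case) {
      fit_traits <- traits[complete.cases(traits[measure_cols]), ,
                           drop = FALSE]
    } else {
      imputation <- impute_missing(traits |> dplyr::select(-"display_height",
                                                           -"proximity"),
                                   tree)
      fit_traits <- imputation$traits |>
        dplyr::left_join(traits[c("species", "display_height", "proximity")],
                         by = "species")
    }
  }

  responses <- c("color_richness", "behavior_richness", "acoustic_richness",
                 "color_diversity", "behavior_diversity", "acoustic_diversity")
  # with very few species the full design (two predictors plus up to four
  # environment dummies) would be rank deficient; drop the covariates then
  model_traits <- fit_traits
  if (nrow(model_traits) < 10) {
    model_traits <- dplyr::select(model_traits, -dplyr::any_of(
      c("display_height", "proximity")))
  }
  fits <- purrr::map(setNames(responses, responses), function(r) {
    mpgls_model(model_traits, r, tree)
  })
  fit_table <- purrr::imap(fits, function(f, r) {
    dplyr::mutate(tidy(f), response = r, .before = 1)
  }) |> dplyr::bind_rows()
  composite <- composite_diversity(fit_traits)

  out <- structure(list(traits = fit_traits, fits = fits,
                        fit_table = fit_table, composite = composite,
                        imputation = imputation, tree = tree,
                        profiles = profiles, blanked = blanked,
                        config = config),
                   class = "ornadiv_pipeline")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$traits, file.path(outdir, "species_traits.csv"),
                   row.names = FALSE)
  utils::write.csv(x$fit_table, file.path(outdir, "mpgls_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(x$composite, file.path(outdir, "composite_diversity.csv"),
                   row.names = FALSE)
  if (!is.null(x$imputation)) {
    utils::write.csv(x$imputation$report,
                     file.path(outdir, "imputation_report.csv"),
                     row.names = FALSE)
  }
  ape::write.tree(x$tree, file.path(outdir, "tree.nwk"))
  invisible(x)
}

#' @export
print.ornadiv_pipeline <- function(x, ...) {
  cat("Courtship-complexity pipeline:", nrow(x$traits), "species,",
      length(x$fits), "mPGLS fits\n")
  print(x$traits, n = 6)
  invisible(x)
}

#' Sampling summary of the reference field study
#'
#' The study-scale sampling figures used as fixed inputs by the worked
#' examples: per modality, the total recorded seconds, number of clips,
#' and species sampled out of the 40 in the family.
#'
#' @return Tibble with columns `modality`, `total_s`, `n_clips`,
#'   `n_species_sampled`, `n_species_total`.
#' @export
study_sampling_summary <- function() {
  tibble::tibble(
    modality = c("behavior", "acoustic"),
    total_s = c(47707.2, 24670.9),
    n_clips = c(961L, 176L),
    n_species_sampled = c(32L, 32L),
    n_species_total = c(40L, 40L))
}

#' Plot species composite diversity as stacked scaled scores
#'
#' @param composite Output of [composite_diversity()].
#' @return A ggplot stacked-bar chart, one bar per species.
#' @export
plot_composite <- function(composite) {
  long <- composite |>
    tidyr::pivot_longer(dplyr::starts_with("scaled_"),
                        names_to = "signal", values_to = "scaled") |>
    dplyr::mutate(signal = sub("^scaled_", "", .data$signal))
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$species,
                                                        .data$composite),
                                     y = .data$scaled,
                                     fill = .data$signal)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "scaled diversity", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a window-size robustness sweep
#'
#' @param sweep Output of [window_sweep()].
#' @param metric `"richness"` or `"diversity"`.
#' @return A ggplot of species scores against window length.
#' @export
plot_window_sweep <- function(sweep, metric = "diversity") {
  dat <- dplyr::filter(sweep, .data$metric == .env$metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$window_len_s, y = .data$value,
                                    color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "window length (s)", y = metric, color = NULL) +
    ggplot2::theme_minimal()
}
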