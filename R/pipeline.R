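#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input_dir` (a directory of study files as written by
#' [write_study()]) or `synthetic` (a [synthetic_config()]) must be given.
#'
#' @param input_dir Directory containing `traits.csv`, `communities.csv`,
#'   `plot_characteristics.csv`, `phylogeny.nwk`, `calibration_scans.csv`
#'   and `survey.csv`.
#' @param synthetic A `synthetic_config` for a generated study.
#' @param focal_species Focal species vector; required with `input_dir`,
#'   derived from the generator otherwise.
#' @param collinearity_threshold Absolute-correlation threshold of the
#'   predictor screen (default 0.7).
#' @param include_overall_q Also compute the combined all-trait Rao's Q?
#' @param outdir Output directory; `NULL` to skip writing files.
#' @param seed Root seed recorded in the manifest (with synthetic input it
#'   overrides the generator seed).
#' @param control GLMM control list, see [glmm_control()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL, focal_species = NULL,
                       collinearity_threshold = 0.7, include_overall_q = FALSE,
                       outdir = NULL, seed = 1L, control = glmm_control()) {
  if (is.null(input_dir) == is.null(synthetic)) {
    hd_abort("supply exactly one of input_dir or synthetic", "configuration")
  }
  if (!is.null(input_dir) && is.null(focal_species)) {
    hd_abort("focal_species is required when reading study files", "configuration")
  }
  if (!is.null(synthetic)) {
    synthetic$seed <- as.integer(seed)
    synthetic <- do.call(synthetic_config, unclass(synthetic))
  }
  structure(list(
    input_dir = input_dir, synthetic = synthetic,
    focal_species = focal_species,
    collinearity_threshold = collinearity_threshold,
    include_overall_q = include_overall_q,
    outdir = outdir, seed = as.integer(seed), control = control
  ), class = "run_config")
}

read_study_dir <- function(dir) {
  list(
    traits = read_trait_table(file.path(dir, "traits.csv")),
    communities = read_community_matrix(file.path(dir, "communities.csv")),
    plot_characteristics =
      read_plot_characteristics(file.path(dir, "plot_characteristics.csv")),
    phylogeny = read_phylogeny(file.path(dir, "phylogeny.nwk")),
    scans = read_calibration_scans(file.path(dir, "calibration_scans.csv")),
    survey = read_sapling_survey(file.path(dir, "survey.csv"))
  )
}

#' Cross-file consistency report
#'
#' Checks species and plot overlap across the study inputs without running
#' the analysis: survey plots and species must exist in the community
#' matrix, survey species must be focal and have trait data, community
#' species must be on the phylogeny, plot characteristics must cover all
#' plots, and all leaf classes must be in the six-class vocabulary.
#'
#' @param config A `run_config`.
#' @return A tibble (`check`, `failure`); zero rows means all checks
#'   passed.
#' @export
validate_inputs <- function(config) {
  study <- if (!is.null(config$synthetic)) {
    simulate_study(config$synthetic)
  } else {
    c(read_study_dir(config$input_dir),
      list(focal_species = config$focal_species))
  }
  fails <- list()
  add <- function(check, items) {
    if (length(items) > 0) {
      fails[[length(fails) + 1]] <<- tibble::tibble(
        check = check, failure = as.character(items)
      )
    }
  }
  comm_sp <- setdiff(names(study$communities), "plot")
  add("survey plot known", setdiff(study$survey$plot, study$communities$plot))
  add("survey species focal", setdiff(study$survey$species, study$focal_species))
  add("focal species in communities", setdiff(study$focal_species, comm_sp))
  add("community species on phylogeny",
      setdiff(comm_sp, study$phylogeny$tip.label))
  add("focal species have traits",
      setdiff(study$focal_species,
              study$traits$species[!is.na(study$traits$LA)]))
  add("plot characteristics cover plots",
      setdiff(study$communities$plot, study$plot_characteristics$plot))
  cls <- unique(unlist(study$survey$leaf_classes))
  add("leaf classes in vocabulary", setdiff(cls, damage_classes()$class_label))
  if (length(fails) == 0) {
    tibble::tibble(check = character(), failure = character())
  } else {
    dplyr::bind_rows(fails)
  }
}

#' Run the full analysis pipeline
#'
#' Generates or reads the study inputs, calibrates the damage classes,
#' computes all diversity metrics, builds and screens the predictor table,
#' standardizes predictors (adding the richness-by-`Q_phylo` interaction
#' when both survive the screen), fits and simplifies the five model sets,
#' and extracts partial residuals for every fixed effect of the best
#' minimal model. With `outdir` set, writes `results_table.csv`,
#' `plot_metrics.csv`, `focal_metrics.csv`, `exclusions.csv`,
#' `partial_residuals.csv`, `fits.json`, `manifest.json` and `run.log`;
#' rerunning with the same config and seed reproduces the CSV outputs
#' byte-identically.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages?
#' @return An object of class `herb_run`: list with the study, calibration,
#'   metrics, pca, screen, predictor table, comparison and partial
#'   residuals.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(stage, ...) {
    msg <- paste0("[", stage, "] ", paste0(...),
                  sprintf(" (%.1fs)", as.numeric(Sys.time() - t0, units = "secs")))
    log_lines <<- c(log_lines, msg)
    if (!quiet) rlang::inform(msg)
  }
  stage <- "setup"
  fail_marker <- function(e) {
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      writeLines(c(paste0("FAILED at stage: ", stage), conditionMessage(e)),
                 file.path(config$outdir, "FAILED"))
      writeLines(log_lines, file.path(config$outdir, "run.log"))
    }
    rlang::abort(paste0("pipeline failed at stage ", stage, ": ",
                        conditionMessage(e)), parent = e)
  }
  withCallingHandlers(
    {
      stage <- "data"
      if (!is.null(config$synthetic)) {
        study <- simulate_study(config$synthetic)
        focal <- study$focal_species
      } else {
        study <- read_study_dir(config$input_dir)
        focal <- config$focal_species
      }
      say(stage, nrow(study$survey), " saplings, ",
          nrow(study$communities), " plots")

      stage <- "calibration"
      calibration <- calibrate_classes(study$scans)
      survey <- sapling_mean_damage(study$survey, calibration)
      say(stage, "mean damage ",
          sprintf("%.3f", mean(survey$mean_damage)))

      stage <- "metrics"
      metrics <- compute_all_metrics(
        study$communities, study$traits, study$phylogeny, focal,
        include_overall_q = config$include_overall_q
      )
      say(stage, ncol(metrics$plot) - 1, " plot metrics, ",
          ncol(metrics$focal) - 2, " focal metrics")

      stage <- "predictors"
      pca <- plot_pca(study$plot_characteristics)
      table_raw <- build_predictor_table(survey, metrics, pca)
      # PC1_abio is part of every model set by design (it absorbs plot-level
      # confounding), so only the diversity predictors are screen candidates
      screen <- collinearity_screen(
        table_raw,
        predictors = setdiff(predictor_columns(table_raw), "PC1_abio"),
        threshold = config$collinearity_threshold
      )
      kept <- c("PC1_abio", screen$kept)
      table_std <- standardize_predictors(table_raw, predictors = kept)
      say(stage, length(kept), " predictors kept, ",
          nrow(screen$exclusions), " excluded")

      stage <- "models"
      comparison <- compare_model_sets(table_std, kept,
                                       control = config$control)
      best <- comparison$comparison$model[1]
      say(stage, "best model: ", best, ", AICc ",
          sprintf("%.1f", comparison$comparison$aicc[1]))

      stage <- "partial_residuals"
      best_fit <- comparison$fits[[best]]
      presid <- purrr::map_dfr(
        setdiff(best_fit$coefficients$term, "(Intercept)"),
        function(p) {
          dplyr::mutate(partial_residuals(best_fit, p), predictor = p,
                        .before = 1)
        }
      )

      run <- structure(list(
        study = study, focal_species = focal, calibration = calibration,
        survey = survey, metrics = metrics, pca = pca, screen = screen,
        kept_predictors = kept,
        predictor_table = table_std, comparison = comparison,
        partial_residuals = presid, config = config
      ), class = "herb_run")

      stage <- "export"
      if (!is.null(config$outdir)) {
        export_run(run, config$outdir, log_lines)
        say(stage, "written to ", config$outdir)
      }
      run
    },
    error = fail_marker
  )
}

export_run <- function(run, outdir, log_lines = character(0)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(run$comparison),
                   file.path(outdir, "results_table.csv"))
  readr::write_csv(run$metrics$plot, file.path(outdir, "plot_metrics.csv"))
  readr::write_csv(run$metrics$focal, file.path(outdir, "focal_metrics.csv"))
  readr::write_csv(run$screen$exclusions, file.path(outdir, "exclusions.csv"))
  readr::write_csv(run$partial_residuals,
                   file.path(outdir, "partial_residuals.csv"))
  fits <- purrr::map(run$comparison$fits, function(f) {
    list(coefficients = f$coefficients, sigma = as.list(f$sigma),
         boundary = as.list(f$boundary), logLik = f$logLik, k = f$k,
         n = f$n, aicc = f$aicc,
         convergence = f$convergence)
  })
  jsonlite::write_json(list(fits = fits, traces = run$comparison$traces),
                       file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "herbdiv",
    version = as.character(utils::packageVersion("herbdiv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = run$config$seed,
    config_hash = rlang::hash(run$config),
    synthetic = !is.null(run$config$synthetic),
    n_saplings = nrow(run$predictor_table),
    best_model = run$comparison$comparison$model[1]
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.herb_run <- function(x, ...) {
  cat("herbdiv pipeline run\n")
  cat("  saplings:", nrow(x$predictor_table),
      " kept predictors:", length(x$screen$kept), "\n")
  print(x$comparison$comparison)
  invisible(x)
}
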