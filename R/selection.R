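# split interaction column names of the form "a_x_b" into their main effects
interaction_mains <- function(term) {
  parts <- strsplit(term, "_x_", fixed = TRUE)[[1]]
  if (length(parts) == 2) parts else NULL
}

is_interaction <- function(term) !is.null(interaction_mains(term))

#' Backward model simplification by AICc
#'
#' Starting from the full fixed-effect set, repeatedly evaluates every
#' single-predictor deletion, applies the deletion giving the largest AICc
#' reduction, and stops when no deletion reduces AICc. Interaction terms
#' (columns named `a_x_b`) are deleted before their main effects: a main
#' effect is not a deletion candidate while an interaction containing it is
#' still in the model. Retained predictors may be non-significant if their
#' deletion would worsen AICc.
#'
#' For speed, candidate deletions are first ranked with the variance
#' parameters held at the current model's estimates (they move very little
#' between adjacent nested models); candidates whose screening AICc is
#' within `screen_margin` of the screening best are then fully refitted with
#' free variance parameters, and a deletion is applied only when its full
#' refit genuinely lowers AICc. When no shortlisted refit improves, every
#' remaining candidate is refitted before the algorithm stops, so the
#' stopping rule is exact and the AICc trace is strictly decreasing by
#' construction.
#'
#' @inheritParams fit_binomial_glmm
#' @param predictors The full fixed-effect set to simplify.
#' @param screen_margin AICc window (on the fixed-variance screening scale)
#'   within which candidate deletions are fully refitted.
#' @return A list with `predictors` (the minimal set), `fit` (the minimal
#'   `herb_glmm`), and `trace` (tibble: `step`, `dropped`, `aicc`, starting
#'   at step 0 with the full model; the AICc sequence is strictly
#'   decreasing).
#' @export
backward_select <- function(data, predictors, response = "y", weights = "w",
                            random = c("species", "plot"), olre = TRUE,
                            control = glmm_control(), screen_margin = 2) {
  fit_one <- function(preds, warm = NULL, fixed = NULL) {
    fit_binomial_glmm(data, preds,
      response = response, weights = weights,
      random = random, olre = olre, control = control, theta_init = warm,
      fixed_sigma = fixed
    )
  }
  current <- fit_one(predictors)
  kept <- predictors
  trace <- list(tibble::tibble(step = 0L, dropped = NA_character_,
                               aicc = current$aicc))
  step <- 0L
  while (length(kept) > 0) {
    protected <- unique(unlist(lapply(kept[vapply(kept, is_interaction, TRUE)],
                                      interaction_mains)))
    candidates <- setdiff(kept, protected)
    if (length(candidates) == 0) break
    # cheap screening pass at the current variance estimates
    screen <- vapply(candidates, function(cand) {
      f <- tryCatch(fit_one(setdiff(kept, cand), fixed = current$sigma_raw),
                    error = function(e) NA_real_)
      if (is.numeric(f)) NA_real_ else f$aicc
    }, numeric(1))
    if (all(is.na(screen))) {
      hd_abort("all candidate deletions failed to fit", "selection")
    }
    ord <- candidates[order(screen)]
    shortlist <- ord[which(screen[ord] <= min(screen, na.rm = TRUE) + screen_margin)]
    refit <- function(cands) {
      fits <- list()
      for (cand in cands) {
        f <- tryCatch(fit_one(setdiff(kept, cand), warm = current$theta),
                      error = function(e) NULL)
        if (!is.null(f)) fits[[cand]] <- f
      }
      fits
    }
    fits <- refit(shortlist)
    aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
    if (length(aiccs) == 0 || min(aiccs) >= current$aicc) {
      # confirm the stop against every remaining candidate
      rest <- refit(setdiff(ord[!is.na(screen[ord])], shortlist))
      fits <- c(fits, rest)
      aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
      if (length(aiccs) == 0) {
        hd_abort("all candidate deletions failed to fit", "selection")
      }
      if (min(aiccs) >= current$aicc) break
    }
    best <- names(which.min(aiccs))
    step <- step + 1L
    kept <- setdiff(kept, best)
    current <- fits[[best]]
    trace[[length(trace) + 1]] <- tibble::tibble(step = step, dropped = best,
                                                 aicc = current$aicc)
  }
  list(predictors = kept, fit = current, trace = dplyr::bind_rows(trace))
}

# metric-family membership used to assemble the five model sets
predictor_family <- function(x) {
  dplyr::case_when(
    x == "PC1_abio" ~ "abiotic",
    x == "richness" ~ "richness",
    x %in% c("Q_phylo", "Qspec_phylo") ~ "phylogenetic",
    grepl("^(CWM_|Q_|Qspec_)", x) ~ "functional",
    grepl("_x_", x, fixed = TRUE) ~ "interaction",
    .default = "other"
  )
}

#' Compare the five nested predictor sets by AICc
#'
#' Builds five candidate models from the screened predictor list — (1) all
#' predictors (plus any interaction columns present), (2) abiotic PC1 and
#' all functional (trait-based) metrics, (3) abiotic PC1 and phylogenetic
#' metrics, (4) abiotic PC1 and species richness, (5) abiotic PC1 only —
#' simplifies each by [backward_select()], and compares the minimal models
#' by AICc, difference to the best (`delta_aicc`) and Akaike weights
#' `exp(-delta/2)` normalized to sum to 1.
#'
#' @inheritParams backward_select
#' @param kept Screened predictor names (main effects; see
#'   [collinearity_screen()]). Interaction columns present in `data` whose
#'   mains are both kept are added to the all-predictors set.
#' @return An object of class `herb_model_comparison`: list with
#'   `comparison` (tibble: `model`, `aicc`, `delta_aicc`, `weight`, ordered
#'   by AICc), `fits` (named list of minimal `herb_glmm` fits), `predictors`
#'   (named list of minimal predictor sets) and `traces`.
#' @export
compare_model_sets <- function(data, kept, response = "y", weights = "w",
                               random = c("species", "plot"), olre = TRUE,
                               control = glmm_control()) {
  fam <- setNames(predictor_family(kept), kept)
  pc1 <- kept[fam == "abiotic"]
  interactions <- setdiff(names(data)[grepl("_x_", names(data), fixed = TRUE)],
                          c("species", "plot", "sapling", "obs", "y", "w"))
  interactions <- interactions[vapply(interactions, function(ia) {
    all(interaction_mains(ia) %in% kept)
  }, TRUE)]
  sets <- list(
    all_predictors = c(kept, interactions),
    functional = c(pc1, kept[fam == "functional"]),
    phylogenetic = c(pc1, kept[fam == "phylogenetic"]),
    species_richness = c(pc1, kept[fam == "richness"]),
    abiotic_only = pc1
  )
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  if (length(empty) > 0) {
    hd_abort(paste0("model set(s) empty after screening: ",
                    paste(empty, collapse = ", ")), "configuration")
  }
  sel <- purrr::map(sets, function(preds) {
    backward_select(data, preds, response = response, weights = weights,
                    random = random, olre = olre, control = control)
  })
  comparison <- tibble::tibble(
    model = names(sel),
    aicc = unname(vapply(sel, function(s) s$fit$aicc, numeric(1)))
  ) |>
    dplyr::mutate(
      delta_aicc = .data$aicc - min(.data$aicc),
      weight = exp(-.data$delta_aicc / 2) / sum(exp(-.data$delta_aicc / 2))
    ) |>
    dplyr::arrange(.data$aicc)
  structure(list(
    comparison = comparison,
    fits = purrr::map(sel, "fit"),
    predictors = purrr::map(sel, "predictors"),
    traces = purrr::map(sel, "trace")
  ), class = "herb_model_comparison")
}

#' @export
print.herb_model_comparison <- function(x, ...) {
  cat("AICc comparison of five minimal models\n")
  print(x$comparison)
  invisible(x)
}

#' Tidy a model-set comparison into a results table
#'
#' One row per fixed effect per minimal model, ordered within models by the
#' absolute size of the standardized estimates, with model-level AICc,
#' difference to the best model and Akaike weight attached.
#'
#' @param x A `herb_model_comparison`.
#' @param ... Unused.
#' @return A tibble (`model`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `aicc`, `delta_aicc`, `weight`).
#' @export
tidy.herb_model_comparison <- function(x, ...) {
  purrr::map_dfr(x$comparison$model, function(m) {
    tidy(x$fits[[m]]) |>
      dplyr::filter(.data$term != "(Intercept)") |>
      dplyr::arrange(dplyr::desc(abs(.data$estimate))) |>
      dplyr::mutate(model = m, .before = 1)
  }) |>
    dplyr::left_join(x$comparison, by = "model")
}

#' @rdname tidy.herb_model_comparison
#' @export
glance.herb_model_comparison <- function(x, ...) x$comparison

#' @rdname tidy.herb_model_comparison
#' @param object A `herb_model_comparison`.
#' @export
autoplot.herb_model_comparison <- function(object, ...) {
  d <- object$comparison |>
    dplyr::mutate(model = stats::reorder(.data$model, -.data$delta_aicc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_aicc, y = .data$model)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("w = %.2f", .data$weight)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = expression(Delta * AICc), y = NULL)
}

#' Single-predictor regression for one focal species
#'
#' Weighted binomial (logit link) regression of damage on a single
#' standardized predictor, restricted to the saplings of one species —
#' the per-species analogue of the community-level mixed model. Fitted with
#' the package's IRLS path (no random effects).
#'
#' @param data A standardized predictor table.
#' @param species Focal species identifier.
#' @param predictor Predictor column name.
#' @return A one-row tibble (`species`, `predictor`, `slope`, `std.error`,
#'   `statistic`, `p.value`, `n`).
#' @export
per_species_regression <- function(data, species, predictor) {
  sub <- data[data$species == species, , drop = FALSE]
  if (nrow(sub) < 3 || length(unique(sub$plot)) < 3) {
    hd_abort(paste0("need >= 3 saplings across >= 3 plots for species ", species),
             "validation")
  }
  if (sd(sub[[predictor]]) == 0) {
    hd_abort(paste0(predictor, " is constant across the plots of ", species),
             "zero_variance")
  }
  fit <- fit_binomial_glmm(sub, predictor, random = character(0), olre = FALSE)
  row <- fit$coefficients[fit$coefficients$term == predictor, ]
  tibble::tibble(
    species = species, predictor = predictor,
    slope = row$estimate, std.error = row$std.error,
    statistic = row$statistic, p.value = row$p.value, n = nrow(sub)
  )
}

#' Partial residuals for one fitted predictor
#'
#' Working residuals on the link (logit) scale plus the fitted contribution
#' of the chosen predictor, `r_i = (y_i - mu_i) / (mu_i (1 - mu_i)) +
#' beta_p x_ip`, suitable for plotting the independent effect of a
#' predictor. An ordinary regression of these values on the predictor
#' recovers approximately `beta_p`.
#'
#' @param fit A `herb_glmm` fit.
#' @param predictor A fixed-effect term of the fit.
#' @return A tibble (`x`, `partial_residual`), one row per sapling.
#' @export
partial_residuals <- function(fit, predictor) {
  if (!predictor %in% colnames(fit$X)) {
    hd_abort(paste0(predictor, " is not a fixed effect of the model"), "argument")
  }
  beta_p <- fit$coefficients$estimate[fit$coefficients$term == predictor]
  mu <- fit$fitted
  wres <- (fit$y - mu) / (mu * (1 - mu))
  tibble::tibble(
    x = fit$X[, predictor],
    partial_residual = wres + beta_p * fit$X[, predictor]
  )
}

#' Plot partial residuals against a predictor
#'
#' @inheritParams partial_residuals
#' @return A ggplot.
#' @export
plot_partial_residuals <- function(fit, predictor) {
  d <- partial_residuals(fit, predictor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$partial_residual)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = predictor, y = "partial residual (logit scale)")
}
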