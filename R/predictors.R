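#' PCA of plot characteristics
#'
#' Stand descriptors (stand age, tree density, canopy cover, herb cover,
#' elevation, aspect) are often strongly intercorrelated; a PCA on the
#' z-standardized variables yields orthogonal axes that can enter models as
#' covariates. The first axis is exposed as `PC1_abio` and oriented so that
#' `stand_age` loads positively, making it interpretable as a stand-age
#' gradient.
#'
#' @param chars A plot-characteristics tibble (see
#'   [read_plot_characteristics()]).
#' @return An object of class `herb_pca`: list with `scores` (tibble, `plot`
#'   plus `PC1`..`PCk`), `loadings` (variables x components matrix) and
#'   `var_explained` (fractions summing to 1).
#' @export
plot_pca <- function(chars) {
  validate_plot_characteristics(chars)
  if (nrow(chars) < 2) hd_abort("need at least 2 plots for a PCA", "validation")
  m <- as.matrix(chars[, plot_char_names()])
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    hd_abort(paste0("constant plot characteristic(s): ",
                    paste(plot_char_names()[sds == 0], collapse = ", ")),
             "zero_variance")
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  if (pc$rotation["stand_age", 1] < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(plot = chars$plot), scores)
  structure(
    list(scores = scores, loadings = pc$rotation, var_explained = ve),
    class = "herb_pca"
  )
}

#' @export
print.herb_pca <- function(x, ...) {
  cat("Plot-characteristics PCA;", length(x$var_explained), "components\n")
  cat("variance explained:", paste(round(100 * x$var_explained, 1), "%"), "\n")
  invisible(x)
}

#' @rdname plot_pca
#' @param x A `herb_pca` object.
#' @param ... Unused.
#' @export
tidy.herb_pca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$loadings),
    var_explained = x$var_explained
  )
}

# canonical predictor ordering used for deterministic tie-breaks:
# plot covariates first, then CWM before Q before Qspec, traits in the
# trait-table order, multivariate before phylogenetic within each family
canonical_predictor_order <- function(x) {
  tn <- trait_names()
  canon <- c(
    "PC1_abio", "richness",
    paste0("CWM_", tn),
    paste0("Q_", tn), "Q_morph", "Q_chem", "Q_all", "Q_phylo",
    paste0("Qspec_", tn), "Qspec_morph", "Qspec_chem", "Qspec_all", "Qspec_phylo"
  )
  ord <- match(x, canon)
  ord[is.na(ord)] <- length(canon) + seq_len(sum(is.na(ord)))
  order(ord)
}

#' Build the per-sapling predictor table
#'
#' Joins plot-level metrics, focal-species metrics and the abiotic PC1 score
#' onto the calibrated sapling survey, producing one row per sapling with
#' the response `y` (mean damage proportion), the trial weight `w` (leaf
#' count), identifiers (`species`, `plot`, `obs`) and one column per
#' candidate predictor.
#'
#' @param survey A sapling survey with `mean_damage` filled in (see
#'   [sapling_mean_damage()]).
#' @param metrics A `herb_metrics` object from [compute_all_metrics()].
#' @param pca A `herb_pca` object from [plot_pca()].
#' @return A tibble, one row per sapling.
#' @export
build_predictor_table <- function(survey, metrics, pca) {
  if (any(is.na(survey$mean_damage))) {
    hd_abort("survey has saplings without mean_damage; run sapling_mean_damage() first",
             "validation")
  }
  pc1 <- dplyr::select(pca$scores, "plot", PC1_abio = "PC1")
  out <- survey |>
    dplyr::transmute(
      species = .data$species, plot = .data$plot, sapling = .data$sapling,
      y = .data$mean_damage, w = as.numeric(.data$leaf_count)
    ) |>
    dplyr::mutate(obs = paste0("obs", dplyr::row_number())) |>
    dplyr::left_join(metrics$plot, by = "plot") |>
    dplyr::left_join(metrics$focal,
                     by = c("plot" = "plot", "species" = "focal_species")) |>
    dplyr::left_join(pc1, by = "plot")
  if (anyNA(out)) {
    hd_abort("predictor table has missing values after joining; check that all survey species are focal species and all plots are covered",
             "validation")
  }
  out
}

# predictor columns of a built table (everything except ids and response)
predictor_columns <- function(data) {
  setdiff(names(data), c("species", "plot", "sapling", "obs", "y", "w"))
}

#' Response-guided collinearity screen
#'
#' Iteratively removes predictors until no pair has `|Pearson r|` above the
#' threshold. At each step the violating pair with the largest `|r|` is
#' found and its member with the weaker absolute Pearson correlation to the
#' response is dropped (ties broken by a canonical predictor ordering: plot
#' covariates, then CWM before Q before Qspec, traits in trait-table order).
#' Correlations are computed over sapling rows.
#'
#' @param data A predictor table from [build_predictor_table()].
#' @param predictors Candidate predictor columns; defaults to every
#'   predictor column of `data`.
#' @param response Response column name (default `"y"`).
#' @param threshold Absolute-correlation threshold in (0, 1); default 0.7.
#' @return A list with `kept` (character vector) and `exclusions` (tibble:
#'   `dropped`, `kept_partner`, `r_pair`, `r_to_y_dropped`, `r_to_y_kept`).
#' @export
collinearity_screen <- function(data, predictors = predictor_columns(data),
                                response = "y", threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) {
    hd_abort("threshold must lie in (0, 1)", "argument")
  }
  x <- as.matrix(data[, predictors, drop = FALSE])
  if (any(apply(x, 2, sd) == 0)) {
    hd_abort("zero-variance predictor(s) in screen", "zero_variance")
  }
  y <- data[[response]]
  r_y <- abs(as.vector(cor(x, y)))
  names(r_y) <- predictors
  kept <- predictors[canonical_predictor_order(predictors)]
  log <- list()
  repeat {
    cm <- abs(cor(x[, kept, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- kept[idx[1]]
    b <- kept[idx[2]]
    # drop the member less correlated with the response; ties keep the one
    # earlier in canonical order (kept is already canonically ordered)
    pair <- c(a, b)[canonical_predictor_order(c(a, b))]
    drop_one <- if (r_y[pair[1]] >= r_y[pair[2]]) pair[2] else pair[1]
    keep_one <- setdiff(pair, drop_one)
    log[[length(log) + 1]] <- tibble::tibble(
      dropped = drop_one, kept_partner = keep_one,
      r_pair = cm[idx[1], idx[2]],
      r_to_y_dropped = r_y[drop_one], r_to_y_kept = r_y[keep_one]
    )
    kept <- setdiff(kept, drop_one)
  }
  list(kept = kept, exclusions = dplyr::bind_rows(log), threshold = threshold)
}

#' Standardize predictors and add the richness-by-Q_phylo interaction
#'
#' Every retained predictor column is z-scored over sapling rows (mean 0,
#' sample SD 1). Interaction columns are the product of the two standardized
#' main effects, themselves re-standardized, and named `a_x_b`. Identifiers,
#' `y` and `w` are untouched.
#'
#' @param data A predictor table.
#' @param predictors Columns to standardize; defaults to all predictor
#'   columns present.
#' @param interactions List of length-2 character vectors naming interaction
#'   pairs; both members must be in `predictors`. Default: the
#'   richness-by-phylogenetic-diversity interaction when both are present.
#' @return The table with standardized predictors and interaction columns.
#' @export
standardize_predictors <- function(data, predictors = predictor_columns(data),
                                   interactions = NULL) {
  if (is.null(interactions) &&
      all(c("richness", "Q_phylo") %in% predictors)) {
    interactions <- list(c("richness", "Q_phylo"))
  }
  for (p in predictors) {
    data[[p]] <- zscore(data[[p]])
  }
  for (ia in interactions %||% list()) {
    if (!all(ia %in% predictors)) {
      hd_abort("interaction terms must be standardized main effects", "argument")
    }
    data[[paste(ia, collapse = "_x_")]] <- zscore(data[[ia[1]]] * data[[ia[2]]])
  }
  data
}
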