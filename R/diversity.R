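#' Standardize trait values across the species pool
#'
#' Each trait is z-scored over the species that have it measured (mean 0,
#' sample SD 1 with the n-1 denominator); missing values stay missing.
#' Standardization uses the full measured pool, not per-plot subsets, so
#' trait distances are comparable across plots.
#'
#' @param traits A trait table (see [read_trait_table()]).
#' @return The trait table with every trait column z-scored.
#' @export
standardize_traits <- function(traits) {
  # structural validation only: the input may itself already be z-scored
  validate_trait_table(traits, check_values = FALSE)
  for (tr in trait_names()) {
    v <- traits[[tr]]
    if (sum(!is.na(v)) < 2) {
      hd_abort(paste0("trait ", tr, " has fewer than 2 measured species"), "validation")
    }
    if (sd(v, na.rm = TRUE) == 0) {
      hd_abort(paste0("trait ", tr, " has zero variance"), "zero_variance")
    }
    traits[[tr]] <- zscore(v)
  }
  traits
}

#' Euclidean trait distance matrix
#'
#' For a single trait the dissimilarity between two species is the absolute
#' difference of their z-scores. For several traits, the z-scored trait block
#' is first rotated by a PCA (all axes kept, no rescaling) so the coordinates
#' are orthogonal, and Euclidean distance is taken over all axes; since a
#' full-rank unscaled PCA is a rotation, this equals Euclidean distance on
#' the z-scores themselves. Only species with complete data on the requested
#' traits enter the matrix.
#'
#' @param z_traits A standardized trait table from [standardize_traits()].
#' @param trait_subset Character vector of trait names (see [trait_names()]).
#' @return A symmetric numeric matrix with species as dimnames.
#' @export
trait_distance_matrix <- function(z_traits, trait_subset) {
  bad <- setdiff(trait_subset, trait_names())
  if (length(trait_subset) < 1 || length(bad) > 0) {
    hd_abort("trait_subset must name at least one known trait", "argument")
  }
  block <- z_traits[, trait_subset, drop = FALSE]
  complete <- stats::complete.cases(block)
  if (sum(complete) < 2) {
    hd_abort("fewer than 2 species with complete data on the trait subset", "validation")
  }
  m <- as.matrix(block[complete, , drop = FALSE])
  rownames(m) <- z_traits$species[complete]
  if (ncol(m) > 1) {
    m <- prcomp(m, center = TRUE, scale. = FALSE)$x
  }
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Cophenetic distances from an ultrametric phylogeny
#'
#' The distance between two tips is the total branch length along the tree
#' path connecting them.
#'
#' @param phylogeny An `ape::phylo` tree with unique tip labels.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_distances <- function(phylogeny) {
  if (anyDuplicated(phylogeny$tip.label)) {
    hd_abort("duplicate tip labels", "validation")
  }
  stats::cophenetic(phylogeny)
}

#' Community-weighted mean of a trait
#'
#' The abundance-weighted mean trait value of a plot, with relative
#' abundances renormalized over the species that have the trait measured.
#' Returned in raw (non-standardized) trait units.
#'
#' @param plot Plot identifier.
#' @param communities A community matrix tibble.
#' @param traits A trait table (raw units).
#' @param trait A trait name.
#' @return A single numeric value.
#' @export
cwm <- function(plot, communities, traits, trait) {
  p <- relative_abundances(communities, plot)
  t_vals <- setNames(traits[[trait]], traits$species)[names(p)]
  keep <- !is.na(t_vals)
  if (!any(keep)) {
    hd_abort(paste0("no species with measured ", trait, " in plot ", plot), "validation")
  }
  sum(p[keep] / sum(p[keep]) * t_vals[keep])
}

#' Rao's quadratic entropy of a plot
#'
#' Rao's Q is the expected dissimilarity between two individuals drawn at
#' random (with replacement) from the community:
#' `Q = sum_i sum_j p_i p_j d_ij`, with relative abundances `p` renormalized
#' over the species present in both the plot and the distance matrix.
#' Self-pairs (d = 0) are included in the double sum, so Q follows the
#' `sum p_i p_j d_ij` convention rather than `2 sum_{i<j}`.
#'
#' @param plot Plot identifier.
#' @param communities A community matrix tibble.
#' @param distances A dissimilarity matrix with species dimnames (from
#'   [trait_distance_matrix()] or [cophenetic_distances()]).
#' @return A single non-negative numeric value; 0 for monocultures.
#' @export
rao_q <- function(plot, communities, distances) {
  p <- relative_abundances(communities, plot)
  sp <- intersect(names(p), rownames(distances))
  if (length(sp) == 0) {
    hd_abort(paste0("no species of plot ", plot, " in the distance matrix"), "validation")
  }
  p <- p[sp] / sum(p[sp])
  drop(p %*% distances[sp, sp, drop = FALSE] %*% p)
}

#' Focal-species dispersion (abundance-weighted MPD analogue)
#'
#' The mean dissimilarity between an individual of the focal species and the
#' other individuals of its plot: `Q^spec = sum_{j != f} p''_j d_fj` with
#' weights `p''` renormalized over non-focal species. By default conspecific
#' (focal-to-focal, d = 0) pairs are excluded, matching the abundance-weighted
#' mean pairwise distance; set `include_conspecifics = TRUE` to weight over
#' all individuals including the focal species itself.
#'
#' @param focal Focal species identifier; must be present in the plot.
#' @param plot Plot identifier.
#' @param communities A community matrix tibble.
#' @param distances A dissimilarity matrix with species dimnames.
#' @param include_conspecifics Count focal-to-focal pairs (distance 0) in the
#'   weighting? Default `FALSE`.
#' @return A single non-negative numeric value.
#' @export
rao_q_specific <- function(focal, plot, communities, distances,
                           include_conspecifics = FALSE) {
  p <- relative_abundances(communities, plot)
  if (!focal %in% names(p)) {
    hd_abort(paste0("focal species ", focal, " absent from plot ", plot), "validation")
  }
  if (!focal %in% rownames(distances)) {
    hd_abort(paste0("focal species ", focal, " missing from the distance matrix"),
             "validation")
  }
  sp <- intersect(names(p), rownames(distances))
  others <- setdiff(sp, focal)
  if (length(others) == 0) {
    hd_abort(paste0("no non-focal species with distance data in plot ", plot),
             "validation")
  }
  qspec_from_p(p, focal, distances, include_conspecifics)
}

# Q^spec kernel on a precomputed relative-abundance vector
qspec_from_p <- function(p, focal, distances, include_conspecifics) {
  sp <- intersect(names(p), rownames(distances))
  others <- setdiff(sp, focal)
  if (include_conspecifics) {
    w <- p[sp] / sum(p[sp])
    sum(w * distances[focal, sp])
  } else {
    w <- p[others] / sum(p[others])
    sum(w * distances[focal, others])
  }
}

#' Compute the full plot- and focal-level metric tables
#'
#' Assembles, for every plot: species richness, the community-weighted mean
#' `CWM_t` and single-trait Rao's Q `Q_t` for each of the seven traits, the
#' multivariate morphological (`Q_morph`) and chemical (`Q_chem`) Rao's Q,
#' optionally an overall all-trait `Q_all`, and the phylogenetic `Q_phylo`
#' from cophenetic distances. For every (plot, focal species) pair the
#' corresponding focal dispersions `Qspec_phylo`, `Qspec_t`, `Qspec_morph`
#' and `Qspec_chem` are computed. All measures are weighted by plot-level
#' abundances. Species without trait data are dropped per metric with weight
#' renormalization; abundance species missing from the phylogeny are an
#' error.
#'
#' @param communities A community matrix tibble.
#' @param traits A raw trait table.
#' @param phylogeny An `ape::phylo` tree covering all community species.
#' @param focal_species Character vector of focal species; each must be
#'   present in every plot.
#' @param include_overall_q Also compute the combined morphological+chemical
#'   `Q_all` and `Qspec_all`? Default `FALSE`.
#' @param include_conspecifics Passed to [rao_q_specific()].
#' @return An object of class `herb_metrics`: a list with tibbles `plot`
#'   (one row per plot) and `focal` (one row per plot-by-focal-species).
#' @export
compute_all_metrics <- function(communities, traits, phylogeny, focal_species,
                                include_overall_q = FALSE,
                                include_conspecifics = FALSE) {
  validate_community_matrix(communities)
  validate_trait_table(traits)
  comm_species <- setdiff(names(communities), "plot")
  missing_tips <- setdiff(comm_species, phylogeny$tip.label)
  if (length(missing_tips) > 0) {
    hd_abort(paste0("community species missing from the phylogeny: ",
                    paste(head(missing_tips, 5), collapse = ", ")), "validation")
  }
  z <- standardize_traits(traits)
  grp <- trait_groups()
  subsets <- c(
    setNames(as.list(trait_names()), trait_names()),
    list(morph = grp$morphological, chem = grp$chemical)
  )
  if (include_overall_q) subsets$all <- c(grp$morphological, grp$chemical)
  dists <- purrr::map(subsets, function(s) trait_distance_matrix(z, s))
  dists$phylo <- cophenetic_distances(phylogeny)

  plots <- communities$plot
  p_list <- lapply(setNames(plots, plots),
                   function(pl) relative_abundances(communities, pl))

  plot_tbl <- tibble::tibble(
    plot = plots,
    richness = vapply(p_list, length, integer(1))
  )
  for (tr in trait_names()) {
    plot_tbl[[paste0("CWM_", tr)]] <-
      vapply(plots, function(pl) cwm(pl, communities, traits, tr), numeric(1))
  }
  for (nm in names(dists)) {
    plot_tbl[[paste0("Q_", nm)]] <-
      vapply(plots, function(pl) rao_q(pl, communities, dists[[nm]]), numeric(1))
  }

  focal_tbl <- tidyr::expand_grid(plot = plots, focal_species = focal_species)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    focal_tbl[[paste0("Qspec_", nm)]] <- purrr::map2_dbl(
      focal_tbl$plot, focal_tbl$focal_species,
      function(pl, f) {
        p <- p_list[[pl]]
        if (!f %in% names(p)) {
          hd_abort(paste0("focal species ", f, " absent from plot ", pl), "validation")
        }
        qspec_from_p(p, f, d, include_conspecifics)
      }
    )
  }

  structure(list(plot = plot_tbl, focal = focal_tbl), class = "herb_metrics")
}

#' @export
print.herb_metrics <- function(x, ...) {
  cat("Community diversity metrics\n")
  cat("  plots:", nrow(x$plot), " focal rows:", nrow(x$focal), "\n")
  print(x$plot, n = 5)
  invisible(x)
}

#' Tidy a metric table into long format
#'
#' @param x A `herb_metrics` object from [compute_all_metrics()].
#' @param ... Unused.
#' @return A long tibble (`plot`, `focal_species` (`NA` for plot-level
#'   rows), `metric`, `value`).
#' @export
tidy.herb_metrics <- function(x, ...) {
  plot_long <- x$plot |>
    tidyr::pivot_longer(-"plot", names_to = "metric", values_to = "value") |>
    dplyr::mutate(focal_species = NA_character_, .after = "plot")
  focal_long <- x$focal |>
    tidyr::pivot_longer(-c("plot", "focal_species"),
                        names_to = "metric", values_to = "value")
  dplyr::bind_rows(plot_long, focal_long)
}
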