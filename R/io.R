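#' Leaf trait vocabulary
#'
#' Seven species-level leaf traits are used throughout: three morphological
#' (leaf area `LA` in mm^2, specific leaf area `SLA` in mm^2 mg^-1, leaf dry
#' matter content `LDMC` in mg g^-1) and four chemical (leaf carbon content
#' `C` in %, carbon-to-nitrogen ratio `CN`, carbon-to-phosphorus ratio `CP`,
#' and polyphenolics content `PHEN` as a mass fraction).
#'
#' @format `trait_names()` returns all seven names; `trait_groups()` returns
#'   a named list with the `morphological` and `chemical` partition.
#' @export
trait_names <- function() c("LA", "SLA", "LDMC", "C", "CN", "CP", "PHEN")

#' @rdname trait_names
#' @export
trait_groups <- function() {
  list(
    morphological = c("LA", "SLA", "LDMC"),
    chemical = c("C", "CN", "CP", "PHEN")
  )
}

validate_trait_table <- function(traits, check_values = TRUE) {
  tn <- trait_names()
  missing_cols <- setdiff(c("species", tn), names(traits))
  if (length(missing_cols) > 0) {
    hd_abort(paste0("trait table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")), "format")
  }
  if (anyDuplicated(traits$species)) {
    hd_abort("duplicate species in trait table", "validation")
  }
  if (!check_values) return(invisible(traits))
  for (tr in tn) {
    v <- traits[[tr]]
    bad <- !is.na(v) & !is.finite(v)
    if (any(bad)) hd_abort(paste0("non-finite values in trait ", tr), "validation")
    pos <- setdiff(tn, "C")
    if (tr %in% pos && any(v <= 0, na.rm = TRUE)) {
      hd_abort(paste0("trait ", tr, " must be strictly positive"), "validation")
    }
    if (tr == "C" && any(v <= 0 | v >= 100, na.rm = TRUE)) {
      hd_abort("leaf C content must lie in (0, 100) %", "validation")
    }
  }
  invisible(traits)
}

#' Read and write species-by-trait tables
#'
#' The trait CSV has a `species` column plus the seven trait columns of
#' [trait_names()]; empty cells denote missing values. Unknown extra columns
#' are dropped with a warning. Values are validated (finiteness, positivity,
#' C within (0, 100) %).
#'
#' @param path Path to a CSV file.
#' @return `read_trait_table()`: a tibble with columns `species` and the
#'   seven traits.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  tn <- trait_names()
  missing_cols <- setdiff(c("species", tn), names(raw))
  if (length(missing_cols) > 0) {
    hd_abort(paste0("trait table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")), "format")
  }
  extra <- setdiff(names(raw), c("species", tn))
  if (length(extra) > 0) {
    rlang::warn(paste0("ignoring unknown trait-table column(s): ",
                       paste(extra, collapse = ", ")))
  }
  out <- tibble::tibble(species = canonical_species(raw$species))
  for (tr in tn) {
    cell <- raw[[tr]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & is.na(num))
    if (length(bad) > 0) {
      hd_abort(paste0("non-numeric value '", cell[bad[1]], "' in trait column ",
                      tr, ", row ", bad[1]), "parse")
    }
    num[cell == ""] <- NA_real_
    out[[tr]] <- num
  }
  validate_trait_table(out)
  out
}

#' @rdname read_trait_table
#' @param traits A validated trait table.
#' @export
write_trait_table <- function(traits, path) {
  validate_trait_table(traits)
  readr::write_csv(traits[, c("species", trait_names())], path, na = "")
  invisible(path)
}

validate_community_matrix <- function(comm) {
  if (!"plot" %in% names(comm)) hd_abort("community matrix needs a 'plot' column", "format")
  if (anyDuplicated(comm$plot)) hd_abort("duplicate plot rows", "validation")
  m <- as.matrix(comm[, setdiff(names(comm), "plot"), drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) {
    hd_abort("abundance counts must be finite and non-negative", "validation")
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    hd_abort("abundance counts must be integers", "validation")
  }
  if (any(rowSums(m) == 0)) {
    hd_abort(paste0("plot(s) with zero total abundance: ",
                    paste(comm$plot[rowSums(m) == 0], collapse = ", ")), "validation")
  }
  invisible(comm)
}

#' Read and write plot-by-species abundance matrices
#'
#' Rows are plots (first column `plot`), remaining columns are species with
#' non-negative integer individual counts; species absent from a plot carry
#' a 0. Every plot must have a positive total count.
#'
#' @param path Path to a CSV file.
#' @return `read_community_matrix()`: a tibble, `plot` column plus one count
#'   column per species (species names canonicalized).
#' @export
read_community_matrix <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    plot = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  names(raw)[-1] <- canonical_species(names(raw)[-1])
  raw[is.na(raw)] <- 0
  validate_community_matrix(raw)
  raw
}

#' @rdname read_community_matrix
#' @param communities A validated community matrix tibble.
#' @export
write_community_matrix <- function(communities, path) {
  validate_community_matrix(communities)
  readr::write_csv(communities, path)
  invisible(path)
}

# relative abundances for one plot, as a named vector over species with
# positive counts
relative_abundances <- function(communities, plot) {
  row <- communities[communities$plot == plot, , drop = FALSE]
  if (nrow(row) != 1) hd_abort(paste0("unknown plot: ", plot), "validation")
  counts <- unlist(row[, setdiff(names(row), "plot")])
  counts <- counts[counts > 0]
  counts / sum(counts)
}

#' Read and write rooted ultrametric phylogenies
#'
#' Trees are exchanged as Newick strings and held as `ape::phylo` objects.
#' Tip labels are canonicalized (underscores become spaces) and must be
#' unique. Ultrametricity is enforced: all root-to-tip path lengths must
#' agree within `tol` times the tree depth.
#'
#' @param path Path to a Newick file.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return `read_phylogeny()`: an `ape::phylo` tree.
#' @export
read_phylogeny <- function(path, tol = 1e-6) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) hd_abort("could not parse Newick file", "format")
  tree$tip.label <- canonical_species(tree$tip.label)
  validate_phylogeny(tree, tol = tol)
  tree
}

validate_phylogeny <- function(tree, tol = 1e-6) {
  if (anyDuplicated(tree$tip.label)) hd_abort("duplicate tip labels", "validation")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    hd_abort("tree must have non-negative branch lengths", "validation")
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  dev <- max(depths) - min(depths)
  if (dev > tol * max(depths)) {
    hd_abort(paste0("tree is not ultrametric: max root-to-tip deviation ",
                    format(dev, digits = 6)), "validation")
  }
  invisible(tree)
}

#' @rdname read_phylogeny
#' @param tree An `ape::phylo` tree.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read and write sapling herbivory surveys
#'
#' Two CSV dialects are accepted and auto-detected from the header. The
#' per-leaf (long) dialect has columns `plot,species,sapling,height_cm,
#' leaf_class` with one row per leaf; the aggregated dialect has
#' `plot,species,sapling,height_cm,leaf_count,mean_damage` with one row per
#' sapling. Both are returned as one row per sapling with `leaf_count`, a
#' `leaf_classes` list column (per-leaf dialect) and `mean_damage`
#' (aggregated dialect; `NA` otherwise).
#'
#' @param path Path to a CSV file.
#' @param max_saplings Maximum saplings allowed per plot-by-species
#'   combination (default 10, the survey design cap).
#' @return `read_sapling_survey()`: a per-sapling tibble.
#' @export
read_sapling_survey <- function(path, max_saplings = 10) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  spec <- list(
    plot = readr::col_character(), species = readr::col_character(),
    sapling = readr::col_character(), height_cm = readr::col_double(),
    leaf_class = readr::col_character(), leaf_count = readr::col_double(),
    mean_damage = readr::col_double()
  )
  raw <- readr::read_csv(
    path, col_types = do.call(readr::cols, spec[intersect(names(spec), header)]),
    progress = FALSE
  )
  base_cols <- c("plot", "species", "sapling", "height_cm")
  if (!all(base_cols %in% names(raw))) {
    hd_abort("survey needs columns plot, species, sapling, height_cm", "format")
  }
  raw$species <- canonical_species(raw$species)
  if ("leaf_class" %in% names(raw)) {
    raw$leaf_class <- as.character(raw$leaf_class)
    unknown <- setdiff(unique(raw$leaf_class), damage_classes()$class_label)
    if (length(unknown) > 0) {
      hd_abort(paste0("unknown damage class label(s): ",
                      paste(unknown, collapse = ", ")), "vocabulary")
    }
    survey <- raw |>
      dplyr::group_by(.data$plot, .data$species, .data$sapling, .data$height_cm) |>
      dplyr::summarise(leaf_count = dplyr::n(),
                       leaf_classes = list(.data$leaf_class), .groups = "drop") |>
      dplyr::mutate(mean_damage = NA_real_)
  } else if (all(c("leaf_count", "mean_damage") %in% names(raw))) {
    survey <- raw |>
      dplyr::mutate(leaf_count = as.integer(.data$leaf_count),
                    leaf_classes = vector("list", dplyr::n())) |>
      dplyr::select("plot", "species", "sapling", "height_cm",
                    "leaf_count", "leaf_classes", "mean_damage")
  } else {
    hd_abort("survey dialect not recognized: need leaf_class or leaf_count+mean_damage",
             "format")
  }
  validate_sapling_survey(survey, max_saplings = max_saplings)
  survey
}

validate_sapling_survey <- function(survey, max_saplings = 10) {
  if (any(survey$leaf_count < 1)) hd_abort("leaf_count must be >= 1", "validation")
  if (any(survey$height_cm < 20 | survey$height_cm > 100)) {
    hd_abort("sapling height must lie in [20, 100] cm", "validation")
  }
  agg <- !purrr::map_lgl(survey$leaf_classes, is.null)
  if (any(purrr::map_int(survey$leaf_classes[agg], length) !=
          survey$leaf_count[agg])) {
    hd_abort("leaf_classes length must equal leaf_count", "validation")
  }
  md <- survey$mean_damage[!agg]
  if (any(!is.na(md) & (md < 0 | md > 1))) {
    hd_abort("mean_damage must lie in [0, 1]", "validation")
  }
  per <- dplyr::count(survey, .data$plot, .data$species)
  if (any(per$n > max_saplings)) {
    hd_abort(paste0("more than ", max_saplings, " saplings for some plot x species"),
             "validation")
  }
  invisible(survey)
}

#' @rdname read_sapling_survey
#' @param survey A per-sapling survey tibble.
#' @param dialect `"long"` (per-leaf rows; requires `leaf_classes`) or
#'   `"aggregated"` (per-sapling rows with `mean_damage`).
#' @export
write_sapling_survey <- function(survey, path, dialect = c("long", "aggregated")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    if (any(purrr::map_lgl(survey$leaf_classes, is.null))) {
      hd_abort("long dialect needs per-leaf classes for every sapling", "format")
    }
    long <- survey |>
      dplyr::select("plot", "species", "sapling", "height_cm", "leaf_classes") |>
      tidyr::unnest_longer("leaf_classes", values_to = "leaf_class")
    readr::write_csv(long, path)
  } else {
    readr::write_csv(
      survey[, c("plot", "species", "sapling", "height_cm", "leaf_count", "mean_damage")],
      path
    )
  }
  invisible(path)
}

#' Read and write plot characteristics
#'
#' One row per plot with the stand descriptors `stand_age` (yr),
#' `tree_density` (stems per plot), `canopy_cover` (%), `herb_cover` (%),
#' `elevation` (m) and `aspect` (degrees; kept as provided, no circular
#' transform).
#'
#' @param path Path to a CSV file.
#' @return `read_plot_characteristics()`: a tibble.
#' @export
read_plot_characteristics <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    plot = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  validate_plot_characteristics(raw)
  raw
}

plot_char_names <- function() {
  c("stand_age", "tree_density", "canopy_cover", "herb_cover", "elevation", "aspect")
}

validate_plot_characteristics <- function(chars) {
  need <- c("plot", plot_char_names())
  missing_cols <- setdiff(need, names(chars))
  if (length(missing_cols) > 0) {
    hd_abort(paste0("plot characteristics lack column(s): ",
                    paste(missing_cols, collapse = ", ")), "format")
  }
  if (anyDuplicated(chars$plot)) hd_abort("duplicate plot rows", "validation")
  m <- as.matrix(chars[, plot_char_names()])
  if (any(!is.finite(m))) hd_abort("plot characteristics must be finite", "validation")
  invisible(chars)
}

#' @rdname read_plot_characteristics
#' @param chars A plot-characteristics tibble.
#' @export
write_plot_characteristics <- function(chars, path) {
  validate_plot_characteristics(chars)
  readr::write_csv(chars[, c("plot", plot_char_names())], path)
  invisible(path)
}

#' Read and write calibration scan tables
#'
#' @param path Path to a CSV with columns `class_label,damage_fraction`.
#' @return `read_calibration_scans()`: a tibble of scans, ready for
#'   [calibrate_classes()].
#' @export
read_calibration_scans <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    class_label = readr::col_character(),
    damage_fraction = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_calibration_scans
#' @param scans A scan tibble (`class_label`, `damage_fraction`).
#' @export
write_calibration_scans <- function(scans, path) {
  readr::write_csv(scans[, c("class_label", "damage_fraction")], path)
  invisible(path)
}
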