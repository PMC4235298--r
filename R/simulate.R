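#' Configuration of the synthetic study generator
#'
#' Bundles every knob of the synthetic forest-plot study: the survey design
#' (27 plots, a 147-species pool with 25-69 woody species per plot, 10
#' dominant focal species, at most 10 saplings per focal species and plot,
#' leaf counts matching a mean of 45.4 with SD 45.3), the trait-evolution
#' model (correlated Brownian motion on the phylogeny), and the true
#' response model (logit-linear damage probability with crossed
#' species/plot random intercepts and an observation-level term).
#'
#' @param seed Root seed; every stage derives its own substream from it, so
#'   e.g. regenerating the herbivory does not alter the phylogeny.
#' @param n_plots Number of study plots.
#' @param richness_range Inclusive range of per-plot woody species richness.
#' @param pool_size Species-pool size.
#' @param n_focal Number of focal (dominant) species carrying the herbivory
#'   survey; forced present in every plot.
#' @param saplings_range Inclusive range of saplings per focal species and
#'   plot (upper bound is the design cap of 10).
#' @param leaves_mean,leaves_sd Moments of the per-sapling leaf count
#'   (lognormal, moment-matched, clipped at 1).
#' @param trait_signal Named Brownian rates per trait (a rate of 0 makes the
#'   trait constant before transformation).
#' @param trait_correlations 7x7 target cross-trait correlation matrix of
#'   the Brownian increments (symmetric positive semidefinite). The default
#'   includes a strongly correlated chemical pair (|r| > 0.7) so the
#'   collinearity screen is exercised.
#' @param intercept True intercept on the logit scale (default
#'   `qlogis(0.08)`, i.e. 8% mean damage).
#' @param beta Named true coefficients on the standardized predictors; names
#'   must match predictor columns (`Q_chem`, `CWM_C`, `richness`,
#'   `Qspec_phylo`, ...).
#' @param sigma_species,sigma_plot,sigma_obs True random-intercept SDs on
#'   the logit scale.
#' @param missing_trait_fraction Fraction of pool species with all traits
#'   missing, sampled with probability inversely related to abundance rank
#'   (never focal species).
#' @param severity_mean,severity_precision Beta-distribution moments of the
#'   per-leaf damage fraction of damaged leaves.
#' @param n_scans_per_class Scanned leaves per damage class in the synthetic
#'   calibration sample.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_plots = 27L,
                             richness_range = c(25L, 69L),
                             pool_size = 147L,
                             n_focal = 10L,
                             saplings_range = c(3L, 10L),
                             leaves_mean = 45.4, leaves_sd = 45.3,
                             trait_signal = setNames(rep(1, 7), trait_names()),
                             trait_correlations = default_trait_correlations(),
                             intercept = qlogis(0.08),
                             beta = c(Q_chem = 0.19, CWM_C = -0.19,
                                      richness = 0.14, Q_C = -0.14,
                                      Qspec_phylo = 0.14, Qspec_LA = -0.10,
                                      CWM_LDMC = 0.08),
                             sigma_species = 0.6, sigma_plot = 0.3,
                             sigma_obs = 0.5,
                             missing_trait_fraction = 0.2,
                             severity_mean = 0.25, severity_precision = 4,
                             n_scans_per_class = 25L) {
  cfg <- list(
    seed = as.integer(seed), n_plots = as.integer(n_plots),
    richness_range = as.integer(richness_range),
    pool_size = as.integer(pool_size), n_focal = as.integer(n_focal),
    saplings_range = as.integer(saplings_range),
    leaves_mean = leaves_mean, leaves_sd = leaves_sd,
    trait_signal = trait_signal, trait_correlations = trait_correlations,
    intercept = intercept, beta = beta,
    sigma_species = sigma_species, sigma_plot = sigma_plot,
    sigma_obs = sigma_obs,
    missing_trait_fraction = missing_trait_fraction,
    severity_mean = severity_mean, severity_precision = severity_precision,
    n_scans_per_class = as.integer(n_scans_per_class)
  )
  if (any(c(cfg$sigma_species, cfg$sigma_plot, cfg$sigma_obs) < 0)) {
    hd_abort("random-intercept SDs must be >= 0", "argument")
  }
  if (cfg$richness_range[1] < 2 || cfg$richness_range[2] > cfg$pool_size ||
      cfg$richness_range[1] > cfg$richness_range[2]) {
    hd_abort("richness_range must lie within [2, pool_size]", "argument")
  }
  if (cfg$n_focal > cfg$richness_range[1]) {
    hd_abort("n_focal cannot exceed the minimum plot richness", "argument")
  }
  R <- cfg$trait_correlations
  if (!isTRUE(all.equal(R, t(R))) || min(eigen(R, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-8) {
    hd_abort("trait_correlations must be symmetric positive semidefinite", "argument")
  }
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_trait_correlations <- function() {
  tn <- trait_names()
  R <- diag(7)
  dimnames(R) <- list(tn, tn)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("LA", "SLA", 0.3)
  set_r("SLA", "LDMC", -0.4)
  set_r("C", "CN", 0.3)
  set_r("C", "CP", 0.3)
  set_r("CN", "CP", 0.85)
  set_r("CN", "PHEN", 0.8)
  set_r("CP", "PHEN", 0.8)
  R
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# deterministic per-stage substreams derived from the root seed
stage_seed <- function(seed, stage) {
  stages <- c("pool", "phylogeny", "traits", "communities", "herbivory", "scans")
  i <- match(stage, stages)
  if (is.na(i)) hd_abort(paste0("unknown stage ", stage), "argument")
  with_preserved_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(stages))[i])
}

# species pool shared by the trait and community stages: lognormal base
# abundance weights; focal species are the most abundant; trait missingness
# hits rare species preferentially. Runs on its own substream without
# disturbing the caller's RNG state.
pool_info <- function(config) {
  with_preserved_seed(stage_seed(config$seed, "pool"), {
    species <- sprintf("sp%03d", seq_len(config$pool_size))
    weight <- rlnorm(config$pool_size, meanlog = 0, sdlog = 1.5)
    focal <- species[order(weight, decreasing = TRUE)[seq_len(config$n_focal)]]
    n_missing <- round(config$missing_trait_fraction * config$pool_size)
    nonfocal <- setdiff(species, focal)
    # selection probability proportional to rarity rank
    rarity <- rank(-weight[match(nonfocal, species)])
    missing <- sample(nonfocal, n_missing, prob = rarity)
    tibble::tibble(species = species, weight = weight,
                   focal = species %in% focal,
                   traits_missing = species %in% missing)
  })
}

#' Focal species of a synthetic configuration
#'
#' @param config A `synthetic_config`.
#' @return Character vector of the `n_focal` dominant species.
#' @export
focal_species <- function(config) {
  info <- pool_info(config)
  info$species[info$focal]
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' A Yule (pure-birth) tree over the species pool, rescaled to total depth
#' 1, standing in for a dated community phylogeny.
#'
#' @param pool_size Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` ultrametric tree with tips `sp001`, `sp002`, ...
#' @export
simulate_phylogeny <- function(pool_size, seed) {
  if (pool_size < 2) hd_abort("pool_size must be >= 2", "argument")
  set.seed(seed)
  tree <- ape::rphylo(pool_size, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(pool_size))
  tree
}

#' Simulate correlated Brownian leaf traits on a phylogeny
#'
#' The seven traits evolve as correlated Brownian motion on the tree
#' (covariance = tree covariance x trait correlation matrix, scaled by the
#' per-trait rates), then each latent value is mapped by a fixed monotone
#' transform into the trait's valid range (log-normal-like for the positive
#' traits, a logistic map into (35, 51) % for leaf C). A configured fraction
#' of species - preferentially rare, never focal - gets all traits set to
#' missing.
#'
#' @param phylogeny Tree over the pool (tips named as in the pool).
#' @param config A `synthetic_config`.
#' @param seed Optional integer seed (default: the trait substream of
#'   `config$seed`).
#' @return A trait table tibble.
#' @export
simulate_traits <- function(phylogeny, config, seed = NULL) {
  set.seed(seed %||% stage_seed(config$seed, "traits"))
  n <- length(phylogeny$tip.label)
  Cmat <- ape::vcv(phylogeny)
  Lt <- chol(Cmat + 1e-10 * diag(n))
  R <- config$trait_correlations
  Z <- matrix(rnorm(n * 7), n, 7)
  latent <- t(Lt) %*% Z %*% chol(R + 1e-12 * diag(7))
  latent <- sweep(latent, 2, sqrt(config$trait_signal[trait_names()]), `*`)
  colnames(latent) <- trait_names()
  rownames(latent) <- rownames(Cmat)
  latent <- latent[phylogeny$tip.label, , drop = FALSE]
  rownames(latent) <- NULL
  traits <- tibble::tibble(
    species = phylogeny$tip.label,
    LA = exp(4.0 + 1.0 * latent[, "LA"]),
    SLA = exp(2.8 + 0.5 * latent[, "SLA"]),
    LDMC = exp(5.8 + 0.3 * latent[, "LDMC"]),
    C = 35 + 16 * plogis(1.2 * latent[, "C"]),
    CN = exp(3.4 + 0.4 * latent[, "CN"]),
    CP = exp(6.0 + 0.5 * latent[, "CP"]),
    PHEN = exp(-3.0 + 0.6 * latent[, "PHEN"])
  )
  info <- pool_info(config)
  drop_sp <- info$species[info$traits_missing]
  for (tr in trait_names()) {
    traits[[tr]][traits$species %in% drop_sp] <- NA_real_
  }
  validate_trait_table(traits)
  traits
}

#' Simulate plot communities and plot characteristics
#'
#' Per plot, richness is drawn uniformly on the configured range; species
#' are sampled from the pool with probability proportional to their
#' lognormal base abundance weight (a minority of species dominate), with
#' the focal species forced present everywhere. Counts are Poisson around
#' each species' relative weight. Plot characteristics follow a latent
#' stand-age axis that drives tree density, canopy cover and herb cover, so
#' a dominant first principal component exists.
#'
#' @param config A `synthetic_config`.
#' @param phylogeny The pool phylogeny (for tip names).
#' @param seed Optional integer seed.
#' @return A list with `communities` (community matrix tibble) and
#'   `plot_characteristics`.
#' @export
simulate_communities <- function(config, phylogeny, seed = NULL) {
  set.seed(seed %||% stage_seed(config$seed, "communities"))
  info <- pool_info(config)
  species <- info$species
  plots <- sprintf("plot%02d", seq_len(config$n_plots))
  counts <- matrix(0, config$n_plots, config$pool_size,
                   dimnames = list(plots, species))
  for (i in seq_len(config$n_plots)) {
    rich <- sample(seq(config$richness_range[1], config$richness_range[2]), 1)
    nonfocal <- sample(species[!info$focal], rich - config$n_focal,
                       prob = info$weight[!info$focal])
    present <- c(species[info$focal], nonfocal)
    wrel <- info$weight[match(present, species)]
    wrel <- wrel / sum(wrel)
    counts[i, present] <- 1 + rpois(length(present), 400 * wrel)
  }
  communities <- dplyr::bind_cols(
    tibble::tibble(plot = plots),
    tibble::as_tibble(counts)
  )
  age <- runif(config$n_plots)
  chars <- tibble::tibble(
    plot = plots,
    stand_age = 15 + 75 * age + rnorm(config$n_plots, 0, 3),
    tree_density = 600 - 250 * age + rnorm(config$n_plots, 0, 60),
    canopy_cover = pmin(pmax(50 + 40 * age + rnorm(config$n_plots, 0, 5), 5), 100),
    herb_cover = pmin(pmax(70 - 40 * age + rnorm(config$n_plots, 0, 8), 1), 100),
    elevation = runif(config$n_plots, 250, 900),
    aspect = runif(config$n_plots, 0, 360)
  )
  validate_community_matrix(communities)
  list(communities = communities, plot_characteristics = chars)
}

#' Simulate calibration scans
#'
#' Scanned leaves per damage class, drawn from the same per-leaf severity
#' distribution the herbivory generator uses, conditioned on each class
#' interval, so calibrated class means estimate the conditional mean
#' severity of the class.
#'
#' @param config A `synthetic_config`.
#' @param seed Optional integer seed.
#' @return A scan tibble (`class_label`, `damage_fraction`).
#' @export
simulate_calibration_scans <- function(config, seed = NULL) {
  set.seed(seed %||% stage_seed(config$seed, "scans"))
  a <- config$severity_mean * config$severity_precision
  b <- (1 - config$severity_mean) * config$severity_precision
  cls <- damage_classes()
  out <- purrr::map_dfr(seq_len(nrow(cls)), function(i) {
    if (cls$class_label[i] == "0%") {
      return(tibble::tibble(class_label = "0%",
                            damage_fraction = rep(0, config$n_scans_per_class)))
    }
    vals <- numeric(0)
    while (length(vals) < config$n_scans_per_class) {
      draw <- rbeta(2000, a, b)
      vals <- c(vals, draw[draw > cls$lower[i] & draw <= cls$upper[i]])
    }
    tibble::tibble(class_label = cls$class_label[i],
                   damage_fraction = vals[seq_len(config$n_scans_per_class)])
  })
  out
}

#' Simulate the herbivory survey with known ground truth
#'
#' For each focal-species sapling, the true damage probability is
#' `pi = plogis(intercept + beta . x + b_species + b_plot + b_obs)`, where
#' the standardized predictors `x` are computed from the synthetic
#' communities, traits, phylogeny and plot characteristics with the same
#' metric and standardization functions the analysis pipeline uses. Each
#' leaf is damaged with probability `pi / severity_mean` (capped at 1) and,
#' if damaged, carries a Beta-distributed damage fraction, so the expected
#' per-leaf damage equals `pi`. Fractions are discretized into the six
#' damage classes, yielding a per-leaf-dialect survey.
#'
#' @param communities,traits,phylogeny,plot_chars Synthetic inputs from the
#'   earlier stages.
#' @param config A `synthetic_config`.
#' @param seed Optional integer seed.
#' @return A list with `survey` (per-sapling tibble with `leaf_classes`)
#'   and `ground_truth` (true coefficients, realized random intercepts,
#'   per-sapling linear predictor and damage probability, and the
#'   standardized predictor table used).
#' @export
simulate_herbivory <- function(communities, traits, phylogeny, plot_chars,
                               config, seed = NULL) {
  set.seed(seed %||% stage_seed(config$seed, "herbivory"))
  focal <- focal_species(config)
  no_traits <- focal[!focal %in% traits$species[!is.na(traits$LA)]]
  if (length(no_traits) > 0) {
    hd_abort(paste0("focal species without traits: ",
                    paste(no_traits, collapse = ", ")), "configuration")
  }
  metrics <- compute_all_metrics(communities, traits, phylogeny, focal)
  pca <- plot_pca(plot_chars)

  # sapling skeleton
  sig2 <- log(1 + (config$leaves_sd / config$leaves_mean)^2)
  mu_ln <- log(config$leaves_mean) - sig2 / 2
  skeleton <- tidyr::expand_grid(plot = communities$plot, species = focal) |>
    dplyr::mutate(n_sap = sample(seq(config$saplings_range[1],
                                     config$saplings_range[2]),
                                 dplyr::n(), replace = TRUE)) |>
    tidyr::uncount(.data$n_sap, .id = "sap_i") |>
    dplyr::mutate(
      sapling = paste0(.data$plot, "_", gsub(" ", "_", .data$species),
                       "_s", .data$sap_i),
      height_cm = round(runif(dplyr::n(), 20, 100), 1),
      leaf_count = pmax(1L, as.integer(round(rlnorm(dplyr::n(), mu_ln, sqrt(sig2))))),
      mean_damage = NA_real_
    ) |>
    dplyr::select(-"sap_i")

  # predictors exactly as the analysis pipeline builds them
  design <- skeleton |>
    dplyr::left_join(metrics$plot, by = "plot") |>
    dplyr::left_join(metrics$focal,
                     by = c("plot" = "plot", "species" = "focal_species")) |>
    dplyr::left_join(dplyr::select(pca$scores, "plot", PC1_abio = "PC1"),
                     by = "plot")
  pred_cols <- setdiff(names(design),
                       c("plot", "species", "sapling", "height_cm",
                         "leaf_count", "mean_damage"))
  std <- standardize_predictors(design, predictors = pred_cols,
                                interactions = list(c("richness", "Q_phylo")))
  beta <- config$beta
  missing_beta <- setdiff(names(beta), names(std))
  if (length(missing_beta) > 0) {
    hd_abort(paste0("beta names not among predictors: ",
                    paste(missing_beta, collapse = ", ")), "argument")
  }
  Xb <- if (length(beta) > 0) {
    drop(as.matrix(std[, names(beta), drop = FALSE]) %*% beta)
  } else {
    rep(0, nrow(std))
  }
  b_species <- setNames(rnorm(length(focal), 0, config$sigma_species), focal)
  b_plot <- setNames(rnorm(nrow(communities), 0, config$sigma_plot),
                     communities$plot)
  b_obs <- rnorm(nrow(std), 0, config$sigma_obs)
  eta <- config$intercept + Xb + b_species[std$species] + b_plot[std$plot] + b_obs
  pi <- plogis(eta)

  # leaf process, exactly mean-preserving: a leaf is damaged with
  # probability q = min(1, pi / severity_mean); damaged leaves carry a
  # Beta-distributed fraction with mean pi / q (the configured severity mean
  # while incidence is still rising, larger once incidence saturates), so
  # E[leaf damage] = q * (pi / q) = pi for every sapling
  phi <- config$severity_precision
  sap_idx <- rep(seq_len(nrow(std)), std$leaf_count)
  q_sap <- pmin(1, pi / config$severity_mean)
  s_sap <- pi / q_sap
  damaged <- rbinom(length(sap_idx), 1, q_sap[sap_idx])
  frac <- numeric(length(sap_idx))
  hit <- damaged == 1
  if (any(hit)) {
    s_leaf <- s_sap[sap_idx][hit]
    frac[hit] <- rbeta(sum(hit), s_leaf * phi, (1 - s_leaf) * phi)
  }
  leaf_classes <- unname(split(damage_class_of(frac),
                               factor(sap_idx, levels = seq_len(nrow(std)))))

  survey <- skeleton
  survey$leaf_classes <- leaf_classes
  validate_sapling_survey(survey, max_saplings = config$saplings_range[2])

  ground_truth <- list(
    intercept = config$intercept,
    beta = beta,
    sigma = c(species = config$sigma_species, plot = config$sigma_plot,
              obs = config$sigma_obs),
    b_species = b_species, b_plot = b_plot, b_obs = b_obs,
    saplings = tibble::tibble(
      plot = std$plot, species = std$species, sapling = std$sapling,
      eta = eta, pi = pi
    ),
    predictors = std
  )
  list(survey = survey, ground_truth = ground_truth)
}

#' Generate a complete synthetic study
#'
#' Runs all generator stages (phylogeny, traits, communities and plot
#' characteristics, calibration scans, herbivory survey) off independent
#' substreams of the root seed and returns every input the analysis
#' pipeline needs plus the ground truth.
#'
#' @param config A `synthetic_config`.
#' @return An object of class `herb_study`: list with `phylogeny`,
#'   `traits`, `communities`, `plot_characteristics`, `scans`, `survey`,
#'   `ground_truth`, `focal_species` and `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  phy <- simulate_phylogeny(config$pool_size,
                            stage_seed(config$seed, "phylogeny"))
  traits <- simulate_traits(phy, config)
  comm <- simulate_communities(config, phy)
  scans <- simulate_calibration_scans(config)
  herb <- simulate_herbivory(comm$communities, traits, phy,
                             comm$plot_characteristics, config)
  structure(list(
    phylogeny = phy, traits = traits, communities = comm$communities,
    plot_characteristics = comm$plot_characteristics, scans = scans,
    survey = herb$survey, ground_truth = herb$ground_truth,
    focal_species = focal_species(config), config = config
  ), class = "herb_study")
}

#' @export
print.herb_study <- function(x, ...) {
  cat("Synthetic herbivory study (seed", x$config$seed, ")\n")
  cat(" ", nrow(x$communities), "plots,", x$config$pool_size, "species pool,",
      length(x$focal_species), "focal species,", nrow(x$survey), "saplings\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the standard input files (trait, community, plot-characteristic
#' and calibration CSVs, Newick phylogeny, per-leaf survey CSV) plus
#' `ground_truth.json`.
#'
#' @param study A `herb_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trait_table(study$traits, file.path(dir, "traits.csv"))
  write_community_matrix(study$communities, file.path(dir, "communities.csv"))
  write_plot_characteristics(study$plot_characteristics,
                             file.path(dir, "plot_characteristics.csv"))
  write_phylogeny(study$phylogeny, file.path(dir, "phylogeny.nwk"))
  write_calibration_scans(study$scans, file.path(dir, "calibration_scans.csv"))
  write_sapling_survey(study$survey, file.path(dir, "survey.csv"), dialect = "long")
  gt <- study$ground_truth
  jsonlite::write_json(list(
    intercept = gt$intercept, beta = as.list(gt$beta),
    sigma = as.list(gt$sigma),
    b_species = as.list(gt$b_species), b_plot = as.list(gt$b_plot),
    saplings = gt$saplings
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
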