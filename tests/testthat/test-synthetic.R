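test_that("phylogeny simulation is ultrametric, deterministic and scaled to
           depth 1", {
  tree <- simulate_phylogeny(2, seed = 1)
  expect_equal(unname(cophenetic_distances(tree)["sp001", "sp002"]), 2)
  t1 <- simulate_phylogeny(40, seed = 9)
  t2 <- simulate_phylogeny(40, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_phylogeny(147, seed = 2)
  expect_equal(length(t3$tip.label), 147)
  depths <- ape::node.depth.edgelength(t3)[1:147]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_error(simulate_phylogeny(1, seed = 1), class = "herbdiv_argument")
})

test_that("trait simulation is reproducible, respects zero rates, and
           carries phylogenetic signal", {
  cfg <- small_config(seed = 4)
  tree <- simulate_phylogeny(cfg$pool_size, seed = 77)
  tr1 <- simulate_traits(tree, cfg, seed = 5)
  tr2 <- simulate_traits(tree, cfg, seed = 5)
  expect_identical(tr1, tr2)

  cfg0 <- small_config(seed = 4,
                       trait_signal = setNames(c(0, rep(1, 6)), trait_names()))
  tr0 <- simulate_traits(tree, cfg0, seed = 5)
  expect_equal(sd(tr0$LA, na.rm = TRUE), 0)

  # Brownian traits are more similar between close relatives: positive
  # association between trait distance and cophenetic distance on average
  cors <- vapply(1:10, function(s) {
    tr <- simulate_traits(tree, cfg, seed = 100 + s)
    ok <- !is.na(tr$LA)
    dt <- as.matrix(dist(scale(log(tr$LA[ok]))))
    dp <- cophenetic_distances(tree)[tr$species[ok], tr$species[ok]]
    cor(dt[lower.tri(dt)], dp[lower.tri(dp)])
  }, numeric(1))
  expect_gt(mean(cors), 0)
})

test_that("default trait correlations include a strong chemical pair", {
  R <- default_trait_correlations()
  chem <- trait_groups()$chemical
  off <- R[chem, chem][upper.tri(R[chem, chem])]
  expect_gte(max(abs(off)), 0.7)
  expect_gte(min(eigen(R, only.values = TRUE)$values), 0)
})

test_that("community simulation respects richness bounds and forces focal
           presence", {
  cfg <- synthetic_config(seed = 8)
  tree <- simulate_phylogeny(cfg$pool_size, seed = 8)
  out1 <- simulate_communities(cfg, tree, seed = 3)
  out2 <- simulate_communities(cfg, tree, seed = 3)
  expect_identical(out1, out2)
  counts <- as.matrix(out1$communities[, -1])
  rich <- rowSums(counts > 0)
  expect_true(all(rich >= 25 & rich <= 69))
  focal <- focal_species(cfg)
  expect_true(all(counts[, focal] > 0))
})

test_that("herbivory with zero effects and zero variances gives damage
           centred on the intercept probability", {
  cfg <- small_config(seed = 13, beta = c(Q_chem = 0), intercept = qlogis(0.1),
                      sigma_species = 0, sigma_plot = 0, sigma_obs = 0)
  study <- simulate_study(cfg)
  expect_equal(unique(round(study$ground_truth$saplings$pi, 12)), 0.1)
  cal <- calibrate_classes(study$scans)
  survey <- sapling_mean_damage(study$survey, cal)
  n_leaves <- sum(survey$leaf_count)
  mc_se <- sqrt(0.1 * 0.9 / n_leaves) + 0.01
  expect_lt(abs(weighted.mean(survey$mean_damage, survey$leaf_count) - 0.1),
            4 * mc_se)
})

test_that("large species variance dominates between-species differences", {
  cfg <- small_config(seed = 14, beta = c(Q_chem = 0),
                      sigma_species = 1.5, sigma_plot = 0, sigma_obs = 0.1)
  study <- simulate_study(cfg)
  cal <- calibrate_classes(study$scans)
  survey <- sapling_mean_damage(study$survey, cal)
  fit <- stats::aov(mean_damage ~ species, data = survey)
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_gt(ms[1], ms[2])
})

test_that("the full study is bit-for-bit reproducible and passes validation", {
  s1 <- simulate_study(small_config(seed = 21))
  s2 <- simulate_study(small_config(seed = 21))
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$communities, s2$communities)
  expect_identical(s1$survey, s2$survey)
  expect_identical(s1$ground_truth$saplings, s2$ground_truth$saplings)
  expect_identical(ape::write.tree(s1$phylogeny), ape::write.tree(s2$phylogeny))
  # substreams: regenerating herbivory does not alter the phylogeny inputs
  herb2 <- simulate_herbivory(s1$communities, s1$traits, s1$phylogeny,
                              s1$plot_characteristics, s1$config, seed = 999)
  expect_false(identical(herb2$survey$leaf_classes, s1$survey$leaf_classes))
  # validation-clean
  expect_silent(herbdiv:::validate_sapling_survey(s1$survey))
  expect_silent(herbdiv:::validate_community_matrix(s1$communities))
  expect_silent(herbdiv:::validate_phylogeny(s1$phylogeny))
})

test_that("written studies read back consistently", {
  study <- simulate_study(small_config(seed = 23))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_identical(read_trait_table(file.path(dir, "traits.csv")), study$traits)
  expect_identical(read_community_matrix(file.path(dir, "communities.csv")),
                   study$communities)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$sigma$species, study$config$sigma_species)
})

test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(richness_range = c(1, 200)),
               class = "herbdiv_argument")
  expect_error(synthetic_config(sigma_obs = -1), class = "herbdiv_argument")
  bad_R <- default_trait_correlations()
  bad_R[1, 2] <- bad_R[2, 1] <- 0.99
  bad_R[1, 3] <- bad_R[3, 1] <- 0.99
  bad_R[2, 3] <- bad_R[3, 2] <- -0.99
  expect_error(synthetic_config(trait_correlations = bad_R),
               class = "herbdiv_argument")
  s <- simulate_study(small_config(seed = 2))
  bad_cfg <- small_config(seed = 2, beta = c(not_a_predictor = 1))
  expect_error(
    simulate_herbivory(s$communities, s$traits, s$phylogeny,
                       s$plot_characteristics, bad_cfg),
    "not_a_predictor", class = "herbdiv_argument"
  )
})
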