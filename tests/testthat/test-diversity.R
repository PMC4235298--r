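test_that("trait standardization is a sample-SD z-score and idempotent", {
  traits <- tiny_traits()
  traits$LA <- c(1, 2, 3, NA)
  z <- standardize_traits(traits)
  expect_equal(z$LA, c(-1, 0, 1, NA))
  z2 <- standardize_traits(z)
  for (tr in trait_names()) expect_equal(z2[[tr]], z[[tr]], tolerance = 1e-12)

  const <- tiny_traits()
  const$CN <- rep(25, 4)
  expect_error(standardize_traits(const), "CN", class = "herbdiv_zero_variance")
})

test_that("single-trait distances are absolute z-score differences", {
  traits <- tiny_traits()
  traits$LA <- c(1, 2, 3, 4)
  z <- standardize_traits(traits)
  d <- trait_distance_matrix(z, "LA")
  expect_equal(d["alpha", "gamma"], abs(z$LA[1] - z$LA[3]))
  expect_equal(diag(d), setNames(rep(0, 4), traits$species))
})

test_that("multivariate PCA distances equal Euclidean distances on z-scores", {
  z <- standardize_traits(tiny_traits())
  chem <- trait_groups()$chemical
  d_pca <- trait_distance_matrix(z, chem)
  d_raw <- as.matrix(dist(as.matrix(z[, chem])))
  dimnames(d_raw) <- dimnames(d_pca)
  expect_equal(d_pca, d_raw, tolerance = 1e-10)
})

test_that("species with identical trait values are at distance zero and
           incomplete species are excluded", {
  traits <- tiny_traits()
  traits$C[2] <- traits$C[1]
  traits$CN[2] <- traits$CN[1]
  traits$CP[2] <- traits$CP[1]
  traits$PHEN[2] <- traits$PHEN[1]
  z <- standardize_traits(traits)
  d <- trait_distance_matrix(z, trait_groups()$chemical)
  expect_equal(d["alpha", "beta"], 0)
  # delta has missing LDMC, so it drops out of morphological distances
  d_m <- trait_distance_matrix(z, trait_groups()$morphological)
  expect_false("delta" %in% rownames(d_m))
})

test_that("cophenetic distances are path-length sums", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_phylogeny(path)
  d <- cophenetic_distances(tree)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  # any ultrametric tree: distances bounded by twice the depth
  tree2 <- simulate_phylogeny(30, seed = 11)
  expect_lte(max(cophenetic_distances(tree2)), 2 + 1e-9)
})

test_that("CWM is the renormalized abundance-weighted trait mean", {
  comm <- counts_to_comm(c(alpha = 1, beta = 3), c(alpha = 5, gamma = 5))
  traits <- tiny_traits()
  traits$LA <- c(0, 4, 2, 1)
  expect_equal(cwm("p1", comm, traits, "LA"), 0.25 * 0 + 0.75 * 4)
  # constant trait gives the constant in every plot
  traits$SLA <- rep(7, 4)
  expect_equal(cwm("p1", comm, traits, "SLA"), 7)
  expect_equal(cwm("p2", comm, traits, "SLA"), 7)
  # a missing-trait species behaves like deleting it and renormalizing
  comm3 <- counts_to_comm(c(alpha = 95, beta = 0, gamma = 0, delta = 5))
  expect_equal(cwm("p1", comm3, traits, "LDMC"),
               cwm("p1", counts_to_comm(c(alpha = 95)), traits, "LDMC"))
  traits$LDMC <- rep(NA_real_, 4)
  expect_error(cwm("p1", comm, traits, "LDMC"), class = "herbdiv_validation")
})

test_that("Rao's Q matches hand computation and is 0 for monocultures", {
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  comm <- counts_to_comm(c(a = 5, b = 5), c(a = 7))
  expect_equal(rao_q("p1", comm, d), 2)
  expect_equal(rao_q("p2", comm, d), 0)
})

test_that("Rao's Q equals the individual-pair enumeration oracle", {
  set.seed(401)
  d <- rand_dist(12)
  for (i in 1:50) {
    counts <- rand_counts(d)
    comm <- counts_to_comm(counts)
    expect_equal(rao_q("p1", comm, d), oracle_rao_q(counts, d),
                 tolerance = 1e-9)
  }
})

test_that("Q is invariant to count scaling and to splitting a species into
           two identical halves", {
  set.seed(402)
  d <- rand_dist(8)
  counts <- setNames(c(4, 6, 2), c("s1", "s2", "s3"))
  comm <- counts_to_comm(counts)
  comm10 <- counts_to_comm(counts * 10)
  expect_equal(rao_q("p1", comm, d), rao_q("p1", comm10, d), tolerance = 1e-12)
  # duplicate s2 as a new species at distance 0, abundance split in half
  d2 <- rbind(cbind(d, s2b = d[, "s2"]), s2b = c(d["s2", ], 0))
  counts2 <- setNames(c(4, 3, 3, 2), c("s1", "s2", "s2b", "s3"))
  expect_equal(rao_q("p1", counts_to_comm(counts2), d2),
               rao_q("p1", comm, d), tolerance = 1e-12)
})

test_that("Q^spec matches the focal x non-focal enumeration oracle", {
  set.seed(403)
  d <- rand_dist(10)
  for (i in 1:50) {
    counts <- rand_counts(d, k = sample(2:8, 1))
    focal <- sample(names(counts), 1)
    comm <- counts_to_comm(counts)
    expect_equal(rao_q_specific(focal, "p1", comm, d),
                 oracle_qspec(counts, focal, d), tolerance = 1e-9)
    expect_equal(rao_q_specific(focal, "p1", comm, d, include_conspecifics = TRUE),
                 oracle_qspec(counts, focal, d, include_conspecifics = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("Q^spec handles the degenerate and constant-distance cases", {
  d <- rand_dist(4)
  comm <- counts_to_comm(c(s1 = 3))
  expect_error(rao_q_specific("s1", "p1", comm, d), class = "herbdiv_validation")
  comm2 <- counts_to_comm(c(s1 = 3, s2 = 9))
  expect_equal(rao_q_specific("s1", "p1", comm2, d), d["s1", "s2"])
  # all non-focal distances equal to c return exactly c
  dc <- matrix(3, 4, 4, dimnames = dimnames(d))
  diag(dc) <- 0
  comm3 <- counts_to_comm(c(s1 = 2, s2 = 5, s3 = 1, s4 = 7))
  expect_equal(rao_q_specific("s2", "p1", comm3, dc), 3)
  expect_error(rao_q_specific("s4", "p1", comm2, d), class = "herbdiv_validation")
})

test_that("compute_all_metrics assembles the full table with expected shape", {
  study <- simulate_study(small_config(seed = 5))
  metrics <- compute_all_metrics(study$communities, study$traits,
                                 study$phylogeny, study$focal_species)
  expect_equal(nrow(metrics$plot), 8)
  expect_equal(nrow(metrics$focal), 8 * 5)
  expect_true(all(c("richness", "Q_chem", "Q_morph", "Q_phylo",
                    paste0("CWM_", trait_names()),
                    paste0("Q_", trait_names())) %in% names(metrics$plot)))
  expect_true(all(c("Qspec_phylo", "Qspec_chem", "Qspec_morph",
                    paste0("Qspec_", trait_names())) %in% names(metrics$focal)))
  expect_false("Q_all" %in% names(metrics$plot))
  q_all <- compute_all_metrics(study$communities, study$traits,
                               study$phylogeny, study$focal_species,
                               include_overall_q = TRUE)
  expect_true(all(c("Q_all", "Qspec_all") %in%
                    c(names(q_all$plot), names(q_all$focal))))
  # all Q non-negative; CWM within the pooled trait range
  expect_true(all(as.matrix(metrics$plot[, grepl("^Q_", names(metrics$plot))]) >= 0))
  expect_true(all(metrics$plot$CWM_C >= min(study$traits$C, na.rm = TRUE) &
                    metrics$plot$CWM_C <= max(study$traits$C, na.rm = TRUE)))
  # identical composition gives identical metric rows
  comm2 <- study$communities
  comm2[2, -1] <- comm2[1, -1]
  m2 <- compute_all_metrics(comm2, study$traits, study$phylogeny,
                            study$focal_species)
  expect_equal(unname(unlist(m2$plot[2, -1])), unname(unlist(m2$plot[1, -1])))
  long <- tidy(metrics)
  expect_true(all(c("plot", "focal_species", "metric", "value") %in% names(long)))
})

test_that("abundance species missing from the phylogeny are a hard error", {
  study <- simulate_study(small_config(seed = 5))
  extra <- study$communities
  extra$ghost_species <- 1L
  expect_error(
    compute_all_metrics(extra, study$traits, study$phylogeny, study$focal_species),
    "ghost", class = "herbdiv_validation"
  )
})
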