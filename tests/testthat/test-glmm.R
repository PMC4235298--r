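test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  expect_equal(aicc(-5, 0, 10), 10)
  expect_lt(abs(aicc(-100, 5, 1e6) - (2 * 100 + 2 * 5)), 1e-4)
  expect_error(aicc(-5, 9, 10), class = "herbdiv_domain")
})

test_that("intercept-only fit with variances pinned at 0 recovers logit(0.5)", {
  data <- tibble::tibble(species = rep(c("a", "b"), 10),
                         plot = rep(c("p1", "p2"), each = 10),
                         obs = paste0("o", 1:20), y = 0.5, w = 10)
  fit <- fit_binomial_glmm(data, fixed_sigma = c(species = 0, plot = 0, obs = 0))
  expect_equal(fit$coefficients$estimate, 0, tolerance = 1e-6)
  expect_equal(fit$aicc, aicc(fit$logLik, fit$k, fit$n), tolerance = 1e-12)
  expect_equal(fit$k, 1)
})

test_that("the no-random-effect limit matches the IRLS GLM oracle", {
  set.seed(61)
  for (i in 1:3) {
    data <- sim_glmm_data(300, beta = c(x1 = 0.5, x2 = -0.3),
                          sigma_species = 0, sigma_plot = 0, sigma_obs = 0)
    fit <- fit_binomial_glmm(data, c("x1", "x2"),
                             fixed_sigma = c(species = 0, plot = 0, obs = 0))
    oracle <- glm(y ~ x1 + x2, family = quasibinomial(), data = data, weights = w)
    expect_equal(fit$coefficients$estimate, unname(coef(oracle)),
                 tolerance = 1e-3)
    se_oracle <- summary(oracle, dispersion = 1)$coefficients[, 2]
    expect_equal(fit$coefficients$std.error, unname(se_oracle), tolerance = 1e-3)
  }
})

test_that("the Laplace fit agrees with an independent glmer cross-check", {
  skip_if_not_installed("lme4")
  set.seed(62)
  data <- sim_glmm_data(600, beta = c(x1 = 0.4, x2 = -0.2),
                        sigma_species = 0.4, sigma_plot = 0.3, sigma_obs = 0.3)
  fit <- fit_binomial_glmm(data, c("x1", "x2"))
  gm <- suppressWarnings(lme4::glmer(
    y ~ x1 + x2 + (1 | species) + (1 | plot) + (1 | obs),
    data = data, family = stats::binomial(), weights = w
  ))
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(gm)),
               tolerance = 0.02)
  sds <- sqrt(c(lme4::VarCorr(gm)$species[1], lme4::VarCorr(gm)$plot[1],
                lme4::VarCorr(gm)$obs[1]))
  expect_equal(unname(fit$sigma), sds, tolerance = 0.05)
})

test_that("fits are invariant to row order", {
  set.seed(63)
  data <- sim_glmm_data(250, beta = c(x1 = 0.5), sigma_obs = 0.2)
  fit1 <- fit_binomial_glmm(data, "x1")
  fit2 <- fit_binomial_glmm(data[sample(nrow(data)), ], "x1")
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-6)
})

test_that("boundary variance components are flagged and reported as zero", {
  set.seed(64)
  data <- sim_glmm_data(400, beta = c(x1 = 0.5),
                        sigma_species = 0, sigma_plot = 0, sigma_obs = 0)
  fit <- fit_binomial_glmm(data, "x1")
  expect_true(any(fit$boundary))
  expect_true(all(fit$sigma[fit$boundary] == 0))
})

test_that("tidy/glance expose the coefficient table and model summaries", {
  set.seed(65)
  data <- sim_glmm_data(200, beta = c(x1 = 0.5), sigma_obs = 0.2)
  fit <- fit_binomial_glmm(data, "x1")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_equal(td$p.value, 2 * pnorm(-abs(td$statistic)))
  gl <- glance(fit)
  expect_equal(gl$AICc, aicc(gl$logLik, gl$k, gl$nobs))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("backward selection returns an already-minimal model unchanged and
           a strictly decreasing AICc trace", {
  set.seed(66)
  data <- sim_glmm_data(400, beta = c(x1 = 0.8, x2 = -0.6),
                        sigma_species = 0.2, sigma_plot = 0.2, sigma_obs = 0.2)
  sel <- backward_select(data, c("x1", "x2"))
  expect_setequal(sel$predictors, c("x1", "x2"))
  expect_equal(nrow(sel$trace), 1)
  data$noise <- rnorm(nrow(data))
  sel2 <- backward_select(data, c("x1", "x2", "noise"))
  expect_true(all(diff(sel2$trace$aicc) < 0))
})

test_that("interaction terms are deleted before their main effects", {
  set.seed(67)
  data <- sim_glmm_data(400, beta = c(x1 = 0.8, x2 = 0.5),
                        sigma_species = 0.2, sigma_plot = 0.2, sigma_obs = 0.2)
  data$x1_x_x2 <- (data$x1 * data$x2 - mean(data$x1 * data$x2)) /
    sd(data$x1 * data$x2)
  sel <- backward_select(data, c("x1", "x2", "x1_x_x2"))
  trace <- sel$trace$dropped[-1]
  if ("x1" %in% trace || "x2" %in% trace) {
    main_step <- min(match(c("x1", "x2"), trace), na.rm = TRUE)
    expect_lt(match("x1_x_x2", trace), main_step)
  }
  expect_true(all(diff(sel$trace$aicc) < 0))
})

test_that("per-species regression matches the GLM oracle and rejects
           degenerate subsets", {
  set.seed(68)
  data <- sim_glmm_data(300, beta = c(x1 = 0.6),
                        sigma_species = 0, sigma_plot = 0, sigma_obs = 0)
  out <- per_species_regression(data, "sp1", "x1")
  sub <- data[data$species == "sp1", ]
  oracle <- glm(y ~ x1, family = quasibinomial(), data = sub, weights = w)
  expect_equal(out$slope, unname(coef(oracle)["x1"]), tolerance = 1e-6)
  sub_const <- dplyr::mutate(data, x1 = 1.5)
  expect_error(per_species_regression(sub_const, "sp1", "x1"),
               class = "herbdiv_zero_variance")
  tiny <- data[data$species == "sp1", ][1:2, ]
  expect_error(per_species_regression(tiny, "sp1", "x1"),
               class = "herbdiv_validation")
})

test_that("partial residuals recover the fitted slope and reduce to working
           residuals for a null predictor", {
  set.seed(69)
  # centred success probability and a modest effect keep the IRLS weights
  # nearly flat in x, so the ordinary-regression check is sharp
  data <- sim_glmm_data(2000, beta = c(x1 = 0.2, x2 = 0),
                        intercept = 0, w_range = c(40, 40),
                        sigma_species = 0, sigma_plot = 0, sigma_obs = 0)
  fit <- fit_binomial_glmm(data, c("x1", "x2"),
                           fixed_sigma = c(species = 0, plot = 0, obs = 0))
  pr <- partial_residuals(fit, "x1")
  expect_equal(nrow(pr), nrow(data))
  slope <- coef(lm(partial_residual ~ x, data = pr))["x"]
  beta1 <- fit$coefficients$estimate[fit$coefficients$term == "x1"]
  expect_lt(abs(unname(slope) - beta1), 1e-2)
  # for beta exactly 0 the partial residual equals the working residual
  fit2 <- fit
  fit2$coefficients$estimate[fit2$coefficients$term == "x2"] <- 0
  pr2 <- partial_residuals(fit2, "x2")
  wres <- (fit$y - fit$fitted) / (fit$fitted * (1 - fit$fitted))
  expect_equal(pr2$partial_residual, wres)
  expect_error(partial_residuals(fit, "nope"), class = "herbdiv_argument")
})
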